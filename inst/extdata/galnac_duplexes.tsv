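duplex_id	target	passenger_5to3	guide_3to5
D1	Hao1	gsasauguGfaaAfGfucaucgacaaL96	gsuscuuacAfcUfuucaGfUfaGfcugsUfsu
D2	Hao1	gsasauguGfaaAfGfucaucgacaaL96	gsuscuuacAfcUfuucaGfUfaGf(Cgn)ugsUfsu
D3	Hao1	gsasauguGfaaAfGfucaucgacaaL96	gsuscuuacAfcUfuucaGfUfaGf(iCgn)ugsUfsu
D4	Ttr	asascaguGfuUfCfUfugcucuauaaL96	ususuugucAfcAfagaacgaGfauasUfsu
D5	Ttr	asascaguGfuUfCfUfugcucuauaaL96	ususuugucAfcAfagaacga(Ggn)auasUfsu
D6	Ttr	asascaguGfuUfCfUfugcucuauaaL96	ususuugucAfcAfagaacga(iGgn)auasUfsu
D7	F12	usgscuuuGfaGfCfCfucagcuucuaL96	uscsacgaaAfcUfcggagucgaagsAfsu
D8	F12	usgscuuuGfaGfCfCfucagcuucuaL96	uscsacgaaAfcUfcggagu(Cgn)gaagsAfsu
D9	F12	usgscuuuGfaGfCfCfucagcuucuaL96	uscsacgaaAfcUfcggagu(iCgn)gaagsAfsu
D10	Ttr	ususcuugCfuCfUfAfuaaaccguguL96	ascsaagaaCfgAfgauauuuggcasCfsa
D11	Ttr	ususcuugCfuCfUfAfuaaaccguguL96	ascsaagaaCfgAfgauauuug(Ggn)casCfsa
D12	Ttr	ususcuugCfuCfUfAfuaaaccguguL96	ascsaagaaCfgAfgauauuug(iGgn)casCfsa
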