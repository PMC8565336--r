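## Shared fixtures: the bundled duplex transcriptions, parsed once.
fixture_duplexes <- galnac_duplexes()
fixture_tm <- galnac_duplex_tm()

## A small deterministic simulation shared by several files.
small_sim <- local({
  cfg <- sim_config(seed = 11L, n_transcripts = 400L)
  generate_utr_set(cfg, guide_seed(fixture_duplexes$D1$guide))
})
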