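test_that("dialect parsing assigns chemistry and linkages token by token", {
  s <- parse_strand("asuscug")
  expect_equal(strand_length(s), 5L)
  expect_true(all(s$residues$chemistry == "2'-OMe"))
  expect_equal(s$linkages, c("PS", "PS", "PO", "PO"))

  s2 <- parse_strand("aAf(Cgn)u")
  expect_equal(s2$residues$base, c("A", "A", "C", "U"))
  expect_equal(s2$residues$chemistry, c("2'-OMe", "2'-F", "GNA", "2'-OMe"))
  expect_true(all(s2$linkages == "PO"))

  g2 <- fixture_duplexes$D2$guide
  expect_equal(strand_length(g2), 23L)
  expect_equal(sum(g2$linkages == "PS"), 4L)
  expect_equal(sum(g2$residues$chemistry == "GNA"), 1L)
  expect_equal(g2$residues$base[g2$residues$chemistry == "GNA"], "C")
})

test_that("parse errors name the offending position", {
  expect_error(parse_strand("acxg"), "position 3")
  expect_error(parse_strand("sacg"), "strand start")
  expect_error(parse_strand("acgs"), "strand end")
  expect_error(parse_strand("ac(Xgn)u"), "unknown token")
  expect_error(parse_strand(""), "empty")
  expect_error(parse_strand("a(Cgn"), "unterminated")
})

test_that("serialize after parse is the identity on canonical strings", {
  ## all 24 bundled strands, in their source orientations
  for (d in fixture_duplexes) {
    expect_identical(strand_to_text(d$passenger), d$passenger$text)
    expect_identical(strand_to_text(d$guide), d$guide$text)
  }
  ## property over generated strands
  set.seed(42)
  for (i in 1:40) {
    txt <- random_strand_text()
    expect_identical(strand_to_text(parse_strand(txt)), txt)
  }
})

test_that("3'->5' source text is stored 5'->3'", {
  g <- parse_strand("acg", orientation = "3'->5'")
  expect_equal(g$residues$base, c("G", "C", "A"))
  expect_identical(strand_to_text(g), "acg")
  expect_identical(strand_to_text(g, orientation = "5'->3'"), "gca")
  ## PS linkages follow their residues through the flip
  g2 <- parse_strand("ascg", orientation = "3'->5'")
  expect_equal(g2$linkages, c("PO", "PS"))
})

test_that("residue invariants reject impossible chemistry combinations", {
  bad <- parse_strand("au")
  bad$residues$base[1] <- "isoC"
  expect_error(seedshift:::validate_strand(bad), "isoC")
  bad2 <- parse_strand("au")
  bad2$residues$base[1] <- "T"
  expect_error(seedshift:::validate_strand(bad2), "T requires")
})

test_that("GNA positions are reported 1-based from the guide 5' end", {
  pos <- function(d) locate_modification(fixture_duplexes[[d]]$guide)
  expect_equal(pos("D1"), integer(0))
  expect_equal(pos("D2"), 5L)
  expect_equal(pos("D5"), 6L)
  expect_equal(pos("D8"), 7L)
  ## isonucleotide swap preserves the position within each sibling pair
  for (pair in list(c("D2", "D3"), c("D5", "D6"),
                    c("D8", "D9"), c("D11", "D12")))
    expect_identical(pos(pair[1]), pos(pair[2]))
})

test_that("guide seeds and degenerate windows follow g-position numbering", {
  expect_equal(guide_seed(fixture_duplexes$D4$guide), "UAUAGAG")
  expect_equal(guide_seed(fixture_duplexes$D1$guide), "UGUCGAU")
  expect_equal(nchar(guide_seed(fixture_duplexes$D1$guide, 2, 2)), 1L)
  expect_error(guide_seed(parse_strand("acg"), 2, 8), "too short")
})

test_that("site derivation obeys the mer8/mer7m8/mer7A1 arithmetic", {
  st <- seed_sites("UAUAGAG")
  expect_equal(st[["mer7m8"]], "CUCUAUA")
  expect_equal(st[["mer8"]], "CUCUAUAA")
  expect_equal(st[["mer7A1"]], "UCUAUAA")
  expect_equal(seed_sites("UGUCGAU")[["mer8"]], "AUCGACAA")
  expect_equal(seed_sites("AAAAAAA")[["mer7m8"]], "UUUUUUU")
  expect_equal(seed_sites("AAAAAAA")[["mer8"]], "UUUUUUUA")
  expect_error(seed_sites("ACGU"), "7-mer")
  ## structural invariants for random seeds
  set.seed(7)
  for (i in 1:20) {
    seed <- paste(sample(c("A", "C", "G", "U"), 7, TRUE), collapse = "")
    st <- seed_sites(seed)
    expect_identical(substr(st[["mer8"]], 2, 8), st[["mer7A1"]])
    expect_identical(substr(st[["mer8"]], 1, 7), st[["mer7m8"]])
  }
})

test_that("guide-derived sites are self-consistent with printed passengers", {
  ## The mer8 site of the guide seed occurs verbatim in the passenger
  ## for D1-D9. For the D10 family the printed passenger carries U, not
  ## A, opposite g1 (g1 = a): the on-target site is a mer7m8, so only
  ## the mer7m8 core is present.
  for (d in paste0("D", 1:9)) {
    dup <- fixture_duplexes[[d]]
    st <- seed_sites(guide_seed(dup$guide))
    expect_true(grepl(st[["mer8"]], strand_bases(dup$passenger), fixed = TRUE),
                info = d)
  }
  for (d in paste0("D", 10:12)) {
    dup <- fixture_duplexes[[d]]
    st <- seed_sites(guide_seed(dup$guide))
    pass <- strand_bases(dup$passenger)
    expect_true(grepl(st[["mer7m8"]], pass, fixed = TRUE), info = d)
    expect_false(grepl(st[["mer8"]], pass, fixed = TRUE), info = d)
  }
})

test_that("duplex construction checks complementarity with a warning only", {
  d <- fixture_duplexes$D1
  expect_lt(d$mismatch_fraction, 0.2)
  expect_warning(
    duplex(parse_strand("aaaaaaaaaa"), parse_strand("cccccccccc"), "bad"),
    "mismatches")
})
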