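# Tiling, positional-scan and PTM-panel library construction.

test_that("tiling the 74-residue arrayed region gives the 60-probe library", {
  lib <- tileSequence(abetaRegionSequence(-23, 51), window = 15, step = 1,
                      abetaStart = -23)
  expect_identical(length(lib), 60L)
  expect_true(all(nchar(probes(lib)$sequence) == 15L))
})

test_that("tiling matches direct window enumeration and reconstructs the input", {
  seq <- abetaRegionSequence(1, 20)
  lib <- tileSequence(seq, window = 15, step = 1)
  expect_identical(length(lib), 6L)
  expect_identical(probes(lib)$sequence, bruteTiles(seq, 15, 1))
  # adjacent step-1 probes share window - 1 residues
  s <- probes(lib)$sequence
  for (k in seq_len(length(s) - 1))
    expect_identical(substr(s[k], 2, 15), substr(s[k + 1], 1, 14))
  # overlaying all tiles reproduces the input
  rec <- paste0(s[1], paste(substr(s[-1], 15, 15), collapse = ""))
  expect_identical(rec, seq)
  # degenerate case: window = length
  one <- tileSequence(seq, window = nchar(seq))
  expect_identical(probes(one)$sequence, seq)
  expect_error(tileSequence("DAEFR", window = 6), "exceeds")
})

test_that("a positional scan is complete, duplicate-free and Hamming-1", {
  scan18 <- positionalScan(abetaRegionSequence(1, 18), abetaStart = 1)
  pr <- probes(scan18)
  expect_identical(sum(pr$role == "substitution"), 342L) # 18 x 19
  expect_identical(sum(pr$role == "wildtype"), 1L)
  expect_false(anyDuplicated(pr$probe_id) > 0)
  # every (position, letter != wt) pair appears exactly once
  sub <- pr[pr$role == "substitution", ]
  expect_identical(nrow(unique(sub[, c("wt_position", "substitution")])),
                   342L)
  wt <- strsplit(scan18@wildtype, "")[[1L]]
  expect_true(all(sub$substitution != wt[sub$wt_position]))
  # Hamming distance 1 from wildtype, by construction and by check
  d <- vapply(seq_len(nrow(sub)), function(k) {
    s <- strsplit(sub$sequence[k], "")[[1L]]
    sum(s != wt)
  }, 0L)
  expect_true(all(d == 1L))
  # 15-mer: 15 x 19 = 285
  expect_identical(sum(probes(positionalScan(abetaRegionSequence(1, 15)))$role
                       == "substitution"), 285L)
  expect_error(positionalScan("DAEFR", alphabet = character(0)), "empty")
  expect_error(positionalScan(parsePeptide("DAEFRHDS[p]")), "unmodified")
})

test_that("scan probe ids carry provenance", {
  scan <- positionalScan("DAEFR", name = "ab1")
  pr <- probes(scan)
  row <- pr[pr$probe_id == "ab1_p03EK", ]
  expect_identical(row$wt_position, 3L)
  expect_identical(row$substitution, "K")
  expect_identical(row$sequence, "DAKFR")
})

test_that("PTM panels pair every variant with an identical-residue control", {
  pe <- ptmPanel(3, 17, "pE3")
  pr <- probes(pe)
  expect_identical(nrow(pr), 2L)
  expect_identical(pr$sequence[pr$role == "control"],
                   abetaRegionSequence(3, 17))
  expect_identical(pr$sequence[pr$role == "ptm-variant"],
                   paste0("E[pE]", abetaRegionSequence(4, 17)))
  iso <- ptmPanel(-1, 14, c("D-Asp1", "iso-Asp1"))
  pri <- probes(iso)
  ctrl <- pri$sequence[pri$role == "control"]
  for (s in pri$sequence[pri$role == "ptm-variant"]) {
    stripped <- gsub("\\[[a-z]+\\]", "", s)
    expect_identical(stripped, ctrl)
  }
})

test_that("the pSer8 panel probe exports with '2' at Abeta position 8", {
  pan <- ptmPanel(1, 15, "pSer8")
  v <- probes(pan)$sequence[probes(pan)$role == "ptm-variant"]
  digit <- writePeptide(parsePeptide(v), dialect = "array-digit")
  expect_identical(digit, "DAEFRHD2GYEVHHQ")
  expect_identical(substr(digit, 8, 8), "2")
})

test_that("incompatible PTM specs are rejected", {
  expect_error(ptmPanel(1, 15, "pSer26"), "outside")
  expect_error(ptmPanel(1, 15, "pE3"), "start at Abeta position 3")
  expect_error(ptmPanel(1, 15, "pFoo"), "unsupported")
})

test_that("probe libraries round-trip through CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  lib <- positionalScan(abetaRegionSequence(1, 18), abetaStart = 1)
  writeProbeLibrary(lib, tmp)
  got <- readProbeLibrary(tmp)
  expect_identical(probes(got), probes(lib))
  expect_identical(got@wildtype, lib@wildtype)
  expect_identical(got@abetaStart, lib@abetaStart)
})
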