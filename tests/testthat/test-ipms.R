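# Variant panel masses and MALDI peak assignment.

test_that("the default panel holds the ten-member mixture with unique names", {
  panel <- buildPanel()
  expect_identical(length(panel), 10L)
  expect_false(anyDuplicated(panelTable(panel)$name) > 0)
  expect_setequal(panelTable(panel)$name,
                  c("Abeta1-40", "Abeta1-42", "Abeta2-40", "Abeta3-40",
                    "AbetapE3-40", "Abeta4-40", "Abeta5-40", "Abeta11-40",
                    "Abeta(-3)-40", "pSer8-Abeta1-40-amide"))
  # masses are consistent with the peptide mass calculator
  tab <- panelTable(panel)
  for (k in seq_len(nrow(tab))) {
    expect_equal(tab$mono[k], peptideMass(panel@peptides[[k]]))
    expect_equal(tab$mh_avg[k],
                 peptideMass(panel@peptides[[k]], "average", "MH+"))
  }
})

test_that("panel mass relationships follow the modification deltas", {
  tab <- panelTable(buildPanel())
  m <- function(n) tab$mono[tab$name == n]
  expect_equal(m("Abeta3-40") - m("AbetapE3-40"), 18.0106, tolerance = 1e-4)
  # the phospho-amide member carries both +79.96633 and -0.984016
  expect_equal(m("pSer8-Abeta1-40-amide") - m("Abeta1-40"),
               79.96633 - 0.984016, tolerance = 1e-5)
  # truncation differences are the summed residue masses
  expect_equal(m("Abeta1-40") - m("Abeta2-40"), 115.02694, tolerance = 1e-4)
})

test_that("panel pI annotations track the charge-relevant modifications", {
  tab <- panelTable(buildPanel())
  pi <- function(n) tab$pi[tab$name == n]
  expect_equal(pi("Abeta1-40"), 5.31, tolerance = 0.01)
  expect_lt(pi("pSer8-Abeta1-40-amide"), pi("Abeta1-40")) # net acidification
  expect_gt(pi("Abeta2-40"), pi("Abeta1-40"))  # one acidic Asp removed
})

test_that("simulated ten-peak spectra are fully and correctly assigned", {
  panel <- buildPanel()
  sim <- simulateSpectrum(panel, weights = rep(1, 10), noiseSd = 0, seed = 5)
  asn <- assignPeaks(sim$spectrum, panel, tolerance = 1.0)
  hits <- asn$assignments[asn$assignments$variant != "unassigned", ]
  expect_setequal(hits$variant, panelTable(panel)$name)
  expect_identical(sum(asn$assignments$variant == "unassigned"), 0L)
  expect_true(all(abs(hits$error) <= 1.0))
})

test_that("jitter below tolerance/2 never misassigns", {
  panel <- buildPanel()
  for (s in 1:20) {
    sim <- simulateSpectrum(panel, weights = rep(1, 10), jitterSd = 0.2,
                            noiseSd = 0, seed = s)
    # cap the realized jitter at tolerance/2 by construction check
    if (max(abs(sim$truth$jitter)) >= 0.5) next
    asn <- assignPeaks(sim$spectrum, panel, tolerance = 1.0)
    hits <- asn$assignments[asn$assignments$variant != "unassigned", ]
    expect_setequal(hits$variant, panelTable(panel)$name)
  }
})

test_that("assignment respects tolerance and is permutation invariant", {
  panel <- buildPanel()
  ref <- panelTable(panel)$mh_avg
  spec <- data.frame(mz = c(ref[1] + 5, ref[2] + 0.3),
                     intensity = c(100, 100))
  asn <- assignPeaks(spec, panel, tolerance = 0.5, centroided = TRUE,
                     minSnr = 0)
  expect_identical(asn$assignments$variant,
                   c("unassigned", panelTable(panel)$name[2]))
  # shuffled peak order gives the same assignment set
  sim <- simulateSpectrum(panel, weights = rep(1, 10), seed = 9)
  sp <- sim$spectrum
  shuffled <- sp[sample(nrow(sp)), ]
  a1 <- assignPeaks(sp, panel)
  a2 <- assignPeaks(shuffled, panel)
  expect_identical(a1$assignments, a2$assignments)
  # shrinking the tolerance never assigns a previously unassigned peak
  aTight <- assignPeaks(sp, panel, tolerance = 0.2)
  un1 <- a1$assignments$mz[a1$assignments$variant == "unassigned"]
  expect_true(all(un1 %in%
    aTight$assignments$mz[aTight$assignments$variant == "unassigned"]))
})

test_that("weight rankings survive the spectrum round trip", {
  panel <- buildPanel()
  w <- c(10, 8, 6, 4, 2, 1, 3, 5, 7, 9) / 10
  sim <- simulateSpectrum(panel, weights = w, noiseSd = 0, seed = 3)
  asn <- assignPeaks(sim$spectrum, panel)
  expect_identical(order(asn$summary$rel_intensity), order(w))
  expect_equal(sum(asn$summary$rel_intensity), 1)
})

test_that("empty spectra give empty assignments", {
  panel <- buildPanel()
  out <- assignPeaks(data.frame(mz = numeric(), intensity = numeric()),
                     panel)
  expect_identical(nrow(out$assignments), 0L)
  expect_true(all(out$summary$rel_intensity == 0))
})

test_that("spectrum TSV and annotation JSON round trips", {
  panel <- buildPanel()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  sim <- simulateSpectrum(panel, seed = 2)
  writeSpectrumTsv(sim$spectrum, tmp)
  got <- readSpectrumTsv(tmp)
  expect_equal(got$mz, sim$spectrum$mz)
  js <- withr::local_tempfile(fileext = ".json")
  exportVariantAnnotations(panel, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(back$name, panelTable(panel)$name)
})
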