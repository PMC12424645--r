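# Wildtype normalization, dominant-negative and core-motif rules, variant
# impact, titration fitting and heatmap scaling.

# Small deterministic intensity table: 5-mer scan, two replicates, no noise.
makeToyDms <- function(wt = "DAEFR", wtLevel = 1000, effects = NULL) {
  lib <- positionalScan(wt, name = "toy", abetaStart = 1)
  pr <- probes(lib)
  eff <- rep(1, nrow(pr))
  if (!is.null(effects))
    for (k in seq_len(nrow(effects)))
      eff[pr$wt_position %in% effects$pos[k] &
            pr$substitution %in% effects$letter[k]] <- effects$r[k]
  tab <- data.frame(probe_id = rep(pr$probe_id, each = 2),
                    antibody = "ab", replicate = rep(1:2, nrow(pr)),
                    intensity = wtLevel * rep(eff, each = 2))
  list(table = tab, library = lib)
}

test_that("normalization divides replicate means by the wildtype mean", {
  toy <- makeToyDms(effects = data.frame(pos = 2, letter = "G", r = 0.4))
  m <- normalizeToWildtype(toy$table, toy$library, "ab")
  expect_equal(ratios(m)[2, "G"], 0.4)
  wt <- strsplit(m@wildtype, "")[[1L]]
  expect_identical(unname(ratios(m)[cbind(1:5, match(wt, colnames(ratios(m))))]),
                   rep(1, 5))
  expect_equal(m@wtMean, 1000)
})

test_that("replicates are aggregated by arithmetic mean and background subtracts", {
  toy <- makeToyDms()
  tab <- toy$table
  # unbalance one probe's replicates: mean(400, 800) / 1000 = 0.6
  id <- probes(toy$library)$probe_id[2]
  tab$intensity[tab$probe_id == id] <- c(400, 800)
  m <- normalizeToWildtype(tab, toy$library, "ab")
  pr <- probes(toy$library)
  expect_equal(ratios(m)[pr$wt_position[2], pr$substitution[2]], 0.6)
  # constant background shifts every mean down before normalization
  tab$background <- 100
  m2 <- normalizeToWildtype(tab, toy$library, "ab")
  expect_equal(ratios(m2)[pr$wt_position[2], pr$substitution[2]],
               (600 - 100) / 900)
})

test_that("a wildtype signal at or below the floor refuses the matrix", {
  toy <- makeToyDms()
  tab <- toy$table
  tab$intensity[tab$probe_id == "toy_wt"] <- 0
  expect_error(normalizeToWildtype(tab, toy$library, "ab"),
               "wildtype signal below floor")
})

test_that("normalization is invariant to rescaling one antibody's intensities", {
  truth <- dmsGroundTruth(seed = 11)
  sim <- simulateDmsArray(truth)
  m1 <- normalizeToWildtype(sim$table, sim$library, "synthetic")
  tab2 <- sim$table
  tab2$intensity <- tab2$intensity * 37.5
  m2 <- normalizeToWildtype(tab2, sim$library, "synthetic")
  expect_equal(ratios(m1), ratios(m2))
  expect_identical(motifString(callCoreMotif(m1)),
                   motifString(callCoreMotif(m2)))
})

test_that("dominant-negative calls follow the strict >50% reduction rule", {
  toy <- makeToyDms(effects = data.frame(pos = c(1, 1, 1),
                                         letter = c("G", "H", "K"),
                                         r = c(0.49, 0.50, 1.2)))
  m <- normalizeToWildtype(toy$table, toy$library, "ab")
  flags <- callDominantNegative(m)
  expect_true(flags[1, "G"])    # r = 0.49: reduced by more than half
  expect_false(flags[1, "H"])   # r = 0.50: boundary, not flagged
  expect_false(flags[1, "K"])   # gain of binding never flags
  wt <- strsplit(m@wildtype, "")[[1L]]
  expect_false(any(flags[cbind(seq_along(wt), match(wt, colnames(flags)))]))
})

test_that("core positions require >= 10 of 19 dominant-negative exchanges", {
  # position 2: exactly 10 letters knocked down; position 3: exactly 9
  toy <- makeToyDms(wt = "DAEFR",
                    effects = rbind(
                      data.frame(pos = 2, letter = setdiff(AbetaFingerprint:::AA20, "A")[1:10], r = 0.1),
                      data.frame(pos = 3, letter = setdiff(AbetaFingerprint:::AA20, "E")[1:9], r = 0.1)))
  m <- normalizeToWildtype(toy$table, toy$library, "ab")
  motif <- callCoreMotif(m)
  expect_identical(motif@counts, c(0L, 10L, 9L, 0L, 0L))
  expect_identical(corePositions(motif), 2L)
  expect_identical(motifString(motif), "XAXXX")
  # the threshold is a knob: at minCount 9 position 3 joins the core
  expect_identical(corePositions(callCoreMotif(m, minCount = 9)), 2:3)
})

test_that("motif caller agrees with the brute-force oracle on random matrices", {
  for (s in 1:1000) {
    m <- randomDms(len = sample(3:8, 1), seed = s)
    got <- callCoreMotif(m)
    want <- bruteCoreMotif(ratios(m), m@wildtype)
    expect_identical(motifString(got), want$motif)
    expect_identical(got@counts, want$counts)
  }
})

test_that("flags and core sets respond monotonically to ratio decreases", {
  m <- randomDms(len = 6, seed = 99)
  f1 <- callDominantNegative(m)
  m2 <- m
  m2@ratios <- m@ratios * 0.8
  wt <- strsplit(m@wildtype, "")[[1L]]
  m2@ratios[cbind(seq_along(wt), match(wt, colnames(m2@ratios)))] <- 1
  f2 <- callDominantNegative(m2)
  expect_true(all(f2[f1])) # decreasing r never removes a flag
  # core sets grow as the count threshold decreases
  cores <- lapply(12:6, function(k) corePositions(callCoreMotif(m, minCount = k)))
  for (i in seq_len(length(cores) - 1))
    expect_true(all(cores[[i]] %in% cores[[i + 1]]))
})

test_that("variant impact classifies fAD and rodent exchanges by the rule", {
  lib18 <- positionalScan(abetaRegionSequence(1, 18), abetaStart = 1)
  truth <- dmsGroundTruth(seed = 3)
  sim <- simulateDmsArray(truth)
  m <- normalizeToWildtype(sim$table, sim$library, "synthetic")
  # overwrite targeted cells for exact rule checks
  m@ratios[6, "R"] <- 0.05  # H6R abolishes binding
  m@ratios[5, "G"] <- 0.9   # R5G tolerated
  rep <- variantImpactReport(m, c("H6R", "R5G", "V18A"))
  expect_identical(rep$class, c("binding-reducing", "tolerated", "tolerated"))
  rep2 <- variantImpactReport(m, "V40A")
  expect_identical(rep2$class, "not covered") # position 40 beyond an 18-mer scan
  full <- variantImpactReport(m)
  expect_setequal(full$variant, c(fADVariants(), rodentVariants()))
  expect_true(all(full$position %in% m@positions))
})

test_that("Boltzmann fits recover a planted EC50 and flag flat series", {
  grid <- 10^seq(-11, -7, length.out = 9)
  ser <- simulateTitration(grid, ec50 = 3e-9, slope = 0.4)
  fit <- fitTitration(ser$concentration, ser$response)
  expect_true(fit@converged)
  expect_equal(ec50(fit), 3e-9, tolerance = 0.01)
  # at x = x50 the curve passes through (top + bottom)/2
  mid <- fit@bottom + (fit@top - fit@bottom) / 2
  pred <- fit@bottom + (fit@top - fit@bottom) /
    (1 + exp((fit@x50 - fit@x50) / fit@slope))
  expect_equal(pred, mid)
  flat <- fitTitration(grid, rep(0.7, 9))
  expect_true(flat@noTransition)
  expect_true(is.na(ec50(flat)))
  expect_error(fitTitration(grid[1:4], ser$response[1:4]), "at least 5")
  expect_error(fitTitration(c(1, 1.2, 1.4, 1.6, 1.8), rnorm(5)), "decade")
})

test_that("selectivity ratio compares two converged titrations", {
  grid <- 10^seq(-11, -7, length.out = 9)
  a <- fitTitration(grid, simulateTitration(grid, ec50 = 1e-8)$response)
  b <- fitTitration(grid, simulateTitration(grid, ec50 = 1e-9)$response)
  expect_equal(selectivityRatio(a, b), 10, tolerance = 0.02)
  flat <- fitTitration(grid, rep(1, 9))
  expect_true(is.na(selectivityRatio(a, flat)))
})

test_that("heatmap scaling is per-antibody min-max and scale invariant", {
  m <- cbind(ab1 = c(0, 50, 100), ab2 = c(10, 10, 30))
  h <- heatmapMatrix(m)
  expect_equal(unname(h[, "ab1"]), c(0, 0.5, 1))
  expect_equal(unname(h[, "ab2"]), c(0, 0, 1))
  expect_equal(heatmapMatrix(m * 1000), h) # scale invariance
  expect_warning(h2 <- heatmapMatrix(cbind(flat = c(5, 5, 5))),
                 "flat profile")
  expect_identical(unname(h2[, 1]), c(0, 0, 0))
})
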