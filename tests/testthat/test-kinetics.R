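# 1:1 Langmuir simulation and fitting.

presetSet <- function(p, concs = c(2, 4, 8, 16, 32) * 1e-9, noiseSd = 0,
                      seeds = NULL) {
  lapply(seq_along(concs), function(i)
    simulateSensorgram(p, concs[i], noiseSd = noiseSd,
                       seed = if (is.null(seeds)) NULL else seeds[i]))
}

test_that("the closed-form sensorgram obeys the 1:1 model's limits", {
  p <- KineticParams(kon = 1e5, koff = 4.1e-4, rmax = 2)
  # at C = KD the association plateau is Rmax/2
  g <- simulateSensorgram(p, conc = kd(p), tAssoc = 1e5, tDissoc = 10)
  plateau <- max(g@response)
  expect_equal(plateau, p@rmax / 2, tolerance = 1e-6)
  # response is continuous at the phase boundary
  g2 <- simulateSensorgram(p, 8e-9)
  i <- max(which(g2@phase == "association"))
  expect_lt(abs(g2@response[i + 1] - g2@response[i]), 1e-3 * p@rmax)
  # doubling kon and koff keeps the plateau, halves the time constant
  p2 <- KineticParams(kon = 2e5, koff = 8.2e-4, rmax = 2)
  ga <- simulateSensorgram(p, 8e-9, tAssoc = 1e5, tDissoc = 10)
  gb <- simulateSensorgram(p2, 8e-9, tAssoc = 1e5, tDissoc = 10)
  expect_equal(max(ga@response), max(gb@response), tolerance = 1e-6)
  t63a <- ga@time[which(ga@response >= (1 - exp(-1)) * max(ga@response))[1]]
  t63b <- gb@time[which(gb@response >= (1 - exp(-1)) * max(gb@response))[1]]
  expect_equal(t63a / t63b, 2, tolerance = 0.05)
  expect_error(simulateSensorgram(p, -1e-9), "positive")
})

test_that("Req is increasing, concave and bounded by Rmax", {
  p <- kineticPreset("phospho-high-affinity")
  C <- seq(1e-10, 1e-6, length.out = 50)
  req <- p@rmax * C / (C + kd(p))
  expect_true(all(diff(req) > 0))
  expect_true(all(diff(diff(req)) < 0))
  expect_true(all(req < p@rmax))
})

test_that("global fit recovers kon and koff from noiseless 5-concentration sets", {
  for (preset in c("phospho-high-affinity", "unmodified-weak")) {
    p <- kineticPreset(preset)
    concs <- kd(p) * c(0.25, 0.5, 1, 2, 4)
    fit <- globalFit1to1(presetSet(p, concs))
    expect_true(fit$converged)
    expect_equal(fit$params@kon, p@kon, tolerance = 0.01)
    expect_equal(fit$params@koff, p@koff, tolerance = 0.01)
    # KD equals koff/kon exactly, and the noiseless residual is negligible
    expect_identical(fit$kd, fit$params@koff / fit$params@kon)
    tot <- sum(unlist(lapply(presetSet(p, concs), function(g) g@response^2)))
    expect_lt(fit$rss, 1e-6 * tot)
  }
})

test_that("a single concentration still fits but warns ill-conditioned", {
  p <- kineticPreset("phospho-moderate")
  expect_warning(fit <- globalFit1to1(presetSet(p, 5e-9)),
                 "ill-conditioned")
  expect_s4_class(fit$params, "KineticParams")
})

test_that("KD stays within 10% under 5% relative noise", {
  p <- kineticPreset("phospho-high-affinity")
  concs <- c(2, 4, 8, 16, 32) * 1e-9
  errs <- vapply(1:25, function(s) {
    grams <- presetSet(p, concs, noiseSd = 0.05 * p@rmax,
                       seeds = s * 10 + seq_along(concs))
    abs(globalFit1to1(grams)$kd - kd(p)) / kd(p)
  }, 0)
  expect_lt(max(errs), 0.10)
})

test_that("steady-state fit recovers KD from exact Req points", {
  kdTrue <- 4.1e-9; rmaxTrue <- 1.5
  C <- c(0.5, 1, 2, 4, 8, 16, 64) * 1e-9
  fit <- steadyStateKd(C, rmaxTrue * C / (kdTrue + C))
  expect_equal(fit$kd, kdTrue, tolerance = 1e-3)
  expect_equal(fit$rmax, rmaxTrue, tolerance = 1e-3)
  # on the fitted curve, Req at C = KD is Rmax/2
  expect_equal(fit$rmax * fit$kd / (fit$kd + fit$kd), fit$rmax / 2)
})

test_that("degenerate steady-state data are rejected as unidentifiable", {
  C <- c(1, 2, 4, 8, 16) * 1e-9
  expect_error(steadyStateKd(C, rep(1, 5)), "unidentifiable")
  # linear-only: KD far above the sampled range
  expect_error(steadyStateKd(C, 1e6 * C), "unidentifiable")
  # saturated-only: KD far below the sampled range
  expect_error(steadyStateKd(C, 2 * C / (1e-13 + C)), "unidentifiable")
  expect_error(steadyStateKd(C[1:3], C[1:3]), "at least 4")
})

test_that("sensorgram CSV round trip preserves traces", {
  p <- kineticPreset("unmodified-moderate")
  grams <- presetSet(p, c(4, 8) * 1e-9)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeSensorgrams(grams, tmp)
  got <- readSensorgrams(tmp)
  expect_identical(length(got), 2L)
  ord <- order(vapply(got, function(g) g@concentration, 0))
  for (i in 1:2) {
    expect_equal(got[[ord[i]]]@response, grams[[i]]@response)
    expect_equal(got[[ord[i]]]@tAssoc, grams[[i]]@tAssoc)
  }
})
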