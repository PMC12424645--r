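# Seedable synthetic-data generators for every pipeline input, with
# ground-truth records, standing in for the study's raw array images.
# All generators are pure functions of (parameters, seed).

#' Ground truth for a synthetic deep-mutational-scan array
#'
#' Defines the planted structure of a synthetic DMS experiment: a wildtype
#' peptide, a planted core span whose substitutions carry a reduced effect
#' ratio, multiplicative log-normal noise, and a wildtype signal level.
#' Chemiluminescent array readouts are positive and right-skewed, hence
#' the multiplicative log-normal noise model. Effect ratios are 1 outside
#' the core span.
#'
#' @param wt wildtype sequence (default: the Abeta1-18 scan).
#' @param abetaStart Abeta coordinate of the wildtype's first residue.
#' @param corePositions Abeta coordinates of the planted core span
#'   (default 3..7, a five-position span).
#' @param coreEffect effect ratio in [0, 1] applied to every substitution
#'   at a core position.
#' @param sigma log-normal noise sigma (log scale).
#' @param wtLevel wildtype mean signal level (arbitrary units).
#' @param seed master seed recorded in the truth.
#' @return A list of class \code{dmsTruth} (also records the full
#'   per-(position, letter) effect matrix).
#' @export
dmsGroundTruth <- function(wt = abetaRegionSequence(1, 18), abetaStart = 1,
                           corePositions = 3:7, coreEffect = 0.1,
                           sigma = 0.2, wtLevel = 1000, seed = 1L) {
  if (sigma < 0) stop("noise sigma must be non-negative")
  if (coreEffect < 0 || coreEffect > 1)
    stop("core effect ratio must lie in [0, 1]")
  wtRes <- strsplit(wt, "")[[1L]]
  coords <- abetaCoords(as.integer(abetaStart), length(wtRes))
  if (!all(corePositions %in% coords))
    stop("core positions must lie within the scanned span")
  effect <- matrix(1, nrow = length(wtRes), ncol = length(AA20),
                   dimnames = list(coords, AA20))
  effect[match(corePositions, coords), ] <- coreEffect
  effect[cbind(seq_along(wtRes), match(wtRes, AA20))] <- 1
  structure(list(wt = wt, abetaStart = as.integer(abetaStart),
                 corePositions = as.integer(corePositions),
                 coreEffect = coreEffect, sigma = sigma, wtLevel = wtLevel,
                 effect = effect, seed = as.integer(seed)),
            class = "dmsTruth")
}

#' Simulate a deep-mutational-scan intensity table
#'
#' Builds the positional-scan library for the truth's wildtype and draws
#' per-replicate intensities
#' intensity = wtLevel x effect ratio x LogNormal(0, sigma); wildtype
#' probes use effect ratio 1. Fully reproducible from the seed.
#'
#' @param truth a \code{\link{dmsGroundTruth}} record.
#' @param replicates replicates per probe (>= 1).
#' @param antibody antibody id written into the table.
#' @param seed RNG seed (defaults to the truth's master seed).
#' @return List with \code{table} (intensity table), \code{library}
#'   (\linkS4class{ProbeLibrary}) and \code{truth}.
#' @examples
#' sim <- simulateDmsArray(dmsGroundTruth(seed = 7))
#' m <- normalizeToWildtype(sim$table, sim$library, "synthetic")
#' corePositions(callCoreMotif(m))
#' @export
simulateDmsArray <- function(truth, replicates = 3L, antibody = "synthetic",
                             seed = truth$seed) {
  stopifnot(inherits(truth, "dmsTruth"), replicates >= 1L)
  lib <- positionalScan(truth$wt, name = "sim", abetaStart = truth$abetaStart)
  pr <- probes(lib)
  eff <- vapply(seq_len(nrow(pr)), function(k) {
    if (pr$role[k] != "substitution") return(1)
    truth$effect[pr$wt_position[k], pr$substitution[k]]
  }, 0)
  n <- nrow(pr) * replicates
  noise <- withSeed(seed, stats::rlnorm(n, 0, truth$sigma))
  tab <- data.frame(
    probe_id = rep(pr$probe_id, each = replicates),
    antibody = antibody,
    replicate = rep(seq_len(replicates), times = nrow(pr)),
    intensity = truth$wtLevel * rep(eff, each = replicates) * noise,
    stringsAsFactors = FALSE)
  list(table = tab, library = lib, truth = truth)
}

#' Simulate a Boltzmann titration series
#'
#' Samples the sigmoid bottom + (top - bottom)/(1 + exp((x50 - x)/slope))
#' on x = log10(concentration) and adds Gaussian noise under the seed.
#'
#' @param grid positive, sorted concentration grid.
#' @param bottom,top plateau responses.
#' @param ec50 midpoint concentration (same units as the grid).
#' @param slope Boltzmann slope on the log10 axis.
#' @param noiseSd Gaussian noise SD (response units).
#' @param seed RNG seed.
#' @return data.frame(concentration, response).
#' @export
simulateTitration <- function(grid, bottom = 0, top = 1, ec50, slope = 0.4,
                              noiseSd = 0, seed = NULL) {
  if (!length(grid)) stop("empty concentration grid")
  if (any(grid <= 0) || is.unsorted(grid))
    stop("grid must be positive and sorted")
  x <- log10(grid)
  y <- bottom + (top - bottom) / (1 + exp((log10(ec50) - x) / slope))
  if (noiseSd > 0)
    y <- y + withSeed(seed, stats::rnorm(length(y), 0, noiseSd))
  data.frame(concentration = grid, response = y)
}

#' Simulate a MALDI-style spectrum over a variant panel
#'
#' Sums Gaussian peaks centered at the panel's [M+H]+ masses, scaled by
#' per-variant weights, over a regular m/z grid, plus a constant baseline
#' and Gaussian noise. Optional per-variant center jitter emulates
#' calibration error. Reproducible from the seed.
#'
#' @param panel a \linkS4class{VariantPanel}.
#' @param weights non-negative per-variant weights (recycled to the panel
#'   size; not all zero).
#' @param fwhm peak full width at half maximum (Da, > 0).
#' @param baseline constant baseline intensity.
#' @param noiseSd additive Gaussian noise SD.
#' @param jitterSd SD of the per-variant peak-center jitter (Da).
#' @param mzStep grid spacing (Da).
#' @param pad grid padding beyond the outermost peaks (Da).
#' @param massType mass scale for the peak centers.
#' @param seed RNG seed.
#' @return List with \code{spectrum} (data.frame mz, intensity) and
#'   \code{truth} (centers, weights, parameters).
#' @export
simulateSpectrum <- function(panel, weights = rep(1, length(panel)),
                             fwhm = 2, baseline = 5, noiseSd = 0,
                             jitterSd = 0, mzStep = 0.05, pad = 60,
                             massType = c("average", "monoisotopic"),
                             seed = NULL) {
  massType <- match.arg(massType)
  if (fwhm <= 0) stop("peak FWHM must be positive")
  weights <- rep_len(weights, length(panel))
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero")
  centers <- if (massType == "average") panelTable(panel)$mh_avg
             else panelTable(panel)$mh_mono
  out <- withSeed(seed, {
    jit <- if (jitterSd > 0) stats::rnorm(length(centers), 0, jitterSd)
           else rep(0, length(centers))
    mz <- seq(min(centers) - pad, max(centers) + pad, by = mzStep)
    s <- fwhm / (2 * sqrt(2 * log(2)))
    y <- rep(baseline, length(mz))
    for (k in seq_along(centers)) {
      if (weights[k] == 0) next
      y <- y + 100 * weights[k] *
        exp(-((mz - centers[k] - jit[k])^2) / (2 * s^2))
    }
    if (noiseSd > 0) y <- pmax(y + stats::rnorm(length(mz), 0, noiseSd), 0)
    list(mz = mz, y = y, jit = jit)
  })
  list(spectrum = data.frame(mz = out$mz, intensity = out$y),
       truth = list(centers = centers, jitter = out$jit, weights = weights,
                    fwhm = fwhm, baseline = baseline, noiseSd = noiseSd,
                    massType = massType, seed = seed))
}

#' Write a ground-truth record as a sidecar JSON
#'
#' @param truth a \code{dmsTruth} (the effect matrix is stored as planted
#'   core positions + core effect) or any truth list from the simulators.
#' @param path output path.
#' @export
writeGroundTruth <- function(truth, path) {
  if (inherits(truth, "dmsTruth"))
    truth <- truth[setdiff(names(truth), "effect")]
  writeStableJson(truth, path)
}
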