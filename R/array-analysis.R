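# From raw probe intensities to wildtype-normalized matrices,
# dominant-negative calls, core motifs, variant impact reports, titration
# EC50s and display-scaled heatmap matrices.

#' Validate an intensity table
#'
#' Intensity tables are long-format data.frames with columns
#' \code{probe_id}, \code{antibody}, \code{replicate}, \code{intensity}
#' and optionally \code{concentration} and \code{background}. Intensities
#' must be non-negative.
#'
#' @param table a data.frame.
#' @return The table, invisibly; errors describe the violation.
#' @export
validateIntensityTable <- function(table) {
  need <- c("probe_id", "antibody", "replicate", "intensity")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(sprintf("intensity table lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(!is.finite(table$intensity)) || any(table$intensity < 0))
    stop("intensities must be finite and non-negative")
  invisible(table)
}

#' Read an intensity table CSV
#'
#' @param path CSV with columns probe_id, antibody, replicate, intensity
#'   and optionally concentration, background.
#' @return A validated data.frame.
#' @export
readIntensityTable <- function(path) {
  validateIntensityTable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' DmsMatrix: wildtype-normalized deep-mutational-scan matrix
#'
#' Entries r[position, letter] are normalized binding ratios
#' (variant mean intensity / wildtype mean intensity). Wildtype cells are
#' exactly 1 by construction. Row names carry the scan's Abeta coordinates
#' when the library provides them.
#'
#' @slot antibody antibody id.
#' @slot wildtype canonical wildtype sequence.
#' @slot positions Abeta coordinates of the scanned positions.
#' @slot ratios numeric matrix, positions x substitution letters.
#' @slot wtMean wildtype mean intensity the matrix was normalized to.
#' @export
setClass("DmsMatrix",
  representation(antibody = "character", wildtype = "character",
                 positions = "integer", ratios = "matrix",
                 wtMean = "numeric"))

setValidity("DmsMatrix", function(object) {
  r <- object@ratios
  if (nrow(r) != nchar(object@wildtype))
    return("ratio matrix rows must match wildtype length")
  if (length(object@positions) != nrow(r))
    return("positions must match matrix rows")
  if (any(!is.finite(r)) || any(r < 0))
    return("ratios must be finite and non-negative")
  wt <- strsplit(object@wildtype, "")[[1L]]
  ok <- vapply(seq_len(nrow(r)), function(i) r[i, wt[i]] == 1, logical(1))
  if (!all(ok)) return("implied wildtype ratio must be exactly 1")
  TRUE
})

setMethod("show", "DmsMatrix", function(object) {
  cat(sprintf("DmsMatrix: %s on %s (%d positions, Abeta %d..%d), wt mean %.4g\n",
              object@antibody, object@wildtype, nrow(object@ratios),
              min(object@positions), max(object@positions), object@wtMean))
})

#' @describeIn DmsMatrix ratio matrix accessor
#' @param x a DmsMatrix
#' @export
ratios <- function(x) x@ratios

#' Normalize a scan's intensities against its wildtype probe
#'
#' Aggregates replicates by arithmetic mean of the raw intensities (an
#' optional \code{background} column is subtracted first, floored at 0) and
#' divides every substitution probe's mean by the wildtype probe's mean.
#' The wildtype mean must exceed a floor of \code{wtFloorFrac} times the
#' antibody's maximum probe mean, otherwise the matrix is refused rather
#' than producing unstable ratios.
#'
#' @param table intensity table (see \code{\link{validateIntensityTable}}).
#' @param library the \linkS4class{ProbeLibrary} from
#'   \code{\link{positionalScan}}.
#' @param antibody antibody id to extract.
#' @param wtFloorFrac wildtype floor as a fraction of the antibody's
#'   maximum probe mean.
#' @return A \linkS4class{DmsMatrix}.
#' @export
normalizeToWildtype <- function(table, library, antibody, wtFloorFrac = 0.01) {
  validateIntensityTable(table)
  pr <- probes(library)
  if (is.na(library@wildtype))
    stop("library has no wildtype scan")
  tab <- table[table$antibody == antibody, , drop = FALSE]
  if (!nrow(tab)) stop(sprintf("no rows for antibody '%s'", antibody))
  if ("concentration" %in% names(tab) &&
      length(unique(tab$concentration)) > 1L)
    stop("multiple concentrations present; subset the table to one")
  y <- tab$intensity
  if ("background" %in% names(tab))
    y <- pmax(y - tab$background, 0)
  means <- tapply(y, tab$probe_id, mean)
  wtId <- pr$probe_id[pr$role == "wildtype"]
  if (length(wtId) != 1L || !wtId %in% names(means))
    stop("wildtype probe missing from the table")
  wtMean <- means[[wtId]]
  if (wtMean <= wtFloorFrac * max(means))
    stop("wildtype signal below floor; matrix not computable")
  wt <- strsplit(library@wildtype, "")[[1L]]
  coords <- abetaCoords(library@abetaStart, length(wt))
  r <- matrix(NA_real_, nrow = length(wt), ncol = length(AA20),
              dimnames = list(coords, AA20))
  r[cbind(seq_along(wt), match(wt, AA20))] <- 1
  sub <- pr[pr$role == "substitution", , drop = FALSE]
  miss <- setdiff(sub$probe_id, names(means))
  if (length(miss))
    stop(sprintf("%d substitution probe(s) missing from the table", length(miss)))
  r[cbind(sub$wt_position, match(sub$substitution, AA20))] <-
    unname(means[sub$probe_id]) / wtMean
  if (anyNA(r)) stop("scan incomplete: matrix has unfilled cells")
  new("DmsMatrix", antibody = antibody, wildtype = library@wildtype,
      positions = coords, ratios = r, wtMean = unname(wtMean))
}

#' Dominant-negative calls
#'
#' An exchange is dominant negative when it reduces binding by more than
#' 50\%, i.e. r < threshold strictly: r = 0.49 is flagged, the boundary
#' r = 0.50 is not, and gains of binding (r > 1) never are. Wildtype cells
#' are never flagged.
#'
#' @param m a \linkS4class{DmsMatrix}.
#' @param threshold normalized-ratio threshold (default 0.5).
#' @return Logical matrix of the same shape as \code{ratios(m)}.
#' @export
callDominantNegative <- function(m, threshold = 0.5) {
  stopifnot(is(m, "DmsMatrix"), threshold > 0, threshold <= 1)
  flags <- m@ratios < threshold
  wt <- strsplit(m@wildtype, "")[[1L]]
  flags[cbind(seq_along(wt), match(wt, AA20))] <- FALSE
  flags
}

#' CoreMotif: core epitope positions of an antibody
#'
#' @slot antibody antibody id.
#' @slot positions Abeta coordinates of all scanned positions.
#' @slot core Abeta coordinates called as core.
#' @slot motif motif string: wildtype letter at core positions, 'X' at
#'   non-conserved positions; same length as the scan.
#' @slot counts per-position dominant-negative counts.
#' @slot minCount count threshold used.
#' @slot threshold ratio threshold used.
#' @export
setClass("CoreMotif",
  representation(antibody = "character", positions = "integer",
                 core = "integer", motif = "character", counts = "integer",
                 minCount = "integer", threshold = "numeric"))

setValidity("CoreMotif", function(object) {
  if (nchar(object@motif) != length(object@positions))
    return("motif length must equal scan length")
  if (!all(object@core %in% object@positions))
    return("core positions must be scanned positions")
  TRUE
})

setMethod("show", "CoreMotif", function(object) {
  cat(sprintf("CoreMotif: %s  %s  (core: %s)\n", object@antibody,
              object@motif,
              if (length(object@core)) paste(object@core, collapse = ",")
              else "none"))
})

#' @describeIn CoreMotif motif string accessor
#' @param x a CoreMotif
#' @export
motifString <- function(x) x@motif

#' @describeIn CoreMotif core Abeta positions accessor
#' @export
corePositions <- function(x) x@core

#' Call the core motif from a DMS matrix
#'
#' A position is a major contributor to the core motif when more than 50\%
#' of its 19 exchanges are dominant negative, i.e. its dominant-negative
#' count reaches \code{minCount} (default 10, the smallest integer
#' exceeding half of 19). The motif string shows the wildtype letter at
#' core positions and 'X' elsewhere.
#'
#' @param m a \linkS4class{DmsMatrix}.
#' @param minCount minimum dominant-negative count for a core position.
#' @param threshold dominant-negative ratio threshold.
#' @return A \linkS4class{CoreMotif}.
#' @export
callCoreMotif <- function(m, minCount = 10L, threshold = 0.5) {
  flags <- callDominantNegative(m, threshold)
  counts <- as.integer(rowSums(flags))
  core <- counts >= as.integer(minCount)
  wt <- strsplit(m@wildtype, "")[[1L]]
  new("CoreMotif", antibody = m@antibody, positions = m@positions,
      core = m@positions[core],
      motif = paste(ifelse(core, wt, "X"), collapse = ""),
      counts = counts, minCount = as.integer(minCount),
      threshold = threshold)
}

#' Built-in variant sets
#'
#' \code{fADVariants}: familial-AD amino-acid exchanges within Abeta
#' (A2V, A2T, H6R English, D7H Taiwan, D7N Tottori, K16Q, L17V).
#' \code{rodentVariants}: the human-to-rodent exchanges R5G and Y10F.
#'
#' @return Character vector of variants in \code{<wt><Abeta pos><sub>}
#'   notation.
#' @export
fADVariants <- function() c("A2V", "A2T", "H6R", "D7H", "D7N", "K16Q", "L17V")

#' @rdname fADVariants
#' @export
rodentVariants <- function() c("R5G", "Y10F")

#' Classify sequence variants against a DMS matrix
#'
#' Each variant (e.g. \code{"H6R"}; positions are Abeta coordinates) is
#' classified \code{binding-reducing} when its normalized ratio falls below
#' the dominant-negative threshold, \code{tolerated} otherwise, or
#' \code{not covered} when the position lies outside the scanned span.
#'
#' @param m a \linkS4class{DmsMatrix}.
#' @param variants character vector of variants; defaults to the built-in
#'   fAD and rodent sets.
#' @param threshold classification threshold on the normalized ratio.
#' @return data.frame with variant, position, wildtype and substituted
#'   letter, normalized ratio, and class.
#' @export
variantImpactReport <- function(m, variants = c(fADVariants(), rodentVariants()),
                                threshold = 0.5) {
  stopifnot(is(m, "DmsMatrix"))
  parsed <- regmatches(variants,
                       regexec("^([A-Z])(-?[0-9]+)([A-Z])$", variants))
  bad <- variants[vapply(parsed, length, 0L) != 4L]
  if (length(bad))
    stop(sprintf("cannot parse variant(s): %s", paste(bad, collapse = ", ")))
  wtSeq <- strsplit(m@wildtype, "")[[1L]]
  out <- lapply(parsed, function(v) {
    pos <- as.integer(v[3L]); wtL <- v[2L]; subL <- v[4L]
    i <- match(pos, m@positions)
    if (is.na(i))
      return(data.frame(variant = v[1L], position = pos, wildtype = wtL,
                        substitution = subL, ratio = NA_real_,
                        class = "not covered", stringsAsFactors = FALSE))
    if (wtSeq[i] != wtL)
      warning(sprintf("variant %s: scan wildtype at Abeta %d is %s, not %s",
                      v[1L], pos, wtSeq[i], wtL))
    r <- m@ratios[i, subL]
    data.frame(variant = v[1L], position = pos, wildtype = wtL,
               substitution = subL, ratio = r,
               class = if (r < threshold) "binding-reducing" else "tolerated",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## ---- titration (Boltzmann) fitting ---------------------------------------

#' DoseResponseFit: sigmoidal (Boltzmann) titration fit
#'
#' response = bottom + (top - bottom) / (1 + exp((x50 - x)/slope)) on
#' x = log10(concentration). EC50 = 10^x50.
#'
#' @slot bottom,top,x50,slope fitted parameters.
#' @slot ec50 10^x50 (concentration units of the input).
#' @slot r2 goodness of fit (1 - SSres/SStot).
#' @slot converged optimizer convergence flag.
#' @slot noTransition TRUE for flat series (no EC50 defined).
#' @export
setClass("DoseResponseFit",
  representation(bottom = "numeric", top = "numeric", x50 = "numeric",
                 slope = "numeric", ec50 = "numeric", r2 = "numeric",
                 converged = "logical", noTransition = "logical"))

setValidity("DoseResponseFit", function(object) {
  if (!object@noTransition && object@top < object@bottom)
    return("top must be >= bottom")
  TRUE
})

setMethod("show", "DoseResponseFit", function(object) {
  if (object@noTransition) {
    cat("DoseResponseFit: no transition (flat series)\n")
  } else {
    cat(sprintf(
      "DoseResponseFit: EC50 = %.4g, bottom = %.3g, top = %.3g, slope = %.3g, r2 = %.4f\n",
      object@ec50, object@bottom, object@top, object@slope, object@r2))
  }
})

#' @describeIn DoseResponseFit EC50 accessor (NA for flat series)
#' @param x a DoseResponseFit
#' @export
ec50 <- function(x) if (x@noTransition) NA_real_ else x@ec50

#' Fit a Boltzmann sigmoid to a titration series
#'
#' Least-squares fit of the four-parameter Boltzmann curve on
#' log10(concentration) with unconstrained slope. Requires at least 5
#' points spanning more than one decade. A flat series (negligible
#' amplitude) is flagged \code{noTransition} and no EC50 is reported.
#'
#' @param concentration concentrations (> 0, same units throughout).
#' @param response measured responses.
#' @return A \linkS4class{DoseResponseFit}.
#' @examples
#' g <- 10^seq(-11, -7, length.out = 9)
#' y <- simulateTitration(g, ec50 = 1e-9)
#' ec50(fitTitration(g, y$response))
#' @export
fitTitration <- function(concentration, response) {
  stopifnot(length(concentration) == length(response),
            all(concentration > 0))
  if (length(concentration) < 5L)
    stop("need at least 5 titration points")
  x <- log10(concentration)
  if (diff(range(x)) <= 1)
    stop("titration must span more than one decade of concentration")
  y <- response
  amp <- diff(range(y))
  if (amp <= 1e-6 * max(abs(y), 1))
    return(new("DoseResponseFit", bottom = mean(y), top = mean(y),
               x50 = NA_real_, slope = NA_real_, ec50 = NA_real_,
               r2 = NA_real_, converged = TRUE, noTransition = TRUE))
  half <- (min(y) + max(y)) / 2
  start <- list(bottom = min(y), top = max(y),
                x50 = x[which.min(abs(y - half))],
                slope = diff(range(x)) / 6)
  fit <- minpack.lm::nlsLM(
    y ~ bottom + (top - bottom) / (1 + exp((x50 - x) / slope)),
    start = start, control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  ss <- sum(stats::resid(fit)^2)
  r2 <- 1 - ss / sum((y - mean(y))^2)
  # a fitted negative slope means the curve decreases with concentration;
  # reparameterize to the increasing orientation
  bottom <- min(cf[["bottom"]], cf[["top"]])
  top <- max(cf[["bottom"]], cf[["top"]])
  new("DoseResponseFit", bottom = bottom, top = top,
      x50 = cf[["x50"]], slope = cf[["slope"]], ec50 = 10^cf[["x50"]],
      r2 = r2, converged = fit$convInfo$isConv %||% TRUE,
      noTransition = FALSE)
}

#' Selectivity ratio between two titrations
#'
#' EC50(a) / EC50(b); reported only when both fits converged with a
#' transition.
#'
#' @param a,b \linkS4class{DoseResponseFit} objects.
#' @return The EC50 ratio, or NA when either fit has no transition.
#' @export
selectivityRatio <- function(a, b) {
  if (a@noTransition || b@noTransition || !a@converged || !b@converged)
    return(NA_real_)
  ec50(a) / ec50(b)
}

## ---- display scaling ------------------------------------------------------

#' Per-antibody min-max heatmap scaling
#'
#' Scales each antibody's probe-intensity vector independently to [0, 1]
#' (min-max), preserving probe order; antibodies are never coupled. An
#' all-equal vector scales to zeros with a "flat profile" warning.
#'
#' @param profiles numeric matrix (probes x antibodies) or a named list of
#'   equal-length vectors.
#' @return Matrix of the same shape with values in [0, 1].
#' @export
heatmapMatrix <- function(profiles) {
  if (is.list(profiles)) profiles <- do.call(cbind, profiles)
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1L)
  out <- apply(profiles, 2L, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) {
      warning("flat profile: all intensities equal; scaled to zeros")
      return(rep(0, length(v)))
    }
    (v - rng[1L]) / diff(rng)
  })
  dimnames(out) <- dimnames(profiles)
  out
}

#' Write a DMS matrix as CSV (positions x 20 letters)
#'
#' @param m a \linkS4class{DmsMatrix}.
#' @param path output path.
#' @export
writeDmsMatrix <- function(m, path) {
  df <- data.frame(abeta_position = m@positions,
                   wildtype = strsplit(m@wildtype, "")[[1L]],
                   m@ratios, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a core motif to JSON
#'
#' @param motif a \linkS4class{CoreMotif}.
#' @param path output path.
#' @export
writeCoreMotif <- function(motif, path) {
  writeStableJson(list(
    antibody = motif@antibody,
    motif = motif@motif,
    positions = motif@positions,
    core_positions = motif@core,
    dominant_negative_counts = motif@counts,
    min_count = motif@minCount,
    ratio_threshold = motif@threshold), path)
}
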