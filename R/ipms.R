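# Theoretical mass table for an Abeta variant panel and assignment of
# observed MALDI peaks to panel members (IP-MS readout emulation).

#' VariantPanel: named Abeta variants with theoretical masses and pI
#'
#' @slot table data.frame: name, sequence (canonical), monoisotopic and
#'   average neutral masses, [M+H]+ masses, theoretical pI.
#' @slot peptides named list of \linkS4class{ModifiedPeptide}.
#' @export
setClass("VariantPanel",
  representation(table = "data.frame", peptides = "list"))

setValidity("VariantPanel", function(object) {
  if (anyDuplicated(object@table$name)) return("variant names must be unique")
  if (!identical(object@table$name, names(object@peptides)))
    return("table and peptide list out of step")
  TRUE
})

setMethod("show", "VariantPanel", function(object) {
  cat(sprintf("VariantPanel with %d variants\n", nrow(object@table)))
  print(object@table[, c("name", "mono", "avg", "mh_avg", "pi")],
        row.names = FALSE, digits = 6)
})

#' @describeIn VariantPanel panel table accessor
#' @param x a VariantPanel
#' @export
panelTable <- function(x) x@table

#' @describeIn VariantPanel number of variants
#' @export
setMethod("length", "VariantPanel", function(x) nrow(x@table))

#' The ten-member synthetic Abeta mixture
#'
#' Specs for the ten-peptide panel used in the IP-MS experiments:
#' Abeta1-40 and 1-42, the N-terminally truncated 2-40, 3-40, pE3-40,
#' 4-40, 5-40 and 11-40, the N-terminally elongated (-3)-40, and
#' pSer8-Abeta1-40 with an amidated C-terminus.
#'
#' @return data.frame of specs consumed by \code{\link{buildPanel}}.
#' @export
defaultPanelSpecs <- function() {
  data.frame(
    name = c("Abeta1-40", "Abeta1-42", "Abeta2-40", "Abeta3-40",
             "AbetapE3-40", "Abeta4-40", "Abeta5-40", "Abeta11-40",
             "Abeta(-3)-40", "pSer8-Abeta1-40-amide"),
    start = c(1L, 1L, 2L, 3L, 3L, 4L, 5L, 11L, -3L, 1L),
    end = c(40L, 42L, rep(40L, 8L)),
    pyroglu = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                FALSE, FALSE),
    phospho = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, 8L),
    amide = c(rep(FALSE, 9L), TRUE),
    stringsAsFactors = FALSE)
}

#' Build an Abeta variant panel with theoretical masses and pI
#'
#' @param specs data.frame with columns name, start, end and optional
#'   pyroglu (logical), phospho (Abeta position or NA), amide (logical);
#'   defaults to the ten-member mixture of \code{\link{defaultPanelSpecs}}.
#' @param pka \linkS4class{PkaSet} for the pI annotation.
#' @return A \linkS4class{VariantPanel}.
#' @examples
#' panel <- buildPanel()
#' panelTable(panel)[, c("name", "mh_avg")]
#' @export
buildPanel <- function(specs = defaultPanelSpecs(), pka = bjellqvistPka()) {
  peps <- vector("list", nrow(specs))
  for (k in seq_len(nrow(specs))) {
    ph <- if ("phospho" %in% names(specs) && !is.na(specs$phospho[k]))
      specs$phospho[k] else integer()
    peps[[k]] <- abetaPeptide(
      specs$start[k], specs$end[k], phospho = ph,
      pyroGlu = isTRUE(specs$pyroglu[k]),
      amide = isTRUE(specs$amide[k]))
  }
  names(peps) <- specs$name
  tab <- data.frame(
    name = specs$name,
    sequence = vapply(peps, writePeptide, ""),
    mono = vapply(peps, peptideMass, 0, kind = "monoisotopic"),
    avg = vapply(peps, peptideMass, 0, kind = "average"),
    mh_mono = vapply(peps, peptideMass, 0, kind = "monoisotopic",
                     adduct = "MH+"),
    mh_avg = vapply(peps, peptideMass, 0, kind = "average", adduct = "MH+"),
    pi = vapply(peps, isoelectricPoint, 0, pka = pka),
    stringsAsFactors = FALSE, row.names = NULL)
  new("VariantPanel", table = tab, peptides = peps)
}

#' Export variant annotations as JSON
#'
#' Writes name, canonical sequence, neutral monoisotopic/average masses,
#' [M+H]+ masses and theoretical pI per variant.
#'
#' @param panel a \linkS4class{VariantPanel}.
#' @param path output path.
#' @export
exportVariantAnnotations <- function(panel, path) {
  writeStableJson(apply(panel@table, 1L, as.list), path)
}

#' Assign spectrum peaks to panel variants
#'
#' Detects centroids as local maxima above \code{minSnr} times the median
#' intensity (or takes the input as already centroided) and matches each
#' peak to the nearest panel [M+H]+ mass within \code{tolerance}. Average
#' masses are used by default (linear/reflector MALDI of >4 kDa peptides);
#' a peak with two panel masses inside the tolerance is flagged ambiguous
#' but still assigned to the nearer one. Relative intensities are peak
#' heights as fractions of the summed assigned heights (semi-quantitative).
#'
#' @param spectrum data.frame with columns \code{mz}, \code{intensity}.
#' @param panel a \linkS4class{VariantPanel}.
#' @param tolerance matching tolerance (Da).
#' @param minSnr centroid threshold as a multiple of the median intensity.
#' @param massType \code{"average"} or \code{"monoisotopic"}.
#' @param centroided TRUE when the input is already a peak list.
#' @return List with \code{assignments} (one row per detected peak:
#'   mz, intensity, variant or "unassigned", mass error, ambiguous flag)
#'   and \code{summary} (per-variant relative intensity).
#' @export
assignPeaks <- function(spectrum, panel, tolerance = 1.0, minSnr = 3,
                        massType = c("average", "monoisotopic"),
                        centroided = FALSE) {
  massType <- match.arg(massType)
  stopifnot(all(c("mz", "intensity") %in% names(spectrum)), tolerance > 0)
  empty <- list(
    assignments = data.frame(mz = numeric(), intensity = numeric(),
                             variant = character(), error = numeric(),
                             ambiguous = logical()),
    summary = data.frame(name = panelTable(panel)$name, rel_intensity = 0))
  if (!nrow(spectrum)) return(empty)
  o <- order(spectrum$mz)
  mz <- spectrum$mz[o]; y <- spectrum$intensity[o]
  if (centroided || length(y) < 3L) {
    peaks <- seq_along(y)
  } else {
    inner <- 2:(length(y) - 1L)
    peaks <- inner[y[inner] > y[inner - 1L] & y[inner] >= y[inner + 1L]]
  }
  floorI <- minSnr * stats::median(y)
  peaks <- peaks[y[peaks] >= floorI]
  if (!length(peaks)) return(empty)
  ref <- if (massType == "average") panelTable(panel)$mh_avg
         else panelTable(panel)$mh_mono
  nm <- panelTable(panel)$name
  rows <- lapply(peaks, function(i) {
    err <- mz[i] - ref
    hit <- which(abs(err) <= tolerance)
    if (!length(hit))
      return(data.frame(mz = mz[i], intensity = y[i],
                        variant = "unassigned", error = NA_real_,
                        ambiguous = FALSE, stringsAsFactors = FALSE))
    best <- hit[which.min(abs(err[hit]))]
    data.frame(mz = mz[i], intensity = y[i], variant = nm[best],
               error = err[best], ambiguous = length(hit) > 1L,
               stringsAsFactors = FALSE)
  })
  asn <- do.call(rbind, rows)
  assigned <- asn[asn$variant != "unassigned", , drop = FALSE]
  tot <- sum(assigned$intensity)
  rel <- vapply(nm, function(v)
    if (tot > 0) sum(assigned$intensity[assigned$variant == v]) / tot else 0,
    0)
  list(assignments = asn,
       summary = data.frame(name = nm, rel_intensity = unname(rel),
                            stringsAsFactors = FALSE))
}

#' Two-column spectrum TSV I/O
#'
#' @param spectrum data.frame with columns mz, intensity.
#' @param path file path.
#' @export
writeSpectrumTsv <- function(spectrum, path) {
  utils::write.table(spectrum[, c("mz", "intensity")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumTsv
#' @export
readSpectrumTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
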