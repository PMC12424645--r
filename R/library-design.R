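# Design of the three arrayed library classes: overlapping tiling windows,
# deep positional-substitution scans, and PTM variant panels.

PROBE_ROLES <- c("tile", "wildtype", "substitution", "ptm-variant", "control")

#' ProbeLibrary: an ordered set of arrayed peptide probes
#'
#' Wraps a probe table with columns \code{probe_id}, \code{sequence}
#' (canonical modified-sequence string), \code{role} (\code{tile},
#' \code{wildtype}, \code{substitution}, \code{ptm-variant},
#' \code{control}), and provenance columns \code{wt_position} (1-based
#' position within the scanned wildtype), \code{abeta_position} (Abeta
#' coordinate of that position, if coordinates are attached) and
#' \code{substitution} (replacement letter). Provenance is carried in the
#' table so downstream analysis never re-parses sequences.
#'
#' @slot probes the probe data.frame.
#' @slot wildtype canonical wildtype sequence for scan libraries
#'   (\code{NA} otherwise).
#' @slot abetaStart Abeta coordinate of the wildtype's first residue.
#' @export
setClass("ProbeLibrary",
  representation(probes = "data.frame", wildtype = "character",
                 abetaStart = "integer"),
  prototype(wildtype = NA_character_, abetaStart = NA_integer_))

setValidity("ProbeLibrary", function(object) {
  pr <- object@probes
  need <- c("probe_id", "sequence", "role", "wt_position", "abeta_position",
            "substitution")
  if (!all(need %in% names(pr)))
    return(sprintf("probe table lacks column(s): %s",
                   paste(setdiff(need, names(pr)), collapse = ", ")))
  if (anyDuplicated(pr$probe_id)) return("probe ids must be unique")
  if (!all(pr$role %in% PROBE_ROLES)) return("unknown probe role")
  sub <- pr[pr$role == "substitution", , drop = FALSE]
  if (nrow(sub) && !is.na(object@wildtype)) {
    wt <- strsplit(object@wildtype, "")[[1L]]
    for (k in seq_len(nrow(sub))) {
      s <- strsplit(sub$sequence[k], "")[[1L]]
      if (length(s) != length(wt) || sum(s != wt) != 1L)
        return(sprintf("substitution probe '%s' is not Hamming distance 1 from wildtype",
                       sub$probe_id[k]))
    }
  }
  TRUE
})

setMethod("show", "ProbeLibrary", function(object) {
  tab <- table(object@probes$role)
  cat(sprintf("ProbeLibrary with %d probes (%s)\n", nrow(object@probes),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  if (!is.na(object@wildtype))
    cat(sprintf("wildtype: %s\n", object@wildtype))
})

#' @describeIn ProbeLibrary probe table accessor
#' @param x a ProbeLibrary
#' @export
probes <- function(x) x@probes

#' @describeIn ProbeLibrary number of probes
#' @export
setMethod("length", "ProbeLibrary", function(x) nrow(x@probes))

newProbeRow <- function(id, seq, role, wtPos = NA, abPos = NA, sub = NA) {
  data.frame(probe_id = id, sequence = seq, role = role,
             wt_position = as.integer(wtPos),
             abeta_position = as.integer(abPos),
             substitution = as.character(sub), stringsAsFactors = FALSE)
}

#' Overlapping tiling library
#'
#' Emits all contiguous windows of width \code{window} left-to-right at the
#' given step. With step 1 adjacent probes overlap by \code{window - 1}
#' residues; the arrayed Abeta -23..51 region (74 residues) at window 15
#' gives the 60-probe pre-screening library.
#'
#' @param seq sequence string (unmodified) or
#'   \linkS4class{ModifiedPeptide}.
#' @param window window width (<= sequence length).
#' @param step step between window starts (>= 1).
#' @param abetaStart optional Abeta coordinate of \code{seq}'s first
#'   residue; probe ids then carry Abeta coordinates.
#' @param prefix probe id prefix.
#' @return A \linkS4class{ProbeLibrary} of \code{floor((L - window)/step) + 1}
#'   tiles.
#' @examples
#' length(tileSequence(abetaRegionSequence(-23, 51), 15, abetaStart = -23))  # 60
#' @export
tileSequence <- function(seq, window = 15L, step = 1L, abetaStart = NA,
                         prefix = "tile") {
  if (is(seq, "ModifiedPeptide")) {
    if (is.na(abetaStart)) abetaStart <- seq@abetaStart
    seq <- paste(seq@residues, collapse = "")
  }
  L <- nchar(seq)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L) stop("window and step must be positive")
  if (window > L) stop("window exceeds sequence length")
  starts <- seq.int(1L, L - window + 1L, by = step)
  coords <- abetaCoords(as.integer(abetaStart), L)
  rows <- lapply(starts, function(s) {
    newProbeRow(sprintf("%s_%03d", prefix, which(starts == s)),
                substr(seq, s, s + window - 1L), "tile",
                wtPos = s, abPos = coords[s])
  })
  new("ProbeLibrary", probes = do.call(rbind, rows))
}

#' Deep positional-substitution scan
#'
#' For every position of an unmodified wildtype peptide, one probe per
#' alphabet letter other than the wildtype letter, plus a single wildtype
#' reference probe: L x (|alphabet| - 1) + 1 probes in total. An 18-mer
#' over the 20 proteinogenic letters yields 342 substitution variants.
#'
#' @param wt wildtype \linkS4class{ModifiedPeptide} (unmodified) or
#'   sequence string.
#' @param alphabet substitution alphabet (default: 20 proteinogenic
#'   letters, cysteine included).
#' @param name scan name used in probe ids.
#' @param abetaStart optional Abeta coordinate of the wildtype's first
#'   residue.
#' @return A \linkS4class{ProbeLibrary}; substitution probe ids encode
#'   provenance as \code{<name>_p<pos><wt><sub>}.
#' @examples
#' scan <- positionalScan(abetaRegionSequence(1, 18), abetaStart = 1)
#' sum(probes(scan)$role == "substitution")  # 342
#' @export
positionalScan <- function(wt, alphabet = AA20, name = "scan",
                           abetaStart = NA) {
  if (is.character(wt)) wt <- ModifiedPeptide(wt, abetaStart = abetaStart)
  else if (!is.na(abetaStart)) abetaStart(wt) <- abetaStart
  if (any(wt@mods != "none") || wt@cTerm != "free-acid")
    stop("positional scans are defined on an unmodified wildtype")
  if (!length(alphabet)) stop("empty substitution alphabet")
  wtSeq <- paste(wt@residues, collapse = "")
  coords <- abetaPositions(wt)
  rows <- list(newProbeRow(sprintf("%s_wt", name), wtSeq, "wildtype"))
  for (i in seq_along(wt@residues)) {
    for (a in setdiff(alphabet, wt@residues[i])) {
      s <- wt@residues
      s[i] <- a
      rows[[length(rows) + 1L]] <- newProbeRow(
        sprintf("%s_p%02d%s%s", name, i, wt@residues[i], a),
        paste(s, collapse = ""), "substitution",
        wtPos = i, abPos = coords[i], sub = a)
    }
  }
  new("ProbeLibrary", probes = do.call(rbind, rows), wildtype = wtSeq,
      abetaStart = wt@abetaStart)
}

#' PTM variant panel
#'
#' Builds the head-to-head panel used for modification-selectivity
#' profiling: each requested PTM variant of an Abeta coordinate span is
#' emitted alongside its unmodified counterpart.
#'
#' Supported specs: \code{"pSer8"}, \code{"pSer26"}, \code{"pE3"},
#' \code{"D-Asp1"}, \code{"iso-Asp1"}, \code{"C-amide"}.
#'
#' @param start,end Abeta coordinate span of the displayed peptide.
#' @param variants character vector of PTM specs.
#' @param prefix probe id prefix.
#' @return A \linkS4class{ProbeLibrary} with one \code{control} probe and
#'   one \code{ptm-variant} probe per spec; every variant's residue string
#'   is identical to the control's.
#' @examples
#' ptmPanel(3, 17, "pE3")                 # AbetapE3-17 + unmodified control
#' ptmPanel(-1, 14, c("D-Asp1", "iso-Asp1"))
#' @export
ptmPanel <- function(start, end, variants, prefix = "ptm") {
  known <- c("pSer8", "pSer26", "pE3", "D-Asp1", "iso-Asp1", "C-amide")
  bad <- setdiff(variants, known)
  if (length(bad))
    stop(sprintf("unsupported PTM spec(s): %s", paste(bad, collapse = ", ")))
  control <- abetaPeptide(start, end)
  rows <- list(newProbeRow(sprintf("%s_control", prefix),
                           writePeptide(control), "control",
                           abPos = start))
  for (v in variants) {
    p <- switch(v,
      "pSer8"    = abetaPeptide(start, end, phospho = 8),
      "pSer26"   = abetaPeptide(start, end, phospho = 26),
      "pE3"      = {
        if (start != 3L)
          stop("pE3 requires the span to start at Abeta position 3")
        abetaPeptide(start, end, pyroGlu = TRUE)
      },
      "D-Asp1"   = abetaPeptide(start, end, dAsp = 1),
      "iso-Asp1" = abetaPeptide(start, end, isoAsp = 1),
      "C-amide"  = abetaPeptide(start, end, amide = TRUE))
    rows[[length(rows) + 1L]] <- newProbeRow(
      sprintf("%s_%s", prefix, v), writePeptide(p), "ptm-variant",
      abPos = start, sub = v)
  }
  new("ProbeLibrary", probes = do.call(rbind, rows),
      abetaStart = as.integer(start))
}

#' Read/write a probe library as CSV
#'
#' The CSV carries the probe table verbatim (probe_id, sequence, role,
#' wt_position, abeta_position, substitution) plus the wildtype sequence in
#' a leading comment line for scan libraries.
#'
#' @param lib a \linkS4class{ProbeLibrary}.
#' @param path file path.
#' @export
writeProbeLibrary <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(lib@wildtype))
    writeLines(sprintf("# wildtype=%s abeta_start=%s", lib@wildtype,
                       lib@abetaStart), con)
  utils::write.csv(lib@probes, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProbeLibrary
#' @export
readProbeLibrary <- function(path) {
  first <- readLines(path, n = 1L)
  wt <- NA_character_; st <- NA_integer_
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("wildtype=(\\S+) abeta_start=(\\S+)", first))[[1L]]
    if (length(m) == 3L) {
      wt <- m[2L]
      st <- suppressWarnings(as.integer(m[3L]))
    }
  }
  pr <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  pr$wt_position <- as.integer(pr$wt_position)
  pr$abeta_position <- as.integer(pr$abeta_position)
  pr$substitution <- as.character(pr$substitution)
  new("ProbeLibrary", probes = pr, wildtype = wt, abetaStart = st)
}
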