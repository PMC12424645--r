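#' @import methods
NULL

#' ModifiedPeptide: a peptide with per-residue modification tags
#'
#' Represents a (possibly modified) peptide as displayed on the arrays or
#' used in solution assays: an ordered run of one-letter residues, a
#' per-position modification tag, N-/C-terminal states, and optionally the
#' Abeta coordinate of its first residue. Abeta numbering has no position 0:
#' coordinates run ..., -2, -1, 1, 2, ... within -23..51 (the APP770
#' 649-722 region).
#'
#' @slot residues character vector of one-letter amino acids.
#' @slot mods per-position tag, one of \code{"none"}, \code{"phospho"},
#'   \code{"pyroglutamate"}, \code{"d-stereo"}, \code{"iso-aspartate"}.
#' @slot nTerm \code{"free-amine"} or \code{"pyroglutamate-cyclized"}.
#' @slot cTerm \code{"free-acid"} or \code{"amide"}.
#' @slot abetaStart Abeta coordinate of residue 1, or \code{NA} for
#'   peptides without Abeta coordinates.
#'
#' @examples
#' p <- parsePeptide("DAEFRHDS[p]GYEVHHQ")
#' abetaStart(p) <- 1
#' p
#' @export
setClass("ModifiedPeptide",
  representation(residues = "character", mods = "character",
                 nTerm = "character", cTerm = "character",
                 abetaStart = "integer"),
  prototype(nTerm = "free-amine", cTerm = "free-acid",
            abetaStart = NA_integer_))

setValidity("ModifiedPeptide", function(object) {
  r <- object@residues; m <- object@mods
  if (length(r) < 1L) return("peptide must contain at least one residue")
  if (!all(r %in% AA20)) {
    bad <- setdiff(unique(r), AA20)
    return(sprintf("unknown residue letter(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(m) != length(r)) return("mods and residues differ in length")
  if (!all(m %in% MOD_TAGS))
    return(sprintf("unknown modification tag(s): %s",
                   paste(setdiff(unique(m), MOD_TAGS), collapse = ", ")))
  i <- which(m == "phospho")
  if (length(i) && !all(r[i] %in% c("S", "T", "Y")))
    return("phospho is only valid on S, T or Y")
  i <- which(m %in% c("d-stereo", "iso-aspartate"))
  if (length(i) && !all(r[i] == "D"))
    return("d-stereo and iso-aspartate are only valid on D")
  i <- which(m == "pyroglutamate")
  if (length(i)) {
    if (!identical(i, 1L)) return("pyroglutamate is only valid at peptide position 1")
    if (!r[1L] %in% c("E", "Q")) return("pyroglutamate is only valid on E or Q")
    if (object@nTerm != "pyroglutamate-cyclized")
      return("a pyroglutamate peptide must have nTerm 'pyroglutamate-cyclized'")
  }
  if (object@nTerm == "pyroglutamate-cyclized" && (!length(i)))
    return("nTerm 'pyroglutamate-cyclized' requires a pyroglutamate tag at position 1")
  if (!object@nTerm %in% c("free-amine", "pyroglutamate-cyclized"))
    return("invalid nTerm")
  if (!object@cTerm %in% c("free-acid", "amide")) return("invalid cTerm")
  s <- object@abetaStart
  if (!is.na(s)) {
    if (s == 0L) return("Abeta numbering has no position 0")
    if (s < -23L || s > 51L) return("abetaStart outside -23..51")
    last <- abetaCoords(s, length(r))[length(r)]
    if (last > 51L) return("peptide extends beyond Abeta position 51")
  }
  TRUE
})

#' Construct a ModifiedPeptide
#'
#' @param residues character vector of one-letter residues, or a single
#'   unmodified sequence string.
#' @param mods per-position modification tags (recycled \code{"none"} by
#'   default).
#' @param nTerm,cTerm terminal states.
#' @param abetaStart Abeta coordinate of the first residue (\code{NA} for
#'   non-Abeta peptides).
#' @return A \linkS4class{ModifiedPeptide}.
#' @export
ModifiedPeptide <- function(residues, mods = NULL, nTerm = "free-amine",
                            cTerm = "free-acid", abetaStart = NA) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1L]]
  if (is.null(mods)) mods <- rep("none", length(residues))
  new("ModifiedPeptide", residues = residues, mods = mods,
      nTerm = nTerm, cTerm = cTerm, abetaStart = as.integer(abetaStart))
}

#' @describeIn ModifiedPeptide number of residues
#' @param x a ModifiedPeptide
#' @export
setMethod("length", "ModifiedPeptide", function(x) length(x@residues))

#' Accessors for ModifiedPeptide
#'
#' \code{residues}, \code{peptideMods}, \code{abetaStart} read slots;
#' \code{abetaStart<-} sets (and revalidates) the Abeta coordinate;
#' \code{abetaPositions} returns per-residue Abeta coordinates (skipping
#' position 0), or 1..L when no coordinates are attached.
#'
#' @param p,x a \linkS4class{ModifiedPeptide}.
#' @param value integer Abeta coordinate.
#' @name peptide-accessors
NULL

#' @rdname peptide-accessors
#' @export
residues <- function(p) p@residues

#' @rdname peptide-accessors
#' @export
peptideMods <- function(p) p@mods

#' @rdname peptide-accessors
#' @export
abetaStart <- function(p) p@abetaStart

#' @rdname peptide-accessors
#' @export
`abetaStart<-` <- function(x, value) {
  x@abetaStart <- as.integer(value)
  validObject(x)
  x
}

#' @rdname peptide-accessors
#' @export
abetaPositions <- function(p) abetaCoords(p@abetaStart, length(p))

setMethod("show", "ModifiedPeptide", function(object) {
  coords <- if (is.na(object@abetaStart)) "" else {
    pos <- abetaPositions(object)
    sprintf(" [Abeta %d..%d]", pos[1L], pos[length(pos)])
  }
  cat(sprintf("ModifiedPeptide (%d aa)%s: %s\n", length(object), coords,
              writePeptide(object)))
})

## ---- modified-sequence grammar -------------------------------------------

# canonical dialect: one-letter residues with optional bracket tags
#   S[p] phospho, E[pE]/Q[pE] N-terminal pyroglutamate, D[d] D-Asp,
#   D[iso] iso-Asp; optional "-NH2" suffix for a C-terminal amide.
# array-digit dialect: figure shorthand in which '2' stands for
#   phospho-serine; no other tags.

TAG2MOD <- c(p = "phospho", pE = "pyroglutamate", d = "d-stereo",
             iso = "iso-aspartate")
MOD2TAG <- c(phospho = "p", pyroglutamate = "pE", `d-stereo` = "d",
             `iso-aspartate` = "iso")

#' Parse a modified-sequence string
#'
#' Reads either the canonical bracket-tag dialect (\code{"DAEFRHDS[p]GY"},
#' \code{"E[pE]FRHDSGY"}, optional \code{"-NH2"} amide suffix) or the
#' array-digit dialect used as figure shorthand on the arrays, where the
#' character \code{'2'} denotes phospho-serine.
#'
#' @param text modified-sequence string.
#' @param dialect \code{"canonical"} (default) or \code{"array-digit"}.
#' @param abetaStart optional Abeta coordinate of the first residue.
#' @return A \linkS4class{ModifiedPeptide}. Canonical strings round-trip
#'   through \code{\link{writePeptide}}.
#' @examples
#' parsePeptide("DAEFRHD2GYEVHHQ", dialect = "array-digit")
#' parsePeptide("E[pE]FRHDSGYEVHHQKL-NH2")
#' @export
parsePeptide <- function(text, dialect = c("canonical", "array-digit"),
                         abetaStart = NA) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("empty sequence string")
  cTerm <- "free-acid"
  if (dialect == "canonical" && grepl("-NH2$", text)) {
    cTerm <- "amide"
    text <- sub("-NH2$", "", text)
  }
  if (dialect == "array-digit") {
    if (grepl("\\[", text))
      stop("bracket tags are not part of the array-digit dialect")
    chars <- strsplit(text, "")[[1L]]
    bad <- setdiff(unique(chars), c(AA20, "2"))
    if (length(bad))
      stop(sprintf("unknown character(s) in array-digit sequence: %s",
                   paste(bad, collapse = ", ")))
    resv <- ifelse(chars == "2", "S", chars)
    modv <- ifelse(chars == "2", "phospho", "none")
    return(ModifiedPeptide(resv, modv, cTerm = cTerm, abetaStart = abetaStart))
  }
  if (grepl("2", text, fixed = TRUE))
    stop("'2' is array-digit shorthand; use dialect = \"array-digit\"")
  m <- gregexpr("([A-Za-z])(\\[(p|pE|d|iso)\\])?", text, perl = TRUE)[[1L]]
  toks <- regmatches(text, list(m))[[1L]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(text))
    stop(sprintf("cannot parse modified-sequence string: '%s'", text))
  resv <- substr(toks, 1L, 1L)
  tags <- sub("^.\\[(.*)\\]$", "\\1", toks)
  modv <- ifelse(tags == toks, "none", unname(TAG2MOD[tags]))
  nTerm <- if (length(modv) && modv[1L] == "pyroglutamate")
    "pyroglutamate-cyclized" else "free-amine"
  ModifiedPeptide(resv, modv, nTerm = nTerm, cTerm = cTerm,
                  abetaStart = abetaStart)
}

#' Write a ModifiedPeptide as a modified-sequence string
#'
#' @param p a \linkS4class{ModifiedPeptide}.
#' @param dialect output dialect; \code{"array-digit"} renders
#'   phospho-serine as \code{'2'} and refuses tags it cannot express.
#' @return A single string; the canonical writer inverts
#'   \code{\link{parsePeptide}}.
#' @export
writePeptide <- function(p, dialect = c("canonical", "array-digit")) {
  dialect <- match.arg(dialect)
  if (dialect == "array-digit") {
    if (p@cTerm == "amide" || any(!p@mods %in% c("none", "phospho")))
      stop("array-digit dialect can only express phospho-serine")
    if (any(p@mods == "phospho" & p@residues != "S"))
      stop("array-digit '2' stands for phospho-serine only")
    return(paste(ifelse(p@mods == "phospho", "2", p@residues), collapse = ""))
  }
  tags <- ifelse(p@mods == "none", "",
                 paste0("[", MOD2TAG[p@mods], "]"))
  out <- paste(paste0(p@residues, tags), collapse = "")
  if (p@cTerm == "amide") out <- paste0(out, "-NH2")
  out
}

#' @describeIn parsePeptide coerce to the canonical string
#' @param x a ModifiedPeptide
#' @param ... ignored
#' @export
setMethod("as.character", "ModifiedPeptide",
          function(x, ...) writePeptide(x))

## ---- Abeta <-> APP770 coordinate map -------------------------------------

#' Map between Abeta and APP770 coordinates
#'
#' The arrayed region spans APP770 residues 649-722, i.e. Abeta -23..51.
#' The map is a bijection over those 74 positions; Abeta has no position 0.
#'
#' @param abetaPos integer vector of Abeta positions in -23..51 (0 forbidden).
#' @param appPos integer vector of APP770 positions in 649..722.
#' @return The corresponding positions in the other numbering.
#' @examples
#' abetaToApp770(c(-23, 1, 51))  # 649 672 722
#' app770ToAbeta(649:650)        # -23 -22
#' @export
abetaToApp770 <- function(abetaPos) {
  abetaPos <- as.integer(abetaPos)
  if (any(abetaPos == 0L)) stop("Abeta numbering has no position 0")
  if (any(abetaPos < -23L | abetaPos > 51L))
    stop("Abeta position outside -23..51")
  ifelse(abetaPos < 0L, abetaPos + APP770_OFFSET_NEG,
         abetaPos + APP770_OFFSET_POS)
}

#' @rdname abetaToApp770
#' @export
app770ToAbeta <- function(appPos) {
  appPos <- as.integer(appPos)
  if (any(appPos < APP770_FIRST | appPos > APP770_LAST))
    stop("APP770 position outside 649..722")
  ifelse(appPos >= APP770_OFFSET_NEG, appPos - APP770_OFFSET_POS,
         appPos - APP770_OFFSET_NEG)
}

## ---- Abeta sequence helpers ----------------------------------------------

#' Abeta region sequences and coordinate-addressed peptides
#'
#' \code{abetaRegionSequence} returns the unmodified sequence of an Abeta
#' coordinate span within -23..51 (position 0 skipped).
#' \code{abetaPeptide} builds a \linkS4class{ModifiedPeptide} for a span,
#' optionally phosphorylated, pyroglutamate-cyclized, Asp-isomerized or
#' C-terminally amidated.
#'
#' @param start,end Abeta coordinates (no 0) with \code{start <= end}.
#' @param phospho Abeta positions (S/T/Y) to phosphorylate.
#' @param pyroGlu cyclize the N-terminal residue (must be E or Q at
#'   \code{start}).
#' @param dAsp,isoAsp Abeta positions (D) to mark as D-Asp / iso-Asp.
#' @param amide amidated C-terminus.
#' @return A character string / \linkS4class{ModifiedPeptide}.
#' @examples
#' abetaRegionSequence(1, 42)
#' abetaPeptide(3, 17, pyroGlu = TRUE)   # AbetapE3-17
#' @export
abetaRegionSequence <- function(start, end) {
  idx <- match(abetaToApp770(start), APP770_FIRST:APP770_LAST)
  idx2 <- match(abetaToApp770(end), APP770_FIRST:APP770_LAST)
  if (idx2 < idx) stop("end precedes start")
  substr(ABETA_REGION, idx, idx2)
}

#' @rdname abetaRegionSequence
#' @export
abetaPeptide <- function(start, end, phospho = integer(), pyroGlu = FALSE,
                         dAsp = integer(), isoAsp = integer(), amide = FALSE) {
  seq <- abetaRegionSequence(start, end)
  resv <- strsplit(seq, "")[[1L]]
  pos <- abetaCoords(as.integer(start), length(resv))
  modv <- rep("none", length(resv))
  place <- function(at, tag) {
    i <- match(as.integer(at), pos)
    if (anyNA(i))
      stop(sprintf("%s position(s) %s outside the Abeta %d..%d span", tag,
                   paste(at[is.na(i)], collapse = ", "), start, end))
    modv[i] <<- tag
  }
  if (length(phospho)) place(phospho, "phospho")
  if (length(dAsp)) place(dAsp, "d-stereo")
  if (length(isoAsp)) place(isoAsp, "iso-aspartate")
  nTerm <- "free-amine"
  if (isTRUE(pyroGlu)) {
    modv[1L] <- "pyroglutamate"
    nTerm <- "pyroglutamate-cyclized"
  }
  ModifiedPeptide(resv, modv, nTerm = nTerm,
                  cTerm = if (amide) "amide" else "free-acid",
                  abetaStart = start)
}

## ---- FASTA and sidecar I/O -----------------------------------------------

#' Read peptides from FASTA with an optional modification sidecar
#'
#' Unmodified sequences are read with \code{Biostrings}; a sidecar TSV with
#' columns \code{id}, \code{position} (1-based peptide position) and
#' \code{tag} (canonical modification tag, or \code{"amide"} applied to the
#' C-terminus) attaches modifications by record id.
#'
#' @param fasta path to a FASTA file of unmodified sequences.
#' @param sidecar optional path to the modification TSV.
#' @return Named list of \linkS4class{ModifiedPeptide}.
#' @export
readPeptideFasta <- function(fasta, sidecar = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  peps <- lapply(as.character(aa), ModifiedPeptide)
  names(peps) <- sub("\\s.*$", "", names(aa))
  if (!is.null(sidecar)) {
    sc <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    stopifnot(all(c("id", "position", "tag") %in% names(sc)))
    for (k in seq_len(nrow(sc))) {
      id <- sc$id[k]
      if (!id %in% names(peps)) stop(sprintf("sidecar id '%s' not in FASTA", id))
      p <- peps[[id]]
      if (sc$tag[k] == "amide") {
        p@cTerm <- "amide"
      } else {
        i <- as.integer(sc$position[k])
        p@mods[i] <- sc$tag[k]
        if (sc$tag[k] == "pyroglutamate") p@nTerm <- "pyroglutamate-cyclized"
      }
      validObject(p)
      peps[[id]] <- p
    }
  }
  peps
}

#' Write unmodified peptide sequences to FASTA
#'
#' @param peps named list of \linkS4class{ModifiedPeptide}.
#' @param path output path.
#' @export
writePeptideFasta <- function(peps, path) {
  seqs <- vapply(peps, function(p) paste(p@residues, collapse = ""), "")
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- names(peps)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
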