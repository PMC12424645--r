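# Theoretical mass and isoelectric-point calculators for modified Abeta
# peptides, used to annotate IP-MS peak identities and CIEF separations.

#' Residue mass table
#'
#' Monoisotopic and average residue masses, modification deltas, and the
#' water/proton constants used by \code{\link{peptideMass}}. The deltas for
#' the Asp stereo/isomer forms are exactly zero (mass-neutral
#' isomerizations); the pyroglutamate delta depends on whether E or Q
#' cyclizes.
#'
#' @return A list with components \code{mono}, \code{avg} (named residue
#'   masses), \code{delta} (modification deltas), \code{water},
#'   \code{proton}.
#' @export
defaultMassTable <- function() {
  list(mono = MONO_MASS, avg = AVG_MASS, delta = MOD_DELTA,
       water = c(mono = WATER_MONO, avg = WATER_AVG),
       proton = c(mono = PROTON_MONO, avg = PROTON_AVG))
}

#' Theoretical peptide mass
#'
#' Sums residue masses plus one water, applies modification deltas
#' (phospho +79.966331 Da monoisotopic; pyroglutamate -18.010565 from E or
#' -17.026549 from Q; C-terminal amide -0.984016; Asp stereo/iso forms 0),
#' and optionally adds a proton for the singly protonated [M+H]+ species.
#'
#' @param p a \linkS4class{ModifiedPeptide} or a sequence string
#'   (canonical dialect).
#' @param kind \code{"monoisotopic"} or \code{"average"}.
#' @param adduct \code{"neutral"} or \code{"MH+"}.
#' @param table a mass table from \code{\link{defaultMassTable}}.
#' @return Mass in Da.
#' @examples
#' peptideMass("GG")                       # 132.0535
#' peptideMass(abetaPeptide(1, 40), "average", "MH+")
#' @export
peptideMass <- function(p, kind = c("monoisotopic", "average"),
                        adduct = c("neutral", "MH+"),
                        table = defaultMassTable()) {
  kind <- match.arg(kind)
  adduct <- match.arg(adduct)
  if (is.character(p)) p <- parsePeptide(p)
  k <- if (kind == "monoisotopic") "mono" else "avg"
  res <- table[[k]][p@residues]
  if (anyNA(res))
    stop(sprintf("residue(s) missing from mass table: %s",
                 paste(unique(p@residues[is.na(res)]), collapse = ", ")))
  mass <- sum(res) + table$water[[k]]
  for (i in seq_along(p@mods)) {
    m <- p@mods[i]
    if (m == "none") next
    key <- if (m == "pyroglutamate")
      paste0("pyroglutamate-", p@residues[i]) else m
    mass <- mass + table$delta[[key]][[k]]
  }
  if (p@cTerm == "amide") mass <- mass + table$delta$amide[[k]]
  if (adduct == "MH+") mass <- mass + table$proton[[k]]
  unname(mass)
}

## ---- isoelectric point ----------------------------------------------------

#' PkaSet: ionizable-group pKa values
#'
#' Named pKa values for the ionizable side chains (D, E, C, Y, H, K, R) and
#' the free termini, plus the two pKa values of a phosphomonoester group
#' (treated as diprotic). The default set is the Bjellqvist table used by
#' common theoretical-pI servers.
#'
#' @slot name set name.
#' @slot values named numeric: \code{Nterm}, \code{Cterm}, \code{D},
#'   \code{E}, \code{C}, \code{Y}, \code{H}, \code{K}, \code{R}.
#' @slot phospho numeric length 2: the two phosphate pKa values.
#' @export
setClass("PkaSet",
  representation(name = "character", values = "numeric", phospho = "numeric"))

setValidity("PkaSet", function(object) {
  need <- c("Nterm", "Cterm", "D", "E", "C", "Y", "H", "K", "R")
  if (!all(need %in% names(object@values)))
    return(sprintf("missing pKa entries: %s",
                   paste(setdiff(need, names(object@values)), collapse = ", ")))
  if (any(object@values <= 0 | object@values >= 14))
    return("all pKa values must lie in (0, 14)")
  if (length(object@phospho) != 2L || any(object@phospho <= 0 | object@phospho >= 14))
    return("phospho needs two pKa values in (0, 14)")
  if (!nzchar(object@name)) return("pKa set must be named")
  TRUE
})

setMethod("show", "PkaSet", function(object) {
  cat(sprintf("PkaSet '%s'\n", object@name))
  print(round(object@values, 2))
  cat(sprintf("phospho pKa: %.2f, %.2f\n", object@phospho[1], object@phospho[2]))
})

#' Bundled pKa sets
#'
#' \code{bjellqvistPka} is the default (it underlies the theoretical pI
#' annotations used for CIEF interpretation); an EMBOSS-style set is
#' provided as an alternative via \code{pkaSet("emboss")}.
#'
#' @param name \code{"bjellqvist"} or \code{"emboss"}.
#' @return A \linkS4class{PkaSet}.
#' @export
bjellqvistPka <- function() {
  new("PkaSet", name = "bjellqvist",
      values = c(Nterm = 7.5, Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0,
                 Y = 10.0, H = 5.98, K = 10.0, R = 12.0),
      phospho = c(1.2, 6.5))
}

#' @rdname bjellqvistPka
#' @export
pkaSet <- function(name = c("bjellqvist", "emboss")) {
  name <- match.arg(name)
  if (name == "bjellqvist") return(bjellqvistPka())
  new("PkaSet", name = "emboss",
      values = c(Nterm = 8.6, Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5,
                 Y = 10.1, H = 6.5, K = 10.8, R = 12.5),
      phospho = c(1.2, 6.5))
}

#' Henderson-Hasselbalch net charge
#'
#' Net charge Q(pH) = sum of positive-group fractions minus sum of
#' negative-group fractions. Phosphorylated residues contribute a diprotic
#' phosphate (and their own hydroxyl no longer ionizes); a
#' pyroglutamate-cyclized N-terminus has no free amine (and the consumed
#' Glu side chain no longer ionizes); an amidated C-terminus has no
#' carboxylate.
#'
#' @param p a \linkS4class{ModifiedPeptide} or sequence string.
#' @param pH pH value(s).
#' @param pka a \linkS4class{PkaSet}.
#' @return Net charge at each pH; strictly decreasing in pH.
#' @export
netCharge <- function(p, pH, pka = bjellqvistPka()) {
  if (is.character(p)) p <- parsePeptide(p)
  v <- pka@values
  posK <- numeric(0)   # pKa of positive groups
  negK <- numeric(0)   # pKa of negative groups
  if (p@nTerm == "free-amine") posK <- c(posK, v[["Nterm"]])
  if (p@cTerm == "free-acid") negK <- c(negK, v[["Cterm"]])
  for (i in seq_along(p@residues)) {
    r <- p@residues[i]; m <- p@mods[i]
    if (m == "phospho") {
      negK <- c(negK, pka@phospho) # side-chain OH esterified; diprotic PO4
      next
    }
    if (m == "pyroglutamate") next # amide-cyclized side chain, no charge
    if (r %in% c("H", "K", "R")) posK <- c(posK, v[[r]])
    if (r %in% c("D", "E", "C", "Y")) negK <- c(negK, v[[r]])
  }
  if (!length(posK) && !length(negK)) stop("peptide has no ionizable group")
  vapply(pH, function(x) {
    sum(1 / (1 + 10^(x - posK))) - sum(1 / (1 + 10^(negK - x)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' Finds the pH at which \code{\link{netCharge}} crosses zero by bisection
#' on (0, 14) to |Q| < 1e-6. Errors if the charge does not change sign over
#' that range (e.g. no acidic or no basic group).
#'
#' @inheritParams netCharge
#' @param tol convergence tolerance on |Q|.
#' @return The pI (pH units).
#' @examples
#' isoelectricPoint(abetaPeptide(1, 40))  # 5.31
#' @export
isoelectricPoint <- function(p, pka = bjellqvistPka(), tol = 1e-6) {
  if (is.character(p)) p <- parsePeptide(p)
  lo <- 0; hi <- 14
  qlo <- netCharge(p, lo, pka); qhi <- netCharge(p, hi, pka)
  if (qlo <= 0 || qhi >= 0)
    stop("net charge does not cross zero in (0, 14); pI undefined")
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    q <- netCharge(p, mid, pka)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
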