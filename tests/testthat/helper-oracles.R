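# Independent oracles used to freeze expected values. These deliberately
# share no code (and, for monoisotopic masses, no constants) with the
# package implementation.

# Monoisotopic mass from elemental composition: residue formulas summed
# atom by atom from atomic masses.
oracleMonoMass <- function(seq) {
  atoms <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
             O = 15.9949146221, S = 31.97207069)
  formulas <- list(
    G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
    S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
    V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
    C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
    L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
    N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
    Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
    E = c(C = 5, H = 7, N = 1, O = 3),
    M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
    H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
    R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
    W = c(C = 11, H = 10, N = 2, O = 1))
  total <- c(H = 2, C = 0, N = 0, O = 1, S = 0) # one water
  for (r in strsplit(seq, "")[[1L]]) {
    f <- formulas[[r]]
    total[names(f)] <- total[names(f)] + f
  }
  sum(total * atoms[names(total)])
}

# Average mass by plain summation over an independently transcribed
# residue-mass table.
oracleAvgMass <- function(seq) {
  avg <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
           C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
           H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
           M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
           T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
  sum(avg[strsplit(seq, "")[[1L]]]) + 18.01528
}

# Brute-force core-motif caller: explicit double loop over positions and
# letters, no matrix ops shared with the implementation.
bruteCoreMotif <- function(ratioMat, wtSeq, threshold = 0.5, minCount = 10L) {
  wt <- strsplit(wtSeq, "")[[1L]]
  motif <- character(length(wt))
  counts <- integer(length(wt))
  for (i in seq_along(wt)) {
    n <- 0L
    for (a in colnames(ratioMat)) {
      if (a == wt[i]) next
      if (ratioMat[i, a] < threshold) n <- n + 1L
    }
    counts[i] <- n
    motif[i] <- if (n >= minCount) wt[i] else "X"
  }
  list(motif = paste(motif, collapse = ""), counts = counts)
}

# Direct window enumeration for tiling.
bruteTiles <- function(seq, window, step) {
  out <- character(0)
  s <- 1L
  while (s + window - 1L <= nchar(seq)) {
    out <- c(out, substr(seq, s, s + window - 1L))
    s <- s + step
  }
  out
}

# A tiny random DmsMatrix for property tests.
randomDms <- function(len = 6L, seed = 1L) {
  set.seed(seed)
  wt <- paste(sample(AbetaFingerprint:::AA20, len, replace = TRUE),
              collapse = "")
  wtv <- strsplit(wt, "")[[1L]]
  r <- matrix(stats::runif(len * 20, 0, 1.5), nrow = len,
              dimnames = list(seq_len(len), AbetaFingerprint:::AA20))
  r[cbind(seq_len(len), match(wtv, colnames(r)))] <- 1
  new("DmsMatrix", antibody = "rand", wildtype = wt,
      positions = seq_len(len), ratios = r, wtMean = 1000)
}
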