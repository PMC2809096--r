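# Independent oracles, deliberately written as plain enumeration /
# textbook DP so they share no code with the package kernels.

# exhaustive single-hit local profile-HMM alignment: enumerate every path
# (entry at any match state, exit from any match state, M/I/D moves) and
# return the best total log-odds score in bits, or -Inf if no path is
# strictly positive. Profile convention matches the package: uniform
# entry log2(1/L), free exit, X scores 0 bits, '*' cannot be emitted.
oracleViterbiLocal <- function(profile, peptide) {
  L <- nrow(profile@matchEmis)
  bg <- profile@background
  mLO <- log2(sweep(profile@matchEmis, 2, bg, "/"))
  iLO <- log2(sweep(profile@insEmis, 2, bg, "/"))
  tr <- log2(profile@trans)
  ch <- strsplit(peptide, "")[[1]]
  n <- length(ch)
  code <- function(a) {
    if (a == "X") return(0L)     # marker handled in em()
    match(a, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  }
  em <- function(mat, k, i) {
    if (ch[i] == "*") return(-Inf)
    if (ch[i] == "X") return(0)
    mat[k, code(ch[i])]
  }
  # value of continuing a path that just emitted residue i at state
  # (type, k); exit allowed from M only
  cont <- function(type, k, i) {
    best <- if (type == "M") 0 else -Inf
    if (type == "M") {
      if (k < L && i < n)
        best <- max(best, tr[k, "MM"] + em(mLO, k + 1, i + 1) +
                      cont("M", k + 1, i + 1))
      if (i < n)
        best <- max(best, tr[k, "MI"] + em(iLO, k, i + 1) +
                      cont("I", k, i + 1))
      if (k < L)
        best <- max(best, tr[k, "MD"] + cont("D", k + 1, i))
    } else if (type == "I") {
      if (k < L && i < n)
        best <- max(best, tr[k, "IM"] + em(mLO, k + 1, i + 1) +
                      cont("M", k + 1, i + 1))
      if (i < n)
        best <- max(best, tr[k, "II"] + em(iLO, k, i + 1) +
                      cont("I", k, i + 1))
    } else {  # D
      if (k < L && i < n)
        best <- max(best, tr[k, "DM"] + em(mLO, k + 1, i + 1) +
                      cont("M", k + 1, i + 1))
      if (k < L)
        best <- max(best, tr[k, "DD"] + cont("D", k + 1, i))
    }
    best
  }
  best <- -Inf
  if (n > 0) {
    for (k in seq_len(L)) {
      for (i in seq_len(n)) {
        s <- -log2(L) + em(mLO, k, i)
        if (is.finite(s)) best <- max(best, s + cont("M", k, i))
      }
    }
  }
  if (is.finite(best) && best > 0) best else -Inf
}

# textbook Gotoh local alignment with affine gaps (full matrices, no
# rolling arrays); gap of length g costs open + g * extend
oracleLocalAlign <- function(qChars, rChars, subst, gapOpen, gapExtend) {
  n <- length(qChars); m <- length(rChars)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gapOpen - gapExtend,
                             E[i + 1, j] - gapExtend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gapOpen - gapExtend,
                             F[i, j + 1] - gapExtend)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + subst[qChars[i], rChars[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  max(H)
}

# random profile with given number of match states (moderately peaked
# emissions so scores are informative but not degenerate)
randomProfile <- function(L, seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cons <- paste(sample(aa, L, replace = TRUE), collapse = "")
  profileHMM(paste0("rand", seed), "GHX",
             consensusEmissions(cons, p = runif(1, 0.4, 0.9)))
}

randomPeptide <- function(len, seed, alphabet = NULL) {
  set.seed(seed)
  if (is.null(alphabet))
    alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
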