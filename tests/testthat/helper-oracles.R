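# Independent oracles used by the test suite.  These deliberately take
# different computational routes from the package code they check.

# Brute-force gapped-motif enumeration: expand.grid over all per-anchor
# candidate positions, then filter on ordering and gap bounds.
oracle_scan <- function(sequence, pattern) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  cand <- lapply(pattern$anchors, function(cls) which(chars %in% cls))
  if (any(lengths(cand) == 0)) return(matrix(integer(0), ncol = length(cand)))
  tuples <- as.matrix(expand.grid(cand, KEEP.OUT.ATTRS = FALSE))
  keep <- rep(TRUE, nrow(tuples))
  k <- length(pattern$anchors)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      gap <- tuples[, i + 1] - tuples[, i] - 1L
      g <- pattern$gaps[[i]]
      keep <- keep & gap >= g[1] & gap <= g[2]
    }
  }
  m <- tuples[keep, , drop = FALSE]
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# random amino-acid sequence (standard alphabet, optional ambiguity letters)
random_seq <- function(n, p_ambig = 0) {
  alph <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
  s <- sample(alph, n, replace = TRUE)
  if (p_ambig > 0) {
    amb <- runif(n) < p_ambig
    s[amb] <- sample(c("X","B","Z","U"), sum(amb), replace = TRUE)
  }
  paste(s, collapse = "")
}

# Mass-action equilibrium solved by bisection on
# g(PL) = (Pt - PL)(La - PL) - Kd*PL over [0, min(Pt, La)].
oracle_fraction_bound <- function(Pt, La, Kd, tol = 1e-16) {
  if (La == 0) return(0)
  g <- function(PL) (Pt - PL) * (La - PL) - Kd * PL
  lo <- 0; hi <- min(Pt, La)
  if (g(hi) == 0) return(hi / Pt)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) < tol * hi) break
  }
  ((lo + hi) / 2) / Pt
}

# Textbook Welch statistic with Satterthwaite degrees of freedom.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Check a compact letter display against its p-value matrix:
# shared letter <=> pair not significant.
cld_consistent <- function(letters_vec, pmat, alpha) {
  n <- length(letters_vec)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                                 strsplit(letters_vec[j], "")[[1]])) > 0
      sig <- !is.na(pmat[i, j]) && pmat[i, j] < alpha
      if (shared == sig) return(FALSE)
    }
  }
  TRUE
}
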