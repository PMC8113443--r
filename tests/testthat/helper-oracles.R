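# Independent oracles, deliberately coded from first principles and kept
# separate from the implementation paths they check.

# Two-sided Fisher exact P by enumeration over all tables with the observed
# margins, using binomial coefficients directly (no dhyper).
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  p_obs <- probs[match(a, xs)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# TMM factors re-implemented directly from the published trim-and-weight
# recipe (reference = column whose 75th-percentile count fraction is closest
# to the mean; doubly trimmed M values; inverse-variance weights; factors
# rescaled to multiply to 1).
oracle_tmm <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  q75 <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j] / lib[j], 0.75), numeric(1))
  ref <- which.min(abs(q75 - mean(q75)))
  one_factor <- function(obs_j) {
    obs <- counts[, obs_j]; nO <- lib[obs_j]
    refc <- counts[, ref]; nR <- lib[ref]
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE) & absE > -1e10
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * abs_trim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- 2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
    if (!is.finite(f)) 1 else f
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# Spearman correlation by explicit rank transform followed by Pearson.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# Paired bootstrap fold changes, plain loops, drawing the identical RNG
# stream (one sample.int(n, n, replace = TRUE) per replicate).
oracle_bootstrap_fc <- function(case_mat, control_mat, n_boot, seed) {
  n <- ncol(case_mat); p <- nrow(case_mat)
  acc <- numeric(p); n_ok <- integer(p)
  set.seed(seed)
  for (k in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    for (i in seq_len(p)) {
      km <- sum(control_mat[i, idx]) / n
      if (km > 0) {
        acc[i] <- acc[i] + (sum(case_mat[i, idx]) / n) / km
        n_ok[i] <- n_ok[i] + 1L
      }
    }
  }
  stats::setNames(ifelse(n_ok > 0, acc / n_ok, NA_real_), rownames(case_mat))
}

# All-pairs brute-force overlap quantification (30%-of-locus rule).
oracle_quantify <- function(reads, loci, min_frac = 0.3) {
  counts <- stats::setNames(numeric(nrow(loci)), loci$id)
  for (j in seq_len(nrow(loci))) {
    for (i in seq_len(nrow(reads))) {
      if (reads$chrom[i] != loci$chrom[j]) next
      if (reads$strand[i] != loci$strand[j]) next
      ov <- min(reads$end[i], loci$end[j]) - max(reads$start[i], loci$start[j])
      if (ov >= min_frac * (loci$end[j] - loci$start[j]))
        counts[j] <- counts[j] + reads$multiplicity[i]
    }
  }
  counts
}

# Ring-scan seed-site count by brute force over every window start.
oracle_ring_count <- function(circ_seq, site) {
  L <- nchar(circ_seq); m <- nchar(site)
  doubled <- paste0(circ_seq, circ_seq)
  sum(vapply(seq_len(L), function(s)
    substr(doubled, s, s + m - 1) == site, logical(1)))
}
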