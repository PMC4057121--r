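# Independent brute-force oracles and small fixture builders.

# geNorm M by the definition, double loop, no shared code with the package.
oracle_m_values <- function(q) {
  g <- ncol(q)
  m <- numeric(g)
  for (j in seq_len(g)) {
    sds <- c()
    for (k in seq_len(g)) {
      if (k == j) next
      a <- log2(q[, j] / q[, k])
      sds <- c(sds, stats::sd(a, na.rm = TRUE))
    }
    m[j] <- mean(sds)
  }
  stats::setNames(m, colnames(q))
}

# BestKeeper consensus by direct rank-and-average enumeration.
oracle_consensus <- function(ct) {
  idx <- exp(rowMeans(log(ct)))
  sdv <- apply(ct, 2, sd)
  cvv <- 100 * sdv / colMeans(ct)
  rv <- apply(ct, 2, function(v) cor(v, idx))
  mr <- (rank(sdv) + rank(cvv) + rank(-rv)) / 3
  list(mean_rank = unname(mr), final_rank = unname(rank(mr, ties.method = "min")))
}

# Random complete Ct table: n samples x g genes, efficiencies near 2.
random_ct_table <- function(n, g, seed) {
  set.seed(seed)
  ct <- matrix(runif(n * g, 18, 32), n, g,
               dimnames = list(paste0("s", seq_len(n)),
                               paste0("g", seq_len(g))))
  eff <- stats::setNames(runif(g, 1.85, 2.1), colnames(ct))
  ct_table(ct, group = rep("all", n), efficiency = eff)
}

# Exact copies in Ct with per-gene offsets: perfectly stable candidates.
shifted_copy_table <- function(base_ct, offsets, efficiency = NULL,
                               group = NULL) {
  g <- length(offsets)
  ct <- sapply(offsets, function(o) base_ct + o)
  dimnames(ct) <- list(paste0("s", seq_along(base_ct)),
                       paste0("g", seq_len(g)))
  if (is.null(group)) group <- rep("all", length(base_ct))
  ct_table(ct, group = group, efficiency = efficiency)
}
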