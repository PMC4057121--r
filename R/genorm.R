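#' Efficiency-corrected relative quantities
#'
#' Converts mean Cts to relative quantities by the comparative Ct method,
#' using each assay's own amplification factor and that gene's lowest Ct
#' (the most concentrated sample) as calibrator:
#' Q = E^(Ct_min - Ct). The calibrator choice only rescales a gene's column
#' and cannot affect ratio-based stability statistics.
#'
#' @param x A [ct_table()].
#' @return Numeric matrix (samples x genes) of quantities in (0, 1], with
#'   per-gene maximum exactly 1; `NA` where the Ct was missing.
#' @export
relative_quantities <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  ct <- x$ct
  allmiss <- colSums(!is.na(ct)) == 0L
  if (any(allmiss))
    stop("gene(s) with no detected Ct: ",
         paste(colnames(ct)[allmiss], collapse = ", "),
         " (exclude undetected genes first)", call. = FALSE)
  cmin <- apply(ct, 2, min, na.rm = TRUE)
  q <- sweep(-sweep(ct, 2, cmin, "-"), 2, log(x$efficiency), "*")
  exp(q)
}

pairwise_log_ratio_sd <- function(lq) {
  g <- ncol(lq)
  v <- matrix(NA_real_, g, g, dimnames = list(colnames(lq), colnames(lq)))
  for (j in seq_len(g - 1)) for (k in (j + 1):g) {
    a <- lq[, j] - lq[, k]
    a <- a[!is.na(a)]
    if (length(a) < 2L)
      stop("fewer than two complete samples for pair ",
           colnames(lq)[j], "/", colnames(lq)[k], call. = FALSE)
    v[j, k] <- v[k, j] <- stats::sd(a)
  }
  v
}

#' geNorm gene-stability values
#'
#' For each gene pair, the pairwise variation is the standard deviation
#' (n - 1 denominator) over samples of the log2 expression ratio; a gene's
#' M value is the mean of its pairwise variations with every other gene.
#' Samples missing either gene of a pair are dropped for that pair only.
#'
#' @param q Relative-quantity matrix from [relative_quantities()] (or a
#'   [ct_table()], converted internally).
#' @return Named numeric vector of M values (lower = more stable).
#' @export
genorm_m_values <- function(q) {
  if (inherits(q, "ct_table")) q <- relative_quantities(q)
  if (ncol(q) < 3L)
    stop("geNorm M needs at least 3 genes", call. = FALSE)
  if (nrow(q) < 2L) stop("need at least 2 samples", call. = FALSE)
  v <- pairwise_log_ratio_sd(log2(q))
  rowMeans(v, na.rm = TRUE)
}

#' geNorm stability analysis with stepwise exclusion
#'
#' Recomputes M values and removes the least stable (highest-M) gene until
#' two remain; those two cannot be separated further and form the
#' recommended pair. Normalization factors over the n most stable genes
#' then give the pairwise variation V(n/n+1); the smallest n whose V falls
#' below the cutoff is the recommended number of reference genes.
#'
#' @param q Relative-quantity matrix or [ct_table()].
#' @param v_cutoff Pairwise-variation threshold below which adding a gene
#'   is unnecessary (default 0.15).
#' @return An object of class `genorm_result`: `m_rounds` (list of named M
#'   vectors per exclusion round), `exclusion_order` (least stable first),
#'   `final_pair`, `stability_order` (most stable first), `ranking` (named
#'   integer vector, 1 = most stable), `v_values` (named by "n/n+1"),
#'   `recommended_n`.
#' @export
genorm <- function(q, v_cutoff = 0.15) {
  if (inherits(q, "ct_table")) q <- relative_quantities(q)
  genes <- colnames(q)
  if (length(genes) < 3L) stop("geNorm needs at least 3 genes", call. = FALSE)
  keep <- genes
  m_rounds <- list()
  exclusion <- character()
  last_m <- NULL
  while (length(keep) > 2L) {
    m <- genorm_m_values(q[, keep, drop = FALSE])
    m_rounds[[length(m_rounds) + 1L]] <- m
    last_m <- m
    # tie at the maximum M: exclude the gene appearing later in input order
    worst <- names(m)[m == max(m)]
    worst <- worst[which.max(match(worst, genes))]
    exclusion <- c(exclusion, worst)
    keep <- setdiff(keep, worst)
  }
  # order the inseparable final pair by M in the last 3-gene round
  pair_m <- last_m[keep]
  final_pair <- keep[order(pair_m, match(keep, genes))]
  stability_order <- c(final_pair, rev(exclusion))
  ranking <- stats::setNames(seq_along(stability_order), stability_order)
  ranking <- ranking[genes]

  v <- v_for_order(q, stability_order)
  below <- which(v < v_cutoff)
  if (length(below)) recommended_n <- unname(below[1]) + 1L
  else {
    recommended_n <- length(genes)
    warning("no V(n/n+1) below ", v_cutoff,
            "; consider using all candidate genes", call. = FALSE)
  }
  structure(list(m_rounds = m_rounds, exclusion_order = exclusion,
                 final_pair = final_pair, stability_order = stability_order,
                 ranking = ranking, v_values = v, v_cutoff = v_cutoff,
                 recommended_n = recommended_n),
            class = "genorm_result")
}

v_for_order <- function(q, stability_order) {
  lq <- log2(q)
  g <- length(stability_order)
  nf_log <- function(n) {
    sub <- lq[, stability_order[seq_len(n)], drop = FALSE]
    rowMeans(sub)                       # log2 of the geometric mean
  }
  v <- numeric(g - 2L)
  names(v) <- paste0(2:(g - 1), "/", 3:g)
  for (n in 2:(g - 1)) {
    d <- nf_log(n) - nf_log(n + 1L)     # NA if any top-(n+1) gene missing
    d <- d[!is.na(d)]
    v[n - 1L] <- stats::sd(d)
  }
  v
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm: recommended pair", paste(x$final_pair, collapse = " + "),
      "| recommended n =", x$recommended_n, "\n")
  cat("stability (most to least):",
      paste(x$stability_order, collapse = " > "), "\n")
  cat("V(n/n+1):",
      paste(sprintf("%s: %.3f", names(x$v_values), x$v_values),
            collapse = ", "), "\n")
  invisible(x)
}
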