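#' Normalize a target gene to reference genes
#'
#' Divides the target's efficiency-corrected relative quantity by the
#' per-sample normalization factor, the geometric mean of the reference
#' genes' quantities. Samples missing the target or any reference are
#' dropped with a warning.
#'
#' @param x A [ct_table()].
#' @param target Gene of interest.
#' @param refs Character vector of reference genes (usually two).
#' @return Named numeric vector of normalized relative expression values.
#' @export
normalize_expression <- function(x, target, refs) {
  stopifnot(inherits(x, "ct_table"), length(refs) >= 1L)
  genes <- c(target, refs)
  q <- relative_quantities(select_genes(x, genes))
  ok <- stats::complete.cases(q)
  if (!all(ok))
    warning(sum(!ok), " sample(s) dropped: missing target or reference Ct")
  q <- q[ok, , drop = FALSE]
  nf <- exp(rowMeans(log(q[, refs, drop = FALSE])))
  q[, target] / nf
}

#' Exact two-sided Mann-Whitney rank-sum test
#'
#' Computes the Mann-Whitney U statistic and a two-sided p-value. When
#' both groups have at most `exact_max` observations and the pooled values
#' carry no ties, the p-value is exact: the null distribution of U is
#' enumerated over all assignments of the pooled ranks to the two groups,
#' and the p-value is the probability of a U at least as far from its null
#' mean as observed. Otherwise a normal approximation with mid-ranks, tie
#' correction and continuity correction is used.
#'
#' @param a,b Numeric vectors, each with at least 2 values (at least 1 for
#'   the approximate path).
#' @param exact_max Largest per-group size for the exact path (default 10).
#' @return List with `u` (the smaller of the two U statistics), `p_value`,
#'   and `method` ("exact" or "normal_approx").
#' @export
rank_sum_test <- function(a, b, exact_max = 10L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L,
            !anyNA(a), !anyNA(b))
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  ua <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  u <- min(ua, ub)
  ties <- anyDuplicated(pooled) > 0L
  mu <- na * nb / 2

  if (!ties && na <= exact_max && nb <= exact_max) {
    combos <- utils::combn(n, na)
    usum <- colSums(matrix(seq_len(n)[combos], nrow = na)) -
      na * (na + 1) / 2
    dev <- abs(ua - mu)
    p <- mean(abs(usum - mu) >= dev - 1e-9)
    return(list(u = u, p_value = p, method = "exact"))
  }
  tie_tab <- table(pooled)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(u = u, p_value = 1, method = "normal_approx"))
  z <- (abs(ua - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(u = u, p_value = p, method = "normal_approx")
}

significance_label <- function(p) {
  if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Compare normalized expression between two groups
#'
#' Normalizes the target to the reference genes, computes the fold change
#' of the treatment group over the control group, and tests the difference
#' with the two-sided Mann-Whitney test. The fold-change group summary is
#' the median by default, consistent with the nonparametric test; the
#' mean-based fold is reported alongside.
#'
#' @inheritParams normalize_expression
#' @param treatment,control Group labels in `x`.
#' @param summary `"median"` (default) or `"mean"`; which fold change is
#'   reported as `fold_change`.
#' @return An object of class `group_comparison`: target, reference pair,
#'   normalized values per group, `fold_change`, `fold_median`,
#'   `fold_mean`, `u_statistic`, `p_value`, `significance` (`"ns"`, `"*"`
#'   p<0.05, `"**"` p<0.01).
#' @export
compare_groups <- function(x, target, refs, treatment, control,
                           summary = c("median", "mean")) {
  summary <- match.arg(summary)
  norm <- normalize_expression(x, target, refs)
  grp <- x$group[match(names(norm), rownames(x$ct))]
  va <- norm[grp == treatment]
  vb <- norm[grp == control]
  if (!length(va) || !length(vb))
    stop("empty group after drops", call. = FALSE)
  fm <- stats::median(va) / stats::median(vb)
  fmean <- mean(va) / mean(vb)
  if (stats::median(vb) == 0 || mean(vb) == 0)
    stop("undefined fold change: zero control summary", call. = FALSE)
  ts <- rank_sum_test(va, vb)
  structure(list(target = target, refs = refs,
                 treatment = treatment, control = control,
                 values_treatment = va, values_control = vb,
                 fold_change = if (summary == "median") fm else fmean,
                 fold_median = fm, fold_mean = fmean,
                 u_statistic = ts$u, p_value = ts$p_value,
                 test_method = ts$method,
                 significance = significance_label(ts$p_value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs refs %s: %s/%s fold %.2f (median; mean %.2f), U = %g, p = %.4g %s\n",
              x$target, paste(x$refs, collapse = "+"),
              x$treatment, x$control, x$fold_median, x$fold_mean,
              x$u_statistic, x$p_value, x$significance))
  invisible(x)
}
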