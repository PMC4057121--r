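#' Model-based (NormFinder-style) stability analysis
#'
#' Decomposes each candidate gene's log2 relative expression into an
#' inter-group component (how far the gene's group means drift apart once
#' per-sample loading is removed) and an intra-group variance, and combines
#' them into a single stability value; lower values mark genes whose
#' expression is least affected by the experimental condition and least
#' noisy within groups.
#'
#' The estimator: (1) each sample's log2-quantity vector is centred by its
#' across-gene mean, removing sample-specific input scaling; (2) per gene
#' and group, the mean and variance of the centred values are computed;
#' (3) the inter-group deviation of each gene (its group mean minus its
#' across-group average) is shrunk toward zero by
#' tau^2 / (tau^2 + s^2_ig / n_g), where tau^2 is the across-gene variance
#' of those deviations within the group; (4) the intra-group variance is
#' corrected for the shared centring term (the across-gene average variance
#' divided by the gene count), with negative estimates clamped to zero;
#' (5) the stability value is the mean over groups of
#' |shrunk deviation| + sqrt(corrected variance / n_g). With a single group
#' the inter-group component is identically zero and genes rank purely by
#' corrected intra-group variance.
#'
#' @param x A [ct_table()] (log2 quantities are derived via
#'   [relative_quantities()]) or a relative-quantity matrix.
#' @param group Group label per sample; defaults to the table's groups.
#'   Pass a single common label for group-free mode.
#' @return An object of class `normfinder_result`: data.frame `stability`
#'   (gene, stability_value, rank), matrices `intergroup` (shrunk
#'   deviations, genes x groups, log2 units), `intragroup_var` (corrected,
#'   log2^2 units), group sizes `n_g`, and `mode` ("grouped" or "single").
#' @export
normfinder <- function(x, group = NULL) {
  if (inherits(x, "ct_table")) {
    if (is.null(group)) group <- x$group
    q <- relative_quantities(x)
  } else q <- x
  stopifnot(!is.null(group), length(group) == nrow(q))
  genes <- colnames(q)
  if (length(genes) < 3L)
    stop("model-based stability needs at least 3 genes", call. = FALSE)

  complete <- stats::complete.cases(q)
  if (!all(complete)) {
    warning(sum(!complete), " sample(s) with missing quantities dropped")
    q <- q[complete, , drop = FALSE]
    group <- group[complete]
  }
  lq <- log2(q)
  grp <- as.character(group)
  labels <- unique(grp)
  n_g <- vapply(labels, function(g) sum(grp == g), integer(1))
  if (any(n_g < 2L))
    stop("every group needs at least 2 samples", call. = FALSE)
  G <- length(genes)

  cent <- lq - rowMeans(lq)                       # remove sample loading
  dbar <- sapply(labels, function(g) colMeans(cent[grp == g, , drop = FALSE]))
  s2 <- sapply(labels, function(g)
    apply(cent[grp == g, , drop = FALSE], 2, stats::var))
  dbar <- matrix(dbar, nrow = G, dimnames = list(genes, labels))
  s2 <- matrix(s2, nrow = G, dimnames = list(genes, labels))

  # centring shares 1/G of the average residual variance across genes
  s2_hat <- sweep(s2, 2, colMeans(s2) / G, "-")
  if (any(s2_hat < 0))
    message("negative corrected variance clamped to 0 for ",
            sum(s2_hat < 0), " gene-group cell(s)")
  s2_hat[s2_hat < 0] <- 0

  if (length(labels) == 1L) {
    z <- matrix(0, G, 1L, dimnames = list(genes, labels))
    mode <- "single"
  } else {
    z_raw <- dbar - rowMeans(dbar)
    tau2 <- pmax(apply(z_raw, 2, stats::var), 0)
    samp_var <- sweep(s2_hat, 2, n_g, "/")
    shrink <- sweep(samp_var, 2, tau2, function(sv, t2)
      ifelse(t2 + sv > 0, t2 / (t2 + sv), 0))
    z <- z_raw * shrink
    mode <- "grouped"
  }
  se <- sqrt(sweep(s2_hat, 2, n_g, "/"))
  stability <- rowMeans(abs(z) + se)
  rank <- rank(stability, ties.method = "first")
  structure(list(stability = data.frame(gene = genes,
                                        stability_value = unname(stability),
                                        rank = unname(rank),
                                        stringsAsFactors = FALSE),
                 intergroup = z, intragroup_var = s2_hat,
                 n_g = n_g, mode = mode),
            class = "normfinder_result")
}

#' Best reference-gene pair under the model-based criterion
#'
#' Scores every gene pair by the stability of the pair's average log2
#' signal: inter-group deviations are averaged, intra-group variances are
#' averaged and quartered (the variance of a two-gene mean), and the two
#' are recombined exactly as for a single gene. A pair whose opposite-sign
#' group shifts cancel can beat any single gene. In single-group mode
#' (no inter-group information) the two lowest individual stability values
#' are returned.
#'
#' @param r A [normfinder()] result.
#' @return List with `pair` (two gene symbols), `stability_value` of the
#'   pair, and `pair_table` (all pairs scored, grouped mode only).
#' @export
normfinder_best_pair <- function(r) {
  stopifnot(inherits(r, "normfinder_result"))
  genes <- r$stability$gene
  if (length(genes) < 2L) stop("need at least 2 genes")
  if (r$mode == "single") {
    message("single-group mode: falling back to the two lowest stability values")
    ord <- order(r$stability$rank)
    pair <- genes[ord[1:2]]
    return(list(pair = pair,
                stability_value = mean(r$stability$stability_value[ord[1:2]]),
                pair_table = NULL))
  }
  idx <- utils::combn(length(genes), 2L)
  score <- apply(idx, 2, function(ij) {
    z <- (r$intergroup[ij[1], ] + r$intergroup[ij[2], ]) / 2
    v <- (r$intragroup_var[ij[1], ] + r$intragroup_var[ij[2], ]) / 4
    mean(abs(z) + sqrt(v / r$n_g))
  })
  best <- which.min(score)
  tab <- data.frame(gene1 = genes[idx[1, ]], gene2 = genes[idx[2, ]],
                    stability_value = score, stringsAsFactors = FALSE)
  list(pair = c(genes[idx[1, best]], genes[idx[2, best]]),
       stability_value = score[best],
       pair_table = tab[order(tab$stability_value), ])
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("model-based stability (", x$mode, " mode, ",
      length(x$n_g), " group(s))\n", sep = "")
  s <- x$stability[order(x$stability$rank), ]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %2d. %-8s %.4f\n", s$rank[i], s$gene[i],
                s$stability_value[i]))
  invisible(x)
}
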