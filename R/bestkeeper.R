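#' BestKeeper index
#'
#' The per-sample geometric mean of the raw Cts of all candidate reference
#' genes. Samples with any missing Ct are dropped (with a warning).
#'
#' @param x A [ct_table()].
#' @return Named numeric vector, one index value per retained sample.
#' @export
bestkeeper_index <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  if (ncol(x$ct) < 2L) stop("index needs at least 2 genes", call. = FALSE)
  ct <- x$ct
  complete <- stats::complete.cases(ct)
  if (!all(complete)) {
    warning(sum(!complete), " incomplete sample(s) dropped from the index")
    ct <- ct[complete, , drop = FALSE]
  }
  if (any(ct <= 0)) stop("invalid Ct: values must be positive", call. = FALSE)
  exp(rowMeans(log(ct)))
}

#' BestKeeper descriptors and mean-of-ranks consensus
#'
#' Per gene, three dispersion/agreement descriptors over the raw Cts:
#' the sample standard deviation (cycles), the coefficient of variation
#' (percent of the mean Ct), and the Pearson correlation with the
#' BestKeeper index. Genes are ranked on each descriptor separately
#' (SD and CV ascending, correlation descending, average ranks on ties)
#' and the mean of the three rankings gives the final rank. Genes with
#' SD > 1.5 cycles are flagged, not removed. Ties in the final ranking are
#' broken in favour of the gene whose three per-measure ranks have the
#' smallest spread (max - min), then by input order.
#'
#' @param x A [ct_table()].
#' @return An object of class `bestkeeper_result`: `descriptors`
#'   (data.frame with gene, ct_sd, ct_cv, r_with_index, rank_sd, rank_cv,
#'   rank_r, mean_rank, final_rank, sd_flag), `index` (per-sample), and
#'   `selected_pair`.
#' @export
bestkeeper <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  ct <- x$ct
  complete <- stats::complete.cases(ct)
  ct <- ct[complete, , drop = FALSE]
  if (nrow(ct) < 3L) stop("need at least 3 complete samples", call. = FALSE)
  genes <- colnames(ct)
  index <- exp(rowMeans(log(ct)))

  sd_ct <- apply(ct, 2, stats::sd)
  cv_ct <- 100 * sd_ct / colMeans(ct)
  r <- vapply(seq_along(genes), function(j) {
    if (sd_ct[j] == 0) {
      warning("zero-variance gene ", genes[j],
              ": correlation with the index undefined", call. = FALSE)
      return(NA_real_)
    }
    stats::cor(ct[, j], index)
  }, numeric(1))

  rankable <- !is.na(r)
  if (sum(rankable) < 2L)
    stop("fewer than 2 rankable genes", call. = FALSE)
  if (any(!rankable))
    message("gene(s) excluded from consensus ranking: ",
            paste(genes[!rankable], collapse = ", "))
  rk <- function(v) {
    out <- rep(NA_real_, length(v))
    out[rankable] <- rank(v[rankable], ties.method = "average")
    out
  }
  cons <- consensus_rank(data.frame(gene = genes,
                                    rank_sd = rk(sd_ct),
                                    rank_cv = rk(cv_ct),
                                    rank_r = rk(-r),   # high positive r best
                                    stringsAsFactors = FALSE))

  structure(list(descriptors = data.frame(gene = genes, ct_sd = unname(sd_ct),
                                          ct_cv = unname(cv_ct),
                                          r_with_index = unname(r),
                                          cons$table[-1],
                                          sd_flag = unname(sd_ct > 1.5),
                                          stringsAsFactors = FALSE),
                 index = index, selected_pair = cons$selected_pair),
            class = "bestkeeper_result")
}

#' Mean-of-ranks consensus over the three BestKeeper measures
#'
#' Averages the three per-measure rankings into a final rank and selects
#' the best pair. A tie in mean rank is broken in favour of the gene whose
#' per-measure ranks have the smallest spread (max - min), i.e. the gene
#' equally stable in all three values; remaining ties fall back to input
#' order.
#'
#' @param per_measure data.frame with columns `gene`, `rank_sd`, `rank_cv`,
#'   `rank_r` (average ranks allowed; `NA` rows are unrankable and
#'   excluded).
#' @return List with `table` (`per_measure` plus `mean_rank` and integer
#'   `final_rank`, ties sharing the lowest rank) and `selected_pair`.
#' @export
consensus_rank <- function(per_measure) {
  stopifnot(all(c("gene", "rank_sd", "rank_cv", "rank_r") %in%
                  names(per_measure)))
  m <- per_measure
  rankable <- !is.na(m$rank_sd) & !is.na(m$rank_cv) & !is.na(m$rank_r)
  if (sum(rankable) < 2L)
    stop("fewer than 2 rankable genes", call. = FALSE)
  m$mean_rank <- (m$rank_sd + m$rank_cv + m$rank_r) / 3
  m$final_rank <- NA_integer_
  m$final_rank[rankable] <- rank(m$mean_rank[rankable], ties.method = "min")
  spread <- pmax(m$rank_sd, m$rank_cv, m$rank_r) -
    pmin(m$rank_sd, m$rank_cv, m$rank_r)
  ord <- order(m$mean_rank, spread, seq_len(nrow(m)), na.last = TRUE)
  ord <- ord[rankable[ord]]
  list(table = m, selected_pair = m$gene[ord[1:2]])
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  d <- x$descriptors[order(x$descriptors$final_rank), ]
  cat("BestKeeper consensus (selected pair:",
      paste(x$selected_pair, collapse = " + "), ")\n")
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %2s. %-8s SD %.2f  CV %.2f%%  r %s%s\n",
                ifelse(is.na(d$final_rank[i]), "-", d$final_rank[i]),
                d$gene[i], d$ct_sd[i], d$ct_cv[i],
                ifelse(is.na(d$r_with_index[i]), "NA",
                       sprintf("%.3f", d$r_with_index[i])),
                ifelse(d$sd_flag[i], "  [SD>1.5]", "")))
  invisible(x)
}
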