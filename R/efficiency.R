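#' Fit amplification efficiency from a dilution series
#'
#' Ordinary least squares of mean Ct on log10(relative concentration); the
#' amplification factor is E = 10^(-1/slope) and percent efficiency is
#' 100 * (E - 1), so a slope of -3.32 cycles per ten-fold dilution
#' corresponds to perfect doubling (100%).
#'
#' @param concentration Relative template concentrations (positive,
#'   dimensionless); at least three distinct values.
#' @param ct Mean Ct at each concentration. Replicates may instead be
#'   supplied via `ct_reps`.
#' @param ct_reps Optional numeric matrix (points x replicates) of raw
#'   replicate Cts, collapsed per point with [collapse_triplicate()] before
#'   fitting; set `collapse = FALSE` to use plain means.
#' @param gene Optional assay label carried through to the result.
#' @param window Percent-efficiency acceptance window, inclusive.
#' @param collapse Apply the triplicate deviation rule to `ct_reps`.
#' @param policy A [qc_policy()] for the collapse step.
#' @return An object of class `efficiency_fit`: list with `gene`, `slope`
#'   (cycles per log10 dilution), `amplification_factor`, `efficiency_pct`,
#'   `r_squared`, `accepted`, `n_points`.
#' @examples
#' d <- 10^-(0:4)
#' fit_efficiency(d, 20 + log(1 / d) / log(2))$efficiency_pct  # 100
#' @export
fit_efficiency <- function(concentration, ct = NULL, ct_reps = NULL,
                           gene = NA_character_, window = c(90, 110),
                           collapse = TRUE, policy = qc_policy()) {
  stopifnot(is.numeric(concentration), all(concentration > 0))
  if (is.null(ct)) {
    if (is.null(ct_reps)) stop("supply ct or ct_reps")
    ct_reps <- as.matrix(ct_reps)
    stopifnot(nrow(ct_reps) == length(concentration))
    ct <- apply(ct_reps, 1, function(v) {
      v <- v[!is.na(v)]
      if (!collapse || length(v) < 2L) return(mean(v))
      r <- collapse_triplicate(v, policy)
      if (r$outcome == "failed") NA_real_ else r$mean_ct
    })
  }
  stopifnot(length(ct) == length(concentration))
  ok <- !is.na(ct)
  if (length(unique(concentration[ok])) < 3L)
    stop("insufficient points: need >= 3 distinct concentrations",
         call. = FALSE)
  fit <- stats::lm(ct[ok] ~ log10(concentration[ok]))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("degenerate dilution series: slope must be negative", call. = FALSE)
  amp <- 10^(-1 / slope)
  eff <- 100 * (amp - 1)
  y <- ct[ok]
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  structure(list(gene = gene, slope = slope,
                 amplification_factor = amp, efficiency_pct = eff,
                 r_squared = r2,
                 accepted = eff >= window[1] && eff <= window[2],
                 n_points = sum(ok)),
            class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("efficiency_fit%s: slope %.4f, E %.3f (%.1f%%), R^2 %.4f, %s\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              x$slope, x$amplification_factor, x$efficiency_pct,
              x$r_squared, if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Read a dilution-series CSV and fit every assay
#'
#' Columns: `gene`, `concentration`, then `ct` or `ct_rep1..3`.
#'
#' @param path CSV path.
#' @inheritParams fit_efficiency
#' @return data.frame with one row per assay: gene, slope, efficiency_pct,
#'   amplification_factor, r_squared, accepted.
#' @export
fit_efficiency_file <- function(path, window = c(90, 110), collapse = TRUE,
                                policy = qc_policy()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "concentration") %in% names(x)))
  fits <- lapply(split(x, x$gene), function(d) {
    if ("ct" %in% names(d))
      f <- fit_efficiency(d$concentration, parse_ct_column(d$ct),
                          gene = d$gene[1], window = window)
    else {
      reps <- as.matrix(d[, grep("^ct_rep", names(d)), drop = FALSE])
      f <- fit_efficiency(d$concentration, ct_reps = reps, gene = d$gene[1],
                          window = window, collapse = collapse,
                          policy = policy)
    }
    data.frame(gene = f$gene, slope = f$slope,
               efficiency_pct = f$efficiency_pct,
               amplification_factor = f$amplification_factor,
               r_squared = f$r_squared, accepted = f$accepted)
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out
}
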