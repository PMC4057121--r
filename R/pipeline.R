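#' Run the full reference-gene workflow
#'
#' Orchestrates QC, detection-based gene exclusion, the three stability
#' analyses on the candidate reference genes, the consensus report, and
#' normalization plus group testing for the genes of interest against each
#' algorithm's recommended pair.
#'
#' Genes of interest share the sample set but are excluded from the
#' stability analyses, keeping condition-responsive genes out of the
#' candidate pool.
#'
#' @param x A [ct_table()], or a long raw triplicate data.frame (as from
#'   [simulate_ct_table()]) collapsed via [ct_table_from_long()].
#' @param genes_of_interest Genes normalized and tested, never used as
#'   stability candidates.
#' @param treatment,control Group labels compared for the genes of
#'   interest; defaults to the first two group labels in the table. Set
#'   `treatment = NULL` to skip the comparison stage.
#' @param efficiency Named amplification factors (only used when `x` is a
#'   raw data.frame).
#' @param v_cutoff geNorm pairwise-variation cutoff (default 0.15).
#' @param policy A [qc_policy()].
#' @param fold_summary Group summary for fold changes, `"median"` or
#'   `"mean"`.
#' @return An object of class `stability_report`: `rankings` (data.frame
#'   gene x geNorm/NormFinder/BestKeeper ranks), `pairs` (per-algorithm
#'   recommended pair), `genorm`, `normfinder`, `bestkeeper` (full
#'   per-algorithm results), `excluded_genes`, `comparisons` (list of
#'   [compare_groups()] results per gene of interest x algorithm), and
#'   `provenance`.
#' @export
run_stability_pipeline <- function(x, genes_of_interest = character(),
                                   treatment = NULL, control = NULL,
                                   efficiency = NULL, v_cutoff = 0.15,
                                   policy = qc_policy(),
                                   fold_summary = c("median", "mean")) {
  fold_summary <- match.arg(fold_summary)
  if (is.data.frame(x)) x <- ct_table_from_long(x, efficiency, policy)
  stopifnot(inherits(x, "ct_table"))

  excl <- exclude_undetected_genes(x, policy)
  tab <- excl$table
  genes_of_interest <- intersect(genes_of_interest, colnames(tab$ct))
  candidates <- setdiff(colnames(tab$ct), genes_of_interest)
  cand_tab <- select_genes(tab, candidates)

  gn <- genorm(cand_tab, v_cutoff = v_cutoff)
  nf <- normfinder(cand_tab)
  nf_pair <- normfinder_best_pair(nf)
  bk <- bestkeeper(cand_tab)

  rankings <- data.frame(
    gene = candidates,
    genorm = unname(gn$ranking[candidates]),
    normfinder = nf$stability$rank[match(candidates, nf$stability$gene)],
    bestkeeper = bk$descriptors$final_rank[match(candidates,
                                                 bk$descriptors$gene)],
    stringsAsFactors = FALSE)
  pairs <- list(genorm = gn$final_pair, normfinder = nf_pair$pair,
                bestkeeper = bk$selected_pair)

  if (is.null(treatment) && length(genes_of_interest)) {
    grps <- unique(tab$group)
    if (length(grps) >= 2L) { treatment <- grps[1]; control <- grps[2] }
  }
  comparisons <- list()
  if (!is.null(treatment) && length(genes_of_interest)) {
    for (goi in genes_of_interest) for (alg in names(pairs)) {
      comparisons[[paste(goi, alg, sep = ".")]] <-
        compare_groups(tab, goi, pairs[[alg]], treatment, control,
                       summary = fold_summary)
    }
  }
  structure(list(rankings = rankings, pairs = pairs,
                 recommended_n = gn$recommended_n,
                 genorm = gn, normfinder = nf, normfinder_pair = nf_pair,
                 bestkeeper = bk, excluded_genes = excl$excluded,
                 comparisons = comparisons,
                 provenance = list(
                   package_version = as.character(utils::packageVersion("refstab")),
                   n_samples = nrow(tab$ct), candidates = candidates,
                   genes_of_interest = genes_of_interest,
                   v_cutoff = v_cutoff, fold_summary = fold_summary)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, top = 4L, ...) {
  cat("Reference-gene stability report\n")
  if (length(x$excluded_genes))
    cat("excluded below detection:",
        paste(x$excluded_genes, collapse = ", "), "\n")
  r <- x$rankings
  mark <- function(v) ifelse(!is.na(v) & v <= top, sprintf("[%d]", v),
                             sprintf(" %s ", v))
  cat(sprintf("%-8s %8s %10s %10s\n", "gene", "geNorm", "NormFinder",
              "BestKeeper"))
  for (i in order(r$genorm))
    cat(sprintf("%-8s %8s %10s %10s\n", r$gene[i], mark(r$genorm)[i],
                mark(r$normfinder)[i], mark(r$bestkeeper)[i]))
  cat("recommended pairs: geNorm", paste(x$pairs$genorm, collapse = "+"),
      "| NormFinder", paste(x$pairs$normfinder, collapse = "+"),
      "| BestKeeper", paste(x$pairs$bestkeeper, collapse = "+"), "\n")
  cat("geNorm recommended gene count:", x$recommended_n, "\n")
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

#' Serialize a stability report to JSON
#'
#' @param x A [run_stability_pipeline()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(x, path) {
  stopifnot(inherits(x, "stability_report"))
  payload <- list(
    rankings = x$rankings,
    pairs = x$pairs,
    recommended_n = x$recommended_n,
    v_values = as.list(x$genorm$v_values),
    excluded_genes = x$excluded_genes,
    comparisons = lapply(x$comparisons, function(cmp)
      list(target = cmp$target, refs = cmp$refs,
           fold_median = cmp$fold_median, fold_mean = cmp$fold_mean,
           u_statistic = cmp$u_statistic, p_value = cmp$p_value,
           significance = cmp$significance)),
    provenance = x$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
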