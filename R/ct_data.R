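#' Ct quality-control policy
#'
#' @param triplicate_tolerance Maximum allowed deviation, in cycles, of one
#'   technical replicate from the other two before it is excluded.
#' @param max_cycles Number of PCR cycles run; Ct values at or beyond this
#'   are treated as not detected.
#' @param detection_exclusion_fraction Fraction of samples that may be
#'   undetected before a gene is excluded from analysis. The default 0 drops
#'   a gene as soon as any sample fails to amplify within `max_cycles`.
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(triplicate_tolerance = 0.5, max_cycles = 40,
                      detection_exclusion_fraction = 0) {
  stopifnot(triplicate_tolerance > 0, max_cycles > 0,
            detection_exclusion_fraction >= 0,
            detection_exclusion_fraction <= 1)
  structure(list(triplicate_tolerance = triplicate_tolerance,
                 max_cycles = max_cycles,
                 detection_exclusion_fraction = detection_exclusion_fraction),
            class = "qc_policy")
}

#' Collapse a technical triplicate to a mean Ct
#'
#' Triplicates are averaged; if one of the three Ct values deviates from
#' each of the other two by more than the tolerance while those two agree
#' within it, the outlier is excluded and the concordant pair is averaged.
#' If no two values agree within the tolerance the record fails and the
#' well set must be re-run.
#'
#' @param cts Numeric vector of up to three replicate Ct values; `NA`
#'   marks a replicate that did not amplify. At least two values required.
#' @param policy A [qc_policy()].
#' @return List with `outcome` (`"accepted"`, `"replicate_dropped"` or
#'   `"failed"`), `mean_ct` (`NA` when failed) and `dropped_index` (index
#'   into `cts` of the excluded replicate, or `NA`).
#' @export
collapse_triplicate <- function(cts, policy = qc_policy()) {
  present <- which(!is.na(cts))
  if (length(present) < 2L)
    stop("insufficient replicates: need at least two Ct values", call. = FALSE)
  tol <- policy$triplicate_tolerance
  v <- cts[present]
  res <- function(outcome, mean_ct = NA_real_, dropped = NA_integer_)
    list(outcome = outcome, mean_ct = mean_ct, dropped_index = dropped)
  if (length(v) == 2L) {
    if (abs(v[1] - v[2]) <= tol) return(res("accepted", mean(v)))
    return(res("failed"))
  }
  gaps <- abs(c(v[1] - v[2], v[1] - v[3], v[2] - v[3]))
  if (all(gaps <= tol)) return(res("accepted", mean(v)))
  for (i in 1:3) {
    others <- v[-i]
    if (abs(others[1] - others[2]) <= tol && all(abs(v[i] - others) > tol))
      return(res("replicate_dropped", mean(others), present[i]))
  }
  res("failed")
}

#' Construct a mean-Ct table
#'
#' The central container of the workflow: mean Ct per sample and gene, with
#' group (and optional tissue) labels per sample and an amplification
#' factor per gene. Missing entries mark assays that did not amplify.
#'
#' @param ct Numeric matrix, samples in rows and genes in columns, with row
#'   and column names; `NA` for not detected.
#' @param group Character/factor of group labels, one per sample.
#' @param efficiency Named numeric of per-gene amplification factors (fold
#'   amplification per cycle; 2 means 100% efficiency). Values must lie in
#'   (1, 2.2]. Default 2 for every gene.
#' @param tissue Optional per-sample tissue labels.
#' @param max_cycles Upper bound for valid Ct values.
#' @param undetected Optional logical matrix marking entries where the
#'   assay never crossed the detection threshold. Defaults to the missing
#'   entries of `ct`; the distinction matters when an entry is missing
#'   because its technical triplicate failed QC rather than because the
#'   gene was below detection (see [exclude_undetected_genes()]).
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(ct, group, efficiency = NULL, tissue = NULL,
                     max_cycles = 40, undetected = NULL) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("ct matrix needs sample rownames and gene colnames")
  if (anyDuplicated(rownames(ct))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(ct))) stop("duplicate gene symbols")
  if (any(ct <= 0 | ct > max_cycles, na.rm = TRUE))
    stop("Ct values must lie in (0, ", max_cycles, "]")
  if (length(group) != nrow(ct)) stop("one group label per sample required")
  if (is.null(efficiency))
    efficiency <- stats::setNames(rep(2, ncol(ct)), colnames(ct))
  if (is.null(names(efficiency)) ||
      !all(colnames(ct) %in% names(efficiency)))
    stop("efficiency must be named for every gene")
  efficiency <- efficiency[colnames(ct)]
  if (any(efficiency <= 1 | efficiency > 2.2))
    stop("amplification factors must lie in (1, 2.2]")
  if (!is.null(tissue) && length(tissue) != nrow(ct))
    stop("one tissue label per sample required")
  if (is.null(undetected)) undetected <- is.na(ct)
  undetected <- as.matrix(undetected)
  stopifnot(identical(dim(undetected), dim(ct)))
  dimnames(undetected) <- dimnames(ct)
  structure(list(ct = ct, group = as.character(group),
                 undetected = undetected,
                 efficiency = efficiency,
                 tissue = if (is.null(tissue)) NULL else as.character(tissue),
                 max_cycles = max_cycles),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat("ct_table:", nrow(x$ct), "samples x", ncol(x$ct), "genes\n")
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$group)),
                               table(x$group)), collapse = ", "), "\n")
  cat("missing entries:", sum(is.na(x$ct)), "\n")
  invisible(x)
}

#' Drop genes expressed below the detection limit
#'
#' A gene is removed when the fraction of its samples that are undetected
#' (no amplification within `max_cycles`) exceeds the policy's
#' `detection_exclusion_fraction`. Entries that are missing only because
#' their technical triplicate failed QC do not count as undetected — a
#' failed well set calls for a repeat run, not a detection-limit
#' exclusion. Retained values are never altered.
#'
#' @param x A [ct_table()].
#' @param policy A [qc_policy()].
#' @return List with `table` (the filtered `ct_table`) and `excluded`
#'   (character vector of removed genes).
#' @export
exclude_undetected_genes <- function(x, policy = qc_policy()) {
  stopifnot(inherits(x, "ct_table"))
  undet <- x$undetected |
    (!is.na(x$ct) & x$ct >= policy$max_cycles)
  frac <- colMeans(undet)
  drop <- names(frac)[frac > policy$detection_exclusion_fraction]
  keep <- setdiff(colnames(x$ct), drop)
  if (length(keep) == 0L)
    stop("all genes excluded: every assay below detection", call. = FALSE)
  list(table = select_genes(x, keep), excluded = drop)
}

#' Subset a ct_table to selected genes
#' @param x A [ct_table()].
#' @param genes Gene symbols to keep.
#' @return A `ct_table` restricted to `genes`.
#' @export
select_genes <- function(x, genes) {
  stopifnot(inherits(x, "ct_table"))
  miss <- setdiff(genes, colnames(x$ct))
  if (length(miss)) stop("genes not in table: ", paste(miss, collapse = ", "))
  out <- x
  out$ct <- x$ct[, genes, drop = FALSE]
  out$undetected <- x$undetected[, genes, drop = FALSE]
  out$efficiency <- x$efficiency[genes]
  out
}

parse_ct_column <- function(txt, what = "ct") {
  txt <- trimws(as.character(txt))
  out <- rep(NA_real_, length(txt))
  nd <- is.na(txt) | txt == "" | toupper(txt) == "ND"
  num <- suppressWarnings(as.numeric(txt))
  bad <- which(!nd & is.na(num))
  if (length(bad))
    stop("non-numeric ", what, " value '", txt[bad[1]], "' at data row ",
         bad[1], " (use 'ND' for no amplification)", call. = FALSE)
  out[!nd] <- num[!nd]
  out
}

#' Read a Ct table from CSV/TSV
#'
#' Canonical long format: columns `sample`, `group`, optional `tissue`,
#' `gene`, then either a single `ct` column, columns `ct_rep1..ct_rep3`, or
#' a `replicate` column with one row per technical replicate. Replicate
#' rows are collapsed with [collapse_triplicate()]; failed well sets become
#' missing entries (with a warning). Wide format (one column per gene after
#' `sample`/`group`/`tissue`) is accepted on read only. The string `"ND"`
#' marks no amplification.
#'
#' @param path File path; tab- or comma-separated decided by extension.
#' @param efficiency Optional named amplification factors per gene
#'   (default 2 for all).
#' @param policy A [qc_policy()].
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, efficiency = NULL, policy = qc_policy()) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  if (!"sample" %in% names(raw)) stop("missing 'sample' column")
  if (!"group" %in% names(raw)) stop("missing 'group' column")
  has_tissue <- "tissue" %in% names(raw)

  if (!"gene" %in% names(raw)) {               # wide format
    genecols <- setdiff(names(raw), c("sample", "group", "tissue"))
    if (anyDuplicated(raw$sample)) stop("duplicate sample rows in wide file")
    ct <- sapply(genecols, function(g) parse_ct_column(raw[[g]], g))
    ct <- matrix(ct, nrow = nrow(raw),
                 dimnames = list(raw$sample, genecols))
    return(ct_table(ct, raw$group, efficiency,
                    tissue = if (has_tissue) raw$tissue else NULL,
                    max_cycles = policy$max_cycles))
  }

  if ("replicate" %in% names(raw)) {
    key <- paste(raw$sample, raw$gene, raw$replicate, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (sample, gene, replicate) at data row ",
           which(duplicated(key))[1], call. = FALSE)
    raw$ct <- parse_ct_column(raw$ct)
  } else if ("ct_rep1" %in% names(raw)) {
    reps <- paste0("ct_rep", 1:3)
    reps <- reps[reps %in% names(raw)]
    wide <- raw
    m <- matrix(sapply(reps, function(cn) parse_ct_column(wide[[cn]], cn)),
                nrow = nrow(wide))
    raw <- wide[rep(seq_len(nrow(wide)), each = ncol(m)),
                setdiff(names(wide), reps), drop = FALSE]
    raw$replicate <- rep(seq_len(ncol(m)), nrow(wide))
    raw$ct <- as.vector(t(m))
  } else if ("ct" %in% names(raw)) {
    key <- paste(raw$sample, raw$gene, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (sample, gene) at data row ",
           which(duplicated(key))[1], call. = FALSE)
    raw$ct <- parse_ct_column(raw$ct)
  } else stop("no ct, ct_rep1..3 or replicate columns found")

  ct_table_from_long(raw, efficiency, policy)
}

collapse_replicate_rows <- function(raw, policy) {
  key <- paste(raw$sample, raw$gene, sep = "\r")
  idx <- split(seq_len(nrow(raw)), key)
  rows <- lapply(idx, function(ii) {
    r1 <- raw[ii[1], , drop = FALSE]
    v <- raw$.ct[ii]
    r1$.undet <- FALSE
    if (all(is.na(v))) {
      r1$.ct <- NA_real_
      r1$.undet <- TRUE                  # never amplified, vs QC failure
    } else if (sum(!is.na(v)) == 1L) {
      r1$.ct <- v[!is.na(v)]
    } else {
      cc <- collapse_triplicate(v, policy)
      r1$.ct <- if (cc$outcome == "failed") NA_real_ else cc$mean_ct
      if (cc$outcome == "failed")
        warning("discordant triplicate for ", r1$sample, "/", r1$gene,
                " set to missing", call. = FALSE)
    }
    r1
  })
  out <- do.call(rbind, rows)
  out[order(match(out$sample, unique(raw$sample)),
            match(out$gene, unique(raw$gene))), , drop = FALSE]
}

#' Build a ct_table from a long data.frame
#'
#' In-memory counterpart of [read_ct_table()] for long-format data with
#' columns `sample`, `group`, `gene`, `ct` and optionally `replicate` and
#' `tissue`. Replicate rows are collapsed with [collapse_triplicate()];
#' failed well sets and `NA` Cts become missing entries.
#'
#' @param df Long-format data.frame.
#' @param efficiency Optional named amplification factors per gene.
#' @param policy A [qc_policy()].
#' @return A [ct_table()].
#' @export
ct_table_from_long <- function(df, efficiency = NULL, policy = qc_policy()) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(df)))
  df$.ct <- as.numeric(df$ct)
  if ("replicate" %in% names(df)) df <- collapse_replicate_rows(df, policy)
  if (is.null(df$.undet)) df$.undet <- is.na(df$.ct)
  samples <- unique(df$sample)
  genes <- unique(df$gene)
  ct <- matrix(NA_real_, length(samples), length(genes),
               dimnames = list(samples, genes))
  idx <- cbind(match(df$sample, samples), match(df$gene, genes))
  ct[idx] <- df$.ct
  undet <- matrix(TRUE, length(samples), length(genes))
  undet[idx] <- df$.undet
  meta <- df[!duplicated(df$sample), , drop = FALSE]
  meta <- meta[match(samples, meta$sample), ]
  ct_table(ct, meta$group, efficiency,
           tissue = if ("tissue" %in% names(df)) meta$tissue else NULL,
           max_cycles = policy$max_cycles, undetected = undet)
}

#' Write a Ct table as long-format CSV
#'
#' Values are written with 17 significant digits so that write-then-read
#' reproduces every Ct bit for bit; missing entries are written as `"ND"`.
#'
#' @param x A [ct_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  long <- expand.grid(sample = rownames(x$ct), gene = colnames(x$ct),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long <- long[order(match(long$sample, rownames(x$ct))), ]
  long$group <- x$group[match(long$sample, rownames(x$ct))]
  if (!is.null(x$tissue))
    long$tissue <- x$tissue[match(long$sample, rownames(x$ct))]
  v <- x$ct[cbind(long$sample, long$gene)]
  long$ct <- ifelse(is.na(v), "ND", sprintf("%.17g", v))
  cols <- c("sample", "group", if (!is.null(x$tissue)) "tissue", "gene", "ct")
  utils::write.csv(long[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
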