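#' Primer-panel acceptance criteria
#'
#' Bundles the computable primer-design and assay-acceptance rules used to
#' screen a candidate reference-gene panel: primer length bounds, GC-content
#' bounds, a maximum amplicon length, and the amplification-efficiency
#' acceptance window. The intended melting temperature is carried as metadata
#' only; no Tm model is applied.
#'
#' @param min_len,max_len Primer length bounds in nucleotides.
#' @param min_gc,max_gc GC-content bounds in percent.
#' @param max_amplicon Amplicons must be shorter than this many base pairs
#'   (strict upper bound).
#' @param efficiency_window Numeric length-2, the percent-efficiency
#'   acceptance window, inclusive at both ends.
#' @param target_tm_c Intended primer melting temperature in Celsius
#'   (informational only).
#' @return An object of class `panel_criteria`.
#' @export
panel_criteria <- function(min_len = 15L, max_len = 25L,
                           min_gc = 40, max_gc = 70,
                           max_amplicon = 250L,
                           efficiency_window = c(90, 110),
                           target_tm_c = 58) {
  stopifnot(min_len <= max_len, min_gc <= max_gc,
            length(efficiency_window) == 2L,
            efficiency_window[1] <= efficiency_window[2])
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_gc = min_gc, max_gc = max_gc,
                 max_amplicon = as.integer(max_amplicon),
                 efficiency_window = as.numeric(efficiency_window),
                 target_tm_c = target_tm_c),
            class = "panel_criteria")
}

assert_dna <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("invalid sequence: empty", call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop("invalid sequence: characters other than A/C/G/T in '", seq, "'",
         call. = FALSE)
  invisible(seq)
}

#' GC content of a primer sequence
#'
#' @param seq A single uppercase A/C/G/T string.
#' @return Percent of bases that are G or C, in \[0, 100\].
#' @examples
#' gc_content("CGAAAGCATTTGCCAAGAAT")  # 40
#' @export
gc_content <- function(seq) {
  assert_dna(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

#' A candidate primer pair
#'
#' @param gene_symbol Gene symbol, unique within a panel.
#' @param forward_seq,reverse_seq Primer sequences, uppercase A/C/G/T.
#' @param amplicon_len_range Integer length-2 (low, high) amplicon length in
#'   bp; a single value is recycled.
#' @param genomic_bp Optional product size on the genomic level, bp.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(gene_symbol, forward_seq, reverse_seq,
                        amplicon_len_range, genomic_bp = NA_integer_) {
  assert_dna(forward_seq)
  assert_dna(reverse_seq)
  if (length(amplicon_len_range) == 1L)
    amplicon_len_range <- rep(amplicon_len_range, 2L)
  amplicon_len_range <- as.integer(amplicon_len_range)
  stopifnot(length(gene_symbol) == 1L, nzchar(gene_symbol),
            amplicon_len_range[1] <= amplicon_len_range[2])
  structure(list(gene_symbol = gene_symbol,
                 forward_seq = forward_seq, reverse_seq = reverse_seq,
                 amplicon_len_range = amplicon_len_range,
                 genomic_bp = as.integer(genomic_bp)),
            class = "primer_pair")
}

#' Check a primer pair against panel criteria
#'
#' Applies the computable design rules to both primers and the amplicon.
#' The amplicon check uses the upper end of the printed length range and
#' requires it to be strictly below `max_amplicon`.
#'
#' @param pair A [primer_pair()].
#' @param criteria A [panel_criteria()].
#' @return Character vector of violated-rule identifiers (empty if the pair
#'   passes). Identifiers are `forward_too_short`, `forward_too_long`,
#'   `forward_gc_low`, `forward_gc_high`, the `reverse_*` counterparts, and
#'   `amplicon_too_long`.
#' @export
check_primer <- function(pair, criteria = panel_criteria()) {
  stopifnot(inherits(pair, "primer_pair"), inherits(criteria, "panel_criteria"))
  out <- character()
  for (side in c("forward", "reverse")) {
    s <- pair[[paste0(side, "_seq")]]
    n <- nchar(s)
    gc <- gc_content(s)
    if (n < criteria$min_len) out <- c(out, paste0(side, "_too_short"))
    if (n > criteria$max_len) out <- c(out, paste0(side, "_too_long"))
    if (gc < criteria$min_gc) out <- c(out, paste0(side, "_gc_low"))
    if (gc > criteria$max_gc) out <- c(out, paste0(side, "_gc_high"))
  }
  if (pair$amplicon_len_range[2] >= criteria$max_amplicon)
    out <- c(out, "amplicon_too_long")
  out
}

#' Read the packaged candidate primer panel
#'
#' Columns: `gene`, `accession`, `fwd`, `rev`, `amplicon_lo`, `amplicon_hi`,
#' `genomic_bp`.
#'
#' @param path CSV path; defaults to the fixture shipped with the package
#'   (14 pan-avian candidate reference genes).
#' @return A data.frame, one row per primer pair.
#' @export
read_primer_panel <- function(path = system.file("extdata", "panel_table1.csv",
                                                 package = "refstab")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "fwd", "rev", "amplicon_lo", "amplicon_hi")
  if (!all(need %in% names(x)))
    stop("panel file lacks columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  if (anyDuplicated(x$gene)) stop("duplicate gene symbols in panel")
  x
}

#' Coerce one panel row to a primer_pair
#' @param panel A data.frame from [read_primer_panel()].
#' @param gene Gene symbol to extract.
#' @return A [primer_pair()].
#' @export
panel_primer_pair <- function(panel, gene) {
  i <- match(gene, panel$gene)
  if (is.na(i)) stop("gene not in panel: ", gene)
  primer_pair(panel$gene[i], panel$fwd[i], panel$rev[i],
              c(panel$amplicon_lo[i], panel$amplicon_hi[i]),
              panel$genomic_bp[i])
}

#' Validate every pair in a panel
#' @inheritParams panel_primer_pair
#' @param criteria A [panel_criteria()].
#' @return data.frame with columns `gene` and `violations` (comma-separated,
#'   empty string when the pair passes).
#' @export
validate_panel <- function(panel, criteria = panel_criteria()) {
  v <- vapply(panel$gene, function(g)
    paste(check_primer(panel_primer_pair(panel, g), criteria), collapse = ","),
    character(1))
  data.frame(gene = panel$gene, violations = unname(v),
             stringsAsFactors = FALSE)
}

#' Read the per-species assay screen
#'
#' Long-format table of assay status per species and gene. Status codes:
#' `measured` (efficiency determined, percent in `efficiency_pct`), `nt`
#' (primer not tested), `nw` (primer tested but not working), `nd`
#' (efficiency not tested). Codes are kept as codes, never coerced to
#' numbers.
#'
#' @param path CSV path; defaults to the packaged nine-species screen.
#' @return data.frame with columns `species`, `gene`, `status`,
#'   `efficiency_pct`.
#' @export
read_assay_screen <- function(path = system.file("extdata", "screen_table2.csv",
                                                 package = "refstab")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(efficiency_pct = "numeric"))
  bad <- setdiff(unique(x$status), c("measured", "nt", "nw", "nd"))
  if (length(bad)) stop("unknown status codes: ", paste(bad, collapse = ", "))
  if (any(x$status == "measured" &
          (is.na(x$efficiency_pct) | x$efficiency_pct <= 0)))
    stop("measured assays must carry a positive percent efficiency")
  if (any(x$status != "measured" & !is.na(x$efficiency_pct)))
    stop("non-measured assays must not carry an efficiency")
  x
}

#' Count established assays for one species
#'
#' An assay is established when its measured efficiency lies inside the
#' acceptance window (inclusive at both ends); untested, not-working and
#' efficiency-untested assays never count.
#'
#' @param screens data.frame from [read_assay_screen()].
#' @param species Species identifier present in `screens`.
#' @param criteria A [panel_criteria()] supplying `efficiency_window`.
#' @return Integer count.
#' @export
count_established <- function(screens, species, criteria = panel_criteria()) {
  if (!species %in% screens$species) stop("unknown species: ", species)
  s <- screens[screens$species == species & screens$status == "measured", ]
  w <- criteria$efficiency_window
  sum(s$efficiency_pct >= w[1] & s$efficiency_pct <= w[2])
}

#' Export panel primers as FASTA
#'
#' Two records per gene with ids `<gene>_F` and `<gene>_R`.
#'
#' @inheritParams panel_primer_pair
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_primer_fasta <- function(panel, path) {
  seqs <- c(rbind(panel$fwd, panel$rev))
  ids <- c(rbind(paste0(panel$gene, "_F"), paste0(panel$gene, "_R")))
  x <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
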