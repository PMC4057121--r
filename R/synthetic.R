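#' Simulation configuration for synthetic Ct data
#'
#' Describes a qPCR study design: per-gene baselines and assay properties,
#' experimental groups with per-gene log2 fold effects, and the noise
#' structure. Group effects are specified in log2 expression units and
#' converted to cycles through each gene's own amplification factor, so a
#' +1 log2 upregulation lowers Ct by 1 / log2(E) cycles.
#'
#' @param genes data.frame with columns `gene`, `baseline_ct` (cycles at
#'   calibrator input), `factor` (amplification factor per cycle),
#'   `noise_sd` (per-sample biological/technical SD, cycles).
#' @param groups data.frame with columns `label` and `n`.
#' @param fold_effect Numeric matrix (genes x groups, dimnames required) of
#'   log2 fold effects relative to baseline; default all zero.
#' @param sample_scaling_sd SD in cycles of the per-sample RNA-input shift
#'   applied to every gene of a sample.
#' @param triplicate_sd SD in cycles of technical replicate noise.
#' @param outlier_rate Probability that a well set has one replicate
#'   displaced by 0.6-3.0 cycles (guaranteed to trip the 0.5-cycle QC
#'   rule).
#' @param max_cycles Detection limit; simulated Cts beyond it are reported
#'   as missing, as a real instrument would.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genes, groups, fold_effect = NULL,
                       sample_scaling_sd = 0, triplicate_sd = 0,
                       outlier_rate = 0, max_cycles = 40) {
  stopifnot(all(c("gene", "baseline_ct", "factor", "noise_sd") %in%
                  names(genes)),
            all(c("label", "n") %in% names(groups)),
            all(groups$n >= 1), all(genes$noise_sd >= 0),
            sample_scaling_sd >= 0, triplicate_sd >= 0,
            outlier_rate >= 0, outlier_rate < 1)
  if (is.null(fold_effect))
    fold_effect <- matrix(0, nrow(genes), nrow(groups),
                          dimnames = list(genes$gene, groups$label))
  stopifnot(identical(rownames(fold_effect), genes$gene),
            identical(colnames(fold_effect), groups$label))
  structure(list(genes = genes, groups = groups, fold_effect = fold_effect,
                 sample_scaling_sd = sample_scaling_sd,
                 triplicate_sd = triplicate_sd, outlier_rate = outlier_rate,
                 max_cycles = max_cycles),
            class = "sim_config")
}

#' Simulate a raw triplicate Ct table
#'
#' Generates Ct = baseline - fold_effect / log2(factor) + sample shift +
#' per-sample gene noise + replicate noise, in triplicate, with optional
#' displaced-replicate outliers. Cts beyond the detection limit are
#' reported as missing. Fully reproducible for a given seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param n_replicates Technical replicates per well set (default 3).
#' @return Long data.frame with columns `sample`, `group`, `gene`,
#'   `replicate`, `ct`, suitable for [ct_table_from_long()].
#' @export
simulate_ct_table <- function(config, seed = 1L, n_replicates = 3L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  g <- config$genes
  out <- list()
  for (gi in seq_len(nrow(config$groups))) {
    glab <- config$groups$label[gi]
    for (si in seq_len(config$groups$n[gi])) {
      sample_id <- sprintf("%s_%02d", glab, si)
      shift <- stats::rnorm(1, 0, config$sample_scaling_sd)
      mu <- g$baseline_ct - config$fold_effect[, gi] / log2(g$factor) +
        shift + stats::rnorm(nrow(g), 0, g$noise_sd)
      for (ri in seq_len(nrow(g))) {
        ct <- mu[ri] + stats::rnorm(n_replicates, 0, config$triplicate_sd)
        if (stats::runif(1) < config$outlier_rate) {
          k <- sample.int(n_replicates, 1)
          ct[k] <- ct[k] + sample(c(-1, 1), 1) * stats::runif(1, 0.6, 3.0)
        }
        out[[length(out) + 1L]] <- data.frame(
          sample = sample_id, group = glab, gene = g$gene[ri],
          replicate = seq_len(n_replicates), ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res$ct[res$ct >= config$max_cycles] <- NA_real_
  rownames(res) <- NULL
  res
}

#' Simulate a dilution series
#'
#' Ct at relative concentration d is baseline + log(1/d) / log(factor) +
#' noise, i.e. a ten-fold series with factor 2 steps by 3.32 cycles per
#' decade.
#'
#' @param gene Assay label.
#' @param factor True amplification factor (> 1).
#' @param n_points Number of dilution points (>= 3).
#' @param step Dilution step between points (default 10-fold).
#' @param noise_sd SD in cycles added to each well.
#' @param baseline_ct Ct of the undiluted sample.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @param n_replicates Wells per dilution point; with more than one,
#'   columns `ct_rep1..n` are returned instead of `ct`.
#' @return data.frame with columns `gene`, `concentration` and `ct` (or
#'   `ct_rep*`).
#' @export
simulate_dilution_series <- function(gene, factor, n_points = 5L, step = 10,
                                     noise_sd = 0, baseline_ct = 20,
                                     seed = 1L, n_replicates = 1L) {
  stopifnot(factor > 1, n_points >= 3L, n_replicates >= 1L)
  conc <- step^-(seq_len(n_points) - 1L)
  ct <- baseline_ct + log(1 / conc) / log(factor)
  if (noise_sd > 0) set.seed(seed)
  out <- data.frame(gene = gene, concentration = conc,
                    stringsAsFactors = FALSE)
  if (n_replicates == 1L) {
    out$ct <- ct + if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else 0
  } else {
    for (r in seq_len(n_replicates))
      out[[paste0("ct_rep", r)]] <-
        ct + if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else 0
  }
  out
}

#' Song-experiment preset
#'
#' A synthetic Area X singing experiment: 5 singing and 7 silent adult
#' male zebra finches, nine stable candidate reference genes plus the
#' immediate early genes EGR1 and CFOS with a +3 log2 (8-fold) singing
#' effect and FOXP2 with no effect, in triplicate. Candidate-gene
#' amplification factors follow the zebra-finch assay screen shipped with
#' the package. Per-sample RNA-input scaling (SD 1.6 cycles) dominates the
#' variance, so raw per-gene Ct SDs exceed 1.5 cycles as observed in
#' microbiopsy material; residual per-gene noise is 0.15 cycles and
#' triplicate repeatability 0.08 cycles.
#'
#' @param seed Integer seed.
#' @param include_undetected Also simulate GUSB far above the detection
#'   limit (reported as missing), exercising detection-based gene
#'   exclusion; off by default, giving 12 samples x 12 genes.
#' @return List with `raw` (long triplicate data.frame), `config` (the
#'   [sim_config()]), `efficiency` (named amplification factors),
#'   `genes_of_interest`, `treatment`, `control`.
#' @export
preset_song_dataset <- function(seed = 1L, include_undetected = FALSE) {
  screen <- utils::read.csv(system.file("extdata", "song_screen_genes.csv",
                                        package = "refstab"),
                            stringsAsFactors = FALSE)
  eff <- stats::setNames(1 + screen$efficiency_pct / 100, screen$gene)
  refs <- data.frame(
    gene = c("18S", "HMBS", "HPRT", "PGK1", "RPS7",
             "SDHA", "TFRC", "VIM", "YWHAZ"),
    baseline_ct = c(8, 26, 27, 24, 23, 25, 26, 24, 23),
    stringsAsFactors = FALSE)
  refs$factor <- unname(eff[refs$gene])
  goi <- data.frame(gene = c("EGR1", "CFOS", "FOXP2"),
                    baseline_ct = c(26, 27, 27),
                    factor = 2.0, stringsAsFactors = FALSE)
  genes <- rbind(refs, goi)
  if (include_undetected)
    genes <- rbind(genes, data.frame(gene = "GUSB", baseline_ct = 44,
                                     factor = unname(eff["GUSB"])))
  genes$noise_sd <- 0.15
  groups <- data.frame(label = c("song", "silent"), n = c(5L, 7L),
                       stringsAsFactors = FALSE)
  fe <- matrix(0, nrow(genes), 2, dimnames = list(genes$gene, groups$label))
  fe[c("EGR1", "CFOS"), "song"] <- 3
  cfg <- sim_config(genes, groups, fold_effect = fe,
                    sample_scaling_sd = 1.6, triplicate_sd = 0.08,
                    outlier_rate = 0.02)
  raw <- simulate_ct_table(cfg, seed = seed)
  efficiency <- stats::setNames(genes$factor, genes$gene)
  list(raw = raw, config = cfg, efficiency = efficiency,
       genes_of_interest = goi$gene,
       treatment = "song", control = "silent")
}
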