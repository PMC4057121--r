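noise_free_config <- function() {
  genes <- data.frame(gene = c("g1", "g2"), baseline_ct = c(20, 25),
                      factor = 2, noise_sd = 0)
  groups <- data.frame(label = c("a", "b"), n = c(2L, 2L))
  sim_config(genes, groups)
}

test_that("with all noise and effects at zero, Ct equals the baseline", {
  raw <- simulate_ct_table(noise_free_config(), seed = 1)
  expect_equal(nrow(raw), 2 * 4 * 3)
  expect_true(all(raw$ct[raw$gene == "g1"] == 20))
  expect_true(all(raw$ct[raw$gene == "g2"] == 25))
})

test_that("the same seed reproduces the table exactly", {
  genes <- data.frame(gene = c("g1", "g2"), baseline_ct = c(20, 25),
                      factor = c(2, 1.95), noise_sd = 0.3)
  groups <- data.frame(label = "a", n = 5L)
  cfg <- sim_config(genes, groups, sample_scaling_sd = 1, triplicate_sd = 0.1,
                    outlier_rate = 0.1)
  expect_identical(simulate_ct_table(cfg, seed = 42),
                   simulate_ct_table(cfg, seed = 42))
  expect_false(identical(simulate_ct_table(cfg, seed = 42),
                         simulate_ct_table(cfg, seed = 43)))
})

test_that("a log2 fold effect shifts group-mean Ct by effect/log2(E)", {
  genes <- data.frame(gene = "g1", baseline_ct = 25, factor = 2,
                      noise_sd = 0.3)
  groups <- data.frame(label = c("ctl", "up"), n = c(1000L, 1000L))
  fe <- matrix(c(0, 3), 1, 2, dimnames = list("g1", c("ctl", "up")))
  cfg <- sim_config(genes, groups, fold_effect = fe)
  raw <- simulate_ct_table(cfg, seed = 2, n_replicates = 1)
  mu <- tapply(raw$ct, raw$group, mean)
  se <- 0.3 * sqrt(2 / 1000)
  expect_lt(abs((mu[["ctl"]] - mu[["up"]]) - 3), 3 * se)
})

test_that("empirical moments converge to configured parameters", {
  genes <- data.frame(gene = "g1", baseline_ct = 25, factor = 2,
                      noise_sd = 0.4)
  groups <- data.frame(label = "a", n = 1000L)
  cfg <- sim_config(genes, groups, sample_scaling_sd = 1.2)
  raw <- simulate_ct_table(cfg, seed = 3, n_replicates = 1)
  expect_lt(abs(mean(raw$ct) - 25), 3 * sqrt(1.2^2 + 0.4^2) / sqrt(1000))
  expect_lt(abs(sd(raw$ct) - sqrt(1.2^2 + 0.4^2)), 0.1)
})

test_that("outliers trip the QC rule and are dropped, not averaged in", {
  genes <- data.frame(gene = "g1", baseline_ct = 25, factor = 2,
                      noise_sd = 0)
  groups <- data.frame(label = "a", n = 200L)
  cfg <- sim_config(genes, groups, triplicate_sd = 0, outlier_rate = 0.5)
  raw <- simulate_ct_table(cfg, seed = 4)
  tab <- suppressWarnings(ct_table_from_long(raw))
  # with zero replicate noise every accepted/dropped well set means 25
  expect_true(all(abs(tab$ct - 25) < 1e-12, na.rm = TRUE))
  expect_gt(sum(!is.na(tab$ct)), 150)
})

test_that("dilution series follows the closed form", {
  d <- simulate_dilution_series("x", 2, n_points = 5)
  expect_equal(diff(d$ct), rep(log2(10), 4))
  expect_equal(d$concentration, 10^-(0:4))
})

test_that("song preset has the documented structure", {
  p <- preset_song_dataset(seed = 5)
  expect_equal(length(unique(p$raw$sample)), 12)
  expect_equal(length(unique(p$raw$gene)), 12)
  expect_equal(nrow(p$raw), 12 * 12 * 3)
  expect_identical(sort(unique(p$raw$group)), c("silent", "song"))
  expect_equal(sum(unique(p$raw[, c("sample", "group")])$group == "song"), 5)
  expect_setequal(p$genes_of_interest, c("EGR1", "CFOS", "FOXP2"))
  # reference candidates carry no configured group effect
  refs <- setdiff(unique(p$raw$gene), p$genes_of_interest)
  expect_true(all(p$config$fold_effect[refs, ] == 0))
  expect_true(all(p$config$fold_effect[c("EGR1", "CFOS"), "song"] == 3))

  pg <- preset_song_dataset(seed = 5, include_undetected = TRUE)
  expect_true(all(is.na(pg$raw$ct[pg$raw$gene == "GUSB"])))
})

test_that("reference genes show near-zero intergroup components", {
  p <- preset_song_dataset(seed = 6)
  tab <- suppressWarnings(ct_table_from_long(p$raw, p$efficiency))
  cand <- select_genes(tab, setdiff(colnames(tab$ct), p$genes_of_interest))
  res <- suppressWarnings(normfinder(cand))
  expect_lt(max(abs(res$intergroup)), 0.35)
})
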