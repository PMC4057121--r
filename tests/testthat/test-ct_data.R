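test_that("triplicate collapse follows the 0.5-cycle deviation rule", {
  r <- collapse_triplicate(c(20.0, 20.1, 20.2))
  expect_identical(r$outcome, "accepted")
  expect_equal(r$mean_ct, 20.1)

  r <- collapse_triplicate(c(20.0, 20.1, 20.9))
  expect_identical(r$outcome, "replicate_dropped")
  expect_equal(r$mean_ct, 20.05)
  expect_identical(r$dropped_index, 3L)

  r <- collapse_triplicate(c(20.0, 21.0, 22.0))
  expect_identical(r$outcome, "failed")
  expect_true(is.na(r$mean_ct))

  # boundary: a deviation of exactly 0.5 is still concordant
  expect_identical(collapse_triplicate(c(20.0, 20.5, 20.25))$outcome,
                   "accepted")
  expect_error(collapse_triplicate(c(20, NA, NA)), "insufficient replicates")
  # duplicates with one missing replicate
  expect_equal(collapse_triplicate(c(20.0, NA, 20.4))$mean_ct, 20.2)
  expect_identical(collapse_triplicate(c(20.0, NA, 20.6))$outcome, "failed")
})

test_that("collapse outcome is invariant to replicate order", {
  set.seed(11)
  for (i in 1:50) {
    v <- round(runif(3, 20, 22), 2)
    base <- collapse_triplicate(v)
    for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      perm <- collapse_triplicate(v[p])
      expect_identical(perm$outcome, base$outcome)
      expect_equal(perm$mean_ct, base$mean_ct)
    }
  }
})

make_small_table <- function() {
  ct <- matrix(c(20, 21, 22, 30, 31, 32), 3, 2,
               dimnames = list(c("s1", "s2", "s3"), c("gA", "gB")))
  ct_table(ct, group = c("a", "a", "b"))
}

test_that("genes below detection are excluded; retained values untouched", {
  ct <- matrix(c(20, 21, 22, NA, NA, NA), 3, 2,
               dimnames = list(c("s1", "s2", "s3"), c("gA", "gGUSB")))
  x <- ct_table(ct, group = rep("g", 3))
  out <- exclude_undetected_genes(x)
  expect_identical(out$excluded, "gGUSB")
  expect_identical(colnames(out$table$ct), "gA")
  expect_identical(out$table$ct[, "gA"], ct[, "gA"])

  clean <- make_small_table()
  out2 <- exclude_undetected_genes(clean)
  expect_identical(out2$excluded, character(0))
  expect_identical(out2$table$ct, clean$ct)

  allna <- ct_table(matrix(NA_real_, 2, 2,
                           dimnames = list(c("s1", "s2"), c("g1", "g2"))),
                    group = c("a", "b"))
  expect_error(exclude_undetected_genes(allna), "all genes excluded")
})

test_that("QC-failed wells do not count as below detection", {
  raw <- expand.grid(sample = c("s1", "s2", "s3"), gene = c("gA", "gB"),
                     replicate = 1:3, stringsAsFactors = FALSE)
  raw$group <- "g"
  raw$ct <- 25
  # one discordant triplicate for gA/s1; gB fully absent in s1
  raw$ct[raw$sample == "s1" & raw$gene == "gA"] <- c(20, 21, 22)
  raw$ct[raw$sample == "s1" & raw$gene == "gB"] <- NA
  tab <- suppressWarnings(ct_table_from_long(raw))
  expect_true(is.na(tab$ct["s1", "gA"]))
  expect_false(tab$undetected["s1", "gA"])
  expect_true(tab$undetected["s1", "gB"])
  out <- exclude_undetected_genes(tab)
  expect_identical(out$excluded, "gB")
})

test_that("long CSV round-trip preserves Cts, groups and missingness", {
  ct <- matrix(c(20.123456789012345, 21.5, NA, 30.1, 31.9, 33.333333333),
               3, 2, dimnames = list(c("s1", "s2", "s3"), c("gA", "gB")))
  x <- ct_table(ct, group = c("a", "a", "b"), tissue = c("t1", "t1", "t2"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(x, f)
  y <- read_ct_table(f)
  expect_identical(y$ct, x$ct)
  expect_identical(y$group, x$group)
  expect_identical(y$tissue, x$tissue)
  expect_identical(is.na(y$ct), is.na(x$ct))
})

test_that("reader handles ND sentinels, triplicates and malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,gene,ct",
               "s1,a,gA,20.0", "s1,a,gB,ND",
               "s2,b,gA,21.0", "s2,b,gB,25.0"), f)
  x <- read_ct_table(f)
  expect_equal(dim(x$ct), c(2, 2))
  expect_true(is.na(x$ct["s1", "gB"]))
  expect_true(x$undetected["s1", "gB"])

  writeLines(c("sample,group,gene,replicate,ct",
               "s1,a,gA,1,20.0", "s1,a,gA,2,20.1", "s1,a,gA,3,20.9",
               "s2,a,gA,1,21.0", "s2,a,gA,2,21.1", "s2,a,gA,3,21.2"), f)
  x <- read_ct_table(f)
  expect_equal(unname(x$ct["s1", "gA"]), 20.05)

  writeLines(c("sample,group,gene,ct",
               "s1,a,gA,20.0", "s1,a,gA,21.0"), f)
  expect_error(read_ct_table(f), "duplicate")

  writeLines(c("sample,group,gene,ct", "s1,a,gA,oops"), f)
  expect_error(read_ct_table(f), "non-numeric")
})

test_that("wide format is accepted on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,gA,gB",
               "s1,a,20.0,30.0", "s2,b,21.0,ND"), f)
  x <- read_ct_table(f)
  expect_equal(unname(x$ct["s1", "gA"]), 20)
  expect_true(is.na(x$ct["s2", "gB"]))
  expect_identical(x$group, c("a", "b"))
})

test_that("ct_rep columns are collapsed on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,group,gene,ct_rep1,ct_rep2,ct_rep3",
               "s1,a,gA,20.0,20.1,20.9",
               "s2,a,gA,21.0,21.1,21.05"), f)
  x <- read_ct_table(f)
  expect_equal(unname(x$ct["s1", "gA"]), 20.05)
  expect_equal(unname(x$ct["s2", "gA"]), mean(c(21, 21.1, 21.05)))
})

test_that("ct_table validates its invariants", {
  m <- matrix(c(20, 45), 1, 2, dimnames = list("s1", c("g1", "g2")))
  expect_error(ct_table(m, group = "a"), "Ct values")
  m2 <- matrix(20, 1, 1, dimnames = list("s1", "g1"))
  expect_error(ct_table(m2, group = "a",
                        efficiency = c(g1 = 2.5)), "amplification factors")
  expect_error(ct_table(m2, group = c("a", "b")), "one group label")
})
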