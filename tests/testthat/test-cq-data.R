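test_that("long-layout files load, collapse replicates, and keep shape", {
  long <- tidyr::expand_grid(
    sample = c("s1", "s2"), gene = c("g1", "g2", "g3"), replicate = 1:3
  )
  withr::with_seed(7, {
    long$cq <- 20 + as.integer(factor(long$gene)) + rnorm(nrow(long), 0, 0.1)
  })
  long$limb <- ifelse(long$sample == "s1", "injured", "uninjured")
  long$treatment <- "vehicle"
  long$timepoint <- "d7"
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(long, path)

  data <- read_cq(path)
  expect_equal(nrow(data), 2)
  expect_equal(sort(cq_genes(data)), c("g1", "g2", "g3"))
  expect_equal(data$limb, c("injured", "uninjured"))
  # collapsed value is the replicate mean
  expected <- mean(long$cq[long$sample == "s1" & long$gene == "g1"])
  expect_equal(data$g1[data$sample == "s1"], expected)
  rs <- replicate_sd(data)
  expect_equal(dim(rs), c(2, 4))
  expect_true(all(rs$g1 > 0))
})

test_that("samples missing a gene are dropped with a warning", {
  long <- tidyr::expand_grid(sample = c("s1", "s2", "s3"),
                             gene = c("g1", "g2", "g3"))
  long$cq <- 20 + seq_len(nrow(long)) / 10
  long <- long[!(long$sample == "s2" & long$gene == "g3"), ]
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(long, path)
  expect_warning(data <- read_cq(path), "s2")
  expect_equal(data$sample, c("s1", "s3"))
})

test_that("duplicate wells and low gene counts are rejected", {
  long <- tidyr::expand_grid(sample = c("s1", "s2"), gene = c("g1", "g2", "g3"))
  long$cq <- 20
  dup <- dplyr::bind_rows(long, long[1, ])
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dup, path)
  expect_error(read_cq(path), "Duplicate")

  two_genes <- dplyr::filter(long, gene != "g3")
  readr::write_csv(two_genes, path)
  expect_error(read_cq(path), "3 gene")
})

test_that("collapse_replicates computes mean/SD and flags noisy triplicates", {
  wells <- tibble::tibble(
    sample = "s1",
    gene = rep(c("a", "b", "c"), times = c(3, 2, 3)),
    cq = c(20, 20, 20, 20, 21, 18.1, 18.3, 19.9)
  )
  expect_warning(out <- collapse_replicates(wells), "s1/c")
  a <- out[out$gene == "a", ]
  expect_equal(a$cq, 20)
  expect_equal(a$replicate_sd, 0)
  expect_false(a$flagged)
  b <- out[out$gene == "b", ]
  expect_equal(b$cq, 20.5)
  expect_equal(b$replicate_sd, sqrt(0.5), tolerance = 1e-12)
  cc <- out[out$gene == "c", ]
  expect_equal(cc$cq, mean(c(18.1, 18.3, 19.9)))
  expect_equal(cc$replicate_sd, oracle_sd(c(18.1, 18.3, 19.9)), tolerance = 1e-12)
  expect_true(cc$replicate_sd > 0.5)
  expect_true(cc$flagged)
})

test_that("cq_to_rq follows the efficiency power law with min-Cq calibrator", {
  cq <- tibble::tibble(sample = c("a", "b", "c"),
                       g1 = c(20, 21, 22), g2 = c(19, 19, 19), g3 = c(25, 23, 24))
  rq <- cq_to_rq(cq)
  expect_equal(rq$g1, c(1, 0.5, 0.25))
  expect_equal(rq$g2, c(1, 1, 1))
  # every gene's max RQ is exactly 1; all RQ in (0, 1]
  for (g in c("g1", "g2", "g3")) {
    expect_equal(max(rq[[g]]), 1)
    expect_true(all(rq[[g]] > 0 & rq[[g]] <= 1))
  }
  # non-default efficiency
  cq2 <- tibble::tibble(sample = c("a", "b"), g1 = c(20, 21),
                        g2 = c(10, 11), g3 = c(30, 29))
  rq2 <- cq_to_rq(cq2, efficiency = 1.9)
  expect_equal(rq2$g1, c(1, 1 / 1.9), tolerance = 1e-12)
  expect_error(cq_to_rq(cq, efficiency = 1.2), "1.6")
})

test_that("log2(RQ) at E = 2 recovers calibrator minus Cq exactly", {
  data <- random_cq(5, 9, seed = 11)
  rq <- cq_to_rq(data)
  cal <- attr(rq, "calibrator_cq")
  for (g in cq_genes(data)) {
    expect_equal(log2(rq[[g]]), cal[[g]] - data[[g]], tolerance = 1e-12)
  }
})

test_that("subsetting commutes with RQ conversion up to a per-gene constant", {
  data <- toy_annotated()
  sliced <- cq_to_rq(data)[data$limb == "injured", ]
  recomputed <- cq_to_rq(data[data$limb == "injured", ])
  # log-ratios between genes are identical either way
  lr_sliced <- log2(sliced$g1 / sliced$g2)
  lr_recomputed <- log2(recomputed$g1 / recomputed$g2)
  expect_equal(lr_sliced, lr_recomputed, tolerance = 1e-12)
  # and the RQ tables differ only by one multiplicative constant per gene
  ratio <- recomputed$g3 / sliced$g3
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-12)
})

test_that("canonical subsets select the expected samples in order", {
  data <- toy_annotated()
  subs <- cq_subsets(data)
  expect_named(subs, c("all_data", "all_uninjured", "all_injured",
                       "all_rapamycin", "all_vehicle"))
  expect_equal(nrow(subs$all_data), 8)
  expect_equal(subs$all_injured$sample, data$sample[data$limb == "injured"])
  expect_equal(subs$all_rapamycin$sample,
               data$sample[data$treatment == "rapamycin"])
  # user-defined subset keeps original order
  subs2 <- cq_subsets(data, extra = list(d7_only = c(timepoint = "d7")))
  expect_equal(subs2$d7_only$sample, data$sample[data$timepoint == "d7"])
  # an empty subset is excluded with a message; the surviving 2-sample
  # treatment subsets additionally warn
  injured_only <- data[data$limb == "injured", ]
  warns <- testthat::capture_warnings(
    expect_message(subs3 <- cq_subsets(injured_only), "all_uninjured")
  )
  expect_true(all(grepl("only 2", warns)))
  expect_length(warns, 2)  # the two 2-sample treatment subsets
  expect_false("all_uninjured" %in% names(subs3))
})

test_that("write/read round-trip preserves Cq values and gene-name case", {
  data <- toy_annotated()
  names(data)[names(data) == "g1"] <- "ACTB"   # mixed-case symbol survives IO
  path <- withr::local_tempfile(fileext = ".csv")
  write_cq(data, path)
  back <- read_cq(path, layout = "wide")
  expect_equal(back$sample, data$sample)
  expect_true("ACTB" %in% cq_genes(back))
  for (g in cq_genes(data)) {
    expect_equal(back[[g]], data[[g]], tolerance = 1e-6)
  }
})
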