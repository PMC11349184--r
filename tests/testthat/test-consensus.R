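fit_all <- function(data) {
  list(bk = bestkeeper(data), gn = genorm(data),
       nf = suppressMessages(normfinder(data)), dc = deltact(data))
}

test_that("aggregate ranks combine by geometric mean with correct ties", {
  data <- random_cq(6, 12, seed = 141)
  f <- fit_all(data)
  agg <- aggregate_ranks(f$bk, f$gn, f$nf, f$dc)
  # closed-form check per gene
  for (i in seq_len(nrow(agg))) {
    ranks <- c(agg$rank_bestkeeper[i], agg$rank_genorm[i],
               agg$rank_normfinder[i], agg$rank_deltact[i])
    expect_equal(agg$geomean_rank[i], prod(ranks)^(1 / 4), tolerance = 1e-12)
    # aggregate bounded by min and max of the method ranks
    expect_gte(agg$geomean_rank[i], min(ranks) - 1e-9)
    expect_lte(agg$geomean_rank[i], max(ranks) + 1e-9)
  }
  expect_equal(sort(agg$rank), 1:6)
  # worked closed-form example: ranks (2, 3, 4, 6) -> (144)^(1/4)
  expect_equal(prod(c(2, 3, 4, 6))^(1 / 4), 3.4641016, tolerance = 1e-6)
  # geNorm's tied best pair both carry rank 1.5
  expect_equal(sum(agg$rank_genorm == 1.5), 2)
})

test_that("a unanimous winner gets aggregate rank exactly 1", {
  # one quiet gene among three loud ones wins every method
  # dominant shared loading so the quiet gene also wins the
  # consensus-correlation method, not only the ratio-based ones
  withr::with_seed(143, {
    n <- 12
    shared <- rnorm(n, 0, 2)
    data <- tibble::tibble(
      sample = paste0("s", 1:n),
      quiet = 20 + shared + rnorm(n, 0, 0.02),
      loudA = 22 + shared + rnorm(n, 0, 0.6),
      loudB = 24 + shared + rnorm(n, 0, 0.9),
      loudC = 26 + shared + rnorm(n, 0, 1.2)
    )
  })
  f <- fit_all(data)
  agg <- aggregate_ranks(f$bk, f$gn, f$nf, f$dc)
  quiet_row <- agg[agg$gene == "quiet", ]
  if (quiet_row$rank_genorm == 1.5) {
    expect_lte(quiet_row$geomean_rank, 1.5^(1 / 4) * 1.0 + 1e-9)
  } else {
    expect_equal(quiet_row$geomean_rank, 1)
  }
  expect_equal(quiet_row$rank, 1L)
})

test_that("mismatched gene sets are refused with the difference named", {
  data <- random_cq(5, 10, seed = 145)
  f <- fit_all(data)
  dc2 <- deltact(data, genes = c("g1", "g2", "g3", "g4"))
  expect_error(aggregate_ranks(f$bk, f$gn, f$nf, dc2), "g5")
})

test_that("normalisation factor is the geometric mean of reference RQs", {
  rq_tab <- tibble::tibble(
    sample = c("s1", "s2"),
    a = c(0.5, 1), b = c(0.5, 0.25), c = c(0.5, 0.25)
  )
  attr(rq_tab, "units") <- "rq"
  nf <- normalization_factor(rq_tab, c("a", "b", "c"))
  expect_equal(nf$nf[1], 0.5)
  expect_equal(nf$nf[2], 0.0625^(1 / 3), tolerance = 1e-12)
  expect_equal(nf$nf[2], 0.3968503, tolerance = 1e-6)
  # permutation invariance
  nf_perm <- normalization_factor(rq_tab, c("c", "a", "b"))
  expect_equal(nf_perm$nf, nf$nf, tolerance = 1e-12)
  # single reference refused, two warned
  expect_error(normalization_factor(rq_tab, "a"), "MIQE")
  expect_warning(normalization_factor(rq_tab, c("a", "b")), "minimum")
  expect_error(suppressWarnings(normalization_factor(rq_tab, c("a", "zzz"))),
               "zzz")
})

test_that("normalising the NF's own references has per-sample geomean 1", {
  data <- toy_annotated()
  rq <- cq_to_rq(data)
  refs <- c("g1", "g2", "g3")
  nf <- normalization_factor(rq, refs)
  normed <- sapply(refs, function(g) rq[[g]] / nf$nf)
  expect_equal(apply(normed, 1, function(x) prod(x)^(1 / 3)),
               rep(1, nrow(rq)), tolerance = 1e-12)
})

test_that("a target identical to the NF normalises to exactly 1", {
  data <- toy_annotated()
  rq <- cq_to_rq(data)
  nf <- suppressWarnings(normalization_factor(rq, c("g1", "g2")))
  rq$target <- nf$nf
  vr <- suppressWarnings(validate_target(rq, "target", c("g1", "g2")))
  expect_equal(vr$samples$normalized, rep(1, nrow(rq)), tolerance = 1e-12)
  expect_equal(vr$groups$cov_normalized, rep(0, nrow(vr$groups)),
               tolerance = 1e-10)
})

test_that("validation reports per-group CoV on the linear scale", {
  data <- toy_annotated()
  rq <- cq_to_rq(data)
  vr <- validate_target(rq, "g4", c("g1", "g2", "g3"),
                        groups = "limb")
  expect_equal(nrow(vr$groups), 2)
  raw <- split(rq$g4, rq$limb)
  for (i in seq_len(nrow(vr$groups))) {
    x <- raw[[vr$groups$limb[i]]]
    expect_equal(vr$groups$cov_raw[i], 100 * oracle_sd(x) / mean(x),
                 tolerance = 1e-12)
  }
  expect_equal(vr$samples$log2_normalized,
               log2(vr$samples$rq / vr$samples$nf), tolerance = 1e-12)
  # warning when the target sits in its own reference set
  expect_warning(validate_target(rq, "g1", c("g1", "g2", "g3")), "own")
})

test_that("normalisation removes injected loading noise from a target", {
  genes <- c(
    lapply(1:3, function(i) gene_spec(paste0("ref", i), 19 + i,
                                      gene_noise_sd = 0.05)),
    list(gene_spec("probe", 24, gene_noise_sd = 0.05))
  )
  design <- tidyr::expand_grid(limb = c("injured", "uninjured"),
                               treatment = c("rapamycin", "vehicle"),
                               timepoint = "d7")
  design$n <- 5L
  sim <- simulate_cq(sim_config(genes, design, loading_sd = 1,
                                replicate_sd = 0, replicates = 1, seed = 151))
  rq <- cq_to_rq(sim$data)
  vr <- validate_target(rq, "probe", c("ref1", "ref2", "ref3"))
  expect_true(mean(vr$groups$cov_normalized) < mean(vr$groups$cov_raw))
})

test_that("rank_stability bundles the four methods consistently", {
  sim <- simulate_study(seed = 7)
  rs <- suppressMessages(rank_stability(sim$data))
  expect_s3_class(rs$aggregate, "aggregate_ranking")
  expect_equal(nrow(rs$aggregate), 11)
  expect_setequal(rs$aggregate$gene, cq_genes(sim$data))
  expect_identical(rs$aggregate,
                   aggregate_ranks(rs$bestkeeper, rs$genorm, rs$normfinder,
                                   rs$deltact))
})
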