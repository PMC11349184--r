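#' BestKeeper consensus-correlation ranking
#'
#' Builds the BestKeeper index — the per-sample geometric mean Cq over all
#' candidate genes, a consensus expression profile reflecting the mean
#' behaviour of the panel — and ranks each candidate by the Pearson
#' correlation (r) of its raw Cq profile with that index. Per-gene Cq
#' standard deviation and coefficient of variation are reported as
#' descriptors; genes with `cq_sd > 1` cycle are flagged (the classical
#' exclusion rule) but never removed from the ranking.
#'
#' @param data A samples-by-genes Cq tibble (raw cycles, not RQ).
#' @param genes Optional character vector of gene columns.
#' @param index `"geometric"` (classical BestKeeper index, default) or
#'   `"arithmetic"` mean of Cq across genes.
#' @return A `bestkeeper` object: list with `stability` (tibble: `gene`,
#'   `r`, `cq_sd`, `cq_cv`, `high_sd` flag, `rank`; rank 1 = highest r),
#'   `index` (tibble: `sample`, `index`) and `index_type`. Ties in r break
#'   by lower `cq_sd`, then gene name. A zero-variance gene has undefined r
#'   and is ranked last.
#' @export
#' @examples
#' sim <- simulate_study(seed = 1)
#' bestkeeper(sim$data)
bestkeeper <- function(data, genes = NULL, index = c("geometric", "arithmetic")) {
  index <- arg_match(index)
  if (is_rq(data)) abort("bestkeeper() expects raw Cq values, not RQ.")
  m <- cq_matrix(data, genes)
  if (nrow(m) < 2) abort("BestKeeper needs at least 2 genes.")
  if (ncol(m) < 3) abort("BestKeeper needs at least 3 samples.")
  idx <- if (index == "geometric") {
    apply(m, 2, geometric_mean)
  } else {
    colMeans(m)
  }
  gene_sd <- apply(m, 1, sd)
  r <- vapply(seq_len(nrow(m)), function(i) {
    if (gene_sd[i] == 0) NA_real_ else cor(m[i, ], idx)
  }, numeric(1))
  tab <- tibble(
    gene = rownames(m),
    r = unname(r),
    cq_sd = unname(gene_sd),
    cq_cv = unname(100 * gene_sd / rowMeans(m)),
    high_sd = unname(gene_sd > 1)
  )
  ord <- order(-ifelse(is.na(tab$r), -Inf, tab$r), tab$cq_sd, tab$gene)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  structure(
    list(
      stability = arrange(tab, .data$rank),
      index = tibble(sample = colnames(m), index = idx),
      index_type = index
    ),
    class = "bestkeeper"
  )
}

#' @export
print.bestkeeper <- function(x, ...) {
  cat("BestKeeper ranking (", x$index_type, " mean index, ",
      nrow(x$index), " samples)\n", sep = "")
  print(x$stability, n = Inf)
  invisible(x)
}
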