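#' Comparative deltaCt stability ranking
#'
#' For every pair of candidate genes the per-sample Cq difference
#' (`dCt = Cq_j - Cq_k`) is formed and its SD over samples computed
#' (unbiased, n-1 denominator): gene pairs that co-vary have consistent dCt
#' and hence low SD. A gene's score is the mean of its pair SDs over all
#' partners (mean, not sum, so scores are comparable across panel sizes;
#' the ranking is identical either way). Lower scores indicate more stable
#' genes. With amplification efficiency 2 the score is identical to the
#' first-round geNorm M value.
#'
#' @param data A samples-by-genes Cq tibble (raw cycles, not RQ).
#' @param genes Optional character vector of gene columns (>= 3).
#' @return A `deltact` object: list with `stability` (tibble `gene`,
#'   `score`, `rank`; ascending score, ties lexicographic) and `pair_sd`
#'   (symmetric matrix of pairwise dCt SDs, zero diagonal).
#' @export
#' @examples
#' sim <- simulate_study(seed = 1)
#' deltact(sim$data)
deltact <- function(data, genes = NULL) {
  if (is_rq(data)) abort("deltact() expects raw Cq values, not RQ.")
  m <- cq_matrix(data, genes)
  if (nrow(m) < 3) abort("deltaCt requires at least 3 genes.")
  if (ncol(m) < 2) abort("deltaCt requires at least 2 samples.")
  k <- nrow(m)
  pair_sd <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pair_sd[i, j] <- pair_sd[j, i] <- sd(m[i, ] - m[j, ])
    }
  }
  score <- rowSums(pair_sd) / (k - 1)
  tab <- tibble(gene = rownames(m), score = unname(score))
  ord <- order(tab$score, tab$gene)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(k)
  structure(
    list(stability = arrange(tab, .data$rank), pair_sd = pair_sd),
    class = "deltact"
  )
}

#' @export
print.deltact <- function(x, ...) {
  cat("deltaCt stability ranking (mean pairwise dCt SD, cycles)\n")
  print(x$stability, n = Inf)
  invisible(x)
}
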