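# geNorm works on log2 ratios of relative quantities. Internally everything
# is computed on the log2(RQ) matrix; Cq input is converted first.

log2_rq_matrix <- function(data, efficiency = 2, genes = NULL) {
  if (!is_rq(data)) data <- cq_to_rq(data, efficiency = efficiency, genes = genes)
  m <- cq_matrix(data, genes)
  if (any(m <= 0)) abort("RQ values must be strictly positive.")
  log2(m)
}

#' Pairwise log-ratio standard deviation of two candidate genes
#'
#' The geNorm building block: the SD over samples of
#' `log2(RQ_a / RQ_b)` (unbiased, n-1 denominator). With efficiency 2 this
#' equals the SD of the per-sample Cq difference `Cq_b - Cq_a` exactly, since
#' per-gene calibrators cancel in the ratio.
#'
#' @param data A samples-by-genes Cq or RQ tibble.
#' @param gene_a,gene_b Gene column names.
#' @param efficiency Amplification efficiency used if `data` holds Cq.
#' @return A single non-negative number (log2 units), symmetric in its genes.
#' @export
pairwise_sd <- function(data, gene_a, gene_b, efficiency = 2) {
  y <- log2_rq_matrix(data, efficiency, genes = cq_genes(data))
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(y)) abort(paste0("Unknown gene: ", g))
  }
  if (nrow(data) < 2) abort("Need at least 2 samples.")
  sd(y[gene_a, ] - y[gene_b, ])
}

all_pairwise_sd <- function(y) {
  k <- nrow(y)
  v <- matrix(0, k, k, dimnames = list(rownames(y), rownames(y)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      v[i, j] <- v[j, i] <- sd(y[i, ] - y[j, ])
    }
  }
  v
}

#' geNorm expression stability values (M)
#'
#' The stability value M of a candidate is the arithmetic mean of its
#' pairwise log2-ratio SDs against every other candidate in the panel;
#' lower M means more stable. Conventionally M < 0.5 indicates a suitable
#' reference in homogeneous sample sets, with M < 1.0 often accepted in
#' transcriptionally plastic scenarios; these thresholds annotate reports
#' and are never applied as filters.
#'
#' @inheritParams pairwise_sd
#' @param genes Optional character vector of gene columns (>= 3).
#' @return Named numeric vector of M values.
#' @export
m_values <- function(data, genes = NULL, efficiency = 2) {
  y <- log2_rq_matrix(data, efficiency, genes)
  if (nrow(y) < 3) abort("M values require at least 3 genes.")
  v <- all_pairwise_sd(y)
  rowSums(v) / (nrow(v) - 1)
}

#' geNorm ranking by iterative elimination
#'
#' Computes M for the full panel, discards the gene with the highest M (the
#' most variable), and repeats on the survivors until a single pair of
#' highly correlated genes remains — the "best pair", which geNorm cannot
#' rank internally and which is reported tied. Ties in M break
#' lexicographically by gene name (and are logged). The pairwise-variation
#' series V(n, n+1) for the ranked panel is computed alongside (see
#' [pairwise_variation()]).
#'
#' @inheritParams m_values
#' @return A `genorm` object: list with
#'   * `ranking`: tibble `gene`, `m` (M at elimination; final-round M for
#'     the best pair), `rank` (1.5/1.5 for the tied best pair, then 3, 4, ...),
#'   * `rounds`: tibble `round`, `gene`, `m`, `eliminated`,
#'   * `best_pair`: character vector of 2,
#'   * `v`: tibble `n_genes`, `v` — the V(n, n+1) series.
#' @export
#' @examples
#' sim <- simulate_study(seed = 1)
#' gn <- genorm(sim$data)
#' gn$best_pair
genorm <- function(data, genes = NULL, efficiency = 2) {
  y <- log2_rq_matrix(data, efficiency, genes)
  if (nrow(y) < 3) abort("geNorm requires at least 3 genes.")
  remaining <- rownames(y)
  rounds <- list()
  elim_order <- character(0)
  elim_m <- numeric(0)
  round_i <- 0L
  while (length(remaining) > 2) {
    round_i <- round_i + 1L
    v <- all_pairwise_sd(y[remaining, , drop = FALSE])
    m <- rowSums(v) / (length(remaining) - 1)
    worst <- remaining[order(-m, remaining)][1]
    if (sum(m == max(m)) > 1) {
      inform(paste0("geNorm round ", round_i, ": tie at M = ",
                    signif(max(m), 6), "; eliminating '", worst,
                    "' (lexicographic)."))
    }
    rounds[[round_i]] <- tibble(round = round_i, gene = remaining,
                                m = unname(m), eliminated = remaining == worst)
    elim_order <- c(elim_order, worst)
    elim_m <- c(elim_m, m[[worst]])
    remaining <- setdiff(remaining, worst)
  }
  final_m <- sd(y[remaining[1], ] - y[remaining[2], ])
  rounds[[round_i + 1L]] <- tibble(round = round_i + 1L, gene = remaining,
                                   m = final_m, eliminated = FALSE)
  best_pair <- sort(remaining)
  ranking <- tibble(
    gene = c(best_pair, rev(elim_order)),
    m = c(final_m, final_m, rev(elim_m)),
    rank = c(1.5, 1.5, seq(3, length.out = length(elim_order)))
  )
  res <- structure(
    list(ranking = ranking, rounds = bind_rows(rounds),
         best_pair = best_pair, v = NULL,
         efficiency = efficiency),
    class = "genorm"
  )
  res$v <- pairwise_variation(res, data = data, genes = genes)
  res
}

#' Pairwise variation V(n, n+1) for increasing reference-gene counts
#'
#' For the geNorm-ranked panel, builds normalisation factors `NF_n` (the
#' per-sample geometric mean RQ of the n most stable genes) and reports
#' `V(n, n+1) = SD over samples of log2(NF_n / NF_(n+1))` for
#' n = 2 ... k-1. A V below the conventional 0.2 annotation means the
#' (n+1)-th gene adds no worthwhile normalisation stability.
#'
#' @param x A `genorm` object.
#' @param data The Cq/RQ tibble the ranking was computed from.
#' @inheritParams m_values
#' @return Tibble with columns `n_genes` (n) and `v`.
#' @export
pairwise_variation <- function(x, data, genes = NULL, efficiency = NULL) {
  stopifnot(inherits(x, "genorm"))
  efficiency <- efficiency %||% x$efficiency
  y <- log2_rq_matrix(data, efficiency, genes)
  ranked <- x$ranking$gene
  if (length(ranked) < 3) abort("V series requires at least 3 ranked genes.")
  nf_log2 <- function(n) colMeans(y[ranked[seq_len(n)], , drop = FALSE])
  ns <- 2:(length(ranked) - 1)
  v <- vapply(ns, function(n) sd(nf_log2(n) - nf_log2(n + 1)), numeric(1))
  tibble(n_genes = ns, v = v)
}

#' @export
print.genorm <- function(x, ...) {
  cat("geNorm stability ranking (best pair: ",
      paste(x$best_pair, collapse = " + "), ")\n", sep = "")
  print(x$ranking, n = Inf)
  cat("\nPairwise variation V(n, n+1):\n")
  print(x$v, n = Inf)
  invisible(x)
}
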