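# broom-style tidiers: tidy() returns the per-gene table, glance() a
# one-row summary. generics::tidy is not a dependency; lightweight generics
# are defined here and dispatch on the result classes.

#' Turn a refstab result into a tidy per-gene tibble
#'
#' @param x A result object (`bestkeeper`, `genorm`, `deltact`,
#'   `normfinder`, `refstab_ranking` or `validation_report`).
#' @param ... Unused.
#' @return A tibble with one row per gene (per group for
#'   `validation_report`).
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a refstab result
#'
#' @inheritParams tidy
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.bestkeeper <- function(x, ...) x$stability

#' @rdname glance
#' @export
glance.bestkeeper <- function(x, ...) {
  tibble(
    n_genes = nrow(x$stability), n_samples = nrow(x$index),
    index_type = x$index_type,
    top_gene = x$stability$gene[1], max_r = max(x$stability$r, na.rm = TRUE),
    min_r = min(x$stability$r, na.rm = TRUE)
  )
}

#' @rdname tidy
#' @export
tidy.genorm <- function(x, ...) x$ranking

#' @rdname glance
#' @export
glance.genorm <- function(x, ...) {
  tibble(
    n_genes = nrow(x$ranking),
    best_pair = paste(x$best_pair, collapse = "+"),
    min_m = min(x$ranking$m), max_m = max(x$ranking$m),
    v_2_3 = x$v$v[x$v$n_genes == 2],
    all_m_below_0.5 = all(x$ranking$m < 0.5),
    all_m_below_1 = all(x$ranking$m < 1)
  )
}

#' @rdname tidy
#' @export
tidy.deltact <- function(x, ...) x$stability

#' @rdname glance
#' @export
glance.deltact <- function(x, ...) {
  tibble(
    n_genes = nrow(x$stability),
    best_gene = x$stability$gene[1],
    min_score = min(x$stability$score), max_score = max(x$stability$score)
  )
}

#' @rdname tidy
#' @export
tidy.normfinder <- function(x, ...) x$stability

#' @rdname glance
#' @export
glance.normfinder <- function(x, ...) {
  tibble(
    n_genes = nrow(x$stability),
    mode = x$mode,
    grouping = paste(x$grouping %||% "none", collapse = "x"),
    best_gene = x$stability$gene[1],
    min_rho = min(x$stability$rho),
    best_pair = if (is.null(x$best_pair)) NA_character_ else
      paste(x$best_pair$genes, collapse = "+"),
    n_truncated = length(x$truncated)
  )
}

#' @rdname tidy
#' @export
tidy.refstab_ranking <- function(x, ...) as_tibble(x$aggregate)

#' @rdname glance
#' @export
glance.refstab_ranking <- function(x, ...) {
  agg <- x$aggregate
  tibble(
    n_genes = nrow(agg),
    top_genes = paste(head(agg$gene, 3), collapse = "+"),
    worst_genes = paste(rev(agg$gene)[1:3], collapse = "+"),
    genorm_best_pair = paste(x$genorm$best_pair, collapse = "+")
  )
}

#' @rdname tidy
#' @export
tidy.validation_report <- function(x, ...) x$groups

#' @rdname glance
#' @export
glance.validation_report <- function(x, ...) {
  tibble(
    target = x$target,
    references = paste(x$reference_genes, collapse = "+"),
    n_groups = nrow(x$groups),
    mean_cov_raw = mean(x$groups$cov_raw),
    mean_cov_normalized = mean(x$groups$cov_normalized),
    cov_reduced = mean(x$groups$cov_normalized) < mean(x$groups$cov_raw)
  )
}
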