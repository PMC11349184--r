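#' Integrated geometric-mean-of-ranks consensus
#'
#' Aggregates the four method rankings (BestKeeper, geNorm, NormFinder,
#' deltaCt) for one dataset into a single consensus order: each gene's four
#' method ranks (1 = most stable; geNorm's tied best pair both count 1.5,
#' preserving the rank sum) are combined by their geometric mean, and genes
#' are ordered by ascending aggregate. Ranks rather than raw scores are
#' combined because the four scores live on incommensurable scales. Ties in
#' the aggregate break by arithmetic-mean rank, then gene name.
#'
#' @param bk A [bestkeeper()] result.
#' @param gn A [genorm()] result.
#' @param nf A [normfinder()] result.
#' @param dc A [deltact()] result.
#' @return An `aggregate_ranking` tibble: `gene`, `rank_bestkeeper`,
#'   `rank_genorm`, `rank_normfinder`, `rank_deltact`, `geomean_rank`,
#'   `rank`.
#' @export
#' @examples
#' sim <- simulate_study(seed = 1)
#' d <- sim$data
#' aggregate_ranks(bestkeeper(d), genorm(d), normfinder(d), deltact(d))
aggregate_ranks <- function(bk, gn, nf, dc) {
  stopifnot(inherits(bk, "bestkeeper"), inherits(gn, "genorm"),
            inherits(nf, "normfinder"), inherits(dc, "deltact"))
  ranks <- list(
    rank_bestkeeper = setNames(bk$stability$rank, bk$stability$gene),
    rank_genorm = setNames(gn$ranking$rank, gn$ranking$gene),
    rank_normfinder = setNames(nf$stability$rank, nf$stability$gene),
    rank_deltact = setNames(dc$stability$rank, dc$stability$gene)
  )
  gene_sets <- lapply(ranks, names)
  genes <- sort(gene_sets[[1]])
  for (i in 2:4) {
    if (!identical(sort(gene_sets[[i]]), genes)) {
      diff <- union(setdiff(gene_sets[[i]], genes), setdiff(genes, gene_sets[[i]]))
      abort(paste0("Method results cover different gene sets; mismatch: ",
                   paste(diff, collapse = ", ")))
    }
  }
  genes <- gene_sets[[1]]  # keep BestKeeper table order as reference
  tab <- tibble(
    gene = genes,
    rank_bestkeeper = as.numeric(ranks$rank_bestkeeper[genes]),
    rank_genorm = as.numeric(ranks$rank_genorm[genes]),
    rank_normfinder = as.numeric(ranks$rank_normfinder[genes]),
    rank_deltact = as.numeric(ranks$rank_deltact[genes])
  )
  rank_mat <- as.matrix(tab[-1])
  tab$geomean_rank <- exp(rowMeans(log(rank_mat)))
  mean_rank <- rowMeans(rank_mat)
  ord <- order(tab$geomean_rank, mean_rank, tab$gene)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  tab <- arrange(tab, .data$rank)
  class(tab) <- c("aggregate_ranking", class(tab))
  tab
}

#' Per-sample normalisation factor from reference-gene RQs
#'
#' The normalisation factor (NF) of a sample is the geometric mean of the
#' RQ values of the chosen reference genes (conventionally the three
#' top-ranked candidates). Target-gene RQs are divided by it. A single
#' reference gene is refused: MIQE guidelines strongly discourage
#' single-gene normalisation, two genes being the minimum (and triggering a
#' warning here).
#'
#' @param rq A samples-by-genes RQ tibble from [cq_to_rq()].
#' @param reference_genes Character vector (>= 2) of reference gene columns.
#' @return Tibble with columns `sample` and `nf` (positive).
#' @export
#' @examples
#' sim <- simulate_study(seed = 1)
#' rq <- cq_to_rq(sim$data)
#' normalization_factor(rq, c("ACTB", "CSNK2A2", "HPRT1"))
normalization_factor <- function(rq, reference_genes) {
  if (!is_rq(rq)) abort("`rq` must be an RQ table from cq_to_rq().")
  missing <- setdiff(reference_genes, cq_genes(rq))
  if (length(missing) > 0) {
    abort(paste0("Unknown reference gene(s): ", paste(missing, collapse = ", ")))
  }
  if (length(reference_genes) < 2) {
    abort(paste0("A single reference gene is refused: MIQE guidelines ",
                 "discourage single-gene normalisation (two is the minimum)."))
  }
  if (length(reference_genes) == 2) {
    warn("Only 2 reference genes: the MIQE minimum; 3 are recommended.")
  }
  m <- cq_matrix(rq, reference_genes)
  out <- tibble(sample = colnames(m), nf = unname(apply(m, 2, geometric_mean)))
  attr(out, "reference_genes") <- reference_genes
  out
}

#' Validate a normalisation factor against a target gene
#'
#' Divides the target gene's RQ by the per-sample NF and compares
#' within-group coefficients of variation (CoV = SD/mean on the linear
#' scale) before and after normalisation: good normalisation removes shared
#' technical variation and so reduces within-group CoV, while revealing any
#' genuine group-linked expression differences in the group means. Log2
#' values are emitted alongside for plotting.
#'
#' @param rq A samples-by-genes RQ tibble from [cq_to_rq()].
#' @param target Target gene column (warned against if it is also a
#'   reference).
#' @param reference_genes Reference genes passed to
#'   [normalization_factor()], or a precomputed NF tibble.
#' @param groups Character vector of annotation columns defining the
#'   within-groups (default `c("limb", "treatment")`).
#' @return A `validation_report` object: list with `samples` (per-sample
#'   raw/normalised linear and log2 values), `groups` (per-group n, means
#'   and CoV before/after, in %), `target`, `reference_genes`.
#' @export
#' @examples
#' sim <- simulate_study(seed = 1)
#' rq <- cq_to_rq(sim$data)
#' validate_target(rq, "SDHA", c("ACTB", "CSNK2A2", "HPRT1"))
validate_target <- function(rq, target, reference_genes,
                            groups = c("limb", "treatment")) {
  if (!is_rq(rq)) abort("`rq` must be an RQ table from cq_to_rq().")
  if (!target %in% cq_genes(rq)) abort(paste0("Unknown target gene: ", target))
  if (is.data.frame(reference_genes)) {
    nf <- reference_genes
    stopifnot(all(c("sample", "nf") %in% names(nf)))
    refs <- attr(nf, "reference_genes") %||% character(0)
  } else {
    refs <- reference_genes
    if (target %in% refs) {
      warn(paste0("Target '", target, "' is one of its own reference genes."))
    }
    nf <- normalization_factor(rq, refs)
  }
  missing_g <- setdiff(groups, names(rq))
  if (length(missing_g) > 0) {
    abort(paste0("Unknown grouping column(s): ", paste(missing_g, collapse = ", ")))
  }
  samples <- tibble(
    sample = sample_ids(rq),
    rq = rq[[target]]
  )
  for (g in groups) samples[[g]] <- rq[[g]]
  samples <- left_join(samples, nf, by = "sample") %>%
    mutate(
      normalized = .data$rq / .data$nf,
      log2_rq = log2(.data$rq),
      log2_normalized = log2(.data$normalized)
    )
  group_tab <- samples %>%
    group_by(across(all_of(groups))) %>%
    summarise(
      n = dplyr::n(),
      mean_raw = mean(.data$rq),
      mean_normalized = mean(.data$normalized),
      cov_raw = 100 * sd(.data$rq) / mean(.data$rq),
      cov_normalized = 100 * sd(.data$normalized) / mean(.data$normalized),
      .groups = "drop"
    )
  if (any(group_tab$n < 2)) {
    warn("Group(s) with fewer than 2 samples have undefined CoV.")
  }
  structure(
    list(samples = samples, groups = group_tab, target = target,
         reference_genes = refs, grouping = groups),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Normalisation-factor validation for target '", x$target,
      "' (refs: ", paste(x$reference_genes, collapse = ", "), ")\n", sep = "")
  print(x$groups, n = Inf)
  invisible(x)
}

#' Run all four stability methods and their consensus on one dataset
#'
#' Convenience wrapper: runs [bestkeeper()], [genorm()], [normfinder()]
#' (ungrouped unless `normfinder_groups` is given) and [deltact()] on the
#' same Cq table and aggregates them with [aggregate_ranks()].
#'
#' @param data A samples-by-genes Cq tibble.
#' @param genes Optional character vector of gene columns.
#' @param efficiency Amplification efficiency for the RQ-based methods.
#' @param normfinder_groups Optional grouping columns for NormFinder.
#' @return A `refstab_ranking` object: list with the four method results
#'   (`bestkeeper`, `genorm`, `normfinder`, `deltact`) and the
#'   `aggregate` table.
#' @export
#' @examples
#' sim <- simulate_study(seed = 1)
#' rank_stability(sim$data)$aggregate
rank_stability <- function(data, genes = NULL, efficiency = 2,
                           normfinder_groups = NULL) {
  bk <- bestkeeper(data, genes = genes)
  gn <- genorm(data, genes = genes, efficiency = efficiency)
  nf <- normfinder(data, groups = normfinder_groups, genes = genes,
                   efficiency = efficiency)
  dc <- deltact(data, genes = genes)
  structure(
    list(bestkeeper = bk, genorm = gn, normfinder = nf, deltact = dc,
         aggregate = aggregate_ranks(bk, gn, nf, dc)),
    class = "refstab_ranking"
  )
}

#' @export
print.refstab_ranking <- function(x, ...) {
  cat("Integrated reference-gene stability ranking\n")
  print(x$aggregate, n = Inf)
  invisible(x)
}
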