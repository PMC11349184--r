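# NormFinder-style model-based variance decomposition on y = log2(RQ).
#
# Per-sample centering across genes removes the shared loading component;
# the intragroup variance of the centered residuals is then bias-corrected
# for the fact that each gene's residual contains -1/k of every gene's own
# error. Grouped mode additionally estimates a per-group intergroup
# difference d for each gene, shrunk towards zero by an empirical-Bayes
# factor built from the between-group variance gamma^2.

#' NormFinder model-based stability
#'
#' Decomposes log2 relative quantities into intragroup variance and
#' (optionally) systematic intergroup differences, and scores each candidate
#' by a stability value rho (log2 units; lower = more stable). In ungrouped
#' mode all samples form one group and `rho = sqrt(sigma2)`, the
#' bias-corrected intragroup SD. In grouped mode each gene additionally gets
#' per-group intergroup differences `d` (weighted to zero across groups),
#' their shrunk versions `d_shrunk`, and
#' `rho = mean over groups of |d_shrunk| + sqrt(shrunk between-group SE^2 +
#' sigma2/n)`, penalising genes whose expression shifts between experimental
#' groups even when they look stable overall, while retaining the
#' within-group sampling term so that a noisy gene with no detectable group
#' bias never scores zero.
#'
#' @param data A samples-by-genes Cq or RQ tibble.
#' @param groups `NULL` for ungrouped analysis, or character vector of
#'   annotation columns (e.g. `"limb"`, or
#'   `c("limb", "treatment", "timepoint")` for the fully crossed grouping).
#' @param genes Optional character vector of gene columns (>= 3; the
#'   centering bias-correction needs k - 2 > 0).
#' @param efficiency Amplification efficiency used if `data` holds Cq.
#' @return A `normfinder` object: list with
#'   * `stability`: tibble `gene`, `rho`, `rank` (ascending rho, ties
#'     lexicographic),
#'   * `groupwise` (grouped mode): tibble `gene`, `group`, `n`, `d`,
#'     `d_shrunk`, `sigma2`, `shrink`,
#'   * `gamma2`: per-gene between-group variance estimates (grouped mode),
#'   * `best_pair` (grouped mode): list `genes`, `stability` — the pair
#'     minimising the combined stability (see Details),
#'   * `mode`, `grouping`, `truncated` (genes whose variance estimates were
#'     truncated at zero).
#' @details The best pair averages the two genes' shrunk intergroup
#'   differences (allowing opposite-signed biases to cancel) and quarters the
#'   summed intragroup variances; the pair's combined stability uses the
#'   same bias-plus-uncertainty form with a pair-level shrinkage recomputed
#'   from the averaged differences.
#' @export
#' @examples
#' sim <- simulate_study(seed = 1)
#' normfinder(sim$data, groups = "limb")
normfinder <- function(data, groups = NULL, genes = NULL, efficiency = 2) {
  y <- log2_rq_matrix(data, efficiency, genes)
  k <- nrow(y)
  if (k < 3) abort("NormFinder requires at least 3 genes (k - 2 > 0).")
  if (is.null(groups)) {
    grp <- rep("all", ncol(y))
    mode <- "ungrouped"
  } else {
    missing <- setdiff(groups, names(data))
    if (length(missing) > 0) {
      abort(paste0("Unknown grouping column(s): ", paste(missing, collapse = ", ")))
    }
    grp <- do.call(paste, c(lapply(groups, function(g) as.character(data[[g]])),
                            sep = "."))
    mode <- "grouped"
  }
  glev <- unique(grp)
  n_g <- vapply(glev, function(g) sum(grp == g), integer(1))
  if (any(n_g < 2)) {
    abort(paste0("Group(s) with fewer than 2 samples: ",
                 paste(glev[n_g < 2], collapse = ", ")))
  }

  # (1) per-sample centering across genes
  r <- sweep(y, 2, colMeans(y))

  # (2)-(3) bias-corrected intragroup variances sigma2[gene, group]
  s2 <- matrix(NA_real_, k, length(glev), dimnames = list(rownames(y), glev))
  z <- s2
  for (g in glev) {
    cols <- grp == g
    s2[, g] <- apply(r[, cols, drop = FALSE], 1, var)
    z[, g] <- rowMeans(r[, cols, drop = FALSE])
  }
  t_hat <- (k / (k - 1)) * colSums(s2)
  sigma2_raw <- (k / (k - 2)) * sweep(s2, 2, t_hat / k^2)
  sigma2 <- pmax(sigma2_raw, 0)
  truncated <- rownames(y)[apply(sigma2_raw < 0, 1, any)]

  if (mode == "ungrouped") {
    rho <- sqrt(sigma2[, 1])
    tab <- tibble(gene = rownames(y), rho = unname(rho))
    groupwise <- NULL
    gamma2 <- NULL
    best_pair <- NULL
  } else {
    w <- n_g / sum(n_g)
    d <- sweep(z, 1, as.vector(z %*% w))           # weighted mean zero per gene
    se2 <- sweep(sigma2, 2, n_g, `/`)              # sigma2/n per (gene, group)
    G <- length(glev)
    gamma2_raw <- rowSums(d^2) / (G - 1) - rowMeans(se2)
    gamma2 <- pmax(gamma2_raw, 0)
    truncated <- union(truncated, rownames(y)[gamma2_raw < 0])
    shrink <- gamma2 / (gamma2 + se2)              # recycles gamma2 by column
    shrink[gamma2 == 0, ] <- 0
    d_shrunk <- d * shrink
    # stability per (gene, group): shrunk bias plus total uncertainty of the
    # group-level estimate (shrunk between-group part + within-group SE);
    # the se2 term keeps a noisy gene with gamma2 = 0 from scoring rho = 0
    rho_ig <- abs(d_shrunk) + sqrt(se2 * shrink + se2)
    rho <- rowMeans(rho_ig)
    tab <- tibble(gene = rownames(y), rho = unname(rho))
    groupwise <- tidyr::expand_grid(gene = rownames(y), group = glev) %>%
      mutate(
        n = n_g[.data$group],
        d = purrr::map2_dbl(.data$gene, .data$group, ~ d[.x, .y]),
        d_shrunk = purrr::map2_dbl(.data$gene, .data$group, ~ d_shrunk[.x, .y]),
        sigma2 = purrr::map2_dbl(.data$gene, .data$group, ~ sigma2[.x, .y]),
        shrink = purrr::map2_dbl(.data$gene, .data$group, ~ shrink[.x, .y])
      )
    best_pair <- normfinder_pair_search(d_shrunk, sigma2, n_g)
  }
  ord <- order(tab$rho, tab$gene)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(k)
  if (length(truncated) > 0) {
    inform(paste0("Variance estimates truncated at zero for: ",
                  paste(truncated, collapse = ", ")))
  }
  structure(
    list(stability = arrange(tab, .data$rank), groupwise = groupwise,
         gamma2 = gamma2, best_pair = best_pair, mode = mode,
         grouping = groups, truncated = truncated),
    class = "normfinder"
  )
}

# Exhaustive search for the pair with minimum combined stability.
normfinder_pair_search <- function(d_shrunk, sigma2, n_g) {
  genes <- rownames(d_shrunk)
  G <- length(n_g)
  best <- NULL
  for (i in seq_along(genes)[-length(genes)]) {
    for (j in (i + 1):length(genes)) {
      d_pair <- (d_shrunk[i, ] + d_shrunk[j, ]) / 2
      v_pair <- (sigma2[i, ] + sigma2[j, ]) / (4 * n_g)
      g2 <- max(sum(d_pair^2) / (G - 1) - mean(v_pair), 0)
      shrink <- if (g2 == 0) rep(0, G) else g2 / (g2 + v_pair)
      stab <- mean(abs(d_pair) + sqrt(v_pair * shrink + v_pair))
      if (is.null(best) || stab < best$stability - 1e-15 ||
          (abs(stab - best$stability) <= 1e-15 &&
           paste(genes[i], genes[j]) < paste(best$genes, collapse = " "))) {
        best <- list(genes = c(genes[i], genes[j]), stability = stab)
      }
    }
  }
  best
}

#' Best reference-gene pair from a grouped NormFinder fit
#'
#' @param x A `normfinder` object fitted with grouping factors.
#' @return List with `genes` (character vector of 2, lexicographic) and
#'   `stability` (the pair's combined stability value).
#' @export
normfinder_best_pair <- function(x) {
  stopifnot(inherits(x, "normfinder"))
  if (x$mode != "grouped") {
    abort("Best-pair selection requires a grouped NormFinder fit.")
  }
  x$best_pair
}

#' @export
print.normfinder <- function(x, ...) {
  cat("NormFinder stability (", x$mode,
      if (x$mode == "grouped") paste0(", grouped by ",
                                      paste(x$grouping, collapse = " x ")),
      ")\n", sep = "")
  print(x$stability, n = Inf)
  if (!is.null(x$best_pair)) {
    cat("\nBest pair: ", paste(x$best_pair$genes, collapse = " + "),
        " (combined stability ", signif(x$best_pair$stability, 4), ")\n",
        sep = "")
  }
  invisible(x)
}
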