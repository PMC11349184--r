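# ggplot2 figure methods. Each result type gets an autoplot(); the raw-Cq
# overview plot has its own function since it works on the data table.

#' Distribution of raw Cq values per candidate gene
#'
#' Box plot of raw Cq values per gene, optionally coloured by an annotation
#' factor — the usual first-pass look at a candidate panel (lower Cq =
#' higher expression).
#'
#' @param data A samples-by-genes Cq tibble.
#' @param colour_by Optional annotation column (e.g. `"limb"`).
#' @param genes Optional character vector of gene columns.
#' @return A ggplot object.
#' @export
plot_cq_distributions <- function(data, colour_by = NULL, genes = NULL) {
  genes <- cq_genes(data, genes)
  long <- tidyr::pivot_longer(data, all_of(genes),
                              names_to = "gene", values_to = "cq")
  long$gene <- factor(long$gene, levels = genes)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$cq))
  if (!is.null(colour_by)) {
    p <- p + ggplot2::geom_boxplot(ggplot2::aes(fill = .data[[colour_by]]))
  } else {
    p <- p + ggplot2::geom_boxplot()
  }
  p + ggplot2::labs(x = NULL, y = "Cq (cycles)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

rank_bar <- function(tab, value, ylab, desc = FALSE) {
  tab <- tab[order(tab$rank, decreasing = TRUE), ]
  tab$gene <- factor(tab$gene, levels = unique(tab$gene))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$gene, y = .data[[value]])) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "least stable → most stable", y = ylab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for stability results
#'
#' `autoplot()` draws the conventional figure for each result type: genes
#' ordered least to most stable with their method score (BestKeeper r,
#' geNorm M, NormFinder rho, deltaCt mean dCt SD), the geNorm V(n, n+1)
#' series with its 0.2 annotation, the consensus geometric-mean ranks, or
#' the before/after log2 expression spread of a validation report.
#'
#' @param object A refstab result object.
#' @param which For `genorm` results: `"m"` (default) or `"v"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-refstab
NULL

#' @rdname autoplot-refstab
#' @exportS3Method ggplot2::autoplot
autoplot.bestkeeper <- function(object, ...) {
  rank_bar(object$stability, "r", "Pearson r with BestKeeper index")
}

#' @rdname autoplot-refstab
#' @exportS3Method ggplot2::autoplot
autoplot.genorm <- function(object, which = c("m", "v"), ...) {
  which <- arg_match(which)
  if (which == "m") {
    rank_bar(object$ranking, "m", "geNorm stability M") +
      ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed")
  } else {
    ggplot2::ggplot(object$v,
                    ggplot2::aes(x = factor(paste0("V", .data$n_genes, "/",
                                                   .data$n_genes + 1),
                                            levels = paste0("V", .data$n_genes,
                                                            "/", .data$n_genes + 1)),
                                 y = .data$v)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::geom_hline(yintercept = 0.2, linetype = "dashed") +
      ggplot2::labs(x = NULL, y = "Pairwise variation V(n, n+1)") +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot-refstab
#' @exportS3Method ggplot2::autoplot
autoplot.deltact <- function(object, ...) {
  rank_bar(object$stability, "score", "Mean pairwise dCt SD (cycles)")
}

#' @rdname autoplot-refstab
#' @exportS3Method ggplot2::autoplot
autoplot.normfinder <- function(object, ...) {
  rank_bar(object$stability, "rho", "NormFinder stability ρ (log2)")
}

#' @rdname autoplot-refstab
#' @exportS3Method ggplot2::autoplot
autoplot.refstab_ranking <- function(object, ...) {
  rank_bar(object$aggregate, "geomean_rank", "Geometric mean rank")
}

#' @rdname autoplot-refstab
#' @exportS3Method ggplot2::autoplot
autoplot.validation_report <- function(object, ...) {
  s <- object$samples
  long <- tidyr::pivot_longer(s, c("log2_rq", "log2_normalized"),
                              names_to = "stage", values_to = "log2_value")
  long$stage <- factor(long$stage, levels = c("log2_rq", "log2_normalized"),
                       labels = c("raw", "normalised"))
  grp <- do.call(paste, c(lapply(object$grouping, function(g) long[[g]]),
                          sep = "\n"))
  long$group <- grp
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$log2_value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey55") +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = NULL, y = paste0("log2 ", object$target, " (RQ)"),
                  title = paste0(object$target, " before/after normalisation")) +
    ggplot2::theme_minimal()
}
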