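#' Read a table of qPCR quantification cycles (Cq)
#'
#' Reads a delimited text file (comma or tab, auto-detected) of raw Cq values
#' and returns a tidy samples-by-genes tibble. Two layouts are supported:
#'
#' * `"long"`: columns `sample`, `gene`, `cq`, an optional `replicate` index,
#'   and optional per-sample factor columns (`limb`, `treatment`, `timepoint`,
#'   `animal`). Technical replicates are collapsed to their arithmetic mean;
#'   the per-well standard deviation is retained (see [replicate_sd()]) and
#'   replicates whose SD exceeds `flag_sd` cycles are flagged with a warning,
#'   never dropped.
#' * `"wide"`: one row per sample, one numeric column per gene, plus the
#'   factor columns.
#'
#' Samples missing a Cq for any gene are dropped (complete-case enforcement,
#' matching the sample-level QC the stability algorithms assume) with a
#' warning naming them.
#'
#' @param path Path to a delimited text file with a header row.
#' @param layout `"auto"` (default), `"long"` or `"wide"`. Auto detection
#'   looks for `gene` and `cq` columns.
#' @param flag_sd Replicate-SD flag threshold in cycles (default 0.5).
#' @return A tibble with one row per sample: `sample`, any factor columns,
#'   and one numeric Cq column per gene, carrying attributes
#'   `replicate_sd` (long input only) and `units = "cq"`.
#' @seealso [write_cq()], [cq_to_rq()], [cq_subsets()]
#' @export
read_cq <- function(path, layout = c("auto", "long", "wide"), flag_sd = 0.5) {
  layout <- arg_match(layout)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- tryCatch(
    readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                      progress = FALSE, trim_ws = TRUE),
    error = function(e) {
      abort(paste0("Could not parse '", path, "': ", conditionMessage(e)))
    }
  )
  # normalise the case of structural columns only; gene symbols keep theirs
  structural <- tolower(names(raw)) %in% c(.annotation_cols, "gene", "cq")
  names(raw)[structural] <- tolower(names(raw)[structural])
  if (layout == "auto") {
    layout <- if (all(c("gene", "cq") %in% names(raw))) "long" else "wide"
  }
  if (layout == "long") {
    required <- c("sample", "gene", "cq")
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0) {
      abort(paste0("Long layout requires columns: ", paste(missing, collapse = ", ")))
    }
    if (!is.numeric(raw$cq)) abort("Column 'cq' must be numeric.")
    key_cols <- intersect(c("sample", "gene", "replicate"), names(raw))
    if (anyDuplicated(raw[key_cols]) > 0) {
      abort("Duplicate (sample, gene, replicate) rows in input.")
    }
    data <- collapse_replicates(raw, flag_sd = flag_sd)
    rep_sd <- tidyr::pivot_wider(
      data, id_cols = "sample", names_from = "gene",
      values_from = "replicate_sd"
    )
    factor_cols <- intersect(setdiff(.annotation_cols, c("sample", "replicate")),
                             names(raw))
    annot <- distinct(raw[c("sample", factor_cols)])
    if (anyDuplicated(annot$sample) > 0) {
      abort("Sample annotations are inconsistent across rows of the same sample.")
    }
    wide <- tidyr::pivot_wider(data, id_cols = "sample",
                               names_from = "gene", values_from = "cq")
    wide <- left_join(annot, wide, by = "sample")
    # keep input sample order
    wide <- wide[match(unique(as.character(raw$sample)), wide$sample), ]
  } else {
    if (!"sample" %in% names(raw)) {
      abort("Wide layout requires a 'sample' column.")
    }
    if (anyDuplicated(raw$sample) > 0) abort("Duplicate sample rows in wide input.")
    wide <- raw
    rep_sd <- NULL
  }
  wide$sample <- as.character(wide$sample)
  genes <- cq_genes(wide)
  if (length(genes) < 3) {
    abort(paste0("Need at least 3 gene columns; found ", length(genes), "."))
  }
  incomplete <- !stats::complete.cases(wide[genes])
  if (any(incomplete)) {
    warn(paste0("Dropping ", sum(incomplete), " sample(s) with missing Cq values: ",
                paste(wide$sample[incomplete], collapse = ", ")))
    wide <- wide[!incomplete, ]
    if (!is.null(rep_sd)) rep_sd <- rep_sd[rep_sd$sample %in% wide$sample, ]
  }
  if (any(as.matrix(wide[genes]) <= 0)) abort("Cq values must be positive.")
  out <- as_tibble(wide)
  attr(out, "units") <- "cq"
  attr(out, "replicate_sd") <- rep_sd
  out
}

#' Collapse technical qPCR replicates
#'
#' Collapses a long tibble of replicate wells to one row per (sample, gene):
#' the arithmetic mean Cq, the replicate standard deviation, and a flag for
#' noisy triplicates. Flagged replicates are reported, never removed —
#' rejection of wells is left to the analyst.
#'
#' @param data Long tibble with columns `sample`, `gene`, `cq` (one row per
#'   well).
#' @param flag_sd Flag threshold for the replicate SD, in cycles.
#' @return Tibble with columns `sample`, `gene`, `cq` (mean), `replicate_sd`
#'   (`NA` for singletons) and `flagged`.
#' @export
#' @examples
#' wells <- tibble::tibble(
#'   sample = "S1", gene = rep(c("ACTB", "GAPDH"), each = 3),
#'   cq = c(20.0, 20.1, 19.9, 18.1, 18.3, 19.9)
#' )
#' collapse_replicates(wells)
collapse_replicates <- function(data, flag_sd = 0.5) {
  stopifnot(all(c("sample", "gene", "cq") %in% names(data)))
  out <- data %>%
    group_by(.data$sample, .data$gene) %>%
    summarise(
      replicate_sd = sd(.data$cq),
      cq = mean(.data$cq),
      .groups = "drop"
    ) %>%
    mutate(flagged = !is.na(.data$replicate_sd) & .data$replicate_sd > flag_sd) %>%
    select("sample", "gene", "cq", "replicate_sd", "flagged")
  if (any(out$flagged)) {
    noisy <- out[out$flagged, ]
    warn(paste0(
      "Replicate SD above ", flag_sd, " cycles for: ",
      paste(paste0(noisy$sample, "/", noisy$gene), collapse = ", "),
      " (flagged, not dropped)"
    ))
  }
  out
}

#' Replicate standard deviations retained by [read_cq()]
#'
#' @param data A Cq tibble returned by [read_cq()] from a long-layout file.
#' @return A samples-by-genes tibble of replicate SDs, or `NULL` when the
#'   input had no replicate structure.
#' @export
replicate_sd <- function(data) attr(data, "replicate_sd")

#' Convert Cq values to linear relative quantities (RQ)
#'
#' Converts quantification cycles to relative quantities with
#' `RQ = E^(calibrator - Cq)`, where `E` is the amplification efficiency
#' (2 = perfect per-cycle doubling) and the calibrator is the per-gene
#' minimum Cq, so every gene's maximum RQ is exactly 1. Any per-gene anchor
#' cancels in the downstream ratio-based statistics; the minimum-Cq anchor is
#' the geNorm convention and keeps RQ in (0, 1].
#'
#' @param data A samples-by-genes Cq tibble.
#' @param efficiency Amplification efficiency, a single value in `[1.6, 2.2]`
#'   applied to all genes (default 2).
#' @param genes Optional character vector of gene columns.
#' @return A tibble of the same shape with RQ values in the gene columns and
#'   attributes `units = "rq"`, `efficiency`, and `calibrator_cq` (named
#'   per-gene vector).
#' @export
#' @examples
#' cq <- tibble::tibble(sample = c("a", "b", "c"), ACTB = c(20, 21, 22),
#'                      GAPDH = c(19, 19, 19), HPRT1 = c(24, 25, 23))
#' cq_to_rq(cq)
cq_to_rq <- function(data, efficiency = 2, genes = NULL) {
  genes <- cq_genes(data, genes)
  if (!is.numeric(efficiency) || length(efficiency) != 1 ||
      efficiency < 1.6 || efficiency > 2.2) {
    abort("`efficiency` must be a single value in [1.6, 2.2].")
  }
  m <- cq_matrix(data, genes)
  calibrator <- apply(m, 1, min)
  rq <- efficiency^(calibrator - m)
  out <- data
  out[genes] <- as.data.frame(t(rq))
  out <- as_tibble(out)
  attr(out, "units") <- "rq"
  attr(out, "efficiency") <- efficiency
  attr(out, "calibrator_cq") <- calibrator
  attr(out, "replicate_sd") <- NULL
  out
}

#' Canonical study subsets of a Cq table
#'
#' Splits an annotated Cq table into the five canonical analysis subsets —
#' all samples, uninjured limbs, injured limbs, rapamycin-treated and
#' vehicle-treated animals — plus any user-defined subsets. Subsetting never
#' reorders the retained samples. Subsets with fewer than 3 samples trigger a
#' warning; subsets with fewer than 2 are dropped with a message (the
#' stability statistics are undefined there).
#'
#' @param data A Cq tibble with `limb` and `treatment` annotation columns.
#' @param extra Optional named list of user subsets, each a named character
#'   vector of `factor = level` pairs, e.g.
#'   `list(d7_only = c(timepoint = "d7"))`.
#' @return Named list of Cq tibbles.
#' @export
#' @examples
#' sim <- simulate_study(seed = 1)
#' sapply(cq_subsets(sim$data), nrow)
cq_subsets <- function(data, extra = NULL) {
  specs <- list(
    all_data = character(0),
    all_uninjured = c(limb = "uninjured"),
    all_injured = c(limb = "injured"),
    all_rapamycin = c(treatment = "rapamycin"),
    all_vehicle = c(treatment = "vehicle")
  )
  if (!is.null(extra)) {
    stopifnot(is.list(extra), !is.null(names(extra)))
    specs <- c(specs, extra)
  }
  out <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    keep <- rep(TRUE, nrow(data))
    for (fac in names(spec)) {
      if (!fac %in% names(data)) {
        abort(paste0("Subset '", nm, "' uses unknown factor column '", fac, "'."))
      }
      keep <- keep & (data[[fac]] == spec[[fac]])
    }
    sub <- data[keep, ]
    for (a in c("units", "efficiency", "calibrator_cq")) {
      attr(sub, a) <- attr(data, a)
    }
    if (nrow(sub) < 2) {
      inform(paste0("Subset '", nm, "' has ", nrow(sub),
                    " sample(s); excluded from analysis."))
      next
    }
    if (nrow(sub) < 3) {
      warn(paste0("Subset '", nm, "' has only ", nrow(sub), " samples."))
    }
    out[[nm]] <- sub
  }
  out
}

#' Write a Cq or RQ table as delimited text
#'
#' Writes the wide (one row per sample) layout with full precision, suitable
#' for re-reading with [read_cq()].
#'
#' @param data A samples-by-genes tibble.
#' @param path Output file path; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_cq <- function(data, path) {
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(data, path)
  } else {
    readr::write_csv(data, path)
  }
  invisible(path)
}
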