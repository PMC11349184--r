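#' Run the full reference-gene stability workflow and write a report bundle
#'
#' Orchestrates the complete analysis on an annotated Cq table: splits it
#' into the five canonical subsets, runs all four stability methods and the
#' integrated consensus on each, computes the geNorm pairwise-variation
#' series, runs grouped NormFinder analyses on the full dataset (by limb,
#' treatment, timepoint, and all three crossed), selects reference genes
#' (top 3 of the full-data aggregate when `reference_genes = "auto"`),
#' validates the requested target genes against the resulting normalisation
#' factor, and writes every table as tidy delimited text together with a
#' JSON run manifest (input checksum, configuration echo, package version,
#' collected warnings).
#'
#' @param data An annotated Cq tibble (from [read_cq()] or [simulate_cq()]).
#' @param out_dir Output directory, created if needed. On any stage error
#'   the partially written bundle is removed.
#' @param efficiency Amplification efficiency for RQ-based methods.
#' @param reference_genes `"auto"` (top 3 of the full-data aggregate) or a
#'   character vector of gene names.
#' @param targets Target genes to validate (default: the two worst-ranked
#'   genes of the full-data aggregate that are not reference genes).
#' @param validation_groups Annotation columns defining validation groups.
#' @param input_path Optional path of the source file, checksummed into the
#'   manifest.
#' @return Invisibly, a list with all in-memory results (`subsets`,
#'   `rankings`, `normfinder_grouped`, `validation`, `manifest`).
#' @export
run_refstab <- function(data, out_dir, efficiency = 2,
                        reference_genes = "auto", targets = NULL,
                        validation_groups = c("limb", "treatment"),
                        input_path = NULL) {
  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)
  emit <- function(tab, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tab, path)
    written <<- c(written, path)
    path
  }
  run <- function() withCallingHandlers({
    subsets <- cq_subsets(data)
    rankings <- list()
    for (nm in names(subsets)) {
      rk <- rank_stability(subsets[[nm]], efficiency = efficiency)
      rankings[[nm]] <- rk
      emit(rk$bestkeeper$stability, paste0(nm, "_bestkeeper"))
      emit(rk$genorm$ranking, paste0(nm, "_genorm"))
      emit(rk$genorm$v, paste0(nm, "_genorm_v"))
      emit(rk$normfinder$stability, paste0(nm, "_normfinder"))
      emit(rk$deltact$stability, paste0(nm, "_deltact"))
      emit(rk$aggregate, paste0(nm, "_aggregate"))
    }
    groupings <- list(injury = "limb", treatment = "treatment",
                      timepoint = "timepoint",
                      all_factors = c("limb", "treatment", "timepoint"))
    groupings <- purrr::keep(groupings, ~ all(.x %in% names(data)))
    nf_grouped <- list()
    for (nm in names(groupings)) {
      res <- normfinder(data, groups = groupings[[nm]], efficiency = efficiency)
      nf_grouped[[nm]] <- res
      emit(res$stability, paste0("normfinder_grouped_", nm))
      emit(res$groupwise, paste0("normfinder_grouped_", nm, "_diagnostics"))
    }
    agg <- rankings$all_data$aggregate
    refs <- if (identical(reference_genes, "auto")) {
      head(agg$gene, 3)
    } else {
      reference_genes
    }
    if (is.null(targets)) {
      targets <- setdiff(rev(agg$gene), refs)[1:2]
    }
    rq <- cq_to_rq(data, efficiency = efficiency)
    nf_tab <- normalization_factor(rq, refs)
    emit(nf_tab, "normalization_factor")
    validation <- list()
    for (tg in targets) {
      vr <- validate_target(rq, tg, refs, groups = validation_groups)
      validation[[tg]] <- vr
      emit(vr$groups, paste0("validation_", tg, "_groups"))
      emit(vr$samples, paste0("validation_", tg, "_samples"))
    }
    manifest <- list(
      package = "refstab",
      version = as.character(utils::packageVersion("refstab")),
      input_md5 = if (!is.null(input_path)) {
        unname(tools::md5sum(input_path))
      },
      n_samples = nrow(data),
      genes = cq_genes(data),
      efficiency = efficiency,
      subsets = lapply(subsets, nrow),
      reference_genes = refs,
      targets = targets,
      validation_groups = validation_groups,
      warnings = warnings_log,
      files = basename(written)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    list(subsets = subsets, rankings = rankings,
         normfinder_grouped = nf_grouped, validation = validation,
         reference_genes = refs, manifest = manifest)
  },
  warning = function(w) {
    note(conditionMessage(w))
    invokeRestart("muffleWarning")
  },
  message = function(m) {
    note(trimws(conditionMessage(m)))
    invokeRestart("muffleMessage")
  })
  out <- tryCatch(run(), error = function(e) {
    # remove partial outputs so a failed run leaves nothing behind
    unlink(written)
    if (created) unlink(out_dir, recursive = TRUE)
    abort(paste0("refstab run failed: ", conditionMessage(e)), parent = e)
  })
  invisible(out)
}
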