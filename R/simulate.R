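#' Describe one simulated candidate reference gene
#'
#' @param name Gene symbol.
#' @param baseline_cq Baseline Cq in cycles (e.g. ~8 for an abundant
#'   rRNA-like gene, 22–26 for modestly expressed genes).
#' @param gene_noise_sd Per-sample biological noise SD, in cycles.
#' @param effects List of condition-linked shifts built with [cq_effect()].
#' @param loading_coupling Fraction (0–1) of the shared per-sample loading
#'   offset this gene reflects. 1 (default) models a gene whose measured Cq
#'   fully tracks input cDNA amount; values below 1 create genes that defeat
#'   consensus-correlation ranking but not ratio-based ranking.
#' @return A `gene_spec` list.
#' @seealso [sim_config()], [simulate_cq()]
#' @export
gene_spec <- function(name, baseline_cq, gene_noise_sd = 0.15,
                      effects = list(), loading_coupling = 1) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(baseline_cq), baseline_cq > 0,
            gene_noise_sd >= 0,
            loading_coupling >= 0, loading_coupling <= 1)
  structure(
    list(name = name, baseline_cq = baseline_cq,
         gene_noise_sd = gene_noise_sd, effects = effects,
         loading_coupling = loading_coupling),
    class = "gene_spec"
  )
}

#' A condition-linked Cq shift for a simulated gene
#'
#' @param delta_cq Shift in cycles added to samples matching the condition.
#'   Positive values mean higher Cq, i.e. lower expression.
#' @param ... One or more `factor = level` pairs (e.g. `limb = "injured"`);
#'   a sample receives the shift only if it matches all of them, so
#'   multi-factor conditions express interactions.
#' @return A `cq_effect` list.
#' @export
#' @examples
#' cq_effect(1.0, limb = "injured")
#' cq_effect(-0.7, limb = "uninjured", treatment = "rapamycin")
cq_effect <- function(delta_cq, ...) {
  when <- c(...)
  stopifnot(is.numeric(delta_cq), length(delta_cq) == 1,
            length(when) > 0, !is.null(names(when)))
  structure(list(delta_cq = delta_cq, when = when), class = "cq_effect")
}

#' Simulation configuration for a factorial qPCR study
#'
#' @param genes List of [gene_spec()] objects.
#' @param design Tibble with columns `limb`, `treatment`, `timepoint`, `n`
#'   giving per-group sample counts.
#' @param loading_sd SD (cycles) of the per-sample global loading offset
#'   shared by all genes — the simulator's model of variation in RNA
#'   isolation and cDNA synthesis efficiency that normalisation should
#'   remove.
#' @param replicate_sd SD (cycles) of technical replicate noise per well.
#' @param replicates Technical replicates per (sample, gene); collapsed to
#'   their mean in the emitted table.
#' @param seed Mandatory integer seed; simulation is fully reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genes, design, loading_sd = 0.8, replicate_sd = 0.1,
                       replicates = 3, seed) {
  if (length(genes) == 0) abort("`genes` must contain at least one gene_spec.")
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_spec")),
            is.data.frame(design),
            all(c("limb", "treatment", "timepoint", "n") %in% names(design)),
            all(design$n >= 0), sum(design$n) >= 4,
            loading_sd >= 0, replicate_sd >= 0, replicates >= 1)
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory.")
  structure(
    list(genes = genes, design = as_tibble(design), loading_sd = loading_sd,
         replicate_sd = replicate_sd, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a Cq dataset with known ground truth
#'
#' Generates replicate-collapsed Cq values under an additive model on the
#' cycle (log-quantity) scale:
#' `Cq(g, s, rep) = baseline(g) + coupling(g) * L(s) + effects(g, s) +
#' N(0, gene_noise_sd(g)) + N(0, replicate_sd)`, with per-sample loading
#' offsets `L(s) ~ N(0, loading_sd)`. Gaussian noise in cycles corresponds to
#' multiplicative (log-normal) noise in quantity, which is how qPCR error
#' behaves.
#'
#' @param config A [sim_config()].
#' @return A list with `data` (annotated samples-by-genes Cq tibble with
#'   replicate SD attribute) and `truth` (list: per-sample `loading` offsets,
#'   per-gene `genes` table of injected noise SDs and couplings, and the
#'   injected `effects`).
#' @export
#' @examples
#' cfg <- default_study_config(seed = 42)
#' sim <- simulate_cq(cfg)
#' dim(sim$data)
simulate_cq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- config$design[config$design$n > 0, ]
  samples <- design %>%
    mutate(.group = row_number()) %>%
    tidyr::uncount(.data$n, .id = "rep_in_group")
  n_s <- nrow(samples)
  samples$sample <- sprintf("S%02d", seq_len(n_s))
  # contralateral design: animals within a treatment x timepoint cell
  samples <- samples %>%
    group_by(.data$treatment, .data$timepoint) %>%
    mutate(animal = sprintf("%s_%s_A%d", substr(.data$treatment, 1, 4),
                            .data$timepoint, .data$rep_in_group)) %>%
    ungroup() %>%
    select("sample", "limb", "treatment", "timepoint", "animal")

  gene_names <- vapply(config$genes, `[[`, character(1), "name")
  withr::with_seed(config$seed, {
    loading <- rnorm(n_s, 0, config$loading_sd)
    cq <- matrix(NA_real_, nrow = length(gene_names), ncol = n_s,
                 dimnames = list(gene_names, samples$sample))
    rep_sd <- cq
    for (gi in seq_along(config$genes)) {
      g <- config$genes[[gi]]
      shift <- rep(0, n_s)
      for (eff in g$effects) {
        match_s <- rep(TRUE, n_s)
        for (fac in names(eff$when)) {
          match_s <- match_s & (samples[[fac]] == eff$when[[fac]])
        }
        shift <- shift + ifelse(match_s, eff$delta_cq, 0)
      }
      mu <- g$baseline_cq + g$loading_coupling * loading + shift +
        rnorm(n_s, 0, g$gene_noise_sd)
      wells <- matrix(rnorm(n_s * config$replicates, 0, config$replicate_sd),
                      nrow = config$replicates) +
        matrix(mu, nrow = config$replicates, ncol = n_s, byrow = TRUE)
      cq[gi, ] <- colMeans(wells)
      rep_sd[gi, ] <- apply(wells, 2, sd)
    }
  })
  data <- dplyr::bind_cols(samples, as_tibble(t(cq)))
  attr(data, "units") <- "cq"
  if (config$replicates > 1) {
    attr(data, "replicate_sd") <-
      dplyr::bind_cols(samples["sample"], as_tibble(t(rep_sd)))
  }
  truth <- list(
    loading = tibble(sample = samples$sample, loading = loading),
    genes = tibble(
      gene = gene_names,
      baseline_cq = vapply(config$genes, `[[`, numeric(1), "baseline_cq"),
      gene_noise_sd = vapply(config$genes, `[[`, numeric(1), "gene_noise_sd"),
      loading_coupling = vapply(config$genes, `[[`, numeric(1), "loading_coupling"),
      n_effects = vapply(config$genes, function(g) length(g$effects), integer(1))
    ),
    effects = setNames(lapply(config$genes, `[[`, "effects"), gene_names)
  )
  list(data = data, truth = truth)
}

#' Default synthetic tendon-injury study configuration
#'
#' Emulates a 2 (limb: injured/uninjured) x 2 (treatment: rapamycin/vehicle)
#' x 2 (timepoint: 7d/21d) factorial design with 35 samples (19 uninjured,
#' 16 injured; 18 rapamycin, 17 vehicle; n = 4–5 per group) and an
#' 11-candidate reference panel spanning high (18S rRNA) to modest
#' abundance. Two genes are deliberately unstable: *SDHA* carries a
#' 1.0-cycle injury-associated increase in Cq (reduced expression after
#' injury) and *GAPDH* a rapamycin-by-injury interaction (expression up in
#' treated uninjured tendon, down in treated injured tendon); *18S* and
#' *UBC* carry elevated biological noise. All remaining candidates are
#' stable by construction.
#'
#' @param seed Integer seed passed to [sim_config()].
#' @return A [sim_config()] ready for [simulate_cq()].
#' @export
default_study_config <- function(seed) {
  design <- tidyr::expand_grid(
    limb = c("uninjured", "injured"),
    treatment = c("rapamycin", "vehicle"),
    timepoint = c("d7", "d21")
  )
  design$n <- c(5L, 5L, 5L, 4L,   # uninjured: rapa d7/d21, vehicle d7/d21
                4L, 4L, 4L, 4L)   # injured
  genes <- list(
    gene_spec("18S",     8,  gene_noise_sd = 0.35),
    gene_spec("ACTB",    17),
    gene_spec("AP3D1",   25),
    gene_spec("B2M",     18),
    gene_spec("CSNK2A2", 24),
    gene_spec("GAPDH",   19, effects = list(
      cq_effect(-0.7, limb = "uninjured", treatment = "rapamycin"),
      cq_effect(0.7,  limb = "injured",   treatment = "rapamycin")
    )),
    gene_spec("HPRT1",   24),
    gene_spec("PAK1IP1", 26),
    gene_spec("RPL13a",  16),
    gene_spec("SDHA",    22, effects = list(cq_effect(1.0, limb = "injured"))),
    gene_spec("UBC",     23, gene_noise_sd = 0.25)
  )
  sim_config(genes = genes, design = design, loading_sd = 0.8,
             replicate_sd = 0.1, replicates = 3, seed = seed)
}

#' Simulate the default study dataset
#'
#' Shorthand for `simulate_cq(default_study_config(seed))`.
#'
#' @inheritParams default_study_config
#' @return See [simulate_cq()].
#' @export
simulate_study <- function(seed) simulate_cq(default_study_config(seed))
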