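#' Describe a paired enrichment/input sequencing design
#'
#' The default mirrors a four-stage developmental time course (embryo,
#' larva, pupa, adult) with three biological replicates, each sequenced
#' as one input and one enrichment library.
#'
#' @param stages Ordered character vector of stage labels.
#' @param replicates Replicates per stage (>= 2).
#' @param depth Expected total counts per library.
#' @param dispersion Negative-binomial dispersion shared by all rows
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param seed Integer seed for the simulator.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(stages = c("embryo", "larva", "pupa", "adult"),
                        replicates = 3L, depth = 2e5,
                        dispersion = 0.05, seed = 1L) {
  if (length(stages) < 1L) stopf("at least one stage is required")
  if (replicates < 2L) stopf("'replicates' must be at least 2")
  if (depth <= 0) stopf("'depth' must be positive")
  if (dispersion < 0) stopf("'dispersion' must be non-negative")
  structure(list(stages = as.character(stages),
                 replicates = as.integer(replicates),
                 depth = depth, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Define the spike-in species added to every library
#'
#' Three classes mirror the control design of spike-in anchored capture
#' experiments: a set of `scaling` species (foreign-transcriptome RNA
#' carrying no NAD cap, used only for normalization), one `sensitivity`
#' species containing a known NAD-capped fraction (5% by default), and
#' one `specificity` species that is 100% m7G-capped and must show no
#' enrichment.
#'
#' @param n_scaling Number of scaling species.
#' @param sensitivity_fraction,specificity_fraction NAD-capped fraction
#'   of the sensitivity and specificity species.
#' @param sensitivity_abundance,specificity_abundance Base abundance of
#'   the two synthetic species (same units as gene base means).
#' @param scaling_meanlog,scaling_sdlog Log-normal quantile parameters
#'   for the deterministic scaling-species abundances.
#' @return Data frame with columns `spikein_id`, `class`, `nad_fraction`,
#'   `base_abundance`.
#' @export
spikein_spec <- function(n_scaling = 100L,
                         sensitivity_fraction = 0.05,
                         specificity_fraction = 0,
                         sensitivity_abundance = 500,
                         specificity_abundance = 500,
                         scaling_meanlog = log(100), scaling_sdlog = 1) {
  stopifnot(n_scaling >= 1L)
  scal <- data.frame(
    spikein_id = sprintf("SPIKE_SCALING_%03d", seq_len(n_scaling)),
    class = "scaling",
    nad_fraction = 0,
    base_abundance = stats::qlnorm(stats::ppoints(n_scaling),
                                   scaling_meanlog, scaling_sdlog),
    stringsAsFactors = FALSE
  )
  syn <- data.frame(
    spikein_id = c("SPIKE_SENSITIVITY", "SPIKE_SPECIFICITY"),
    class = c("sensitivity", "specificity"),
    nad_fraction = c(sensitivity_fraction, specificity_fraction),
    base_abundance = c(sensitivity_abundance, specificity_abundance),
    stringsAsFactors = FALSE
  )
  out <- rbind(scal, syn)
  if (any(out$nad_fraction < 0 | out$nad_fraction > 1)) {
    stopf("nad_fraction must lie in [0, 1]")
  }
  if (any(out$base_abundance <= 0)) stopf("base_abundance must be positive")
  out
}

# Enrichment-fraction gain of a spike-in species: a species with no
# NAD-capped molecules is captured at baseline (gain 1); the NAD-capped
# portion is captured `capture_efficiency`-fold more efficiently.
spikein_effective_gain <- function(nad_fraction, capture_efficiency) {
  1 + nad_fraction * capture_efficiency
}

#' Simulate paired enrichment/input count libraries
#'
#' Input libraries draw negative-binomial counts around base abundances
#' scaled to the library depth. Enrichment libraries multiply each row's
#' abundance by its capture gain — `truth$gain` for genes, `1 +
#' nad_fraction * capture_efficiency` for spike-ins — and renormalize to
#' depth, reproducing the compositional distortion that spike-in
#' anchored normalization must undo.
#'
#' @param genes Gene table ([generate_gene_models()]).
#' @param truth Truth table ([plant_truth()]), aligned with `genes`.
#' @param design A [design_spec()].
#' @param spikeins A [spikein_spec()] data frame.
#' @param expr_model Function of `n` returning positive per-gene base
#'   means.
#' @param capture_efficiency Fold-capture advantage of a fully NAD-capped
#'   molecule over an uncapped one in the enrichment step.
#' @param gain_by_stage Optional genes-by-stages numeric matrix of
#'   per-stage gene gains, overriding `truth$gain` (used to simulate
#'   stage-specific capping dynamics).
#' @return A [count_matrix()]; the expected (noise-free) count matrix is
#'   attached as attribute `"mu"`.
#' @export
simulate_counts <- function(genes, truth, design = design_spec(),
                            spikeins = spikein_spec(),
                            expr_model = function(n) rlnorm(n, log(100), 1),
                            capture_efficiency = 600,
                            gain_by_stage = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (!identical(genes$gene_id, truth$gene_id)) {
    stopf("'genes' and 'truth' must be aligned on gene_id")
  }
  if (design$depth <= 0) stopf("zero depth")
  n_gene <- nrow(genes)
  stages <- design$stages
  if (!is.null(gain_by_stage)) {
    gain_by_stage <- as.matrix(gain_by_stage)
    if (nrow(gain_by_stage) != n_gene || ncol(gain_by_stage) != length(stages)) {
      stopf("'gain_by_stage' must be a %d x %d matrix", n_gene, length(stages))
    }
  }

  local_seed(derive_seed(design$seed, 101L), {
    base_gene <- expr_model(n_gene)
    if (any(base_gene <= 0)) stopf("expr_model must yield positive means")
    base <- c(base_gene, spikeins$base_abundance)
    ids <- c(genes$gene_id, spikeins$spikein_id)
    spike_gain <- spikein_effective_gain(spikeins$nad_fraction,
                                         capture_efficiency)

    lib_meta <- expand.grid(fraction = c("input", "enrichment"),
                            replicate = seq_len(design$replicates),
                            stage = stages,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
    lib_meta <- lib_meta[, c("stage", "replicate", "fraction")]
    lib_meta$library_id <- sprintf("%s_r%d_%s", lib_meta$stage,
                                   lib_meta$replicate,
                                   ifelse(lib_meta$fraction == "input",
                                          "in", "en"))

    mu <- matrix(0, nrow = length(ids), ncol = nrow(lib_meta),
                 dimnames = list(ids, lib_meta$library_id))
    for (j in seq_len(nrow(lib_meta))) {
      st <- lib_meta$stage[j]
      gg <- if (is.null(gain_by_stage)) truth$gain
            else gain_by_stage[, match(st, stages)]
      w <- if (lib_meta$fraction[j] == "input") base
           else base * c(gg, spike_gain)
      mu[, j] <- design$depth * w / sum(w)
    }

    counts <- matrix(0L, nrow = nrow(mu), ncol = ncol(mu),
                     dimnames = dimnames(mu))
    for (j in seq_len(ncol(mu))) {
      counts[, j] <- if (design$dispersion == 0) {
        rpois(nrow(mu), mu[, j])
      } else {
        rnbinom(nrow(mu), mu = mu[, j], size = 1 / design$dispersion)
      }
    }

    rows <- data.frame(
      gene_id = ids,
      is_spikein = c(rep(FALSE, n_gene), rep(TRUE, nrow(spikeins))),
      spikein_class = c(rep(NA_character_, n_gene), spikeins$class),
      stringsAsFactors = FALSE
    )
    cm <- count_matrix(counts, lib_meta[, c("library_id", "stage",
                                            "replicate", "fraction")], rows)
    attr(cm, "mu") <- mu
    cm
  })
}
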