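#' Build a validated run configuration
#'
#' Collects every tunable of the pipeline with its standard default:
#' 2-fold calling cutoff, minimum cluster size 3, L scan over 1-5 kb,
#' 10000 permutations, Z cutoff 1.3, significance 0.05. Unknown fields
#' are rejected so typos in config files fail early.
#'
#' @param ... Named overrides of the defaults, or a single named list.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    mode = "full",            # simulate | analyze | full
    outdir = "nadrna-run",
    annotation = NULL, counts = NULL, libraries = NULL,
    # simulator
    n_genes = 2000L, base_rate = 0.1, gain = 8,
    n_clusters = 0L, cluster_size = 4L, max_intra_gap = 2000L,
    length_bias = 0, depth = 2e5, replicates = 3L, dispersion = 0.05,
    capture_efficiency = 600,
    stages = c("embryo", "larva", "pupa", "adult"),
    # calling
    cutoff = 2, min_input = 10, pseudocount = 1,
    # clusters
    L_list = c(1, 2, 3, 4, 5), N_min = 3L, n_perm = 10000L,
    # signatures / features
    z_cutoff = 1.3, significance = 0.05,
    seed = 1L
  )
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && is.list(args[[1]])) {
    args <- args[[1]]
  }
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) {
    stopf("unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, args)
  if (!cfg$mode %in% c("simulate", "analyze", "full")) {
    stopf("mode must be simulate, analyze or full")
  }
  if (cfg$cutoff < 1) stopf("cutoff must be at least 1")
  if (cfg$N_min < 3) stopf("N_min must be at least 3")
  if (any(cfg$L_list <= 0)) stopf("L_list must be positive")
  if (cfg$n_perm < 1) stopf("n_perm must be positive")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are [run_config()] fields.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Run the pipeline: simulate, analyze, or both
#'
#' `simulate` writes a synthetic dataset (annotation BED6+3, counts and
#' library-sheet TSVs, ground-truth TSV) under `outdir`. `analyze` reads
#' annotation + counts, normalizes on the scaling spike-ins, calls
#' NAD-RNAs, assesses the spike-in controls, computes saturation curves,
#' runs the physical-cluster scan per stage, calls stage signatures, and
#' writes the feature analyses. `full` chains both. Every output table
#' is listed in a JSON manifest together with parameters and seed;
#' identical configuration and seed give identical outputs.
#'
#' @param config A [run_config()] (or named list of overrides).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    annotation = config$annotation %||% file.path(config$outdir, "annotation.bed"),
    counts = config$counts %||% file.path(config$outdir, "counts.tsv"),
    libraries = config$libraries %||% file.path(config$outdir, "libraries.tsv"),
    truth = file.path(config$outdir, "truth.tsv")
  )

  if (config$mode %in% c("simulate", "full")) {
    genes <- generate_gene_models(config$n_genes,
                                  seed = derive_seed(config$seed, 1L))
    truth <- plant_truth(genes, base_rate = config$base_rate,
                         gain = config$gain, n_clusters = config$n_clusters,
                         cluster_size = config$cluster_size,
                         max_intra_gap = config$max_intra_gap,
                         length_bias = config$length_bias,
                         seed = derive_seed(config$seed, 2L))
    design <- design_spec(stages = config$stages,
                          replicates = config$replicates,
                          depth = config$depth,
                          dispersion = config$dispersion,
                          seed = derive_seed(config$seed, 3L))
    cm <- simulate_counts(genes, truth, design,
                          capture_efficiency = config$capture_efficiency)
    write_gene_annotation(genes, paths$annotation)
    write_count_matrix(cm, paths$counts, paths$libraries)
    write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    sidecar <- file.path(config$outdir, "simulation-params.json")
    jsonlite::write_json(
      c(unclass(config)[c("n_genes", "base_rate", "gain", "n_clusters",
                          "cluster_size", "max_intra_gap", "length_bias",
                          "depth", "replicates", "dispersion",
                          "capture_efficiency", "stages", "seed")]),
      sidecar, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  manifest <- NULL
  if (config$mode %in% c("analyze", "full")) {
    genes <- read_gene_annotation(paths$annotation)
    cm <- read_count_matrix(paths$counts, paths$libraries)
    factors <- compute_scale_factors(cm)
    tab <- compute_fold_enrichment(cm, factors,
                                   pseudocount = config$pseudocount)
    calls <- call_nad_rnas(tab, cutoff = config$cutoff,
                           min_input = config$min_input)
    controls <- assess_spikein_controls(tab)

    sat <- do.call(rbind, lapply(seq_len(ncol(cm$counts)), function(j) {
      s <- saturation_curve(cm$counts[, j],
                            seed = derive_seed(config$seed, 400L + j))
      cbind(library_id = colnames(cm$counts)[j], s)
    }))

    cluster_rows <- list()
    signature_rows <- list()
    for (k in seq_along(config$stages)) {
      st <- config$stages[k]
      called_ids <- calls$called[[st]]
      called_genes <- genes[genes$gene_id %in% called_ids, , drop = FALSE]
      if (nrow(called_genes) >= config$N_min) {
        scan <- scan_L_settings(called_genes, genes, L_list = config$L_list,
                                N_min = config$N_min, n_perm = config$n_perm,
                                seed = derive_seed(config$seed, 500L + k))
        cluster_rows[[st]] <- cbind(stage = st, scan$summary)
      }
    }
    M <- enrichment_matrix(calls)
    sig <- zscore_transform(M)
    sig_lists <- call_signatures(sig, cutoff = config$z_cutoff)
    signature_tab <- do.call(rbind, lapply(names(sig_lists), function(st) {
      if (!length(sig_lists[[st]])) return(NULL)
      data.frame(stage = st, gene_id = sig_lists[[st]],
                 stringsAsFactors = FALSE)
    })) %||% data.frame(stage = character(0), gene_id = character(0))

    gene_tab <- calls$table[!calls$table$is_spikein, , drop = FALSE]
    called_any <- gene_tab[gene_tab$is_called, , drop = FALSE]
    called_any$gene_length <-
      genes$gene_length[match(called_any$gene_id, genes$gene_id)]
    deciles <- if (nrow(called_any) >= 10) enrichment_deciles(called_any)
               else NULL

    utr_rows <- list()
    for (st in config$stages) {
      sub <- gene_tab[gene_tab$stage == st, , drop = FALSE]
      expressed <- sub$mean_input_norm >= config$min_input
      nad <- sub$gene_id[sub$is_called]
      m7g <- sub$gene_id[expressed & !sub$is_called]
      for (utr in c("utr5_len", "utr3_len")) {
        a <- genes[[utr]][match(nad, genes$gene_id)]
        b <- genes[[utr]][match(m7g, genes$gene_id)]
        a <- a[a > 0]          # zero UTR = missing annotation
        b <- b[b > 0]
        if (length(a) >= 2 && length(b) >= 2 && (sd(a) > 0 || sd(b) > 0)) {
          w <- compare_utr_lengths(a, b)
          utr_rows[[paste(st, utr)]] <- data.frame(
            stage = st, utr = sub("_len", "", utr),
            mean_nad = w$mean_a, mean_m7g = w$mean_b,
            t = w$t, p = w$p, stringsAsFactors = FALSE)
        }
      }
    }

    tab_biotype <- tabulate_calls(calls$called, genes, "biotype")
    tab_chrom <- tabulate_calls(calls$called, genes, "chrom")

    tables <- list(
      enrichment = calls$table,
      spikein_controls = controls$report,
      saturation = sat,
      signatures = signature_tab,
      tabulation_biotype = tab_biotype,
      tabulation_chrom = tab_chrom
    )
    if (length(cluster_rows)) {
      tables$clusters <- do.call(rbind, cluster_rows)
    }
    if (!is.null(deciles)) tables$deciles <- deciles
    if (length(utr_rows)) tables$utr_tests <- do.call(rbind, utr_rows)

    manifest <- write_results(tables, config$outdir,
                              params = unclass(config)[setdiff(names(config),
                                                               "outdir")],
                              seed = config$seed)
  }
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
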