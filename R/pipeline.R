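#' Demonstration pipeline configuration
#'
#' An end-to-end configuration on synthetic data: a five-sample cytometry
#' cohort (5,000 events each), 50 bulk mixtures of six reference types and a
#' 3,000-cell single-cell matrix, all with planted ground truth.  Every
#' stage seed derives from the single top-level `seed`.
#'
#' @param out_dir output directory.
#' @param seed master integer seed.
#' @param n_samples,n_events cohort shape.
#' @param n_bulk bulk mixture count.
#' @param n_cells_per_type single-cell counts per planted type.
#' @param n_boot stability bootstrap replicates.
#' @param k neighbour count for clustering.
#' @return a named config list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("phenotime_run_"), seed = 1L,
                        n_samples = 5, n_events = 5000, n_bulk = 50,
                        n_cells_per_type = 500, n_boot = 20, k = 60) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = c("simulate", "transform", "cluster", "annotate", "compose",
               "deconvolve", "ic_activity", "sc"),
    simulate = list(n_samples = n_samples, n_events = n_events),
    transform = list(mode = "logicle"),
    cluster = list(k = k, cd45_channel = "CD45", cd45_mode = "quantile",
                   n_boot = n_boot),
    deconvolve = list(alpha = 0.25, folds = 10, n_bulk = n_bulk,
                      noise_sd = 0.1),
    sc = list(n_cells_per_type = n_cells_per_type,
              min_genes = 200, min_cells = 3, max_mito = 0.05)
  )
}

pipeline_config_keys <- function() {
  c("out_dir", "seed", "stages", "simulate", "transform", "cluster",
    "annotate", "compose", "deconvolve", "ic_activity", "sc")
}

validate_config <- function(config) {
  unknown <- setdiff(names(config), pipeline_config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config field 'out_dir' is required")
  if (is.null(config$seed)) stop("config field 'seed' is required: ",
                                 "all randomness must be explicitly seeded")
  if (!is.null(config$cluster$k) && !is.null(config$simulate$n_events) &&
      config$cluster$k >= config$simulate$n_events)
    stop("invalid config field 'k': k (", config$cluster$k,
         ") must be smaller than n_events (", config$simulate$n_events, ")")
  invisible(config)
}

write_tsv <- function(x, path, rownames_col = NULL) {
  df <- as.data.frame(x)
  if (!is.null(rownames_col)) df <- cbind(setNames(list(rownames(x)),
                                                   rownames_col), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the phenotime pipeline
#'
#' Executes the configured stages in dependency order
#' (simulate -> transform -> cluster -> annotate -> compose |
#' deconvolve | ic_activity | sc), writes per-stage TSV outputs under
#' `out_dir` and a JSON run manifest with per-output MD5 checksums and
#' per-stage wall times.  Deterministic stages reproduce identical checksums
#' when re-run with the same configuration.
#'
#' @param config a config list (see [demo_config()]) or path to a YAML file.
#' @return the run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stages <- config$stages %||% c("simulate", "transform", "cluster",
                                 "annotate", "compose", "deconvolve",
                                 "ic_activity", "sc")
  manifest <- list(tool = "phenotime", version = "0.1.0",
                   config_hash = digest_config(config), stages = list())
  outputs <- character()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    files <- fn()
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      outputs = as.list(tools::md5sum(files)))
    outputs <<- c(outputs, files)
    invisible(NULL)
  }

  run_stage("simulate", function() {
    sim <- config$simulate %||% list()
    cc <- default_cohort_config(n_samples = sim$n_samples %||% 5,
                                n_events = sim$n_events %||% 5000,
                                seed = derive_seed(seed, 1L))
    state$cohort <- generate_event_cohort(cc)
    files <- character()
    truth <- data.frame()
    for (nm in names(state$cohort)) {
      f <- file.path(out_dir, paste0("events_", nm, ".csv"))
      write_events_csv(state$cohort[[nm]], f)
      files <- c(files, f)
      truth <- rbind(truth, data.frame(sample_id = nm,
                                       event = seq_along(state$cohort[[nm]]$truth$labels),
                                       label = state$cohort[[nm]]$truth$labels))
    }
    tf <- write_tsv(truth, file.path(out_dir, "truth_labels.tsv"))
    mf <- file.path(out_dir, "cohort_manifest.json")
    jsonlite::write_json(list(samples = names(state$cohort),
                              panel = default_panel(),
                              seed = seed,
                              truth_labels = "truth_labels.tsv"),
                         mf, auto_unbox = TRUE, pretty = TRUE)
    c(files, tf, mf)
  })

  run_stage("transform", function() {
    mode <- (config$transform %||% list())$mode %||% "logicle"
    tables <- lapply(state$cohort, function(t) {
      if (mode == "logicle") auto_logicle_transform(t)$stained
      else arcsinh_transform(t, cofactor = (config$transform$cofactor %||% 150))
    })
    state$merged <- merge_samples(tables)
    state$truth <- unlist(lapply(state$cohort, function(t) t$truth$labels),
                          use.names = FALSE)
    f <- file.path(out_dir, "events_transformed.tsv")
    write_tsv(cbind(sample_id = state$merged$provenance,
                    as.data.frame(state$merged$values)), f)
  })

  run_stage("cluster", function() {
    cl <- config$cluster %||% list()
    res <- two_round_cluster(state$merged, k = cl$k %||% 60,
                             cd45_channel = cl$cd45_channel %||% "CD45",
                             cd45_mode = cl$cd45_mode %||% "quantile",
                             seed = derive_seed(seed, 2L))
    state$pheno <- res
    kept <- state$merged
    kept$values <- kept$values[res$kept_mask, , drop = FALSE]
    kept$provenance <- kept$provenance[res$kept_mask]
    state$kept <- kept
    stab <- cluster_stability(kept, res$round2_labels[res$kept_mask],
                              n_boot = cl$n_boot %||% 20, k = cl$k %||% 60,
                              seed = derive_seed(seed, 3L))
    state$stability <- stab
    f1 <- write_tsv(data.frame(sample_id = state$merged$provenance,
                               round1 = res$round1_labels,
                               kept = res$kept_mask,
                               round2 = res$round2_labels),
                    file.path(out_dir, "phenoclusters.tsv"))
    f2 <- write_tsv(stab, file.path(out_dir, "cluster_stability.tsv"))
    c(f1, f2)
  })

  run_stage("annotate", function() {
    summ <- summarize_markers(state$kept,
                              state$pheno$round2_labels[state$pheno$kept_mask])
    state$annotations <- summ
    df <- do.call(rbind, lapply(summ, function(s) {
      data.frame(cluster = s$cluster, annotation = s$annotation,
                 t(s$medians), check.names = FALSE)
    }))
    write_tsv(df, file.path(out_dir, "marker_summaries.tsv"))
  })

  run_stage("compose", function() {
    comp <- composition(state$pheno$round2_labels[state$pheno$kept_mask],
                        state$kept$provenance)
    state$composition <- comp
    f1 <- write_tsv(unclass(comp), file.path(out_dir, "composition.tsv"),
                    rownames_col = "sample_id")
    if (nrow(comp) < 3) return(f1)  # correlations need >= 3 samples
    rep_ct <- correlate(comp, axis = "celltypes")
    f2 <- write_tsv(rep_ct$r, file.path(out_dir, "cluster_correlation_r.tsv"),
                    rownames_col = "cluster")
    f3 <- write_tsv(rep_ct$p, file.path(out_dir, "cluster_correlation_p.tsv"),
                    rownames_col = "cluster")
    c(f1, f2, f3)
  })

  run_stage("deconvolve", function() {
    dc <- config$deconvolve %||% list()
    profiles <- synthetic_reference_profiles(seed = derive_seed(seed, 4L))
    weights <- random_mixing_weights(dc$n_bulk %||% 50,
                                     seed = derive_seed(seed, 5L))
    bulk <- generate_bulk_mixtures(bulk_config(profiles, weights,
                                               noise_sd = dc$noise_sd %||% 0.1,
                                               seed = derive_seed(seed, 6L)))
    panel <- build_reference(
      expression_matrix(log2(profiles + 1),
                        norm_state = c("tpm", "quantile", "log2")),
      setNames(colnames(profiles), colnames(profiles)))
    res <- deconvolve(bulk, panel, alpha = dc$alpha %||% 0.25,
                      folds = dc$folds %||% 10, seed = derive_seed(seed, 7L))
    state$bulk <- bulk
    state$deconv <- res
    f1 <- write_tsv(res$coefficients, file.path(out_dir, "deconvolution.tsv"),
                    rownames_col = "sample_id")
    f2 <- write_tsv(attr(bulk, "truth_weights"),
                    file.path(out_dir, "deconvolution_truth.tsv"),
                    rownames_col = "sample_id")
    mf <- file.path(out_dir, "deconvolution_meta.json")
    jsonlite::write_json(list(alpha = res$alpha, folds = res$folds,
                              lambda = res$lambda, seed = res$seed),
                         mf, auto_unbox = TRUE, pretty = TRUE)
    c(f1, f2, mf)
  })

  run_stage("ic_activity", function() {
    ics <- synthetic_ic_sets()
    act <- ic_activity(state$bulk, ics)
    state$activity <- act
    write_tsv(unclass(act), file.path(out_dir, "ic_activity.tsv"),
              rownames_col = "ic")
  })

  run_stage("sc", function() {
    sc <- config$sc %||% list()
    npc <- sc$n_cells_per_type %||% 500
    ics <- synthetic_ic_sets()
    cfg <- sc_config(
      cell_types = setNames(rep(npc, 6),
                            c("Tumor", "MG", "MDM", "Neutrophil", "CD4T", "CD8T")),
      gene_clusters = ics,
      programs = list(list(cluster = "IC_MDM", cell_types = c("MDM", "MG"),
                           shift = 2),
                      list(cluster = "IC_Neutrophil", cell_types = "Neutrophil",
                           shift = 2),
                      list(cluster = "IC_CD4T", cell_types = c("CD4T", "CD8T"),
                           shift = 2)),
      seed = derive_seed(seed, 8L))
    mat <- generate_sc_matrix(cfg)
    res <- sc_ic_analysis(mat$values, mat$cell_types, ics,
                          min_genes = sc$min_genes %||% 200,
                          min_cells = sc$min_cells %||% 3,
                          max_mito = sc$max_mito %||% 0.05)
    state$sc <- res
    files <- character()
    for (ic in names(res$fractions)) {
      f <- write_tsv(res$fractions[[ic]],
                     file.path(out_dir, paste0("sc_fractions_", ic, ".tsv")),
                     rownames_col = "subcluster")
      files <- c(files, f)
    }
    qf <- file.path(out_dir, "sc_qc_report.json")
    jsonlite::write_json(res$qc_report, qf, auto_unbox = TRUE, pretty = TRUE)
    c(files, qf)
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# Stable hash of the configuration (stage parameters and seeds).
digest_config <- function(config) {
  as.character(tools::md5sum(files = {
    f <- tempfile()
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
    f
  }))
}
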