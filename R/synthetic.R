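#' Population specification for synthetic cytometry cohorts
#'
#' Populations are Gaussian on the *transformed* (arcsinh) scale, which is
#' how cytometry populations are usually modeled; the generator maps events
#' back through the inverse transform so downstream pipelines exercise their
#' own transform step on raw-scale values.
#'
#' @param name population name.
#' @param mean_by_channel named numeric vector of transformed-scale means.
#' @param sd_by_channel named numeric vector of standard deviations (> 0);
#'   channels omitted here default to the corresponding mean's channel with
#'   sd 0.25.
#' @param fraction population fraction in `[0, 1]`.
#' @param is_debris flag marking a CD45-low non-immune population.
#' @param truth_label planted truth label (defaults to `name`).
#' @return a `population_spec` object.
#' @export
population_spec <- function(name, mean_by_channel, sd_by_channel = NULL,
                            fraction, is_debris = FALSE, truth_label = name) {
  if (is.null(names(mean_by_channel)) || any(!nzchar(names(mean_by_channel))))
    stop("mean_by_channel must be a named vector")
  if (is.null(sd_by_channel))
    sd_by_channel <- setNames(rep(0.25, length(mean_by_channel)),
                              names(mean_by_channel))
  if (any(sd_by_channel <= 0)) stop("all sd must be > 0")
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  structure(list(name = name, mean_by_channel = mean_by_channel,
                 sd_by_channel = sd_by_channel, fraction = fraction,
                 is_debris = isTRUE(is_debris), truth_label = truth_label),
            class = "population_spec")
}

#' Default synthetic cytometry panel
#'
#' Mirrors a CD45-enrichment flow panel: lineage markers plus size (FSC-A)
#' and granularity (SSC-A) proxies, so noncanonical marker combinations
#' (e.g. CD3+CD14+CD66b+) can be configured directly.
#' @return character vector of channel names.
#' @export
default_panel <- function() {
  c("FSC-A", "SSC-A", "CD45", "CD3", "CD4", "CD8", "CD14", "CD19", "CD66b")
}

pop_means <- function(...) {
  base <- setNames(rep(0.5, length(default_panel())), default_panel())
  ov <- c(...)
  base[names(ov)] <- ov
  base
}

#' Default synthetic populations
#'
#' Five canonical archetypes (microglia, monocyte-derived macrophages,
#' neutrophils, T cells, CD45-low debris) plus a rare noncanonical
#' CD3+CD14+CD66b+ myeloid spike at 2%.  Means are on the arcsinh display
#' scale (cofactor 150); marker-positive channels sit around 4-5 units,
#' negative channels around 0.5, so planted clusters are well separated but
#' not degenerate.
#'
#' @param spike_fraction fraction of the noncanonical spike (default 0.02).
#' @param debris_fraction fraction of CD45-low debris (default 0.20).
#' @return list of [population_spec()] objects whose fractions sum to 1.
#' @export
default_populations <- function(spike_fraction = 0.02, debris_fraction = 0.20) {
  rest <- 1 - spike_fraction - debris_fraction
  if (rest <= 0) stop("spike and debris fractions leave no room for immune populations")
  # immune archetype share of the remainder
  sh <- c(MG = 0.32, MDM = 0.26, Neutrophil = 0.19, Tcell = 0.23)
  list(
    population_spec("MG",
      pop_means("FSC-A" = 3.5, "SSC-A" = 3.0, CD45 = 3.0, CD14 = 4.0),
      fraction = rest * sh[["MG"]]),
    population_spec("MDM",
      pop_means("FSC-A" = 4.0, "SSC-A" = 3.5, CD45 = 4.5, CD14 = 4.8),
      fraction = rest * sh[["MDM"]]),
    population_spec("Neutrophil",
      pop_means("FSC-A" = 3.8, "SSC-A" = 4.5, CD45 = 4.0, CD14 = 2.5, CD66b = 4.5),
      fraction = rest * sh[["Neutrophil"]]),
    population_spec("Tcell",
      pop_means("FSC-A" = 2.5, "SSC-A" = 1.5, CD45 = 4.8, CD3 = 4.5,
                CD4 = 3.0, CD8 = 2.5),
      fraction = rest * sh[["Tcell"]]),
    population_spec("Debris",
      pop_means("FSC-A" = 1.0, "SSC-A" = 1.0, CD45 = 0.3),
      fraction = debris_fraction, is_debris = TRUE),
    population_spec("CD3_CD14_CD66b",
      pop_means("FSC-A" = 3.8, "SSC-A" = 3.5, CD45 = 4.2, CD3 = 4.2,
                CD14 = 4.2, CD66b = 4.0),
      fraction = spike_fraction, truth_label = "CD3_CD14_CD66b")
  )
}

#' Synthetic cohort configuration
#'
#' @param samples list of per-sample specs, each a list with `sample_id`,
#'   `n_events` and optionally `fraction_overrides` (named vector of
#'   population fractions replacing the defaults; the full set must still
#'   sum to 1).
#' @param panel ordered channel names; must include a CD45-like channel.
#' @param doublet_rate expected doublet proportion, in `[0, 0.2]`.
#' @param cofactor arcsinh cofactor of the simulated transform (default 150,
#'   fluorescence convention).
#' @param seed integer seed.
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(samples, panel = default_panel(), doublet_rate = 0.02,
                          cofactor = 150, seed = 1L) {
  if (anyDuplicated(panel)) stop("channel names must be unique")
  if (!any(grepl("CD45", panel))) stop("panel must include a CD45-like channel")
  if (doublet_rate < 0 || doublet_rate > 0.2)
    stop("doublet_rate must lie in [0, 0.2]")
  for (s in samples) {
    if (is.null(s$sample_id) || is.null(s$n_events) || s$n_events < 1)
      stop("each sample needs a sample_id and n_events >= 1")
  }
  structure(list(samples = samples, panel = panel, doublet_rate = doublet_rate,
                 cofactor = cofactor, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default five-sample demonstration cohort
#'
#' Five samples of 5,000 events each with mild per-sample variation in
#' population fractions (spike and debris fractions held fixed), the
#' configuration used by the package's end-to-end recovery demonstrations.
#'
#' @param n_samples number of samples (default 5).
#' @param n_events events per sample (default 5000).
#' @param seed integer seed.
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(n_samples = 5, n_events = 5000, seed = 1L) {
  jit <- with_seed(derive_seed(seed, 971L), {
    lapply(seq_len(n_samples), function(i) runif(4, -0.015, 0.015))
  })
  samples <- lapply(seq_len(n_samples), function(i) {
    base <- vapply(default_populations(), function(p) p$fraction, numeric(1))
    names(base) <- vapply(default_populations(), function(p) p$name, character(1))
    adj <- jit[[i]] - mean(jit[[i]])  # zero-sum jitter keeps the total at 1
    base[c("MG", "MDM", "Neutrophil", "Tcell")] <-
      base[c("MG", "MDM", "Neutrophil", "Tcell")] + adj
    list(sample_id = sprintf("S%02d", i), n_events = n_events,
         fraction_overrides = base)
  })
  cohort_config(samples, seed = seed)
}

#' Generate a synthetic cytometry cohort with planted truth
#'
#' Events are drawn per population from independent per-channel Gaussians on
#' the arcsinh-transformed scale and mapped back to the raw scale, so a
#' downstream pipeline exercises its own transform.  Doublets are synthesized
#' as channel-wise sums of two random singlet events (the standard
#' idealization of coincidence events) and labeled `"doublet"`.
#'
#' @param config a [cohort_config()].
#' @param populations list of [population_spec()]; fractions must sum to 1.
#' @return list of raw [event_table()]s, one per sample; each carries a
#'   `truth` element with per-event labels and, for doublets, the parent row
#'   indices.
#' @export
generate_event_cohort <- function(config, populations = default_populations()) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  pop_names <- vapply(populations, function(p) p$name, character(1))
  for (p in populations) {
    bad <- setdiff(names(p$mean_by_channel), config$panel)
    if (length(bad))
      stop("population '", p$name, "' references unknown channel(s): ",
           paste(bad, collapse = ", "))
  }
  base_frac <- setNames(vapply(populations, function(p) p$fraction, numeric(1)),
                        pop_names)
  out <- vector("list", length(config$samples))
  for (si in seq_along(config$samples)) {
    s <- config$samples[[si]]
    frac <- base_frac
    if (!is.null(s$fraction_overrides)) {
      ov <- s$fraction_overrides
      bad <- setdiff(names(ov), pop_names)
      if (length(bad)) stop("fraction override for unknown population(s): ",
                            paste(bad, collapse = ", "))
      frac[names(ov)] <- ov
    }
    if (abs(sum(frac) - 1) > 1e-9)
      stop("population fractions for sample '", s$sample_id,
           "' sum to ", format(sum(frac)), ", not 1")
    out[[si]] <- with_seed(derive_seed(config$seed, si), {
      n <- as.integer(s$n_events)
      n_doub <- rbinom(1, n, config$doublet_rate)
      n_sing <- n - n_doub
      pop_idx <- sample.int(length(populations), n_sing, replace = TRUE,
                            prob = frac)
      m <- matrix(0.0, n, length(config$panel),
                  dimnames = list(NULL, config$panel))
      for (pi in seq_along(populations)) {
        rows <- which(pop_idx == pi)
        if (!length(rows)) next
        p <- populations[[pi]]
        for (ch in config$panel) {
          mu <- if (ch %in% names(p$mean_by_channel)) p$mean_by_channel[[ch]] else 0.5
          sdv <- if (ch %in% names(p$sd_by_channel)) p$sd_by_channel[[ch]] else 0.25
          m[rows, ch] <- rnorm(length(rows), mu, sdv)
        }
      }
      labels <- c(vapply(populations, function(p) p$truth_label, character(1))[pop_idx],
                  rep("doublet", n_doub))
      # transformed -> raw through the inverse arcsinh
      raw_sing <- sinh(m[seq_len(n_sing), , drop = FALSE]) * config$cofactor
      parents <- NULL
      raw <- raw_sing
      if (n_doub > 0) {
        parents <- matrix(sample.int(n_sing, 2 * n_doub, replace = TRUE),
                          ncol = 2)
        raw <- rbind(raw_sing,
                     raw_sing[parents[, 1], , drop = FALSE] +
                       raw_sing[parents[, 2], , drop = FALSE])
      }
      tb <- event_table(raw, s$sample_id)
      tb$truth <- list(labels = labels, doublet_parents = parents,
                       cofactor = config$cofactor)
      tb
    })
  }
  names(out) <- vapply(config$samples, function(s) s$sample_id, character(1))
  out
}

# ---------------------------------------------------------------------------
# Bulk mixtures

#' Synthetic bulk-mixture configuration
#'
#' @param reference_profiles genes x cell-types nonnegative matrix on the
#'   linear scale.
#' @param mixing_weights samples x cell-types matrix; rows must sum to 1 and
#'   be nonnegative.
#' @param noise_sd Gaussian noise sd applied on the log2 scale.
#' @param seed integer seed.
#' @return a `bulk_config` object.
#' @export
bulk_config <- function(reference_profiles, mixing_weights, noise_sd = 0.1,
                        seed = 1L) {
  if (any(reference_profiles < 0)) stop("reference profiles must be nonnegative")
  if (!identical(colnames(reference_profiles), colnames(mixing_weights)))
    stop("dimension mismatch: weights and profiles must share cell-type columns")
  if (any(mixing_weights < 0)) stop("mixing weights must be >= 0")
  rs <- rowSums(mixing_weights)
  if (any(abs(rs - 1) > 1e-9))
    stop("each sample's mixing weights must sum to 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(reference_profiles = reference_profiles,
                 mixing_weights = mixing_weights,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "bulk_config")
}

#' Generate synthetic bulk mixtures
#'
#' Per-sample expression is the weight-combination of the reference profiles
#' on the linear scale; Gaussian noise of sd `noise_sd` is added after
#' `log2(x + 1)`, matching the log2 scale of the downstream analysis.
#'
#' @param config a [bulk_config()].
#' @return an [expression_matrix()] on the log2 scale carrying the truth
#'   mixing weights as attribute `truth_weights`.
#' @export
generate_bulk_mixtures <- function(config) {
  if (!inherits(config, "bulk_config")) stop("config must be a bulk_config")
  P <- config$reference_profiles            # genes x types
  W <- config$mixing_weights                # samples x types
  lin <- P %*% t(W)                         # genes x samples
  colnames(lin) <- rownames(W) %||% sprintf("mix%03d", seq_len(nrow(W)))
  lg <- log2(lin + 1)
  if (config$noise_sd > 0) {
    lg <- lg + with_seed(config$seed,
                         matrix(rnorm(length(lg), 0, config$noise_sd),
                                nrow(lg), ncol(lg)))
  }
  m <- expression_matrix(lg, norm_state = c("tpm", "quantile", "log2"))
  attr(m, "truth_weights") <- W
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic purified reference profiles
#'
#' Six cell types (CD45neg, MG, MDM, Neutrophil, CD4T, CD8T) with blocks of
#' type-specific marker genes on top of a shared lognormal baseline; used as
#' the planted reference for deconvolution and immune-gene-cluster recovery
#' tests.  Gene blocks are exposed through [synthetic_ic_sets()].
#'
#' @param n_genes total gene count (default 600).
#' @param markers_per_type marker genes per cell type (default 60).
#' @param seed integer seed.
#' @return genes x cell-types nonnegative matrix (linear scale).
#' @export
synthetic_reference_profiles <- function(n_genes = 600, markers_per_type = 60,
                                         seed = 7L) {
  types <- c("CD45neg", "MG", "MDM", "Neutrophil", "CD4T", "CD8T")
  if (markers_per_type * length(types) > n_genes)
    stop("n_genes too small for the marker blocks")
  with_seed(seed, {
    base <- matrix(2^rnorm(n_genes * length(types), 3, 0.3),
                   n_genes, length(types),
                   dimnames = list(sprintf("G%04d", seq_len(n_genes)), types))
    for (ti in seq_along(types)) {
      rows <- (ti - 1) * markers_per_type + seq_len(markers_per_type)
      base[rows, ti] <- base[rows, ti] * 2^runif(markers_per_type, 4, 6)
    }
    base
  })
}

#' Planted immune-gene-cluster definitions for the synthetic references
#'
#' One gene cluster per cell type, consisting of that type's marker block in
#' [synthetic_reference_profiles()]; e.g. `IC_MDM` tracks the planted MDM
#' weight in synthetic mixtures.
#'
#' @inheritParams synthetic_reference_profiles
#' @return named list of gene-id vectors (a gene-cluster set).
#' @export
synthetic_ic_sets <- function(n_genes = 600, markers_per_type = 60) {
  types <- c("CD45neg", "MG", "MDM", "Neutrophil", "CD4T", "CD8T")
  out <- lapply(seq_along(types), function(ti) {
    rows <- (ti - 1) * markers_per_type + seq_len(markers_per_type)
    sprintf("G%04d", rows)
  })
  setNames(out, paste0("IC_", types))
}

#' Random mixing weights on the simplex
#'
#' @param n_samples number of mixtures.
#' @param types cell-type names.
#' @param seed integer seed.
#' @return samples x types matrix of Dirichlet(1) weights (rows sum to 1).
#' @export
random_mixing_weights <- function(n_samples,
                                  types = c("CD45neg", "MG", "MDM",
                                            "Neutrophil", "CD4T", "CD8T"),
                                  seed = 11L) {
  with_seed(seed, {
    g <- matrix(-log(runif(n_samples * length(types))), n_samples,
                dimnames = list(sprintf("mix%03d", seq_len(n_samples)), types))
    g / rowSums(g)
  })
}

# ---------------------------------------------------------------------------
# Single-cell matrices

#' Synthetic single-cell configuration
#'
#' @param cell_types named integer vector of per-type cell counts (>= 1).
#' @param gene_clusters named list of gene-id vectors (the planted immune
#'   gene clusters).
#' @param programs list of programs, each `list(cluster =, cell_types =,
#'   shift =)`: the named gene cluster is mean-shifted by `shift` in the
#'   listed cell types.
#' @param baseline_mean,baseline_sd baseline expression scale.
#' @param mito_fraction_range interval in `[0, 1]` from which each cell's
#'   mitochondrial fraction is drawn uniformly.
#' @param n_extra_genes background genes outside all clusters.
#' @param seed integer seed.
#' @return an `sc_config` object.
#' @export
sc_config <- function(cell_types, gene_clusters, programs,
                      baseline_mean = 1, baseline_sd = 0.4,
                      mito_fraction_range = c(0.005, 0.04),
                      n_extra_genes = 100, seed = 1L) {
  if (any(cell_types < 1)) stop("cell counts must be >= 1")
  if (any(mito_fraction_range < 0) || any(mito_fraction_range > 1) ||
      mito_fraction_range[1] > mito_fraction_range[2])
    stop("mito_fraction_range must be an interval within [0, 1]")
  for (pr in programs) {
    if (!pr$cluster %in% names(gene_clusters))
      stop("program references unknown gene cluster: ", pr$cluster)
    bad <- setdiff(pr$cell_types, names(cell_types))
    if (length(bad))
      stop("program references unknown cell type(s): ", paste(bad, collapse = ", "))
    if (!is.finite(pr$shift)) stop("shift magnitudes must be finite")
  }
  structure(list(cell_types = cell_types, gene_clusters = gene_clusters,
                 programs = programs, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 mito_fraction_range = mito_fraction_range,
                 n_extra_genes = n_extra_genes, seed = as.integer(seed)),
            class = "sc_config")
}

#' Generate a synthetic single-cell expression matrix
#'
#' Cells are drawn per type from a truncated Gaussian baseline; genes of a
#' program are mean-shifted by the stated magnitude in the stated cell types.
#' Ten `MT-*` genes are added and scaled per cell so that the mitochondrial
#' fraction of total expression equals a uniform draw from
#' `mito_fraction_range`.
#'
#' @param config an [sc_config()].
#' @return list with `values` (genes x cells matrix), `cell_types` (per-cell
#'   labels), `mito_fractions` (per-cell planted fractions) and
#'   `gene_clusters` (the planted cluster definitions).
#' @export
generate_sc_matrix <- function(config) {
  if (!inherits(config, "sc_config")) stop("config must be an sc_config")
  with_seed(config$seed, {
    cl_genes <- unique(unlist(config$gene_clusters))
    genes <- c(cl_genes, sprintf("BG%04d", seq_len(config$n_extra_genes)))
    mito <- sprintf("MT-%02d", 1:10)
    n_cells <- sum(config$cell_types)
    cells <- sprintf("cell%05d", seq_len(n_cells))
    type_of <- rep(names(config$cell_types), config$cell_types)

    mu <- matrix(config$baseline_mean, length(genes), length(config$cell_types),
                 dimnames = list(genes, names(config$cell_types)))
    for (pr in config$programs) {
      g <- intersect(config$gene_clusters[[pr$cluster]], genes)
      mu[g, pr$cell_types] <- mu[g, pr$cell_types] + pr$shift
    }
    v <- matrix(rnorm(length(genes) * n_cells,
                      mean = mu[, type_of], sd = config$baseline_sd),
                length(genes), n_cells, dimnames = list(genes, cells))
    v <- pmax(v, 0)
    mf <- runif(n_cells, config$mito_fraction_range[1],
                config$mito_fraction_range[2])
    tot <- colSums(v)
    tot[tot == 0] <- 1
    mito_tot <- mf / (1 - mf) * tot
    mv <- matrix(rep(mito_tot / length(mito), each = length(mito)),
                 length(mito), n_cells, dimnames = list(mito, cells))
    list(values = rbind(v, mv),
         cell_types = setNames(type_of, cells),
         mito_fractions = setNames(mf, cells),
         gene_clusters = config$gene_clusters)
  })
}

# ---------------------------------------------------------------------------
# Planted-partition graphs

#' Generate a planted-partition graph
#'
#' Undirected simple graph: within-community edges appear with probability
#' `p_in`, between-community edges with `p_out < p_in`.
#'
#' @param n_communities number of communities.
#' @param size nodes per community.
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @return a `pheno_graph` (unit edge weights) with planted `labels`.
#' @export
generate_planted_graph <- function(n_communities, size, p_in, p_out, seed = 1L) {
  if (p_out >= p_in) stop("p_out must be strictly smaller than p_in")
  if (p_in > 1 || p_out < 0) stop("probabilities must lie in [0, 1]")
  n <- n_communities * size
  labels <- rep(seq_len(n_communities), each = size)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  p <- ifelse(labels[pairs[, 1]] == labels[pairs[, 2]], p_in, p_out)
  keep <- with_seed(seed, runif(nrow(pairs)) < p)
  structure(list(n_nodes = n, k = NA_integer_,
                 edges = data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                                    weight = 1),
                 labels = labels),
            class = "pheno_graph")
}
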