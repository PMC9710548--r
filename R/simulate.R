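#' Default synthetic joint-modality configuration
#'
#' A five-population PBMC-like mixture (T cells, monocytes, B cells, NK
#' cells, dendritic cells) with type-specific RNA marker modules and
#' bimodal ADT markers whose positivity pattern includes the real-world
#' overlaps (CD8 on T and NK cells, CD16 on NK cells and monocytes, CD11b
#' on myeloid and NK cells, HLA-DR on B cells, monocytes and DCs, CD11c on
#' DCs and monocytes). Counts are negative binomial with log-normal
#' per-cell library-size factors; each ADT marker is a two-component
#' negative-binomial mixture with distinct low/high modes whose mode
#' masses follow the cell-type mixing proportions rather than a forced
#' 50/50 split.
#'
#' @param n_cells number of cells (default 5000).
#' @param intermediate_frac fraction of cells carrying two simultaneous
#'   type programs (default 0.05).
#' @param fold_change expression fold change of a type's module genes in
#'   that type's cells (default 64, i.e. 2^6).
#' @param module_size marker-module genes per type (default 25).
#' @param n_background_genes unstructured genes (default 400).
#' @param nb_size negative-binomial size (inverse dispersion) for RNA
#'   counts (default 2).
#' @param libsize_sigma sd of the log-normal per-cell library-size factor
#'   (default 0.3).
#' @param n_mito_genes,mito_frac mitochondrial genes ("MT-" prefixed) and
#'   their expected share of counts (defaults 10 and 0.02).
#' @param seed default seed recorded in the config (default 1).
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(n_cells = 5000, intermediate_frac = 0.05,
                       fold_change = 64, module_size = 25,
                       n_background_genes = 400, nb_size = 2,
                       libsize_sigma = 0.3, n_mito_genes = 10,
                       mito_frac = 0.02, seed = 1) {
  types <- data.frame(
    name = c("Tcell", "Monocyte", "Bcell", "NK", "DC"),
    prop = c(0.35, 0.25, 0.20, 0.10, 0.10),
    stringsAsFactors = FALSE)
  markers <- data.frame(
    marker = c("CD3", "CD8", "CD2", "CD56", "CD16", "CD14", "CD11b",
               "CD19", "CD20", "HLA-DR", "CD11c"),
    low_mean = 8, low_size = 4, high_mean = 150, high_size = 25,
    stringsAsFactors = FALSE)
  positive_types <- list(
    CD3 = "Tcell", CD8 = c("Tcell", "NK"), CD2 = c("Tcell", "NK"),
    CD56 = "NK", CD16 = c("NK", "Monocyte"), CD14 = "Monocyte",
    CD11b = c("Monocyte", "NK", "DC"), CD19 = "Bcell", CD20 = "Bcell",
    `HLA-DR` = c("Bcell", "Monocyte", "DC"), CD11c = c("DC", "Monocyte"))
  map <- list(
    Tcell = c("CD3", "CD8"), Monocyte = c("CD14", "CD11b"),
    Bcell = c("CD19", "CD20", "HLA-DR"), NK = c("CD56", "CD2"),
    DC = c("CD11c", "HLA-DR"))
  cfg <- list(n_cells = n_cells, types = types,
              intermediate_frac = intermediate_frac,
              fold_change = fold_change, module_size = module_size,
              module_base_mean = 1, n_background_genes = n_background_genes,
              nb_size = nb_size, libsize_sigma = libsize_sigma,
              n_mito_genes = n_mito_genes, mito_frac = mito_frac,
              markers = markers, positive_types = positive_types,
              marker_map = map, rna_modules = NULL, seed = seed)
  validate_sim_config(cfg)
}

#' Validate a synthetic-data configuration
#'
#' @param cfg a `SimConfig` list.
#' @return the config, with class `SimConfig`, or an error.
#' @export
validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$types$prop) - 1) > 1e-9) {
    stop(sprintf("cell-type proportions must sum to 1 (got %.12g)",
                 sum(cfg$types$prop)))
  }
  if (any(cfg$types$prop <= 0)) stop("all mixing proportions must be positive")
  if (cfg$fold_change <= 1) stop("planted marker fold change must exceed 1")
  with(cfg$markers, {
    if (any(c(low_mean, high_mean, low_size, high_size) <= 0)) {
      stop("ADT mode means and sizes must be positive")
    }
  })
  if (cfg$intermediate_frac < 0 || cfg$intermediate_frac >= 1) {
    stop("intermediate_frac must be in [0, 1)")
  }
  unknown <- setdiff(unlist(cfg$positive_types), cfg$types$name)
  if (length(unknown)) {
    stop(sprintf("positive_types references unknown type(s): %s",
                 paste(unique(unknown), collapse = ", ")))
  }
  structure(cfg, class = "SimConfig")
}

#' A configuration with an RNA/protein-discordant population
#'
#' Replaces part of the T-cell mass with an "NKT-like" population whose
#' transcriptome runs the NK cytotoxicity module but whose surface
#' phenotype is that of a T cell (CD3/CD8 positive, CD56/CD2/CD16
#' negative). Transcriptome scoring calls these cells NK; protein eCDF
#' scoring calls them T — the discordance pattern seen between cytotoxic
#' T and NK cells in real PBMC data.
#'
#' @param discordant_frac mixing proportion of the discordant population
#'   (default 0.10, taken from the T-cell share).
#' @param ... passed to [sim_config()].
#' @return list of class `SimConfig`.
#' @export
sim_config_discordant <- function(discordant_frac = 0.10, ...) {
  cfg <- sim_config(...)
  cfg$types <- rbind(cfg$types,
                     data.frame(name = "NKT", prop = discordant_frac))
  i <- cfg$types$name == "Tcell"
  cfg$types$prop[i] <- cfg$types$prop[i] - discordant_frac
  # transcriptome: share the NK module; surface: T markers only
  cfg$rna_module_of <- c(stats::setNames(cfg$types$name[-nrow(cfg$types)],
                                         cfg$types$name[-nrow(cfg$types)]),
                         NKT = "NK")
  cfg$positive_types <- lapply(cfg$positive_types, function(tys) {
    if (any(c("CD3", "CD8") %in% tys)) tys else tys
  })
  cfg$positive_types$CD3 <- c(cfg$positive_types$CD3, "NKT")
  cfg$positive_types$CD8 <- c(cfg$positive_types$CD8, "NKT")
  validate_sim_config(cfg)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.module_genes <- function(cfg) {
  mods <- lapply(cfg$types$name, function(ty) {
    src <- if (!is.null(cfg$rna_module_of)) cfg$rna_module_of[[ty]] else ty
    sprintf("MOD-%s-%02d", src, seq_len(cfg$module_size))
  })
  names(mods) <- cfg$types$name
  mods
}

#' Simulate a joint scRNA-seq/CITE-seq dataset with known truth
#'
#' RNA counts are negative binomial around per-gene base means scaled by
#' per-cell log-normal library-size factors; each cell type's marker
#' module is multiplied by the configured fold change in that type's cells
#' (intermediate cells run two modules at once). ADT counts come from each
#' marker's high negative-binomial mode in cells of the marker's positive
#' types and from the low mode otherwise. Identical config and seed give
#' bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (default: the config's seed).
#' @return list with `rna` and `adt` [count_matrix()] objects and `truth`
#'   (class `SyntheticTruth`): per-cell `label` and `label2` (second
#'   program for intermediate cells, else NA), `modules` (type -> planted
#'   genes), `marker_positive` (marker -> positive cell mask),
#'   `marker_map`, and the config.
#' @export
simulate_joint <- function(cfg, seed = cfg$seed) {
  cfg <- validate_sim_config(cfg)
  .with_seed(seed, {
    n <- cfg$n_cells
    types <- cfg$types$name
    label <- sample(types, n, replace = TRUE, prob = cfg$types$prop)
    label2 <- rep(NA_character_, n)
    n_int <- round(cfg$intermediate_frac * n)
    if (n_int > 0 && length(types) > 1) {
      idx <- sample(n, n_int)
      label2[idx] <- vapply(label[idx], function(l) {
        sample(setdiff(types, l), 1)
      }, "")
    }

    mods <- .module_genes(cfg)
    mod_genes <- unique(unlist(mods, use.names = FALSE))
    bg_genes <- sprintf("BG-%04d", seq_len(cfg$n_background_genes))
    mito_genes <- if (cfg$n_mito_genes > 0)
      sprintf("MT-%02d", seq_len(cfg$n_mito_genes)) else character(0)
    genes <- c(mod_genes, bg_genes, mito_genes)

    base <- c(stats::setNames(rep(cfg$module_base_mean, length(mod_genes)),
                              mod_genes),
              stats::setNames(stats::rgamma(length(bg_genes), 2, 2), bg_genes))
    non_mito_total <- sum(base)
    if (length(mito_genes)) {
      mito_total <- cfg$mito_frac / (1 - cfg$mito_frac) * non_mito_total
      base <- c(base, stats::setNames(rep(mito_total / length(mito_genes),
                                          length(mito_genes)), mito_genes))
    }

    size_factor <- exp(stats::rnorm(n, 0, cfg$libsize_sigma))
    mu <- matrix(base, length(genes), n, dimnames = list(genes, NULL))
    for (ci in seq_len(n)) {
      active <- c(label[ci], label2[ci])
      active <- active[!is.na(active)]
      planted <- unique(unlist(mods[active], use.names = FALSE))
      mu[planted, ci] <- mu[planted, ci] * cfg$fold_change
      mu[, ci] <- mu[, ci] * size_factor[ci]
    }
    rna <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$nb_size),
                  nrow(mu), ncol(mu))
    cell_ids <- sprintf("cell-%05d", seq_len(n))
    rna_cm <- count_matrix(rna, feature_ids = genes, cell_ids = cell_ids,
                           modality = "RNA")

    mk <- cfg$markers
    marker_positive <- list()
    adt <- matrix(0L, nrow(mk), n,
                  dimnames = list(mk$marker, cell_ids))
    for (r in seq_len(nrow(mk))) {
      pos_ty <- cfg$positive_types[[mk$marker[r]]]
      pos <- label %in% pos_ty | (!is.na(label2) & label2 %in% pos_ty)
      adt[r, ] <- ifelse(pos,
                         stats::rnbinom(n, mu = mk$high_mean[r], size = mk$high_size[r]),
                         stats::rnbinom(n, mu = mk$low_mean[r], size = mk$low_size[r]))
      marker_positive[[mk$marker[r]]] <- pos
    }
    adt_cm <- count_matrix(adt, feature_ids = mk$marker, cell_ids = cell_ids,
                           modality = "ADT")

    truth <- structure(list(label = stats::setNames(label, cell_ids),
                            label2 = stats::setNames(label2, cell_ids),
                            modules = mods,
                            marker_positive = marker_positive,
                            marker_map = marker_map(cfg$marker_map),
                            config = cfg, seed = seed),
                       class = "SyntheticTruth")
    list(rna = rna_cm, adt = adt_cm, truth = truth)
  })
}

#' Simulate a labeled pseudo-bulk reference
#'
#' Per-type pseudo-bulk samples drawn from the same per-gene means the
#' joint simulator uses (module genes at the planted fold change in their
#' own type), at higher sequencing depth, so that reference-based gene-set
#' construction can recover the planted modules.
#'
#' @param cfg a [sim_config()].
#' @param samples_per_type pseudo-bulk samples per type (>= 1, default 5).
#' @param depth mean scaling relative to a single cell (default 50).
#' @param seed integer seed (default: config seed + 1).
#' @return a [reference_expression()].
#' @export
simulate_reference <- function(cfg, samples_per_type = 5, depth = 50,
                               seed = cfg$seed + 1) {
  cfg <- validate_sim_config(cfg)
  if (samples_per_type < 1) stop("samples_per_type must be >= 1")
  .with_seed(seed, {
    mods <- .module_genes(cfg)
    mod_genes <- unique(unlist(mods, use.names = FALSE))
    bg_genes <- sprintf("BG-%04d", seq_len(cfg$n_background_genes))
    genes <- c(mod_genes, bg_genes)
    base <- c(stats::setNames(rep(cfg$module_base_mean, length(mod_genes)),
                              mod_genes),
              stats::setNames(stats::rgamma(length(bg_genes), 2, 2), bg_genes))
    cols <- list()
    labels <- character(0)
    for (ty in cfg$types$name) {
      mu <- base * depth
      mu[mods[[ty]]] <- mu[mods[[ty]]] * cfg$fold_change
      for (s in seq_len(samples_per_type)) {
        cols[[length(cols) + 1L]] <-
          stats::rnbinom(length(mu), mu = mu, size = cfg$nb_size * 10)
        labels <- c(labels, ty)
      }
    }
    v <- do.call(cbind, cols)
    colnames(v) <- sprintf("%s-%d", labels, stats::ave(seq_along(labels),
                                                       labels, FUN = seq_along))
    reference_expression(v, gene_ids = genes, sample_labels = labels)
  })
}

#' Curated-style gene-set collection from the planted truth
#'
#' Returns GMT-style sets (one per type: the planted module genes plus a
#' handful of background decoys that reference DE will screen out) and the
#' type -> set-name mapping, mirroring how curated collections are
#' intersected with reference DE results.
#'
#' @param truth `SyntheticTruth` from [simulate_joint()].
#' @param n_decoys background decoy genes appended to each set (default 5).
#' @return list with `collections` (named list of gene vectors) and
#'   `type_map` (type -> set name).
#' @export
truth_collections <- function(truth, n_decoys = 5) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  cfg <- truth$config
  bg <- sprintf("BG-%04d", seq_len(min(n_decoys, cfg$n_background_genes)))
  collections <- list()
  type_map <- list()
  for (ty in names(truth$modules)) {
    nm <- paste0(ty, "_module")
    collections[[nm]] <- c(truth$modules[[ty]], bg)
    type_map[[ty]] <- nm
  }
  list(collections = collections, type_map = type_map)
}

#' Weighted gene sets taken directly from the planted truth
#'
#' Bypasses reference DE: each type's set is exactly its planted module
#' with a constant weight (default the planted log2 fold change). Useful
#' when the reference route is unavailable or deliberately skipped.
#'
#' @param truth `SyntheticTruth` from [simulate_joint()].
#' @param types which types to build sets for (default: the base mixture
#'   types in the config).
#' @param weight constant per-gene weight (default log2 of the planted
#'   fold change).
#' @return list of [weighted_gene_set()] objects.
#' @export
truth_weighted_sets <- function(truth, types = truth$config$types$name,
                                weight = log2(truth$config$fold_change)) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  lapply(types, function(ty) {
    weighted_gene_set(ty, truth$modules[[ty]],
                      rep(weight, length(truth$modules[[ty]])))
  })
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d cells, %d types, %d intermediate\n",
              length(x$label), length(unique(x$label)), sum(!is.na(x$label2))))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file.
#' @return for `read_sim_config`, a validated `SimConfig`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- sim_config()
  for (nm in intersect(names(y), c("n_cells", "intermediate_frac",
                                   "fold_change", "module_size",
                                   "module_base_mean", "n_background_genes",
                                   "nb_size", "libsize_sigma",
                                   "n_mito_genes", "mito_frac", "seed"))) {
    cfg[[nm]] <- y[[nm]]
  }
  if (!is.null(y$types)) {
    cfg$types <- data.frame(name = vapply(y$types, `[[`, "", "name"),
                            prop = vapply(y$types, function(t) as.numeric(t$prop), 0),
                            stringsAsFactors = FALSE)
  }
  if (!is.null(y$markers)) {
    cfg$markers <- do.call(rbind, lapply(y$markers, function(m) {
      data.frame(marker = m$marker, low_mean = m$low_mean,
                 low_size = m$low_size, high_mean = m$high_mean,
                 high_size = m$high_size, stringsAsFactors = FALSE)
    }))
    cfg$positive_types <- stats::setNames(
      lapply(y$markers, function(m) as.character(m$positive_types)),
      vapply(y$markers, `[[`, "", "marker"))
  }
  if (!is.null(y$marker_map)) cfg$marker_map <- lapply(y$marker_map, as.character)
  if (!is.null(y$qc)) cfg$qc <- y$qc
  validate_sim_config(cfg)
}

#' @rdname read_sim_config
#' @param cfg a `SimConfig`.
#' @export
write_sim_config <- function(cfg, path) {
  y <- list(n_cells = cfg$n_cells, intermediate_frac = cfg$intermediate_frac,
            fold_change = cfg$fold_change, module_size = cfg$module_size,
            module_base_mean = cfg$module_base_mean,
            n_background_genes = cfg$n_background_genes,
            nb_size = cfg$nb_size, libsize_sigma = cfg$libsize_sigma,
            n_mito_genes = cfg$n_mito_genes, mito_frac = cfg$mito_frac,
            seed = cfg$seed,
            types = lapply(seq_len(nrow(cfg$types)), function(i) {
              list(name = cfg$types$name[i], prop = cfg$types$prop[i])
            }),
            markers = lapply(seq_len(nrow(cfg$markers)), function(i) {
              m <- cfg$markers[i, ]
              list(marker = m$marker, low_mean = m$low_mean,
                   low_size = m$low_size, high_mean = m$high_mean,
                   high_size = m$high_size,
                   positive_types = cfg$positive_types[[m$marker]])
            }),
            marker_map = cfg$marker_map)
  if (!is.null(cfg$qc)) y$qc <- cfg$qc
  yaml::write_yaml(y, path)
  invisible(path)
}
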