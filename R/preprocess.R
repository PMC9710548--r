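#' Filter cells on detected genes and mitochondrial content
#'
#' Keeps cells that detect at least `min_genes` genes (nonzero count) and
#' whose mitochondrial fraction is at most `max_mito_frac`. By default the
#' mitochondrial fraction is the share of total counts falling on genes
#' whose identifier starts with `mito_prefix`; set
#' `mito_measure = "genes"` to use the share of detected genes instead.
#' Both thresholds are inclusive.
#'
#' @param rna RNA [count_matrix()].
#' @param min_genes minimum detected genes per cell (default 1000).
#' @param max_mito_frac maximum mitochondrial fraction (default 0.05).
#' @param mito_prefix identifier prefix marking mitochondrial genes
#'   (default `"MT-"`; use `"mt-"` for mouse).
#' @param mito_measure `"counts"` (default) or `"genes"`.
#' @return list with `counts` (the filtered [count_matrix()]) and `report`
#'   (a `QcReport` with per-cell statistics and in/kept tallies).
#' @export
qc_filter_cells <- function(rna, min_genes = 1000, max_mito_frac = 0.05,
                            mito_prefix = "MT-",
                            mito_measure = c("counts", "genes")) {
  stopifnot(inherits(rna, "CountMatrix"))
  if (rna$modality != "RNA") stop("qc_filter_cells expects an RNA CountMatrix")
  mito_measure <- match.arg(mito_measure)
  v <- rna$values
  detected <- Matrix::colSums(v > 0)
  is_mito <- startsWith(rna$feature_ids, mito_prefix)
  if (mito_measure == "counts") {
    tot <- Matrix::colSums(v)
    mito <- if (any(is_mito)) Matrix::colSums(v[is_mito, , drop = FALSE]) else
      rep(0, ncol(v))
    mito_frac <- ifelse(tot > 0, mito / tot, 0)
  } else {
    mito_det <- if (any(is_mito)) Matrix::colSums(v[is_mito, , drop = FALSE] > 0) else
      rep(0, ncol(v))
    mito_frac <- ifelse(detected > 0, mito_det / detected, 0)
  }
  keep <- detected >= min_genes & mito_frac <= max_mito_frac
  if (!any(keep)) {
    stop(sprintf(
      "no cells pass QC (min_genes = %d detected genes, max_mito_frac = %g)",
      min_genes, max_mito_frac))
  }
  kept <- count_matrix(v[, keep, drop = FALSE],
                       feature_ids = rna$feature_ids,
                       cell_ids = rna$cell_ids[keep], modality = "RNA")
  report <- structure(list(
    n_cells_in = ncol(v), n_cells_kept = sum(keep),
    n_genes_in = nrow(v), n_genes_kept = nrow(v),
    detected_genes = stats::setNames(as.integer(detected), rna$cell_ids),
    mito_fraction = stats::setNames(as.numeric(mito_frac), rna$cell_ids),
    min_genes = min_genes, max_mito_frac = max_mito_frac,
    mito_measure = mito_measure), class = "QcReport")
  list(counts = kept, report = report)
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QcReport: %d/%d cells kept, %d/%d genes kept\n",
              x$n_cells_kept, x$n_cells_in, x$n_genes_kept, x$n_genes_in))
  invisible(x)
}

#' Remove genes detected in too few cells
#'
#' Keeps genes with a nonzero count in at least `min_cells` cells.
#'
#' @param rna RNA [count_matrix()].
#' @param min_cells minimum number of cells (default 100).
#' @return the filtered [count_matrix()] (possibly with zero genes; callers
#'   must handle that downstream).
#' @export
filter_genes_min_cells <- function(rna, min_cells = 100) {
  stopifnot(inherits(rna, "CountMatrix"))
  if (rna$modality != "RNA") stop("filter_genes_min_cells expects an RNA CountMatrix")
  n_cells <- Matrix::rowSums(rna$values > 0)
  keep <- n_cells >= min_cells
  count_matrix(rna$values[keep, , drop = FALSE],
               feature_ids = rna$feature_ids[keep],
               cell_ids = rna$cell_ids, modality = "RNA")
}

#' Log-normalize RNA counts
#'
#' Each entry becomes `ln(1 + count / libsize * scale_factor)` where the
#' library size is the cell's total count over the current gene universe.
#'
#' @param rna RNA [count_matrix()].
#' @param scale_factor library-size scale factor (default 10000).
#' @return a [normalized_matrix()] with `normalization = "lognorm"`.
#' @export
lognormalize_rna <- function(rna, scale_factor = 10000) {
  stopifnot(inherits(rna, "CountMatrix"))
  lib <- Matrix::colSums(rna$values)
  if (any(lib == 0)) {
    stop(sprintf("zero library size for cell(s): %s",
                 paste(utils::head(rna$cell_ids[lib == 0], 5), collapse = ", ")))
  }
  v <- as.matrix(rna$values)
  v <- log1p(sweep(v, 2, lib, "/") * scale_factor)
  normalized_matrix(v, rna$feature_ids, rna$cell_ids, "lognorm")
}

#' Centered log-ratio normalize ADT counts
#'
#' `y_i = ln(x_i + 1) - mean(ln(x + 1))` over the chosen margin: the
#' classical per-cell CLR (across markers within a cell, the default) or
#' per-marker (across cells).
#'
#' @param adt ADT [count_matrix()].
#' @param margin `"cell"` (default) or `"marker"`.
#' @return a [normalized_matrix()] with `normalization = "clr"`.
#' @export
clr_normalize_adt <- function(adt, margin = c("cell", "marker")) {
  stopifnot(inherits(adt, "CountMatrix"))
  if (adt$modality != "ADT") stop("clr_normalize_adt expects an ADT CountMatrix")
  margin <- match.arg(margin)
  v <- log1p(as.matrix(adt$values))
  v <- if (margin == "cell") {
    sweep(v, 2, colMeans(v), "-")
  } else {
    sweep(v, 1, rowMeans(v), "-")
  }
  normalized_matrix(v, adt$feature_ids, adt$cell_ids, "clr")
}

#' Z-score each feature across cells
#'
#' Centers every feature row to mean 0 and scales it to unit variance
#' (sample standard deviation, n-1). Constant rows become all-zero and are
#' flagged with a warning rather than producing NaN.
#'
#' @param m a [normalized_matrix()].
#' @return a [normalized_matrix()] with `"zscored-"` prepended to the
#'   normalization tag.
#' @export
zscore_scale <- function(m) {
  stopifnot(inherits(m, "NormalizedMatrix"))
  v <- m$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  const <- sdv == 0 | is.na(sdv)
  if (any(const)) {
    warning(sprintf("%d constant feature row(s) set to zero", sum(const)))
    sdv[const] <- 1
  }
  v <- sweep(sweep(v, 1, mu, "-"), 1, sdv, "/")
  v[const, ] <- 0
  tag <- if (startsWith(m$normalization, "zscored-")) m$normalization else
    paste0("zscored-", m$normalization)
  normalized_matrix(v, m$feature_ids, m$cell_ids, tag)
}
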