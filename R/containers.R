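#' chimpr: multi-label cell typing of joint scRNA-seq/CITE-seq data
#'
#' Scores every cell for every candidate cell type on the transcriptome
#' (variance-adjusted gene-set distances calibrated to a permutation-null
#' gamma CDF), discretizes surface-protein (ADT) markers with an exact
#' two-cluster split, and multiplies the two so that protein evidence can
#' only veto, never inflate, a transcriptome score. See the package
#' vignette for the model and its assumptions.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a raw count matrix
#'
#' A `CountMatrix` holds non-negative integer counts as features x cells,
#' with unique feature and cell identifiers and a modality tag. It is the
#' entry container for both RNA and ADT data.
#'
#' @param values matrix or Matrix sparse matrix of non-negative counts,
#'   features in rows, cells in columns.
#' @param feature_ids character vector of unique feature identifiers;
#'   defaults to `rownames(values)`.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   `colnames(values)`.
#' @param modality `"RNA"` or `"ADT"`.
#' @return an object of class `CountMatrix` with elements `values`
#'   (a `dgCMatrix`), `feature_ids`, `cell_ids`, `modality`.
#' @export
count_matrix <- function(values, feature_ids = rownames(values),
                         cell_ids = colnames(values),
                         modality = c("RNA", "ADT")) {
  modality <- match.arg(modality)
  values <- methods::as(methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(values@x < 0)) stop("counts must be non-negative")
  if (any(values@x != round(values@x))) stop("counts must be integers")
  if (is.null(feature_ids) || is.null(cell_ids)) {
    stop("feature_ids and cell_ids are required (set dimnames or pass explicitly)")
  }
  feature_ids <- as.character(feature_ids)
  cell_ids <- as.character(cell_ids)
  if (length(feature_ids) != nrow(values)) stop("feature_ids length != nrow(values)")
  if (length(cell_ids) != ncol(values)) stop("cell_ids length != ncol(values)")
  .check_unique(feature_ids, "feature_ids")
  .check_unique(cell_ids, "cell_ids")
  dimnames(values) <- list(feature_ids, cell_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 cell_ids = cell_ids, modality = modality),
            class = "CountMatrix")
}

.check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup)) {
    stop(sprintf("duplicate %s: %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix [%s]: %d features x %d cells, %d nonzeros\n",
              x$modality, nrow(x$values), ncol(x$values),
              length(x$values@x)))
  invisible(x)
}

#' Construct a normalized expression matrix
#'
#' @param values dense numeric matrix, features x cells.
#' @param feature_ids,cell_ids identifiers (default taken from dimnames).
#' @param normalization one of `"lognorm"`, `"clr"`, `"zscored-lognorm"`,
#'   `"zscored-clr"`.
#' @return an object of class `NormalizedMatrix`.
#' @export
normalized_matrix <- function(values, feature_ids = rownames(values),
                              cell_ids = colnames(values),
                              normalization = c("lognorm", "clr",
                                                "zscored-lognorm",
                                                "zscored-clr")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  feature_ids <- as.character(feature_ids)
  cell_ids <- as.character(cell_ids)
  if (length(feature_ids) != nrow(values)) stop("feature_ids length != nrow(values)")
  if (length(cell_ids) != ncol(values)) stop("cell_ids length != ncol(values)")
  .check_unique(feature_ids, "feature_ids")
  .check_unique(cell_ids, "cell_ids")
  dimnames(values) <- list(feature_ids, cell_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 cell_ids = cell_ids, normalization = normalization),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix [%s]: %d features x %d cells\n",
              x$normalization, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a cells x cell-types score matrix
#'
#' All entries must lie in [0,1]; for `method = "cite_binary"` entries must
#' be exactly 0 or 1.
#'
#' @param values numeric matrix, cells in rows, cell types in columns.
#' @param cell_ids,type_names identifiers (default from dimnames).
#' @param method scoring method that produced the values: `"camml"`,
#'   `"ecdf"`, `"cite_binary"`, or `"chimp"`.
#' @return an object of class `ScoreMatrix`.
#' @export
score_matrix <- function(values, cell_ids = rownames(values),
                         type_names = colnames(values),
                         method = c("camml", "ecdf", "cite_binary", "chimp")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("scores must not be NA")
  if (any(values < 0 | values > 1)) stop("scores must lie in [0,1]")
  if (method == "cite_binary" && any(values != 0 & values != 1)) {
    stop("cite_binary scores must be exactly 0 or 1")
  }
  cell_ids <- as.character(cell_ids)
  type_names <- as.character(type_names)
  if (length(cell_ids) != nrow(values)) stop("cell_ids length != nrow(values)")
  if (length(type_names) != ncol(values)) stop("type_names length != ncol(values)")
  .check_unique(cell_ids, "cell_ids")
  .check_unique(type_names, "type_names")
  dimnames(values) <- list(cell_ids, type_names)
  structure(list(values = values, cell_ids = cell_ids,
                 type_names = type_names, method = method),
            class = "ScoreMatrix")
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix [%s]: %d cells x %d types\n",
              x$method, nrow(x$values), length(x$type_names)))
  invisible(x)
}

#' Construct a weighted cell-type gene set
#'
#' @param cell_type cell-type name.
#' @param genes character vector of member gene identifiers (no duplicates).
#' @param weights positive per-gene weights (typically reference logFC);
#'   defaults to 1 for every gene.
#' @return an object of class `WeightedGeneSet`.
#' @export
weighted_gene_set <- function(cell_type, genes, weights = rep(1, length(genes))) {
  genes <- as.character(genes)
  weights <- as.numeric(weights)
  if (length(genes) == 0) stop(sprintf("gene set '%s' is empty", cell_type))
  if (length(genes) != length(weights)) stop("genes and weights differ in length")
  .check_unique(genes, sprintf("genes in set '%s'", cell_type))
  if (anyNA(weights) || any(weights <= 0)) {
    stop(sprintf("all weights in set '%s' must be positive", cell_type))
  }
  structure(list(cell_type = as.character(cell_type)[1], genes = genes,
                 weights = stats::setNames(weights, genes)),
            class = "WeightedGeneSet")
}

#' @export
print.WeightedGeneSet <- function(x, ...) {
  cat(sprintf("WeightedGeneSet '%s': %d genes, weight range [%.3g, %.3g]\n",
              x$cell_type, length(x$genes), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Construct a labeled reference expression matrix
#'
#' @param values normalized (or pseudo-bulk) expression, genes x samples.
#' @param gene_ids gene identifiers; default `rownames(values)`.
#' @param sample_labels one cell-type label per sample column.
#' @return an object of class `ReferenceExpression`.
#' @export
reference_expression <- function(values, gene_ids = rownames(values),
                                 sample_labels) {
  values <- as.matrix(values)
  gene_ids <- as.character(gene_ids)
  sample_labels <- as.character(sample_labels)
  if (length(gene_ids) != nrow(values)) stop("gene_ids length != nrow(values)")
  if (length(sample_labels) != ncol(values)) stop("one label per sample required")
  if (length(unique(sample_labels)) < 2) {
    stop("reference needs at least 2 distinct cell-type labels")
  }
  rownames(values) <- gene_ids
  structure(list(values = values, gene_ids = gene_ids,
                 sample_labels = sample_labels),
            class = "ReferenceExpression")
}

#' Construct a cell-type to ADT-marker map
#'
#' @param entries named list: cell type -> character vector of ADT marker
#'   identifiers. An entry of length 0 is not allowed; leave a type out of
#'   the map to have it pass through unmodified downstream.
#' @return an object of class `MarkerMap`.
#' @export
marker_map <- function(entries) {
  if (is.null(names(entries)) || any(names(entries) == "")) {
    stop("entries must be a fully named list (cell type -> markers)")
  }
  .check_unique(names(entries), "cell types in marker map")
  entries <- lapply(entries, as.character)
  empty <- names(entries)[lengths(entries) == 0]
  if (length(empty)) {
    stop(sprintf("empty marker list for mapped type(s): %s",
                 paste(empty, collapse = ", ")))
  }
  structure(list(entries = entries), class = "MarkerMap")
}

#' @export
print.MarkerMap <- function(x, ...) {
  cat(sprintf("MarkerMap: %d cell types\n", length(x$entries)))
  for (ty in names(x$entries)) {
    cat(sprintf("  %s: %s\n", ty, paste(x$entries[[ty]], collapse = ", ")))
  }
  invisible(x)
}
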