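#' One-vs-rest log2 fold change per gene
#'
#' For each gene, `log2((mean in-group + pseudocount) /
#' (mean out-group + pseudocount))` over the reference samples. This is the
#' effect size used to select and weight gene-set members.
#'
#' @param ref a [reference_expression()].
#' @param cell_type in-group label; must occur in `ref$sample_labels`.
#' @param pseudocount added to both group means before the ratio (default 1).
#' @return named numeric vector of per-gene logFC values.
#' @export
one_vs_rest_logfc <- function(ref, cell_type, pseudocount = 1) {
  stopifnot(inherits(ref, "ReferenceExpression"))
  in_group <- ref$sample_labels == cell_type
  if (!any(in_group)) {
    stop(sprintf("cell type '%s' not in reference; available: %s", cell_type,
                 paste(sort(unique(ref$sample_labels)), collapse = ", ")))
  }
  mu_in <- rowMeans(ref$values[, in_group, drop = FALSE])
  mu_out <- rowMeans(ref$values[, !in_group, drop = FALSE])
  stats::setNames(log2((mu_in + pseudocount) / (mu_out + pseudocount)),
                  ref$gene_ids)
}

#' Build weighted cell-type gene sets from a labeled reference
#'
#' For each requested type, genes passing the one-vs-rest logFC threshold
#' (strictly greater than `logfc_min`) are intersected with the union of
#' the curated gene sets mapped to that type; surviving genes are weighted
#' by their logFC.
#'
#' @param ref a [reference_expression()].
#' @param collections named list of curated gene sets (e.g. from
#'   [read_gmt()]).
#' @param type_map named list: cell type -> character vector of set names
#'   in `collections` representing it.
#' @param types cell types to build (default: all of `names(type_map)`).
#' @param logfc_min logFC selection threshold (default 5, strict).
#' @param pseudocount passed to [one_vs_rest_logfc()].
#' @return list of [weighted_gene_set()] objects, one per type.
#' @export
build_weighted_sets <- function(ref, collections, type_map,
                                types = names(type_map), logfc_min = 5,
                                pseudocount = 1) {
  lapply(types, function(ty) {
    if (is.null(type_map[[ty]])) {
      stop(sprintf("no curated gene-set mapping for cell type '%s'", ty))
    }
    missing_sets <- setdiff(type_map[[ty]], names(collections))
    if (length(missing_sets)) {
      stop(sprintf("mapped set(s) not in collections for '%s': %s", ty,
                   paste(missing_sets, collapse = ", ")))
    }
    curated <- unique(unlist(collections[type_map[[ty]]], use.names = FALSE))
    lfc <- one_vs_rest_logfc(ref, ty, pseudocount)
    de_genes <- names(lfc)[lfc > logfc_min]
    members <- intersect(de_genes, curated)
    if (length(members) == 0) {
      stop(sprintf(
        "empty gene set for '%s': no gene passes logFC > %g and is in the curated set(s)",
        ty, logfc_min))
    }
    weighted_gene_set(ty, members, lfc[members])
  })
}
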