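#' Read a count matrix from disk
#'
#' Supports the 10x-style MatrixMarket triplet layout (a directory, or a
#' `matrix.mtx` path, with sibling `features.tsv`/`genes.tsv` and
#' `barcodes.tsv`) and dense delimited tables with a header row of cell
#' barcodes and feature identifiers in the first column.
#'
#' @param path directory or file path.
#' @param format `"mtx_triplet"` or `"dense_table"`.
#' @param modality `"RNA"` or `"ADT"`.
#' @param feature_column which column of the features file carries the
#'   identifier to use (10x files have ID in column 1 and display name in
#'   column 2). Default 1.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = c("mtx_triplet", "dense_table"),
                        modality = c("RNA", "ADT"), feature_column = 1) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (format == "mtx_triplet") {
    files <- .locate_mtx_triplet(path)
    m <- tryCatch(Matrix::readMM(files$matrix),
                  error = function(e) stop(sprintf(
                    "failed to parse MTX file '%s': %s", files$matrix,
                    conditionMessage(e))))
    feats <- utils::read.table(files$features, sep = "\t",
                               stringsAsFactors = FALSE, quote = "",
                               comment.char = "")
    bars <- utils::read.table(files$barcodes, sep = "\t",
                              stringsAsFactors = FALSE, quote = "",
                              comment.char = "")
    if (nrow(feats) != nrow(m)) {
      stop(sprintf("format error: features file has %d entries but matrix declares %d rows",
                   nrow(feats), nrow(m)))
    }
    if (nrow(bars) != ncol(m)) {
      stop(sprintf("format error: barcodes file has %d entries but matrix declares %d columns",
                   nrow(bars), ncol(m)))
    }
    if (feature_column > ncol(feats)) stop("feature_column exceeds features file width")
    count_matrix(m, feature_ids = feats[[feature_column]],
                 cell_ids = bars[[1]], modality = modality)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             row.names = 1, check.names = FALSE,
                             stringsAsFactors = FALSE)
    count_matrix(as.matrix(tab), feature_ids = rownames(tab),
                 cell_ids = colnames(tab), modality = modality)
  }
}

.locate_mtx_triplet <- function(path) {
  dir <- if (dir.exists(path)) path else dirname(path)
  pick <- function(cands, what) {
    for (f in cands) {
      p <- file.path(dir, f)
      if (file.exists(p)) return(p)
    }
    stop(sprintf("no %s file found under '%s'", what, dir))
  }
  list(matrix = if (!dir.exists(path) && file.exists(path)) path else
         pick("matrix.mtx", "matrix.mtx"),
       features = pick(c("features.tsv", "genes.tsv"), "features/genes"),
       barcodes = pick("barcodes.tsv", "barcodes"))
}

#' Write a count matrix as an MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` into `dir`.
#' Round-trips exactly through [read_counts()].
#'
#' @param x a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$values, file.path(dir, "matrix.mtx"))
  writeLines(x$feature_ids, file.path(dir, "features.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read gene sets in GMT format
#'
#' One set per tab-separated line: set name, description, then member
#' genes.
#'
#' @param path GMT file.
#' @return named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("malformed GMT line (need name, description, >=1 gene): '%s'",
                   substr(ln, 1, 60)))
    }
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    sets[[parts[1]]] <- genes
  }
  .check_unique(names(sets), "GMT set names")
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors, or a list of
#'   [weighted_gene_set()] objects.
#' @param path output file.
#' @param descriptions optional per-set description column (default "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (length(sets) && inherits(sets[[1]], "WeightedGeneSet")) {
    sets <- stats::setNames(lapply(sets, `[[`, "genes"),
                            vapply(sets, `[[`, "", "cell_type"))
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read weighted gene sets from a GMT file plus optional weights sidecar
#'
#' The sidecar is a TSV with columns `set_name`, `gene`, `weight`. Genes
#' without a sidecar entry get weight 1; weights must be positive.
#'
#' @param path GMT file.
#' @param weights_path optional sidecar TSV.
#' @return list of [weighted_gene_set()] objects.
#' @export
read_weighted_sets <- function(path, weights_path = NULL) {
  sets <- read_gmt(path)
  wtab <- NULL
  if (!is.null(weights_path)) {
    wtab <- utils::read.table(weights_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    need <- c("set_name", "gene", "weight")
    if (!all(need %in% names(wtab))) {
      stop("weights sidecar must have columns set_name, gene, weight")
    }
  }
  lapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    w <- rep(1, length(genes))
    if (!is.null(wtab)) {
      sub <- wtab[wtab$set_name == nm, ]
      idx <- match(sub$gene, genes)
      w[idx[!is.na(idx)]] <- sub$weight[!is.na(idx)]
    }
    weighted_gene_set(nm, genes, w)
  })
}

#' Write weighted gene sets as GMT plus weights sidecar
#'
#' @param sets list of [weighted_gene_set()] objects.
#' @param path GMT output file.
#' @param weights_path sidecar TSV output file.
#' @return `path`, invisibly.
#' @export
write_weighted_sets <- function(sets, path, weights_path) {
  write_gmt(sets, path)
  tab <- do.call(rbind, lapply(sets, function(s) {
    data.frame(set_name = s$cell_type, gene = s$genes,
               weight = unname(s$weights), stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, weights_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cell-type to ADT-marker map
#'
#' TSV lines of the form `cell_type<TAB>marker1,marker2,...`.
#'
#' @param path TSV file.
#' @return a [marker_map()].
#' @export
read_marker_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  entries <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop(sprintf("malformed marker map line: '%s'", ln))
    }
    entries[[parts[1]]] <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  }
  marker_map(entries)
}

#' Write a cell-type to ADT-marker map
#'
#' @param map a [marker_map()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  stopifnot(inherits(map, "MarkerMap"))
  writeLines(vapply(names(map$entries), function(ty) {
    paste0(ty, "\t", paste(map$entries[[ty]], collapse = ","))
  }, ""), path)
  invisible(path)
}

#' Write a score matrix as CSV (cells x types, header row of type names)
#'
#' @param x a [score_matrix()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  stopifnot(inherits(x, "ScoreMatrix"))
  utils::write.csv(as.data.frame(x$values), path, row.names = TRUE)
  invisible(path)
}

#' Read a score matrix from CSV
#'
#' @param path CSV written by [write_scores()].
#' @param method scoring method tag for the result.
#' @return a [score_matrix()].
#' @export
read_scores <- function(path, method = c("camml", "ecdf", "cite_binary", "chimp")) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  score_matrix(as.matrix(tab), method = match.arg(method))
}
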