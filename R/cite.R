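#' Exact two-cluster split of one ADT marker
#'
#' Partitions the values of a single marker into a "low" and a "high"
#' cluster by minimizing the total within-cluster sum of squares over all
#' two-cluster partitions of the real line. In one dimension the optimal
#' two-cluster partition is always a threshold on the sorted values, so
#' the optimum is found exactly by scanning the n-1 split points — the
#' same objective iterative two-center clustering targets, without seed
#' sensitivity.
#'
#' @param values numeric vector, one value per cell (>= 2 distinct values
#'   required).
#' @param marker_id identifier recorded in the result.
#' @return an object of class `SplitResult` with `marker_id`, `cut_value`
#'   (midpoint between the boundary neighbors), `low_center`,
#'   `high_center`, `n_high`, `high` (logical per-cell membership in the
#'   high cluster, input order), and `method = "two_means"`.
#' @export
two_means_split <- function(values, marker_id = "marker") {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  if (length(unique(values)) < 2) {
    stop(sprintf(
      "degenerate marker '%s': all values identical; treat it as uninformative",
      marker_id))
  }
  ord <- order(values)
  v <- values[ord]
  n <- length(v)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  k <- seq_len(n - 1)
  # within-SS of {v[1..k]} and {v[k+1..n]} via sum(x^2) - (sum x)^2 / m
  ss_left <- cs2[k] - cs[k]^2 / k
  ss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  tot <- ss_left + ss_right
  tot[v[k] == v[k + 1]] <- Inf  # equal values cannot straddle the cut
  k_best <- which.min(tot)
  low_center <- cs[k_best] / k_best
  high_center <- (cs[n] - cs[k_best]) / (n - k_best)
  cut <- (v[k_best] + v[k_best + 1]) / 2
  high <- logical(n)
  high[ord[(k_best + 1):n]] <- TRUE
  structure(list(marker_id = marker_id, cut_value = cut,
                 low_center = low_center, high_center = high_center,
                 n_high = n - k_best, high = high, method = "two_means"),
            class = "SplitResult")
}

#' Median split of one ADT marker
#'
#' Assigns "high" to values strictly above the median. Provided as the
#' comparison baseline for the two-cluster split: it forces (at most) half
#' of the cells into the high cluster regardless of how many cells truly
#' carry the marker.
#'
#' @param values numeric vector (>= 2 values).
#' @param marker_id identifier recorded in the result.
#' @return a `SplitResult` with `method = "median"`; for all-equal input
#'   `n_high` is 0 and the centers are flagged degenerate.
#' @export
median_split <- function(values, marker_id = "marker") {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  med <- stats::median(values)
  high <- values > med
  low_center <- if (any(!high)) mean(values[!high]) else NA_real_
  high_center <- if (any(high)) mean(values[high]) else NA_real_
  structure(list(marker_id = marker_id, cut_value = med,
                 low_center = low_center, high_center = high_center,
                 n_high = sum(high), high = high, method = "median"),
            class = "SplitResult")
}

#' @export
print.SplitResult <- function(x, ...) {
  cat(sprintf("SplitResult [%s] '%s': cut %.4g, centers %.4g / %.4g, n_high %d\n",
              x$method, x$marker_id, x$cut_value, x$low_center,
              x$high_center, x$n_high))
  invisible(x)
}

.adt_values <- function(adt, marker) {
  ids <- if (inherits(adt, "CountMatrix")) adt$feature_ids else adt$feature_ids
  if (!marker %in% ids) stop(sprintf("ADT marker '%s' not found in matrix", marker))
  as.numeric(adt$values[marker, ])
}

#' Binary cell-type call from ADT markers
#'
#' Splits each of the type's markers into low/high clusters and ORs the
#' high-cluster memberships: a cell is positive for the type if any of its
#' markers falls in the high cluster. Markers whose values are all
#' identical are uninformative; they are excluded with a warning, and if
#' every marker of the type is degenerate the type passes through with all
#' bits 1 (so downstream multiplication leaves transcriptome scores
#' untouched rather than zeroing the whole type).
#'
#' @param adt ADT [count_matrix()] or [normalized_matrix()].
#' @param markers character vector of marker identifiers for one type.
#' @return integer vector of 0/1 bits, one per cell.
#' @export
binarize_celltype <- function(adt, markers) {
  n <- ncol(adt$values)
  calls <- matrix(FALSE, n, 0)
  for (mk in markers) {
    v <- .adt_values(adt, mk)
    sp <- tryCatch(two_means_split(v, mk), error = function(e) e)
    if (inherits(sp, "error")) {
      warning(sprintf("marker '%s' is degenerate and was excluded", mk))
      next
    }
    calls <- cbind(calls, sp$high)
  }
  if (ncol(calls) == 0) {
    warning(sprintf(
      "all markers degenerate (%s); type passes through with bits 1",
      paste(markers, collapse = ", ")))
    return(rep(1L, n))
  }
  as.integer(rowSums(calls) > 0)
}

#' Discretized CITE-seq score matrix
#'
#' Applies [binarize_celltype()] to every mapped type. Types listed in
#' `types` but absent from the map pass through with all bits 1 (flagged).
#'
#' @param adt ADT [count_matrix()] (default splitting scale is raw counts)
#'   or a [normalized_matrix()] of CLR values.
#' @param map a [marker_map()].
#' @param types cell types to produce, default the mapped types.
#' @return a [score_matrix()] with `method = "cite_binary"`.
#' @export
cite_binary_scores <- function(adt, map, types = names(map$entries)) {
  stopifnot(inherits(map, "MarkerMap"))
  bits <- sapply(types, function(ty) {
    if (is.null(map$entries[[ty]])) {
      warning(sprintf("cell type '%s' has no mapped markers; bits set to 1", ty))
      rep(1L, ncol(adt$values))
    } else {
      binarize_celltype(adt, map$entries[[ty]])
    }
  })
  score_matrix(bits, cell_ids = adt$cell_ids, type_names = types,
               method = "cite_binary")
}

#' Per-marker split diagnostics
#'
#' Two-cluster and median split summaries for every marker in the map, for
#' inspection of the cut-offs against the marker's count distribution.
#'
#' @param adt ADT [count_matrix()] or [normalized_matrix()].
#' @param map a [marker_map()].
#' @return data.frame with one row per marker and method.
#' @export
split_diagnostics <- function(adt, map) {
  markers <- unique(unlist(map$entries, use.names = FALSE))
  do.call(rbind, lapply(markers, function(mk) {
    v <- .adt_values(adt, mk)
    rows <- lapply(list(two_means = function() two_means_split(v, mk),
                        median = function() median_split(v, mk)),
                   function(f) tryCatch(f(), error = function(e) NULL))
    do.call(rbind, lapply(rows[!vapply(rows, is.null, TRUE)], function(sp) {
      data.frame(marker = mk, method = sp$method, cut = sp$cut_value,
                 low_center = sp$low_center, high_center = sp$high_center,
                 n_high = sp$n_high, stringsAsFactors = FALSE)
    }))
  }))
}

#' Continuous CITE-seq eCDF scores
#'
#' For each marker, every cell is scored by its quantile position in the
#' marker's empirical CDF (right-continuous: score = fraction of cells
#' with value <= the cell's value, so ties share a score and the maximum
#' scores exactly 1). A type's score is the maximum over its markers.
#'
#' @param adt_norm [normalized_matrix()] of normalized/scaled ADT values
#'   (a raw [count_matrix()] is also accepted).
#' @param map a [marker_map()].
#' @param types cell types to produce, default the mapped types.
#' @return a [score_matrix()] with `method = "ecdf"`; entries in (0, 1].
#' @export
ecdf_scores <- function(adt_norm, map, types = names(map$entries)) {
  stopifnot(inherits(map, "MarkerMap"))
  n <- ncol(adt_norm$values)
  marker_ecdf <- function(mk) {
    v <- .adt_values(adt_norm, mk)
    rank(v, ties.method = "max") / n
  }
  scores <- sapply(types, function(ty) {
    mks <- map$entries[[ty]]
    if (is.null(mks)) {
      stop(sprintf("cell type '%s' has no mapped markers for eCDF scoring", ty))
    }
    do.call(pmax, lapply(mks, marker_ecdf))
  })
  score_matrix(scores, cell_ids = adt_norm$cell_ids, type_names = types,
               method = "ecdf")
}
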