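#' Integrate transcriptome scores with binary ADT calls
#'
#' Multiplies each transcriptome (CAMML) score by the corresponding
#' discretized CITE-seq bit, aligning cells and types by identifier. The
#' result can never exceed the transcriptome score in any entry: protein
#' evidence can veto a cell type (bit 0 zeroes the score) or leave it
#' untouched (bit 1), making the integration strictly conservative.
#'
#' @param camml [score_matrix()] with continuous transcriptome scores.
#' @param cite_bits [score_matrix()] with `method = "cite_binary"`.
#' @return a [score_matrix()] with `method = "chimp"`.
#' @export
combine_scores <- function(camml, cite_bits) {
  stopifnot(inherits(camml, "ScoreMatrix"), inherits(cite_bits, "ScoreMatrix"))
  if (cite_bits$method != "cite_binary") {
    stop("cite_bits must be a cite_binary ScoreMatrix")
  }
  .align_diff <- function(a, b, what) {
    d <- c(setdiff(a, b), setdiff(b, a))
    if (length(d)) {
      stop(sprintf("misaligned %s between score matrices: %s", what,
                   paste(utils::head(d, 10), collapse = ", ")))
    }
  }
  .align_diff(camml$cell_ids, cite_bits$cell_ids, "cell ids")
  .align_diff(camml$type_names, cite_bits$type_names, "type names")
  bits <- cite_bits$values[camml$cell_ids, camml$type_names, drop = FALSE]
  score_matrix(camml$values * bits, method = "chimp")
}

#' Single-label assignment from a score matrix
#'
#' Assigns each cell the type with the highest score; cells with all-zero
#' scores are `"unassigned"`. Exact ties are broken lexicographically on
#' the type name (optionally after comparing a secondary score matrix,
#' e.g. raw transcriptome scores under an integrated matrix) and flagged.
#'
#' @param scores a [score_matrix()].
#' @param tiebreak_scores optional secondary [score_matrix()] consulted
#'   before the lexicographic rule on exact ties.
#' @return data.frame with `cell_id`, `label`, `top_score`, `tied`
#'   (logical).
#' @export
assign_single_label <- function(scores, tiebreak_scores = NULL) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  v <- scores$values
  ord <- order(scores$type_names)  # lexicographic fallback built into max.col order
  v_ord <- v[, ord, drop = FALSE]
  types_ord <- scores$type_names[ord]
  top <- apply(v_ord, 1, max)
  labels <- character(nrow(v))
  tied <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    if (top[i] == 0) {
      labels[i] <- "unassigned"
      next
    }
    cand <- which(v_ord[i, ] == top[i])
    if (length(cand) > 1) {
      tied[i] <- TRUE
      if (!is.null(tiebreak_scores)) {
        tb <- tiebreak_scores$values[scores$cell_ids[i],
                                     types_ord[cand], drop = TRUE]
        cand <- cand[tb == max(tb)]
      }
    }
    labels[i] <- types_ord[cand[1]]
  }
  if (any(tied)) {
    message(sprintf("%d cell(s) had tied top scores; ties broken deterministically",
                    sum(tied)))
  }
  data.frame(cell_id = scores$cell_ids, label = labels, top_score = top,
             tied = tied, stringsAsFactors = FALSE)
}

#' Compare assigned label proportions to reference proportions
#'
#' Computes per-type proportions over the assigned cells (the
#' `"unassigned"` mass is excluded from the denominator), then Pearson's
#' product-moment correlation with its t-distribution p-value and the mean
#' squared error against the reference proportions over the shared types.
#'
#' @param labels data.frame from [assign_single_label()], or a character
#'   vector of labels.
#' @param reference named numeric vector of reference proportions (e.g.
#'   flow cytometry fractions).
#' @param types the full set of types the labeling could produce; defaults
#'   to the labels actually observed. Types in `reference` but outside
#'   this set are dropped; shared types with no assigned cells get
#'   estimated proportion 0.
#' @return list of class `ProportionComparison`: `table` (type, estimated,
#'   reference), `pearson_r`, `p_value`, `mse`.
#' @export
compare_proportions <- function(labels, reference,
                                types = NULL) {
  lab <- if (is.data.frame(labels)) labels$label else as.character(labels)
  lab <- lab[lab != "unassigned"]
  if (!length(lab)) stop("no assigned cells to compare")
  if (is.null(types)) types <- unique(lab)
  shared <- intersect(names(reference), types)
  if (length(shared) < 3) {
    stop(sprintf("need >= 3 shared types for a meaningful correlation (got %d)",
                 length(shared)))
  }
  est <- vapply(shared, function(ty) mean(lab == ty), 0)
  ref <- as.numeric(reference[shared])
  if (stats::sd(est) == 0 || stats::sd(ref) == 0) {
    warning("a proportion vector is constant; correlation undefined")
    r <- NA_real_
    p <- NA_real_
  } else {
    ct <- stats::cor.test(est, ref, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(
    table = data.frame(type = shared, estimated = unname(est),
                       reference = ref, stringsAsFactors = FALSE),
    pearson_r = r, p_value = p,
    mse = mean((est - ref)^2)), class = "ProportionComparison")
}

#' @export
print.ProportionComparison <- function(x, ...) {
  cat(sprintf("ProportionComparison: r = %.3f (p = %.3g), MSE = %.4g\n",
              x$pearson_r, x$p_value, x$mse))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Modified Shannon diversity index of per-cell type scores
#'
#' For each cell, scores are smoothed by `epsilon`, normalized to
#' proportions `p_i = (s_i + epsilon) / sum_j (s_j + epsilon)`, and the
#' Shannon entropy `-sum p_i ln p_i` is returned. The smoothing removes
#' exact zeros so that two cells positive for the same single type but
#' with different score strengths get different entropies: the stronger
#' call gets the lower entropy. Values lie in [0, ln(R)] for R types,
#' with the maximum attained exactly when all scores are equal.
#'
#' @param scores a [score_matrix()] (any method) or a numeric matrix,
#'   cells x types.
#' @param epsilon smoothing parameter (default 0.001).
#' @return list of class `MsdiResult`: `msdi` (named per-cell vector),
#'   `epsilon`, `R`.
#' @export
msdi <- function(scores, epsilon = 0.001) {
  v <- if (inherits(scores, "ScoreMatrix")) scores$values else as.matrix(scores)
  if (any(v < 0)) stop("scores must be non-negative")
  p <- v + epsilon
  p <- p / rowSums(p)
  h <- -rowSums(p * log(p))
  h[h < 0] <- 0  # guard tiny negative round-off at R = 1
  structure(list(msdi = stats::setNames(h, rownames(v)), epsilon = epsilon,
                 R = ncol(v)), class = "MsdiResult")
}

#' @export
print.MsdiResult <- function(x, ...) {
  cat(sprintf("MsdiResult: %d cells, R = %d, epsilon = %g, median = %.4g\n",
              length(x$msdi), x$R, x$epsilon, stats::median(x$msdi)))
  invisible(x)
}

#' One-vs-rest Wilcoxon marker detection across groups
#'
#' For every group, compares each feature between the group's cells and
#' all other cells with a two-sided Wilcoxon rank-sum test and an effect
#' size: the difference of group means for bounded score matrices
#' (`scale = "score"`), or the log2 ratio of pseudocounted group means for
#' counts (`scale = "counts"`). Only upregulated features with effect
#' strictly above `logfc_min` are kept, ranked by effect descending.
#'
#' @param feature_matrix numeric matrix, cells x features.
#' @param groups factor or character vector of group labels per cell
#'   (>= 2 groups, each with >= 2 cells).
#' @param logfc_min effect threshold (default 0.01, strict).
#' @param scale `"score"` (difference of means) or `"counts"` (log2
#'   pseudocount ratio).
#' @param p_adjust if `TRUE`, add Benjamini-Hochberg adjusted p-values
#'   (per group, across all tested features).
#' @param pseudocount for `scale = "counts"` (default 1).
#' @return data.frame with `group`, `feature`, `logFC`, `p_value`,
#'   optional `p_adj`, and `rank` within group.
#' @export
discordance_de <- function(feature_matrix, groups, logfc_min = 0.01,
                           scale = c("score", "counts"), p_adjust = FALSE,
                           pseudocount = 1) {
  scale <- match.arg(scale)
  x <- if (inherits(feature_matrix, "ScoreMatrix")) feature_matrix$values else
    as.matrix(feature_matrix)
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) stop("one group label per cell (row) required")
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) {
    stop(sprintf("group(s) with < 2 cells: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  out <- list()
  for (g in names(tab)) {
    in_g <- groups == g
    mu_in <- colMeans(x[in_g, , drop = FALSE])
    mu_out <- colMeans(x[!in_g, , drop = FALSE])
    eff <- if (scale == "score") mu_in - mu_out else
      log2((mu_in + pseudocount) / (mu_out + pseudocount))
    keep <- which(eff > logfc_min & mu_in > mu_out)
    if (!length(keep)) next
    pv <- vapply(keep, function(j) {
      # exact for small tie-free samples, normal approximation otherwise
      suppressWarnings(stats::wilcox.test(x[in_g, j], x[!in_g, j])$p.value)
    }, 0)
    df <- data.frame(group = g, feature = colnames(x)[keep],
                     logFC = unname(eff[keep]), p_value = unname(pv),
                     stringsAsFactors = FALSE)
    if (p_adjust) df$p_adj <- stats::p.adjust(df$p_value, "BH")
    df <- df[order(-df$logFC), ]
    df$rank <- seq_len(nrow(df))
    out[[g]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
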