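#' Variance-adjusted squared distances for one gene set
#'
#' For each cell `c`, `d2_c = sum_j w_j * x_{c,j}^2 / var_j`: a squared
#' Mahalanobis-style distance from the origin with a diagonal covariance
#' given by the per-gene variances, weighted per gene. On centered
#' (Z-scored) data the origin is the per-gene mean, so `d2` measures joint
#' deviation of a cell's set genes from the population average.
#'
#' @param x numeric matrix, cells x set genes.
#' @param weights positive per-gene weights, length `ncol(x)`.
#' @param gene_vars positive per-gene variances, length `ncol(x)`;
#'   defaults to the sample variance of each column of `x`.
#' @return numeric vector of squared distances, one per cell (all >= 0).
#' @export
vam_distance <- function(x, weights, gene_vars = apply(x, 2, stats::var)) {
  x <- as.matrix(x)
  if (ncol(x) == 0) stop("empty gene set after variance filtering")
  if (length(weights) != ncol(x) || length(gene_vars) != ncol(x)) {
    stop("weights and gene_vars must have one entry per set gene")
  }
  if (any(weights <= 0)) stop("weights must be positive")
  if (any(gene_vars <= 0)) stop("gene_vars must be positive (drop zero-variance genes upstream)")
  drop(x^2 %*% (weights / gene_vars))
}

#' Permutation-null squared distances
#'
#' Each permutation independently shuffles every gene's values across
#' cells, breaking gene-gene correlation while preserving each gene's
#' marginal distribution (and hence its variance), then recomputes the
#' variance-adjusted distances. The pooled values form the null sample
#' used to calibrate observed distances.
#'
#' @param x numeric matrix, cells x set genes.
#' @param weights positive per-gene weights.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   output.
#' @param gene_vars per-gene variances (default: sample variance of `x`
#'   columns, which permutation preserves).
#' @return numeric vector of length `n_perm * nrow(x)` of null distances.
#' @export
null_distances <- function(x, weights, n_perm = 100, seed = 1,
                           gene_vars = apply(x, 2, stats::var)) {
  x <- as.matrix(x)
  if (n_perm < 1) stop("n_perm must be >= 1")
  rng <- .seeded_rng(seed)
  n <- nrow(x)
  out <- numeric(n_perm * n)
  for (p in seq_len(n_perm)) {
    xp <- apply(x, 2, function(col) col[rng$sample_int(n)])
    out[((p - 1) * n + 1):(p * n)] <- vam_distance(xp, weights, gene_vars)
  }
  out
}

# Isolated RNG stream: seeds deterministically, leaves the caller's
# .Random.seed exactly as it found it.
.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  swap_in <- function() {
    env$outer <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv(), inherits = FALSE) else NULL
    if (is.null(env$state)) set.seed(seed) else
      assign(".Random.seed", env$state, envir = globalenv())
  }
  swap_out <- function() {
    env$state <- get(".Random.seed", globalenv(), inherits = FALSE)
    if (is.null(env$outer)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", env$outer, envir = globalenv())
  }
  list(sample_int = function(n) {
    swap_in()
    on.exit(swap_out())
    sample.int(n)
  })
}

#' Fit a gamma distribution to null distances by the method of moments
#'
#' `shape = mean^2 / var`, `rate = mean / var`; optionally refined by
#' maximum likelihood (`fit_method = "mle"`, Newton iterations on the
#' gamma log-likelihood starting from the moment estimates).
#'
#' @param null_d2 positive null squared distances (>= 30 values).
#' @param fit_method `"moments"` (default) or `"mle"`.
#' @return an object of class `GammaFit` with `shape`, `rate`, `n_null`,
#'   `fit_method`.
#' @export
fit_gamma <- function(null_d2, fit_method = c("moments", "mle")) {
  fit_method <- match.arg(fit_method)
  null_d2 <- null_d2[null_d2 > 0]
  if (length(null_d2) < 30) stop("need at least 30 positive null values")
  m <- mean(null_d2)
  v <- stats::var(null_d2)
  if (v == 0) stop("degenerate null: all null distances identical")
  shape <- m^2 / v
  rate <- m / v
  if (fit_method == "mle") {
    # Newton on shape using the profile likelihood; rate = shape / mean.
    s <- log(m) - mean(log(null_d2))
    for (i in 1:50) {
      g <- log(shape) - digamma(shape) - s
      h <- 1 / shape - trigamma(shape)
      step <- g / h
      shape_new <- shape - step
      if (shape_new <= 0) shape_new <- shape / 2
      if (abs(shape_new - shape) < 1e-10 * shape) {
        shape <- shape_new
        break
      }
      shape <- shape_new
    }
    rate <- shape / m
  }
  structure(list(shape = shape, rate = rate, n_null = length(null_d2),
                 fit_method = fit_method), class = "GammaFit")
}

#' @export
print.GammaFit <- function(x, ...) {
  cat(sprintf("GammaFit (%s): shape %.4g, rate %.4g (n = %d)\n",
              x$fit_method, x$shape, x$rate, x$n_null))
  invisible(x)
}

#' Score cells for weighted cell-type gene sets
#'
#' The core transcriptome scoring step: for each gene set, compute
#' variance-adjusted squared distances for every cell, calibrate them
#' against a permutation null summarized by a fitted gamma distribution,
#' and report the gamma CDF value — a score in [0,1] measuring how
#' enriched the cell is for the set relative to chance.
#'
#' @param norm_rna a [normalized_matrix()], typically Z-scored
#'   log-normalized expression.
#' @param sets list of [weighted_gene_set()] objects.
#' @param n_perm permutations per set (default 100).
#' @param seed integer seed for the permutation null.
#' @param fit_method gamma fitting method, see [fit_gamma()].
#' @return a [score_matrix()] with `method = "camml"`.
#' @export
score_cell_types <- function(norm_rna, sets, n_perm = 100, seed = 1,
                             fit_method = c("moments", "mle")) {
  stopifnot(inherits(norm_rna, "NormalizedMatrix"))
  fit_method <- match.arg(fit_method)
  type_names <- vapply(sets, `[[`, "", "cell_type")
  .check_unique(type_names, "cell types in sets")
  scores <- matrix(NA_real_, ncol(norm_rna$values), length(sets),
                   dimnames = list(norm_rna$cell_ids, type_names))
  for (k in seq_along(sets)) {
    set <- sets[[k]]
    present <- set$genes %in% norm_rna$feature_ids
    if (!any(present)) {
      stop(sprintf("gene set '%s' has no genes present in the matrix",
                   set$cell_type))
    }
    if (!all(present)) {
      warning(sprintf("gene set '%s': %d/%d genes absent from matrix, dropped",
                      set$cell_type, sum(!present), length(present)))
    }
    genes <- set$genes[present]
    x <- t(norm_rna$values[genes, , drop = FALSE])
    gv <- apply(x, 2, stats::var)
    ok <- gv > 0
    if (!any(ok)) {
      stop(sprintf("gene set '%s' is empty after zero-variance filtering",
                   set$cell_type))
    }
    x <- x[, ok, drop = FALSE]
    w <- unname(set$weights[genes][ok])
    gv <- gv[ok]
    d2 <- vam_distance(x, w, gv)
    null <- null_distances(x, w, n_perm = n_perm, seed = seed + k,
                           gene_vars = gv)
    fit <- fit_gamma(null, fit_method)
    scores[, k] <- stats::pgamma(d2, shape = fit$shape, rate = fit$rate)
  }
  score_matrix(scores, method = "camml")
}
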