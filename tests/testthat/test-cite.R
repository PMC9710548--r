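test_that("two-cluster split solves the documented examples exactly", {
  sp <- two_means_split(c(0, 0, 0, 10, 10, 10))
  expect_equal(sp$n_high, 3)
  expect_equal(sp$low_center, 0)
  expect_equal(sp$high_center, 10)
  expect_equal(sp$cut_value, 5)

  sp2 <- two_means_split(c(1, 2, 3, 10, 11))
  oracle <- brute_force_two_means(c(1, 2, 3, 10, 11))
  expect_equal(sp2$n_high, 2)
  expect_equal(sp2$n_high, oracle$n_high)
  expect_identical(which(sp2$high), c(4L, 5L))

  expect_error(two_means_split(c(5, 5)), "degenerate")
  expect_error(two_means_split(5), "at least 2")
})

test_that("the scan agrees with the exhaustive oracle and with iterative clustering", {
  set.seed(17)
  agree_kmeans <- 0
  run <- 0
  for (i in 1:300) {
    n <- sample(5:200, 1)
    v <- switch(sample(3, 1),
                rnorm(n),
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 5)),
                rpois(n, 10))
    if (length(unique(v)) < 2) next
    run <- run + 1
    sp <- two_means_split(v)
    oracle <- brute_force_two_means(v)
    wss <- sum((v[!sp$high] - mean(v[!sp$high]))^2) +
      sum((v[sp$high] - mean(v[sp$high]))^2)
    expect_equal(wss, oracle$wss, tolerance = 1e-8)
    km <- suppressWarnings(stats::kmeans(v, centers = 2, nstart = 25))
    if (km$tot.withinss >= wss - 1e-8) agree_kmeans <- agree_kmeans + 1
  }
  expect_gte(agree_kmeans / run, 0.99)
})

test_that("split labels are invariant under increasing affine transforms", {
  set.seed(23)
  for (i in 1:20) {
    v <- c(rnorm(40), rnorm(20, 4))
    a <- two_means_split(v)
    b <- two_means_split(2.5 * v + 7)
    expect_identical(a$high, b$high)
  }
})

test_that("median split halves the data and differs from the two-cluster split
           on unbalanced mixtures", {
  sp <- median_split(c(1, 2, 3, 4))
  expect_equal(sp$cut_value, 2.5)
  expect_equal(sp$n_high, 2)
  expect_equal(median_split(rep(3, 5))$n_high, 0)
  # 30% high mode: the two-cluster split tracks the true mass, the median
  # is forced to one half
  set.seed(29)
  n <- 4000
  v <- c(rnbinom(0.7 * n, mu = 8, size = 4), rnbinom(0.3 * n, mu = 150, size = 10))
  tm <- two_means_split(v)
  md <- median_split(v)
  expect_lt(abs(tm$n_high / n - 0.30), 0.02)
  # ties at the median keep n_high at or just under one half
  expect_equal(md$n_high / n, 0.50, tolerance = 0.02)
  expect_lte(md$n_high / n, 0.50)
})

test_that("binary type calls OR their markers' high-cluster membership", {
  # cells: CD4-high/CD8-low, both-low, both-high, CD8-high
  adt <- make_counts(matrix(c(200, 2,
                              3, 1,
                              180, 170,
                              2, 210), 2, 4),
                     modality = "ADT", feature_ids = c("CD4", "CD8"),
                     cell_ids = paste0("c", 1:4))
  bits <- binarize_celltype(adt, c("CD4", "CD8"))
  expect_identical(bits, c(1L, 0L, 1L, 1L))
  # single-marker type reduces to that marker's call
  expect_identical(binarize_celltype(adt, "CD4"), c(1L, 0L, 1L, 0L))
  expect_error(binarize_celltype(adt, "CD99"), "CD99")
  # all markers degenerate -> pass-through bits 1 (both steps warn)
  adt2 <- make_counts(matrix(5, 1, 4), modality = "ADT",
                      feature_ids = "FLAT", cell_ids = paste0("c", 1:4))
  w <- testthat::capture_warnings(bits2 <- binarize_celltype(adt2, "FLAT"))
  expect_match(w, "excluded", all = FALSE)
  expect_match(w, "passes through", all = FALSE)
  expect_identical(bits2, rep(1L, 4))
})

test_that("two-cluster positive counts track a well-separated mixture's truth", {
  set.seed(31)
  n <- 3000
  pos <- rbinom(n, 1, 0.5) == 1
  v <- ifelse(pos, rnorm(n, 8, 1), rnorm(n, 0, 1))  # 8 sd separation
  sp <- two_means_split(v)
  expect_lt(abs(sp$n_high - sum(pos)) / n, 0.02)
})

test_that("eCDF scores are right-continuous quantile positions with max over markers", {
  adt <- make_counts(matrix(c(5, 1, 3, 9, 1, 7, 7, 2), 2, 4, byrow = FALSE),
                     modality = "ADT", feature_ids = c("M1", "M2"),
                     cell_ids = paste0("c", 1:4))
  map <- marker_map(list(X = "M1", Y = c("M1", "M2")))
  sc <- ecdf_scores(adt, map)
  # M1 values 5,3,1,7 -> distinct scores are a permutation of 1/4..4/4
  expect_setequal(sc$values[, "X"], c(1, 2, 3, 4) / 4)
  expect_equal(unname(sc$values[which.max(adt$values["M1", ]), "X"]), 1)
  # two-marker type is the elementwise max of marker eCDFs
  m1 <- rank(as.numeric(adt$values["M1", ]), ties.method = "max") / 4
  m2 <- rank(as.numeric(adt$values["M2", ]), ties.method = "max") / 4
  expect_equal(unname(sc$values[, "Y"]), pmax(m1, m2))
  # ties share a score and scores are monotone in the raw value
  adt_t <- make_counts(matrix(c(2, 2, 5, 1), 1, 4), modality = "ADT",
                       feature_ids = "M", cell_ids = paste0("c", 1:4))
  st <- ecdf_scores(adt_t, marker_map(list(Z = "M")))
  expect_equal(unname(st$values[1, "Z"]), unname(st$values[2, "Z"]))
  expect_true(all(diff(st$values[order(as.numeric(adt_t$values[1, ])), "Z"]) >= 0))
})

test_that("binary score matrices pass mapped types through when unmapped", {
  adt <- make_counts(matrix(c(200, 2, 3, 1, 180, 170, 2, 210), 2, 4),
                     modality = "ADT", feature_ids = c("CD4", "CD8"),
                     cell_ids = paste0("c", 1:4))
  map <- marker_map(list(T = c("CD4", "CD8")))
  expect_warning(sc <- cite_binary_scores(adt, map, types = c("T", "Unmapped")),
                 "no mapped markers")
  expect_equal(unname(sc$values[, "Unmapped"]), rep(1, 4))
  expect_identical(sc$method, "cite_binary")
})
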