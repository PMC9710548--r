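mk_scores <- function(v, method = "camml", cells = sprintf("c%d", seq_len(nrow(v))),
                      types = sprintf("T%d", seq_len(ncol(v)))) {
  score_matrix(v, cell_ids = cells, type_names = types, method = method)
}

test_that("integration multiplies scores by bits and never raises a score", {
  camml <- mk_scores(matrix(c(0.8, 0.3, 0.5, 0.9), 2, 2))
  bits <- mk_scores(matrix(c(0, 1, 1, 1), 2, 2), method = "cite_binary")
  ch <- combine_scores(camml, bits)
  expect_identical(ch$method, "chimp")
  expect_equal(unname(ch$values[1, 1]), 0)    # bit 0 vetoes
  expect_equal(unname(ch$values[2, 1]), 0.3)  # bit 1 keeps the score
  expect_true(all(ch$values <= camml$values))
  # all-ones bits are the identity
  ones <- mk_scores(matrix(1, 2, 2), method = "cite_binary")
  expect_equal(combine_scores(camml, ones)$values, camml$values)
  # alignment is by identifier, not position
  bits_perm <- score_matrix(bits$values[2:1, 2:1, drop = FALSE],
                            method = "cite_binary")
  expect_equal(combine_scores(camml, bits_perm)$values, ch$values)
  bad <- mk_scores(matrix(1, 2, 2), method = "cite_binary",
                   cells = c("c1", "zz"))
  expect_error(combine_scores(camml, bad), "misaligned cell ids.*zz")
})

test_that("integration is conservative on fuzzed inputs, exactly", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    k <- sample(2:6, 1)
    camml <- mk_scores(matrix(runif(n * k), n, k))
    bits <- mk_scores(matrix(rbinom(n * k, 1, 0.5), n, k),
                      method = "cite_binary")
    ch <- combine_scores(camml, bits)
    expect_true(all(ch$values <= camml$values))
  }
})

test_that("single-label assignment takes the argmax with documented edge cases", {
  sc <- mk_scores(matrix(c(0.9, 0, 0.7, 0.1, 0, 0.7), 3, 2), types = c("T", "B"))
  lab <- suppressMessages(assign_single_label(sc))
  expect_identical(lab$label, c("T", "unassigned", "B"))
  expect_equal(lab$top_score, c(0.9, 0, 0.7))
  expect_true(lab$tied[3])   # 0.7/0.7 tie -> lexicographically first type
  expect_false(any(lab$tied[1:2]))
  # a secondary score matrix can break ties before the lexicographic rule
  tb <- mk_scores(matrix(c(0.2, 0.5, 0.1, 0.3, 0.5, 0.9), 3, 2),
                  types = c("T", "B"))
  lab2 <- suppressMessages(assign_single_label(sc, tiebreak_scores = tb))
  expect_identical(lab2$label[3], "B")
})

test_that("proportion comparison reproduces its closed-form examples", {
  labels <- rep(c("A", "B", "C", "D"), each = 25)
  ref <- c(A = 0.4, B = 0.3, C = 0.2, D = 0.1)
  cmp <- suppressWarnings(compare_proportions(labels, ref))
  # estimated (.25 x 4) vs (.4,.3,.2,.1) -> mse = 0.0125
  expect_equal(cmp$mse, 0.0125, tolerance = 1e-12)
  # identical proportions -> r = 1, mse = 0
  labels2 <- c(rep("A", 40), rep("B", 30), rep("C", 20), rep("D", 10))
  cmp2 <- compare_proportions(labels2, ref)
  expect_equal(cmp2$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cmp2$mse, 0, tolerance = 1e-12)
  expect_lt(cmp2$p_value, 0.05)
  # constant shift: r stays 1, mse = shift^2
  ref3 <- ref - 0.05
  cmp3 <- compare_proportions(labels2, ref3)
  expect_equal(cmp3$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cmp3$mse, 0.05^2, tolerance = 1e-12)
  # mse is symmetric in the two proportion vectors and order-invariant
  est <- c(A = 0.4, B = 0.3, C = 0.2, D = 0.1)
  cmp4 <- suppressWarnings(compare_proportions(labels, est[c(3, 1, 4, 2)]))
  expect_equal(cmp4$mse, cmp$mse, tolerance = 1e-12)
  expect_error(compare_proportions(c("A", "B"), c(A = 0.5, B = 0.5)),
               "3 shared types")
  # unassigned mass is excluded from the denominator
  cmp5 <- compare_proportions(c(labels2, rep("unassigned", 100)), ref)
  expect_equal(cmp5$mse, 0, tolerance = 1e-12)
})

test_that("the entropy index matches its closed forms and bounds", {
  # uniform over R = 5 -> ln 5
  sc <- mk_scores(matrix(0.6, 1, 5))
  expect_equal(unname(msdi(sc)$msdi), log(5), tolerance = 1e-12)
  # (1,0,0,0,0) with eps = 0.001, recomputed directly from the formula
  p <- (c(1, 0, 0, 0, 0) + 0.001) / sum(c(1, 0, 0, 0, 0) + 0.001)
  expected <- -sum(p * log(p))
  got <- unname(msdi(mk_scores(matrix(c(1, 0, 0, 0, 0), 1, 5)))$msdi)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got, 0.0315, tolerance = 1e-3)
  # R = 1 -> 0
  expect_equal(unname(msdi(mk_scores(matrix(0.4, 1, 1)))$msdi), 0,
               tolerance = 1e-12)
  # bounds on fuzzed inputs, equality at ln R iff all equal
  set.seed(47)
  for (i in 1:30) {
    R <- sample(2:8, 1)
    v <- matrix(runif(10 * R), 10, R)
    h <- msdi(mk_scores(v))$msdi
    expect_true(all(h >= 0 & h <= log(R) + 1e-12))
    expect_lt(max(h), log(R))
  }
  # a lone positive score: entropy strictly decreasing in its strength
  grid <- seq(0.1, 1, by = 0.1)
  hs <- vapply(grid, function(s) {
    unname(msdi(mk_scores(matrix(c(s, 0, 0, 0, 0), 1, 5)))$msdi)
  }, 0)
  expect_true(all(diff(hs) < 0))
})

test_that("one-vs-rest Wilcoxon marker detection keeps upregulated effects only", {
  # exhaustive rank-sum oracle for {1,2,3} vs {4,5,6}
  expect_equal(exact_ranksum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  x <- cbind(up_in_A = c(4, 5, 6, 1, 2, 3),
             flat = rep(2, 6),
             up_in_B = c(0, 0, 0, 3, 3.5, 4))
  rownames(x) <- paste0("c", 1:6)
  groups <- rep(c("A", "B"), each = 3)
  de <- discordance_de(x, groups, logfc_min = 0.01, scale = "score")
  expect_equal(de$p_value[de$group == "A" & de$feature == "up_in_A"], 0.1,
               tolerance = 1e-12)
  # flat feature excluded everywhere; each marker only in its own group
  expect_false("flat" %in% de$feature)
  expect_identical(de$feature[de$group == "A"], "up_in_A")
  expect_identical(de$feature[de$group == "B"], "up_in_B")
  # ranking is by effect size descending
  x2 <- cbind(big = c(10, 10, 10, 0, 0, 0), small = c(1, 1, 1, 0, 0, 0))
  rownames(x2) <- paste0("c", 1:6)
  de2 <- discordance_de(x2, groups, scale = "score")
  a <- de2[de2$group == "A", ]
  expect_identical(a$feature[a$rank], c("big", "small"))
  # counts scale uses a pseudocounted log2 ratio
  de3 <- discordance_de(x2, groups, scale = "counts")
  expect_equal(de3$logFC[de3$group == "A" & de3$feature == "big"],
               log2(11 / 1), tolerance = 1e-12)
  expect_error(discordance_de(x2, c("A", "A", "A", "A", "A", "B")), "< 2 cells")
  expect_error(discordance_de(x2, rep("A", 6)), "2 groups")
})
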