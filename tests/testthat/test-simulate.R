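test_that("configuration invariants are enforced", {
  cfg <- sim_config()
  expect_s3_class(cfg, "SimConfig")
  bad <- cfg
  bad$types$prop[1] <- bad$types$prop[1] + 0.01
  expect_error(validate_sim_config(bad), "sum to 1")
  bad2 <- cfg
  bad2$fold_change <- 1
  expect_error(validate_sim_config(bad2), "fold change")
  bad3 <- cfg
  bad3$positive_types$CD3 <- "Martian"
  expect_error(validate_sim_config(bad3), "Martian")
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- sim_config(n_cells = 150)
  a <- simulate_joint(cfg, seed = 7)
  b <- simulate_joint(cfg, seed = 7)
  expect_identical(as.matrix(a$rna$values), as.matrix(b$rna$values))
  expect_identical(as.matrix(a$adt$values), as.matrix(b$adt$values))
  expect_identical(a$truth$label, b$truth$label)
  c <- simulate_joint(cfg, seed = 8)
  expect_false(identical(as.matrix(a$rna$values), as.matrix(c$rna$values)))
  # the generator leaves the caller's RNG state untouched
  set.seed(1)
  before <- .Random.seed
  simulate_joint(cfg, seed = 3)
  expect_identical(.Random.seed, before)
})

test_that("intermediate cells carry exactly two distinct labels at the set rate", {
  cfg <- sim_config(n_cells = 1000, intermediate_frac = 0.1)
  sim <- simulate_joint(cfg, seed = 2)
  n2 <- sum(!is.na(sim$truth$label2))
  expect_equal(n2, 100)
  pairs <- !is.na(sim$truth$label2)
  expect_true(all(sim$truth$label[pairs] != sim$truth$label2[pairs]))
})

test_that("planted ADT bimodality is recovered by the two-cluster split", {
  cfg <- sim_config(n_cells = 2000, intermediate_frac = 0)
  sim <- simulate_joint(cfg, seed = 5)
  for (mk in c("CD3", "CD19", "CD14")) {
    truth_pos <- sim$truth$marker_positive[[mk]]
    sp <- two_means_split(as.numeric(sim$adt$values[mk, ]), mk)
    expect_lt(abs(sp$n_high - sum(truth_pos)) / cfg$n_cells, 0.02)
  }
})

test_that("a null configuration plants no recoverable signal", {
  cfg <- sim_config(n_cells = 400, intermediate_frac = 0)
  cfg$fold_change <- 1.0000001  # effectively no module signal
  sim <- simulate_joint(cfg, seed = 9)
  norm <- zscore_scale(lognormalize_rna(sim$rna))
  sets <- truth_weighted_sets(sim$truth)
  sc <- score_cell_types(norm, sets, n_perm = 50, seed = 1)
  # own-type cells score no better than others without planted fold change
  own <- sc$values[cbind(seq_along(sim$truth$label),
                         match(sim$truth$label, sc$type_names))]
  expect_lt(abs(mean(own) - mean(sc$values)), 0.1)
})

test_that("the pseudo-bulk reference carries the planted fold changes", {
  cfg <- sim_config()
  ref <- simulate_reference(cfg, samples_per_type = 4, seed = 3)
  expect_setequal(unique(ref$sample_labels), cfg$types$name)
  lfc <- one_vs_rest_logfc(ref, "Tcell")
  planted <- sprintf("MOD-Tcell-%02d", 1:25)
  # fold change 2^6 against 4 other types -> logFC near log2(64 * 5 / 9) ~ 5.15
  expect_gt(min(lfc[planted]), 5)
  # other types' modules are depleted (negative), background near zero
  expect_lt(max(lfc[setdiff(names(lfc), planted)]), 2)
  expect_error(simulate_reference(cfg, samples_per_type = 0), ">= 1")
})

test_that("YAML configs round-trip and the shipped default parses", {
  cfg <- sim_config(n_cells = 123)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n_cells, 123)
  expect_equal(back$types, cfg$types)
  expect_equal(back$marker_map, cfg$marker_map)
  expect_equal(back$positive_types[order(names(back$positive_types))],
               cfg$positive_types[order(names(cfg$positive_types))])
  shipped <- system.file("extdata", "default_sim.yaml", package = "chimpr")
  cfg2 <- read_sim_config(shipped)
  expect_equal(cfg2$n_cells, 5000)
  expect_equal(cfg2$qc$min_genes, 100)
  # identical generator output whether configured in code or from the file
  a <- simulate_joint(sim_config(n_cells = 200), seed = 4)
  cfg3 <- cfg2
  cfg3$n_cells <- 200
  b <- simulate_joint(validate_sim_config(cfg3), seed = 4)
  expect_identical(as.matrix(a$rna$values), as.matrix(b$rna$values))
})

test_that("protein integration removes cross-type false positives when the
           transcriptome is ambiguous", {
  # at a weak planted fold change the transcriptome-only labels err across
  # types; multiplying in the ADT bits recovers a large share of them
  cfg <- sim_config(n_cells = 1200, fold_change = 3)
  sim <- simulate_joint(cfg, seed = 1)
  rna <- filter_genes_min_cells(
    qc_filter_cells(sim$rna, min_genes = 100, max_mito_frac = 0.05)$counts, 5)
  adt <- count_matrix(sim$adt$values[, rna$cell_ids, drop = FALSE],
                      feature_ids = sim$adt$feature_ids,
                      cell_ids = rna$cell_ids, modality = "ADT")
  norm <- zscore_scale(lognormalize_rna(rna))
  sets <- truth_weighted_sets(sim$truth)
  camml <- suppressWarnings(score_cell_types(norm, sets, n_perm = 50, seed = 1))
  bits <- cite_binary_scores(adt, sim$truth$marker_map,
                             types = camml$type_names)
  chimp <- combine_scores(camml, bits)
  tr <- sim$truth
  k <- rna$cell_ids
  ok <- function(lab) lab == tr$label[k] |
    (!is.na(tr$label2[k]) & lab == tr$label2[k])
  acc_chimp <- mean(ok(suppressMessages(
    assign_single_label(chimp, tiebreak_scores = camml))$label))
  acc_camml <- mean(ok(suppressMessages(assign_single_label(camml))$label))
  expect_gt(acc_chimp, acc_camml)
})

test_that("the discordant configuration plants an RNA/protein conflict", {
  cfg <- sim_config_discordant(n_cells = 300)
  expect_equal(sum(cfg$types$prop), 1)
  sim <- simulate_joint(cfg, seed = 11)
  nkt <- names(sim$truth$label)[sim$truth$label == "NKT"]
  expect_gt(length(nkt), 10)
  # NKT cells are CD3/CD8 positive but CD56 negative
  expect_true(all(sim$truth$marker_positive$CD3[sim$truth$label == "NKT"]))
  expect_false(any(sim$truth$marker_positive$CD56[sim$truth$label == "NKT"]))
  # and their transcriptome module is the NK module
  expect_identical(sim$truth$modules$NKT, sim$truth$modules$NK)
})
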