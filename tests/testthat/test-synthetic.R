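test_that("simulated property tables are reproducible and satisfy table invariants", {
  t1 <- simulate_property_table(49, seed = 7)
  t2 <- simulate_property_table(49, seed = 7)
  expect_identical(t1, t2)
  expect_equal(unname(apply(t1$normalized, 1, min)), rep(0, 49))
  expect_equal(unname(apply(t1$normalized, 1, max)), rep(1, 49))
  single <- simulate_property_table(1, seed = 3)
  expect_length(single$property_ids, 1)
  expect_equal(delta_property(single, "prop01", "A", "A"), 0)
})

test_that("simulated mutant datasets carry exact ground truth at zero noise", {
  pt <- packaged_table()
  cfg <- simulation_config(seed = 2L, n_mutants = 30L, noise_sd = 0)
  ds <- simulate_mutation_dataset(pt, cfg)
  gt <- attr(ds, "ground_truth")
  fm <- build_feature_matrix(ds, pt, encodings = "delta",
                             property_ids = gt$true_subset)
  fit <- fit_multiple_regression(fm, ds$records$response)
  expect_equal(fit$R, 1.0, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), c(gt$beta0, gt$beta), tolerance = 1e-8)
  # bit-identical regeneration
  expect_identical(ds$records, simulate_mutation_dataset(pt, cfg)$records)
  # records respect the dataset invariants by construction
  expect_true(all(ds$records$wild != ds$records$mutant))
  chars <- strsplit(ds$sequence, "")[[1]]
  expect_identical(chars[ds$records$position], ds$records$wild)
})

test_that("the seq_window and structural signal encodings also close the loop", {
  pt <- packaged_table()
  for (enc in c("seq_window", "structural")) {
    cfg <- simulation_config(seed = 6L, n_mutants = 24L, noise_sd = 0,
                             encoding = enc)
    ds <- simulate_mutation_dataset(pt, cfg)
    gt <- attr(ds, "ground_truth")
    fm <- build_feature_matrix(ds, pt, encodings = enc,
                               property_ids = gt$true_subset, k = cfg$k)
    fit <- fit_multiple_regression(fm, ds$records$response)
    expect_equal(fit$R, 1.0, tolerance = 1e-10)
  }
})

test_that("helical traces give realistic 8 A neighborhoods", {
  st <- simulate_structure(10, "helix", seed = 1)
  expect_gte(length(neighbors_within_radius(st, 5, 8)), 4)
  lone <- simulate_structure(1, "helix", seed = 1)
  expect_identical(neighbors_within_radius(lone, 1, 8), integer(0))
  expect_identical(simulate_structure(10, "helix", seed = 4)$residues,
                   simulate_structure(10, "helix", seed = 4)$residues)
})

test_that("random packing respects the minimum C-alpha separation", {
  st <- simulate_structure(40, "random_packed", seed = 11)
  xyz <- as.matrix(st$residues[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  diag(d) <- Inf
  expect_gte(min(d), 3.8)
})

test_that("labelled sets honor the configured class counts and margin", {
  pt <- packaged_table()
  sim <- simulate_classification_dataset(
    pt, simulation_config(seed = 9L, class_margin = 0.5))
  tab <- table(sim$labeled$labels)
  expect_equal(unname(tab[["increase"]]), 15)
  expect_equal(unname(tab[["decrease"]]), 13)
  gt <- attr(sim$labeled, "ground_truth")
  dcol <- sim$labeled$features[, paste0(gt$separating_property, ":delta")]
  expect_true(all(dcol[sim$labeled$labels == "increase"] >= 0.5))
  expect_true(all(dcol[sim$labeled$labels == "decrease"] <= -0.5))
  expect_true(all(abs(sim$dataset$records$response) > 0))
  # custom counts
  sim2 <- simulate_classification_dataset(
    pt, simulation_config(seed = 9L, n_increase = 6L, n_decrease = 6L))
  expect_equal(length(sim2$labeled$labels), 12L)
})
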