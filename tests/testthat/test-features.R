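test_that("mutation-induced property change is antisymmetric and zero on identity", {
  pt <- packaged_table()
  expect_equal(delta_property(pt, "prop01", "A", "A"), 0)
  set.seed(42)
  for (i in 1:25) {
    pair <- sample(mutprop:::AA_CODES, 2)
    pid <- sample(pt$property_ids, 1)
    expect_equal(delta_property(pt, pid, pair[1], pair[2]),
                 -delta_property(pt, pid, pair[2], pair[1]))
  }
  tt <- toy_table(G = 0.1, V = 0.9)
  expect_equal(delta_property(tt, "toy", "G", "V"), 0.8)
  tt2 <- toy_table(A = 0.0, K = 1.0)
  expect_equal(delta_property(tt2, "toy", "A", "K"), 1.0)
  expect_equal(delta_property(tt2, "toy", "K", "A"), -1.0)
  expect_error(delta_property(pt, "prop01", "X", "A"), "unknown")
})

test_that("sequence-window effect matches hand-computed sums and truncates at termini", {
  tt <- toy_table(G = 0.1, A = 0.2, K = 0.3, V = 0.9)
  expect_equal(local_sequence_effect(tt, "toy", "GAK", 2, "V", k = 1),
               (0.1 + 0.2 + 0.3) - 0.9)
  expect_equal(local_sequence_effect(tt, "toy", "GAK", 1, "V", k = 1),
               (0.1 + 0.2) - 0.9)
  expect_error(local_sequence_effect(tt, "toy", "GAK", 4, "V", k = 1), "outside")
  expect_error(local_sequence_effect(tt, "toy", "GAK", 2, "V", k = -1),
               "non-negative")
})

test_that("window effect at k = 0 equals the negated property change everywhere", {
  pt <- packaged_table()
  set.seed(7)
  seq_str <- paste(sample(mutprop:::AA_CODES, 40, replace = TRUE), collapse = "")
  chars <- strsplit(seq_str, "")[[1]]
  for (pos in c(1, 2, 20, 39, 40)) {
    mut <- sample(setdiff(mutprop:::AA_CODES, chars[pos]), 1)
    expect_equal(local_sequence_effect(pt, "prop05", seq_str, pos, mut, k = 0),
                 -delta_property(pt, "prop05", chars[pos], mut))
  }
})

test_that("spatial neighborhoods follow the Euclidean threshold", {
  # three collinear residues 5 A apart
  sc <- structure_context(1:3, c("G", "G", "K"), x = c(0, 5, 10),
                          y = c(0, 0, 0), z = c(0, 0, 0))
  expect_identical(neighbors_within_radius(sc, 2, 8), c(1L, 3L))
  expect_identical(neighbors_within_radius(sc, 1, 8), 2L)
  expect_identical(neighbors_within_radius(sc, 1, 4), integer(0))
  single <- structure_context(1, "A", 0, 0, 0)
  expect_identical(neighbors_within_radius(single, 1, 8), integer(0))
  expect_error(neighbors_within_radius(sc, 99, 8), "absent")
})

test_that("neighborhoods are symmetric and grow monotonically with radius", {
  st <- simulate_structure(30, "random_packed", seed = 9)
  pos <- st$residues$position
  for (r in c(5, 8, 12)) {
    nb <- lapply(pos, function(p) neighbors_within_radius(st, p, r))
    names(nb) <- pos
    for (i in pos) {
      for (j in nb[[as.character(i)]]) {
        expect_true(i %in% nb[[as.character(j)]])
      }
    }
  }
  pt <- packaged_table()
  sums <- vapply(c(4, 6, 8, 10, 14),
                 function(r) surrounding_property_sum(pt, "prop01", st, pos[5], r),
                 numeric(1))
  expect_true(all(diff(sums) >= 0))
})

test_that("surrounding-residue sum matches the hand-counted toy structure", {
  tt <- toy_table(G = 0.1, K = 0.3, V = 0.9, A = 0.5)
  # center at origin with three neighbors (G, G, K) at 5 A
  sc <- structure_context(1:4, c("A", "G", "G", "K"),
                          x = c(0, 5, -5, 0), y = c(0, 0, 0, 5),
                          z = c(0, 0, 0, 0))
  expect_equal(surrounding_property_sum(tt, "toy", sc, 1, 8), 2 * 0.1 + 0.3)
  expect_equal(structural_effect(tt, "toy", sc, 1, "V", 8), 0.5 - 0.9)
  # isolated residue: Psur = 0, so Pstr = -Pmut
  single <- structure_context(1, "A", 0, 0, 0)
  expect_equal(surrounding_property_sum(tt, "toy", single, 1, 8), 0)
  expect_equal(structural_effect(tt, "toy", single, 1, "K", 8), -0.3)
  # identity substitution: Pstr = Psur - Pwild, not zero
  expect_equal(structural_effect(tt, "toy", sc, 1, "A", 8), 0.5 - 0.5)
  expect_equal(structural_effect(tt, "toy", single, 1, "A", 8), -0.5)
})

test_that("feature matrices have the contracted shape, order and determinism", {
  pt <- packaged_table()
  cfg <- simulation_config(seed = 21L, n_mutants = 12L, encoding = "structural")
  ds <- simulate_mutation_dataset(pt, cfg)

  fm <- build_feature_matrix(ds, pt, encodings = "delta")
  expect_identical(dim(fm), c(12L, 49L))

  fm2 <- build_feature_matrix(ds, pt, encodings = c("seq_window", "delta"),
                              property_ids = pt$property_ids[1:3], k = 2)
  expect_identical(dim(fm2), c(12L, 6L))
  # deterministic order: delta block first regardless of request order
  expect_identical(attr(fm2, "encoding"), rep(c("delta", "seq_window"), each = 3))
  expect_identical(attr(fm2, "property"), rep(pt$property_ids[1:3], 2))

  fm3 <- build_feature_matrix(ds, pt, encodings = c("delta", "structural"))
  expect_identical(dim(fm3), c(12L, 98L))
  expect_identical(fm3, build_feature_matrix(ds, pt,
                                             encodings = c("delta", "structural")))

  ds_noseq <- mutant_dataset(ds$records)
  expect_error(build_feature_matrix(ds_noseq, pt, encodings = "seq_window"),
               "no sequence")
  expect_error(build_feature_matrix(ds_noseq, pt, encodings = "structural"),
               "no structure")
  expect_error(build_feature_matrix(ds, pt, encodings = "delta",
                                    property_ids = "bogus"), "unknown property")
})
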