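test_that("the shape library has valid cut-outs with genuine ambiguity", {
  lib <- shape_library()
  expect_equal(length(lib$shapes), 5)
  expect_equal(lib$plus_id, 4)
  n_compat <- vapply(lib$cutouts, function(ct) length(ct$compatible), 1L)
  expect_true(all(n_compat >= 1))
  n_real <- vapply(lib$cutouts, function(ct) sum(ct$compatible != lib$plus_id),
                   1L)
  expect_true(any(n_real >= 2))
  # the lookup covers every (shape, window) pair
  expect_false(any(is.na(lib$lookup)))
  # a cut-out is always compatible with the shape that produced it
  for (s in seq_len(5)) {
    for (w in seq_along(lib$windows)) {
      ct <- lib$cutouts[[lib$lookup[s, w]]]
      expect_true((s - 1L) %in% ct$compatible)
    }
  }
})

test_that("the band-reading grammar encodes runs plus band succession", {
  Tm <- decoration_reading_grammar(build_vase(3))
  expect_equal(unname(colSums(Tm)), rep(1, 4))
  expect_equal(unname(diag(Tm)), rep(0.75, 4))  # 4 repetitions per band
  # band order top-to-bottom: oblique-up, horizontal, oblique-down, vertical
  expect_equal(Tm[1, 3], 0.25)  # from oblique-up to the line
  expect_equal(Tm[2, 1], 0.25)  # from the line to oblique-down
  expect_equal(Tm[4, 2], 0.25)  # from oblique-down to vertical
  expect_equal(Tm[3, 4], 0.25)  # wrap: vertical back to oblique-up
  # lower-complexity vases leave the missing motifs with uniform columns
  T1 <- decoration_reading_grammar(build_vase(1))
  expect_equal(unname(T1[, 3]), rep(0.25, 4))
})

test_that("cut-out series are deterministic per seed and cover all shapes", {
  lib <- shape_library()
  s1 <- generate_cutout_series(lib, 100, seed = 3)
  s2 <- generate_cutout_series(lib, 100, seed = 3)
  expect_identical(s1, s2)
  expect_false(identical(s1$true_shape,
                         generate_cutout_series(lib, 100, seed = 4)$true_shape))
  expect_setequal(unique(s1$true_shape), 0:3)     # every non-"+" shape appears
  expect_false(lib$plus_id %in% s1$true_shape)    # "+" is never a truth
  expect_equal(nrow(s1), 100)
  expect_error(generate_cutout_series(lib, 0), "length")
})

test_that("trial decisions follow the compatibility-masked posterior", {
  lib <- shape_library()
  cfg <- cpast_config()
  # ambiguous cue, prior concentrated on one compatible shape -> that shape
  ct <- list(cutout_id = 1L, compatible = c(1L, 2L))
  prev <- c(0.1, 0.6, 0.2, 0.05, 0.05)
  rec <- run_trial(ct, prev, diag(5), lib, epsilon = cfg$epsilon)
  expect_equal(rec$decision, 1)
  expect_equal(sum(rec$posterior), 1)
  # prior concentrated on the wrong compatible shape -> miss against truth 2
  expect_false(rec$decision == 2)
  # unambiguous cue wins regardless of a concentrated prior elsewhere
  ct1 <- list(cutout_id = 2L, compatible = 3L)
  prev2 <- c(0.5, 0.3, 0.1, 0.05, 0.05)
  rec2 <- run_trial(ct1, prev2, matrix(0.2, 5, 5), lib,
                    epsilon = cfg$epsilon)
  expect_equal(rec2$decision, 3)
  # the "+" aversion keeps it from being selected even when most probable
  ct_plus <- list(cutout_id = 3L, compatible = c(0L, 4L))
  prev3 <- c(0.05, 0.05, 0.05, 0.05, 0.8)
  rec3 <- run_trial(ct_plus, prev3, diag(5), lib, plus_penalty = -8,
                    epsilon = cfg$epsilon)
  expect_equal(rec3$decision, 0)
  expect_error(run_trial(ct, c(1, 1, 0, 0, 0), diag(5), lib), "normalised")
})

test_that("the categorisation run freezes the transferred matrix", {
  lib <- shape_library()
  cfg <- cpast_config()
  series <- generate_cutout_series(lib, 100, seed = 6)
  B2 <- run_episode(build_vase(3), cfg, seed = 2)$learned_B2
  snapshot <- B2 + 0
  res <- run_experiment2(B2, series, cfg, seed = 6)
  expect_identical(B2, snapshot)
  expect_equal(nrow(res$trials), 100)
  expect_true(res$hit_rate >= 0 && res$hit_rate <= 1)
  expect_equal(res$hit_rate, mean(res$trials$hit))
  expect_true(all(res$trials$hit == (res$trials$decision ==
                                       res$trials$true_shape)))
  # identical seeds reproduce the full hit sequence
  res2 <- run_experiment2(B2, series, cfg, seed = 6)
  expect_identical(res$trials, res2$trials)
  # wrong dimension is a configuration error
  expect_error(run_experiment2(matrix(1 / 6, 6, 6), series, cfg), "config error")
})

test_that("full-support transferred priors always resolve unambiguous cues", {
  lib <- shape_library()
  cfg <- cpast_config()
  series <- generate_cutout_series(lib, 100, seed = 8)
  unamb <- vapply(lib$cutouts[series$cutout_id], function(ct) {
    sum(ct$compatible != lib$plus_id) == 1
  }, logical(1))
  set.seed(40)
  for (i in 1:3) {
    B2 <- normalize_columns(matrix(stats::runif(16, 0.2, 2), 4, 4))
    res <- run_experiment2(B2, series, cfg, seed = i)
    expect_true(all(res$trials$hit[unamb]))
    expect_gte(res$hit_rate, mean(unamb))
  }
})

test_that("embedding pads unseen shapes with floor rows and marginal columns", {
  eps <- 1e-3
  B2 <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2)
  B5 <- cpast:::embed_b2_shapes(B2, 5, eps)
  expect_equal(unname(colSums(B5)), rep(1, 5), tolerance = 1e-12)
  # unseen rows carry only the floor
  expect_true(all(B5[3:5, 1:2] < 0.01))
  # unseen columns repeat the trained agent's marginal over seen shapes
  expect_equal(B5[, 3], B5[, 4])
  expect_gt(sum(B5[1:2, 3]), 0.98)
})
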