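test_that("configurations validate their fields with explicit errors", {
  expect_error(cpast_config(timesteps = 2), "timesteps")
  expect_error(cpast_config(dirichlet_seed = 0), "dirichlet_seed")
  expect_error(cpast_config(epsilon = 0.9), "epsilon")
  expect_error(cpast_config(w_risk = -1), "weights")
  expect_error(cpast_config(policy_temperature = -0.1), "policy_temperature")
  expect_error(cpast_config(b2_persistence = -1), "b2_persistence")
  cfg <- cpast_config()
  expect_s3_class(cfg, "cpast_config")
  expect_equal(cfg$n_rows * cfg$n_cols, 900)
})

test_that("YAML configs round-trip, override defaults and reject unknown keys", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.yaml")
  writeLines(c("timesteps: 48", "epsilon: 0.01"), path)
  cfg <- read_config(path)
  expect_equal(cfg$timesteps, 48L)
  expect_equal(cfg$epsilon, 0.01)
  expect_equal(cfg$n_rows, 30L)  # untouched default
  writeLines("not_a_key: 1", path)
  expect_error(read_config(path), "unknown keys")
  out <- file.path(dir, "resolved.yaml")
  write_config(cpast_config(trials = 7), out)
  expect_equal(read_config(out)$trials, 7L)
})

test_that("a foraging command writes its artifact set reproducibly", {
  cfg <- cpast_config(timesteps = 16)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- cmd_forage(cfg, complexity = 2, seed = 7, out_dir = d1)
  f2 <- cmd_forage(cfg, complexity = 2, seed = 7, out_dir = d2)
  expect_true(all(file.exists(f1)))
  # identical config + seed -> byte-identical text artifacts
  for (k in c("scanpath", "heatmap_csv", "b2_csv", "b2_json", "metrics")) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
  # transfer artifact reloads as the episode's learned matrix
  back <- read_b2_transfer(f1[["b2_csv"]])
  ep <- run_episode(build_vase(2), cfg, seed = 7)
  expect_equal(back$B2, unname(ep$learned_B2), tolerance = 1e-15)
  expect_equal(back$meta$config_hash, ep$config_hash)
})

test_that("a categorisation command consumes a transfer file end to end", {
  cfg <- cpast_config(timesteps = 16, trials = 40)
  dir <- withr::local_tempdir()
  files <- cmd_forage(cfg, complexity = 3, seed = 2, out_dir = dir)
  o1 <- cmd_categorise(files[["b2_csv"]], cfg, seed = 5, out_dir = dir)
  trials <- utils::read.csv(o1[["trials"]])
  expect_equal(nrow(trials), 40)
  summary <- jsonlite::read_json(o1[["summary"]])
  expect_true(summary$hit_rate >= 0 && summary$hit_rate <= 1)
  expect_equal(summary$hit_rate, mean(trials$hit))
  # rerun is byte-identical
  d2 <- withr::local_tempdir()
  o2 <- cmd_categorise(files[["b2_csv"]], cfg, seed = 5, out_dir = d2)
  expect_identical(readLines(o1[["trials"]]), readLines(o2[["trials"]]))
  expect_error(cmd_categorise(file.path(dir, "missing.csv"), cfg), "not found")
})

test_that("episode metrics summarise an episode consistently", {
  ep <- run_episode(build_vase(1), cpast_config(timesteps = 20), seed = 3)
  m <- episode_metrics(ep)
  expect_equal(m$bbox_area, m$h * m$w)
  expect_equal(m$cpast_entropy, cpast_entropy(ep$learned_B2)$entropy_total)
  expect_equal(m$complexity, 1)
})

test_that("the reproduce command refuses underpowered configurations", {
  expect_error(cmd_reproduce(cpast_config(), seeds = 1:5), "20 seeds")
})

test_that("the reproduce report can be regenerated from a saved sweep", {
  cfg <- cpast_config(timesteps = 12, trials = 20)
  sw <- run_sweep(0:1, 1:2, cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  # bypass the seed guard only through the precomputed-sweep path: the guard
  # protects fresh simulation, regeneration is deterministic reporting
  r1 <- cmd_reproduce(cfg, seeds = 1:20, series_seeds = 1:2, out_dir = d1,
                      sweep = sw)
  r2 <- cmd_reproduce(cfg, seeds = 1:20, series_seeds = 1:2, out_dir = d2,
                      sweep = sw)
  expect_identical(r1$summary, r2$summary)
  expect_identical(readLines(file.path(d1, "reproduce_summary.csv")),
                   readLines(file.path(d2, "reproduce_summary.csv")))
  expect_named(r1$verdicts,
               c("vi_increases", "entropy_increases", "hit_rate_increases"))
})
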