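test_that("scenes and measurements are pure functions of (config, seed)", {
  cfg <- tiny_scene_config(seed = 17)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$stations, s2$stations)
  expect_identical(s1$covariates, s2$covariates)
  expect_identical(lapply(s1$layers, function(l) l$geometry),
                   lapply(s2$layers, function(l) l$geometry))

  m1 <- generate_measurements(s1)
  m2 <- generate_measurements(s2)
  expect_identical(m1$response, m2$response)
  expect_identical(as.data.frame(m1$design), as.data.frame(m2$design))

  # serialized scenes are byte-identical
  d1 <- file.path(tempdir(), "scene_a"); d2 <- file.path(tempdir(), "scene_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_scene(s1, d1); write_scene(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 10)
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("a serialized scene reloads with identical stations and geometry", {
  cfg <- tiny_scene_config(seed = 18)
  scene <- generate_scene(cfg)
  dir <- file.path(tempdir(), "scene_rt")
  unlink(dir, recursive = TRUE)
  write_scene(scene, dir)
  back <- read_scene(dir)
  expect_equal(back$stations$station_id, scene$stations$station_id)
  expect_equal(back$stations$x, scene$stations$x, tolerance = 1e-12)
  expect_equal(back$stations$altitude, scene$stations$altitude,
               tolerance = 1e-12)
  expect_equal(sort(names(back$layers)), sort(names(scene$layers)))
  expect_equal(back$layers$temple$geometry, scene$layers$temple$geometry,
               tolerance = 1e-12)
  expect_equal(back$layers$forest$geometry[[1]],
               scene$layers$forest$geometry[[1]], tolerance = 1e-12)
  expect_equal(back$layers$ndvi$geometry$values,
               scene$layers$ndvi$geometry$values, tolerance = 1e-12)
  expect_equal(back$layers$road$sign_prior, "negative")

  # reloaded scenes generate identical measurements
  m1 <- generate_measurements(scene)
  m2 <- generate_measurements(back)
  expect_equal(m2$response, m1$response, tolerance = 1e-9)
})

test_that("Poisson layer counts concentrate at intensity x area", {
  lambda_km2 <- 0.31
  area_km2 <- 400  # tiny scene region 20 x 20 km
  expected <- lambda_km2 * area_km2
  counts <- vapply(1:6, function(s) {
    nrow(generate_scene(tiny_scene_config(seed = 40 + s))$layers$temple$geometry)
  }, numeric(1))
  expect_true(all(abs(counts - expected) <= 4 * sqrt(expected)))
  # and not all identical (they are random draws)
  expect_gt(length(unique(counts)), 1)
})

test_that("zero point-process intensities give empty, constant-flagged columns", {
  cfg <- tiny_scene_config(seed = 19)
  cfg$intensities$temple_per_km2 <- 0
  cfg$intensities$cemetery_per_km2 <- 0
  cfg$true_model <- data.frame(column = c("nox", "forest@500"),
                               share = c(0.7, 0.3), stringsAsFactors = FALSE)
  scene <- generate_scene(cfg)
  expect_equal(nrow(scene$layers$temple$geometry), 0)
  meas <- generate_measurements(scene)
  ci <- column_info(meas$design)
  temple_cols <- ci$column[!is.na(ci$layer) & ci$layer == "temple"]
  expect_true(all(ci$constant[ci$column %in% temple_cols]))
  expect_true(all(as.data.frame(meas$design)[, temple_cols] == 0))
})

test_that("a missing true-model column is reported by name", {
  cfg <- tiny_scene_config(seed = 20)
  cfg$true_model <- data.frame(column = c("nox", "nosuch@500"),
                               share = c(0.5, 0.5), stringsAsFactors = FALSE)
  scene <- generate_scene(cfg)
  expect_error(generate_measurements(scene), "nosuch@500")
})

test_that("noiseless measurements recover the planted coefficients exactly", {
  cfg <- tiny_scene_config(seed = 21, noise_sd = 0)
  meas <- generate_measurements(generate_scene(cfg))
  truth <- meas$truth$coefficients
  X <- as.data.frame(meas$design)[, truth$column]
  f <- fit_ols(X, meas$response)
  expect_equal(unname(f$coefficients[truth$column]), truth$coefficient,
               tolerance = 1e-8)
  expect_equal(f$intercept, meas$truth$intercept, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-10)
})

test_that("noise calibration hits the target population R2", {
  r2s <- vapply(1:8, function(s) {
    meas <- generate_measurements(generate_scene(tiny_scene_config(seed = 50 + s)))
    truth <- meas$truth$coefficients
    fit_ols(as.data.frame(meas$design)[, truth$column], meas$response)$r2
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.75), 0.05)

  # closed-form response to inflating the noise: R2 = 1 / (1 + sigma2/var(signal))
  pairs <- vapply(1:6, function(s) {
    cfg <- tiny_scene_config(seed = 200 + s)
    meas <- generate_measurements(generate_scene(cfg))
    sig_var <- meas$truth$signal_var
    cfg2 <- tiny_scene_config(seed = 200 + s,
                              noise_sd = 2 * meas$truth$noise_sd)
    meas2 <- generate_measurements(generate_scene(cfg2))
    truth2 <- meas2$truth$coefficients
    r2_2 <- fit_ols(as.data.frame(meas2$design)[, truth2$column],
                    meas2$response)$r2
    r2_2 - 1 / (1 + (2 * meas$truth$noise_sd)^2 / sig_var)
  }, numeric(1))
  expect_lt(abs(mean(pairs)), 0.08)
})

test_that("the response mean matches intercept plus mean signal", {
  meas <- generate_measurements(generate_scene(tiny_scene_config(seed = 23)))
  truth <- meas$truth$coefficients
  X <- as.matrix(as.data.frame(meas$design)[, truth$column])
  signal_mean <- mean(X %*% truth$coefficient)
  se <- meas$truth$noise_sd / sqrt(length(meas$response))
  expect_lt(abs(mean(meas$response) - (meas$truth$intercept + signal_mean)),
            3 * se + 1e-9)
})

test_that("recovery experiments are deterministic and degrade with noise", {
  cfg <- tiny_scene_config(seed = 60)
  r1 <- recovery_experiment(cfg, 2, run_cv = FALSE)
  r2 <- recovery_experiment(cfg, 2, run_cv = FALSE)
  expect_identical(r1$per_replicate, r2$per_replicate)
  expect_equal(r1$recovery_rate, r2$recovery_rate)
  expect_true(all(!r1$per_replicate$failed))
  expect_true(all(r1$per_replicate$tp + r1$per_replicate$fp ==
                    vapply(strsplit(r1$per_replicate$selected, ";"), length,
                           numeric(1))))

  # recovery is non-increasing along a 3-point noise ladder
  rates <- vapply(c(0.5, 4, 12), function(nsd) {
    cfg_n <- tiny_scene_config(seed = 70, noise_sd = nsd)
    recovery_experiment(cfg_n, 20, run_cv = FALSE)$recovery_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_gt(rates[1], rates[3])  # the ladder spans a real degradation
})

test_that("every selected model in an experiment satisfies the hard gates", {
  cfg <- tiny_scene_config(seed = 80)
  for (i in 1:3) {
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + i
    meas <- generate_measurements(generate_scene(cfg_i))
    m <- forward_select(meas$design, meas$response)
    expect_gt(nrow(m$terms), 0)
    constrained <- m$terms$sign_prior != "unconstrained"
    expect_true(all(sign(m$terms$coefficient[constrained]) ==
                      ifelse(m$terms$sign_prior[constrained] == "positive",
                             1, -1)))
    if (nrow(m$terms) >= 2) {
      X <- as.data.frame(meas$design)[, m$terms$column]
      expect_true(all(vif(X) < 3))
    }
    expect_equal(sum(m$terms$incremental_r2), m$r2, tolerance = 1e-9)
  }
})
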