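test_that("depth profiles are linear from surface to deep", {
  spec <- tiny_spec(depth_profiles = list(
    T1 = c(surface = 1200, deep = 900), T1rho = c(surface = 60, deep = 40),
    T2 = c(surface = 50, deep = 50), T2star = c(surface = 35, deep = 20)))
  truth <- build_truth(spec, seed = 3)
  # constant profile: every in-mask T2 pixel equals 50
  expect_true(all(truth$params$T2[truth$mask] == 50))
  # linear profile: midpoint of an odd-height column is the midrange value
  j <- truth$piston_center_col
  h <- truth$heights_px[j]
  col <- truth$params$T2star[seq_len(h), j]
  expect_equal(col[1], 35)
  expect_equal(col[h], 20)
  if (h %% 2 == 1) expect_equal(col[(h + 1) / 2], 27.5)
  expect_equal(diff(col), rep(diff(col)[1], h - 1)) # constant slope
})

test_that("truth heights follow the configured normal distribution", {
  spec <- tiny_spec("control") # 2.77 +/- 0.19 mm
  h <- vapply(1:400, function(s) build_truth(spec, seed = s)$height_true_mm,
              numeric(1))
  se <- 0.19 / sqrt(length(h))
  expect_lt(abs(mean(h) - 2.77), 3 * se)
  # mask column heights agree with the floored truth height
  truth <- build_truth(spec, seed = 7)
  ch <- colSums(truth$mask) * spec$pixel_spacing
  nonzero <- ch[ch > 0]
  expect_true(all(abs(nonzero - truth$height_true_mm) <= spec$pixel_spacing))
})

test_that("loading compresses columns by the configured strain, floored", {
  lm <- default_load_model("control", strain_spa = c(0.10, 0.15),
                           strain_ppa = c(0.02, 0.04))
  spec <- phantom_spec("control", grid_rows = 28, grid_cols = 64,
                       height_mean = 20 * 0.232 + 0.01, height_sd = 0,
                       load_model = lm)
  truth <- build_truth(spec, seed = 1)
  j <- truth$piston_center_col
  expect_equal(truth$heights_px[j], 20L)
  # identity at delta0
  expect_identical(apply_load(truth, "delta0", spec), truth)
  # 10% sub-pistonal strain on a 20-pixel column leaves 18 pixels
  l1 <- apply_load(truth, "delta1", spec)
  expect_equal(l1$heights_px[j], 18L)
  # mask area strictly decreases with load level
  l2 <- apply_load(truth, "delta2", spec)
  expect_lt(sum(l2$mask), sum(l1$mask))
  expect_lt(sum(l1$mask), sum(truth$mask))
  # per-column heights are non-increasing in load level
  expect_true(all(l1$heights_px <= truth$heights_px))
  expect_true(all(l2$heights_px <= l1$heights_px))
})

test_that("exposure applies the leaf multipliers exactly on the truth", {
  spec <- tiny_spec("HT")
  truth <- build_truth(spec, seed = 5)
  post <- apply_exposure(truth, spec)
  lab <- qmricart:::leaf_labels(truth$mask, truth$piston_center_col,
                                qmricart:::spa_cols_n(spec))
  leaves <- c("SPA_upper", "SPA_lower", "PPA_upper", "PPA_lower")
  for (p in c("T1", "T1rho", "T2", "T2star")) {
    for (k in 1:4) {
      idx <- lab == k
      m <- spec$exposure_multipliers[[p]][[leaves[k]]]
      expect_equal(post$params[[p]][idx] / truth$params[[p]][idx],
                   rep(m, sum(idx)), tolerance = 1e-12)
    }
  }
  # HT default scales sub-pistonal upper-half T1 by 1.040
  expect_equal(spec$exposure_multipliers$T1[["SPA_upper"]], 1.040)
  # unit multipliers give the identity
  spec1 <- tiny_spec("HT", exposure_multipliers = qmricart:::unit_multipliers())
  t1 <- build_truth(spec1, seed = 5)
  expect_equal(apply_exposure(t1, spec1)$params, t1$params)
})

test_that("synthesis matches the forward model and the Rician noise law", {
  spec <- tiny_spec("control", noise_sigma = 0)
  truth <- build_truth(spec, seed = 2)
  pr <- qmri_protocol("T2_SE")
  ser <- synthesize_series(truth, pr, noise_sigma = 0, seed = 1)
  px <- which(truth$mask, arr.ind = TRUE)[10, ]
  expect_equal(ser$stack[px[1], px[2], ],
               forward_signal("T2_SE",
                              c(s0 = spec$s0,
                                tau = truth$params$T2[px[1], px[2]]),
                              pr$times))
  # zero-signal background has Rayleigh mean sigma * sqrt(pi/2)
  noisy <- synthesize_series(truth, pr, noise_sigma = 10, seed = 4)
  bg <- noisy$stack[rep(!truth$mask, length(pr$times))]
  expect_equal(mean(bg), 10 * sqrt(pi / 2), tolerance = 0.02)
  # determinism: same seed gives bit-identical stacks
  again <- synthesize_series(truth, pr, noise_sigma = 10, seed = 4)
  expect_identical(noisy$stack, again$stack)
  expect_error(synthesize_series(truth, pr, noise_sigma = -1, seed = 1),
               class = "qc_validation_error")
})

test_that("study generation follows the serial design and is deterministic", {
  study <- generate_study(arms = c(control = 1), seed = 9,
                          spec_args = list(grid_rows = 24, grid_cols = 64,
                                           noise_sigma = 5))
  smp <- study$samples$control_01
  n_series <- sum(vapply(smp$series, function(ses)
    sum(lengths(ses)), integer(1)))
  expect_equal(n_series, 2 * 3 * 4) # sessions x loads x modalities
  again <- generate_study(arms = c(control = 1), seed = 9,
                          spec_args = list(grid_rows = 24, grid_cols = 64,
                                           noise_sigma = 5))
  expect_identical(smp$series$pre$delta1$T2_SE$stack,
                   again$samples$control_01$series$pre$delta1$T2_SE$stack)
  expect_equal(nrow(study$manifest), 1)
})

test_that("invalid phantom configurations are rejected with the field name", {
  expect_error(phantom_spec("control", grid_rows = 8), "grid_rows",
               class = "qc_config_error")
  expect_error(phantom_spec("control", noise_sigma = -1), "noise_sigma",
               class = "qc_config_error")
  expect_error(phantom_spec("control", height_mean = 0.4), "height_mean",
               class = "qc_config_error")
  lm <- default_load_model("control")
  lm$delta1$strain_spa <- 1.2
  expect_error(phantom_spec("control", load_model = lm), "strain",
               class = "qc_config_error")
  lm0 <- default_load_model("control")
  lm0$delta0 <- list(strain_spa = 0.1, strain_ppa = 0)
  expect_error(phantom_spec("control", load_model = lm0), "delta0",
               class = "qc_config_error")
})
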