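test_that("forward models evaluate their closed forms", {
  expect_equal(forward_signal("T2_SE", c(s0 = 100, tau = 50), 0), 100)
  expect_equal(forward_signal("T2_SE", c(s0 = 100, tau = 50), 50),
               100 * exp(-1))
  # inversion-recovery null point at TI = T1 * ln(b)
  expect_equal(forward_signal("T1_IR", c(s0 = 100, tau = 800, b = 2),
                              800 * log(2)), 0)
  expect_error(forward_signal("T2_SE", c(s0 = 100, tau = -5), 10),
               class = "qc_validation_error")
})

test_that("echo selection keeps echoes below the cutoff for T2/T2* only", {
  expect_length(select_times(qmri_protocol("T2_SE")$times, "T2_SE", 60), 7)
  expect_length(select_times(qmri_protocol("T2star_GRE")$times, "T2star_GRE", 60), 11)
  expect_length(select_times(qmri_protocol("T1_IR")$times, "T1_IR", 60), 6)
  expect_length(select_times(qmri_protocol("T1rho_SL")$times, "T1rho_SL", 60), 5)
  expect_error(select_times(qmri_protocol("T2_SE")$times, "T2_SE", 20),
               class = "qc_degenerate_error")
})

test_that("adjusted R2 penalises the degrees of freedom", {
  y <- c(1, 2, 3, 4, 5, 6, 7)
  expect_equal(adjusted_r2(y, y, 2), 1)
  expect_equal(adjusted_r2(y, rep(mean(y), 7), 2), 1 - 1 * 6 / 4)
  # hand-computed: SStot = 26, SSres = 2, n = 3, p = 1
  expect_equal(adjusted_r2(c(10, 5, 3), c(9, 6, 3), 1),
               1 - (2 / 26) * 2 / 1)
  expect_error(adjusted_r2(rep(1, 5), rep(1, 5), 2),
               class = "qc_degenerate_error")
})

test_that("noiseless fits recover the generating parameters", {
  for (mod in qmri_modalities()) {
    pr <- qmri_protocol(mod)
    truth <- switch(mod,
      T1_IR = list(s0 = 100, tau = 900, b = 1.9),
      T1rho_SL = list(s0 = 120, tau = 45),
      T2_SE = list(s0 = 100, tau = 40),
      T2star_GRE = list(s0 = 80, tau = 25))
    sel <- select_times(pr$times, mod, 60)
    sig <- forward_signal(mod, truth, pr$times[sel])
    fit <- fit_pixel(mod, pr$times[sel], sig)
    expect_true(fit$converged)
    expect_equal(unname(fit$params["tau"]), truth$tau,
                 tolerance = 1e-4, label = paste(mod, "tau"))
    expect_equal(unname(fit$params["s0"]), truth$s0,
                 tolerance = 1e-4, label = paste(mod, "s0"))
    if (mod == "T1_IR") {
      expect_equal(unname(fit$params["b"]), truth$b, tolerance = 1e-4)
    }
    expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  }
})

test_that("nonlinear fit agrees with the exhaustive grid-search oracle", {
  pr <- qmri_protocol("T2_SE")
  sel <- select_times(pr$times, "T2_SE", 60)
  times <- pr$times[sel]
  set.seed(42)
  rel <- numeric(100)
  for (i in 1:100) {
    clean <- forward_signal("T2_SE", c(s0 = 100, tau = 40), times)
    y <- sqrt((clean + 2 * rnorm(length(times)))^2 +
                (2 * rnorm(length(times)))^2)
    fit <- fit_pixel("T2_SE", times, y)
    oracle <- grid_search_decay(times, y, c(20, 80), c(80, 120))
    rel[i] <- abs(fit$params[["tau"]] - oracle$tau) / oracle$tau
  }
  expect_lt(median(rel), 0.01)
})

test_that("fit matches an independent Levenberg-Marquardt implementation", {
  skip_if_not_installed("minpack.lm")
  pr <- qmri_protocol("T1rho_SL")
  set.seed(7)
  for (i in 1:5) {
    clean <- forward_signal("T1rho_SL", c(s0 = 100, tau = 50), pr$times)
    y <- clean + rnorm(length(pr$times), sd = 1.5)
    y <- pmax(y, 0)
    fit <- fit_pixel("T1rho_SL", pr$times, y)
    ref <- minpack.lm::nlsLM(y ~ s0 * exp(-t / tau),
                             data = list(y = y, t = pr$times),
                             start = list(s0 = max(y), tau = 30),
                             lower = c(1e-8, 1), upper = c(1e4, 500))
    expect_equal(unname(fit$params["tau"]), coef(ref)[["tau"]],
                 tolerance = 1e-4)
  }
})

test_that("map fitting applies the quality gate as specified", {
  spec <- tiny_spec("control", noise_sigma = 0)
  truth <- build_truth(spec, seed = 2)
  ser <- synthesize_series(truth, qmri_protocol("T2_SE"), 0, seed = 1)
  map <- fit_map(ser, truth$mask)
  expect_true(all(map$valid[truth$mask])) # noiseless: all valid
  expect_true(all(is.na(map$value[!truth$mask])))
  tt <- truth$params$T2[truth$mask]
  expect_lt(max(abs(map$value[truth$mask] - tt) / tt), 1e-4)

  # pure-noise pixels are overwhelmingly rejected at threshold 0.95
  set.seed(11)
  nt <- 7
  noise <- array(sqrt(rnorm(40 * 25 * nt)^2 + rnorm(40 * 25 * nt)^2),
                 dim = c(40, 25, nt))
  nser <- acq_series(noise, qmri_protocol("T2_SE")$times[1:nt], "T2_SE", 0.232,
                     list())
  nmap <- fit_map(nser, matrix(TRUE, 40, 25))
  expect_gt(mean(!nmap$valid), 0.95)
  expect_lte(sum(nmap$valid), 40 * 25) # valid pixels are a subset of the mask

  # raising the threshold never increases the valid count
  spec2 <- tiny_spec("control")
  truth2 <- build_truth(spec2, seed = 3)
  ser2 <- synthesize_series(truth2, qmri_protocol("T2_SE"),
                            spec2$noise_sigma, seed = 5)
  counts <- vapply(c(0.5, 0.8, 0.95, 0.99), function(th) {
    sum(fit_map(ser2, truth2$mask,
                fit_options("T2_SE", r2_threshold = th))$valid)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(fit_map(ser2, matrix(FALSE, 24, 64)),
               class = "qc_validation_error")
})

test_that("fitted T2 is nearly unbiased at the default noise level", {
  spec <- tiny_spec("control")
  truth <- build_truth(spec, seed = 4)
  ser <- synthesize_series(truth, qmri_protocol("T2_SE"),
                           spec$noise_sigma, seed = 6)
  map <- fit_map(ser, truth$mask)
  sel <- map$valid & truth$mask
  expect_gt(sum(sel), 500)
  rel_bias <- (map$value[sel] - truth$params$T2[sel]) / truth$params$T2[sel]
  expect_lt(abs(median(rel_bias)), 0.02)
})

test_that("degenerate pixels are flagged, not fitted", {
  pr <- qmri_protocol("T2_SE")
  f <- fit_pixel("T2_SE", pr$times[1:5], rep(3, 5))
  expect_true(f$degenerate)
  expect_false(f$converged)
})
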