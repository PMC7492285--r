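# Shared fixtures and independent oracles, built in code at test time.

# Small, fast phantom spec: full sample width but a compact grid.
tiny_spec <- function(arm = "control", ...) {
  phantom_spec(arm, grid_rows = 24, grid_cols = 64, ...)
}

# Exhaustive signed-rank oracle: enumerate all 2^n sign patterns of the
# non-zero differences and count patterns at least as extreme (two-sided,
# symmetric statistic V around its null mean n(n+1)/4).
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 15)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  mean(abs(v_all - mu) >= abs(v_obs - mu))
}

# Brute-force 2-D grid-search oracle for a mono-exponential decay fit.
grid_search_decay <- function(times, y, tau_range, s0_range,
                              tau_step = 0.1, s0_step = 0.1) {
  taus <- seq(tau_range[1], tau_range[2], by = tau_step)
  s0s <- seq(s0_range[1], s0_range[2], by = s0_step)
  E <- exp(-outer(1 / taus, times))       # n_tau x n_t
  yy <- sum(y * y)
  ye <- as.vector(E %*% y)                # n_tau
  ee <- rowSums(E * E)
  # SSR(tau, s0) = yy - 2 s0 ye + s0^2 ee, minimised over the full grid
  ssr <- outer(ye, s0s, function(a, s) -2 * s * a) +
    outer(ee, s0s, function(e, s) s^2 * e) + yy
  idx <- arrayInd(which.min(ssr), dim(ssr))
  list(tau = taus[idx[1]], s0 = s0s[idx[2]], ssr = min(ssr))
}

# Random segmentation masks with enough non-empty columns to satisfy the
# piston-geometry invariants; per-column pixel sets may be non-contiguous.
random_mask <- function(seed, nr = 30, nc = 120, spacing = 0.232) {
  set.seed(seed)
  m <- matrix(FALSE, nr, nc)
  filled <- 20:105
  for (j in filled) {
    h <- sample(1:nr, 1)
    rows <- sort(sample(seq_len(nr), h))
    m[rows, j] <- TRUE
  }
  seg_mask(m, spacing, piston_center_col = 62)
}

# Constant-value parameter map over a mask (for aggregation oracles).
uniform_map <- function(mask, value = 50) {
  v <- matrix(NA_real_, nrow(mask), ncol(mask))
  v[mask] <- value
  structure(list(value = v, s0 = v, b = v, adj_r2 = v, valid = mask,
                 mask = mask, modality = "T2_SE",
                 options = fit_options("T2_SE"), meta = list()),
            class = "parameter_map")
}
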