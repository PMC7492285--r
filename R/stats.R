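# The paired statistical battery: Wilcoxon matched pairs for exposure
# effects at rest, paired t for pre- vs post-exposure loading responses,
# Friedman + Dunn for absolute values across load levels, repeated-measures
# ANOVA for heights and pixel counts, and step-down Holm correction.

qmri_test <- function(method, statistic, p_value, n, degenerate = FALSE,
                      details = list()) {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, degenerate = degenerate,
                 details = details),
            class = "qmri_test")
}

#' @export
print.qmri_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %s, n = %d%s\n", x$method,
              format(x$statistic), format(x$p_value), x$n,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test on paired observations. Zero differences are
#' dropped; the exact distribution is used for up to `exact_max_n` non-zero
#' untied differences, otherwise the normal approximation with tie
#' correction (no continuity correction). All-zero differences yield a
#' degenerate result with p = 1.
#'
#' @param pre,post paired numeric vectors of equal length.
#' @param exact_max_n largest n for which the exact null distribution is
#'   enumerated.
#' @return A `qmri_test` (statistic is the signed-rank sum V).
#' @export
wilcoxon_matched <- function(pre, post, exact_max_n = 25L) {
  if (length(pre) != length(post)) qc_validation_error("pre/post length mismatch")
  d <- post - pre
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) {
    return(qmri_test("Wilcoxon matched pairs", NA_real_, 1, 0, degenerate = TRUE))
  }
  exact <- n <= exact_max_n && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    wilcox.test(nz, mu = 0, alternative = "two.sided", exact = exact,
                correct = FALSE)
  )
  qmri_test("Wilcoxon matched pairs", ht$statistic, ht$p.value, n,
            details = list(exact = exact))
}

#' Paired Student's t test
#'
#' Two-sided paired t test on `post - pre`; zero-variance differences are
#' flagged degenerate (p = NA).
#'
#' @param pre,post paired numeric vectors of equal length (n >= 2).
#' @return A `qmri_test`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) qc_validation_error("pre/post length mismatch")
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 2L) qc_validation_error("paired t needs at least 2 complete pairs")
  if (sd(post - pre) == 0) {
    return(qmri_test("Paired t", NA_real_, NA_real_, n, degenerate = TRUE))
  }
  ht <- t.test(post, pre, paired = TRUE)
  qmri_test("Paired t", ht$statistic, ht$p.value, n)
}

#' Friedman test with Dunn's post-hoc comparisons
#'
#' Friedman chi-square over within-sample ranks (mid-ranks for ties) of the
#' values at the three load levels, followed by Dunn's pairwise z tests on
#' mean ranks with Bonferroni scaling over the three load pairs. Incomplete
#' rows are dropped and reported.
#'
#' @param x numeric matrix or data frame, one row per sample, one column per
#'   load level (3 columns).
#' @return List with `overall` (a `qmri_test`) and `pairwise` (tibble with
#'   `comparison`, `z`, `p_raw`, `p_adj`), plus `n_dropped`.
#' @export
friedman_dunn <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) qc_validation_error("expected one column per load level (3)")
  cc <- complete.cases(x)
  n_dropped <- sum(!cc)
  x <- x[cc, , drop = FALSE]
  n <- nrow(x)
  if (n < 3L) qc_validation_error("need at least 3 complete load triples")
  k <- 3
  ranks <- t(apply(x, 1, rank))
  rbar <- colMeans(ranks)
  if (all(apply(ranks, 1, function(r) all(r == r[1])))) {
    # every sample fully tied across loads: no evidence of a load effect
    ht <- list(statistic = 0, p.value = 1)
  } else {
    ht <- friedman.test(x)
  }
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  cn <- colnames(x) %||% paste0("load", seq_len(k))
  pw <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    z <- (rbar[a] - rbar[b]) / se
    p_raw <- 2 * pnorm(-abs(z))
    tibble::tibble(comparison = paste(cn[a], "vs", cn[b]), z = unname(z),
                   p_raw = p_raw, p_adj = min(1, ncol(pairs) * p_raw))
  })
  list(overall = qmri_test("Friedman", ht$statistic, ht$p.value, n),
       pairwise = dplyr::bind_rows(pw), n_dropped = n_dropped)
}

#' One-way repeated-measures ANOVA
#'
#' F test for a within-subject factor (load level) with subject blocking and
#' no sphericity correction; used for sample heights and ROI pixel counts
#' across load levels. Constant data are flagged degenerate.
#'
#' @param x numeric matrix or data frame, one row per subject, one column
#'   per condition (>= 2 columns, >= 3 complete rows).
#' @return A `qmri_test` (statistic is the F value; degrees of freedom in
#'   `details`).
#' @export
rm_anova <- function(x) {
  x <- as.matrix(x)
  cc <- complete.cases(x)
  x <- x[cc, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) qc_validation_error("need at least 3 complete cases")
  if (k < 2L) qc_validation_error("need at least 2 conditions")
  if (var(as.vector(x)) == 0) {
    return(qmri_test("RM-ANOVA", NA_real_, NA_real_, n, degenerate = TRUE))
  }
  df <- data.frame(y = as.vector(x),
                   subject = factor(rep(seq_len(n), times = k)),
                   cond = factor(rep(seq_len(k), each = n)))
  fit <- aov(y ~ cond + Error(subject/cond), data = df)
  tab <- summary(fit)[["Error: subject:cond"]][[1]]
  Fv <- tab["cond", "F value"]
  pv <- tab["cond", "Pr(>F)"]
  if (!is.finite(Fv)) {
    return(qmri_test("RM-ANOVA", NA_real_, NA_real_, n, degenerate = TRUE))
  }
  qmri_test("RM-ANOVA", Fv, pv, n,
            details = list(df1 = tab["cond", "Df"], df2 = tab["Residuals", "Df"]))
}

#' Step-down Holm adjustment with rejection flags
#'
#' Bonferroni-Holm family-wise error control: p values are sorted
#' ascending, the i-th smallest is multiplied by (m - i + 1), running maxima
#' are taken and capped at 1; hypotheses are rejected while the adjusted p
#' stays at or below `alpha`.
#'
#' @param p numeric vector of p values in `[0, 1]` (NA allowed, passed
#'   through).
#' @param alpha family-wise significance level.
#' @return List with `adjusted` (same order as input) and `reject` (logical).
#' @export
holm_adjust <- function(p, alpha = 0.01) {
  if (!length(p)) return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) qc_validation_error("p values must lie in [0, 1]")
  adjusted <- p.adjust(p, method = "holm")
  reject <- !is.na(adjusted) & adjusted <= alpha
  list(adjusted = adjusted, reject = reject)
}
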