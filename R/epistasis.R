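#' Per-probe DUSP1 effect (DE) in a given Zfp36 background
#'
#' The DUSP1 effect of a transcript is the mean expression ratio of
#' Dusp1-null to Dusp1-wild-type macrophages under LPS, computed on the
#' log2 scale as a difference of replicate means. In the Zfp36 wild-type
#' background (WT vs Dusp1KO) this is DE1; in the Zfp36aa background
#' (Zfp36aa vs DoubleMut) it is DE2. The log2 value equals both the log2
#' ratio of group geometric means and the mean of all pairwise replicate
#' log-ratios.
#'
#' @param log2_matrix numeric matrix of log2 intensities (probes x
#'   samples).
#' @param design sample design data frame.
#' @param background `"zfp36_wt"` (DE1: Dusp1KO vs WT) or `"zfp36_aa"`
#'   (DE2: DoubleMut vs Zfp36aa).
#' @param timepoint optional timepoint label to subset LPS samples on.
#' @return named numeric vector of per-probe log2 DE values.
#' @export
compute_de <- function(log2_matrix, design,
                       background = c("zfp36_wt", "zfp36_aa"),
                       timepoint = NULL) {
  background <- match.arg(background)
  pair <- if (background == "zfp36_wt") c("WT", "Dusp1KO") else
    c("Zfp36aa", "DoubleMut")
  null_mat <- .lps_group(log2_matrix, design, pair[2], timepoint)
  wt_mat <- .lps_group(log2_matrix, design, pair[1], timepoint)
  rowMeans(null_mat) - rowMeans(wt_mat)
}

# LPS-treated replicate submatrix for one genotype
.lps_group <- function(log2_matrix, design, genotype, timepoint = NULL) {
  sel <- design$genotype == genotype & design$treatment == "LPS"
  if (!is.null(timepoint)) sel <- sel & design$timepoint == timepoint
  if (sum(sel) < 2L)
    stop(sprintf("need >= 2 LPS-treated replicates of genotype '%s'",
                 genotype))
  log2_matrix[, design$sample_id[sel], drop = FALSE]
}

#' Test the difference between DE1 and DE2 for one transcript
#'
#' Given the LPS-treated log2 replicate values of the four genotypes,
#' tests the no-epistasis null DE1 = DE2.
#'
#' Two error models are available. `"pairwise"` follows the published
#' procedure: form all pairwise log2 ratios Dusp1KO/WT (the DE1 sample,
#' n x m values) and DoubleMut/Zfp36aa (the DE2 sample) and compare them
#' by a two-sample Welch t-test. Because the n x m ratios are built from
#' only n + m replicates they are dependent, and the test is
#' anti-conservative (with 3 + 3 replicates its standard error
#' understates the true SE of DE1 - DE2 by a factor of 2).
#' `"groupwise"` is the calibrated alternative: a t-test on DE1 - DE2
#' with the variance propagated from the four replicate-group variances
#' and Welch-Satterthwaite degrees of freedom.
#'
#' Degenerate inputs: when every replicate variance is zero the test is
#' undecidable by data; equal DE values give p = 1, unequal ones give a
#' p at the smallest positive double together with `degenerate = TRUE`.
#'
#' @param wt_reps,ko_reps,zfp_reps,dbl_reps numeric vectors of log2
#'   replicate values (>= 2 each) for WT, Dusp1KO, Zfp36aa and DoubleMut.
#' @param error_model `"pairwise"` (default, mirrors the published
#'   analysis) or `"groupwise"`.
#' @return list with `p_value`, `de1`, `de2`, `t`, `df`, `error_model`
#'   and `degenerate`.
#' @export
pairwise_ratio_test <- function(wt_reps, ko_reps, zfp_reps, dbl_reps,
                                error_model = c("pairwise", "groupwise")) {
  error_model <- match.arg(error_model)
  reps <- list(wt_reps, ko_reps, zfp_reps, dbl_reps)
  if (any(vapply(reps, length, 1L) < 2L))
    stop("each genotype needs >= 2 replicates")
  de1 <- mean(ko_reps) - mean(wt_reps)
  de2 <- mean(dbl_reps) - mean(zfp_reps)
  if (error_model == "pairwise") {
    r1 <- as.vector(outer(ko_reps, wt_reps, "-"))
    r2 <- as.vector(outer(dbl_reps, zfp_reps, "-"))
    v1 <- stats::var(r1); v2 <- stats::var(r2)
    n1 <- length(r1); n2 <- length(r2)
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    v <- vapply(reps, function(r) stats::var(r) / length(r), 0)
    se2 <- sum(v)
    df <- se2^2 / sum(v^2 / (vapply(reps, length, 1L) - 1L))
  }
  if (se2 <= 0 || !is.finite(df)) {
    eq <- isTRUE(all.equal(de1, de2))
    return(list(p_value = if (eq) 1 else .Machine$double.xmin,
                de1 = de1, de2 = de2, t = if (eq) 0 else Inf, df = NA_real_,
                error_model = error_model, degenerate = TRUE))
  }
  tt <- (de1 - de2) / sqrt(se2)
  list(p_value = 2 * stats::pt(-abs(tt), df), de1 = de1, de2 = de2,
       t = tt, df = df, error_model = error_model, degenerate = FALSE)
}

# vectorized p-values across probes from the four group matrices
.p_diff_vec <- function(wt, ko, zf, db, error_model) {
  rv <- function(m) rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L)
  de1 <- rowMeans(ko) - rowMeans(wt)
  de2 <- rowMeans(db) - rowMeans(zf)
  if (error_model == "pairwise") {
    # sample variance of the n x m dependent pairwise ratios:
    # SS = m (n-1) s_num^2 + n (m-1) s_den^2, denominator nm - 1
    pv <- function(num, den) {
      n <- ncol(num); m <- ncol(den)
      (m * (n - 1) * rv(num) + n * (m - 1) * rv(den)) / (n * m - 1)
    }
    v1 <- pv(ko, wt); v2 <- pv(db, zf)
    n1 <- ncol(ko) * ncol(wt); n2 <- ncol(db) * ncol(zf)
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    vs <- lapply(list(wt, ko, zf, db), function(m) rv(m) / ncol(m))
    ns <- vapply(list(wt, ko, zf, db), ncol, 1L)
    se2 <- Reduce(`+`, vs)
    df <- se2^2 / Reduce(`+`, Map(function(v, n) v^2 / (n - 1L), vs, ns))
  }
  tt <- (de1 - de2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 <= 0 | !is.finite(df)
  if (any(degen)) {
    eq <- abs(de1 - de2) < sqrt(.Machine$double.eps)
    p[degen & eq] <- 1
    p[degen & !eq] <- .Machine$double.xmin
  }
  list(p = p, degenerate = degen)
}

#' Classify DE1 vs DE2 difference p-values into significance tiers
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return factor with levels `ns` (p >= 0.01), `significant`
#'   (0.0001 <= p < 0.01) and `highly_significant` (p < 0.0001).
#' @export
classify_tiers <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  factor(ifelse(is.na(p), NA, ifelse(p < 1e-4, "highly_significant",
                                     ifelse(p < 0.01, "significant", "ns"))),
         levels = c("ns", "significant", "highly_significant"))
}

#' Through-origin regression of DE2 on DE1
#'
#' Fits the global epistasis summary: the regression of per-transcript
#' log2 DE2 on log2 DE1, whose slope measures the average fraction of
#' the DUSP1 effect that survives mutation of the TTP phosphorylation
#' sites (slope 1 = no epistasis; slope < 1 = TTP-phosphorylation-
#' mediated attenuation).
#'
#' The default is least squares through the origin
#' (\eqn{\hat\beta = \sum xy / \sum x^2}), because the no-epistasis null
#' is the diagonal through the origin; `mode = "free_intercept"` fits
#' ordinary least squares. The 95% CI is the analytic t interval
#' (df n - 1 through origin, n - 2 with intercept) or a seeded
#' case-resampling bootstrap percentile interval (`ci = "bootstrap"`).
#'
#' Because DE1 is itself a noisy replicate average, the naive slope is
#' attenuated toward zero (regression dilution): its expectation is
#' roughly \eqn{\beta \sum\delta^2 / (\sum\delta^2 + m v_x)} where
#' \eqn{v_x} is the sampling variance of DE1. Supplying `x_error_var`
#' (e.g. estimated from replicate variances; see
#' [epistasis_analysis()]) applies the method-of-moments
#' errors-in-variables correction
#' \eqn{\hat\beta = \sum xy / (\sum x^2 - m v_x)}, with a bootstrap CI.
#'
#' @param de1_log2,de2_log2 numeric vectors of per-transcript log2 DE
#'   values (same length, n >= 3, finite).
#' @param mode `"through_origin"` (default) or `"free_intercept"`.
#' @param conf_level confidence level for the slope CI (default 0.95).
#' @param x_error_var optional sampling variance of the DE1 values:
#'   either a single pooled value or a per-transcript vector (estimated
#'   values are resampled along with the points in the bootstrap);
#'   triggers the attenuation-corrected estimator (through-origin only).
#' @param ci `"t"` (analytic, default) or `"bootstrap"`; the corrected
#'   estimator always uses the bootstrap.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap.
#' @return object of class `epistasis_fit` with components `slope`,
#'   `intercept`, `ci` (length-2), `conf_level`, `n`, `residual_sd`,
#'   `mode`, `ci_method`, `x_error_var`, and the data.
#' @examples
#' x <- seq(0.2, 2, length.out = 10)
#' fit <- fit_epistasis_regression(x, 0.5 * x)
#' coef(fit)  # slope 0.5
#' @export
fit_epistasis_regression <- function(de1_log2, de2_log2,
                                     mode = c("through_origin",
                                              "free_intercept"),
                                     conf_level = 0.95, x_error_var = NULL,
                                     ci = c("t", "bootstrap"),
                                     n_boot = 2000, seed = 1L) {
  mode <- match.arg(mode); ci <- match.arg(ci)
  x <- as.numeric(de1_log2); y <- as.numeric(de2_log2)
  if (length(x) != length(y)) stop("DE1 and DE2 must have the same length")
  if (length(x) < 3L) stop("need at least 3 transcripts")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("DE values must be finite")
  if (all(x == 0)) stop("all DE1 values are zero: slope undefined")
  n <- length(x)
  corrected <- !is.null(x_error_var)
  if (corrected) {
    if (mode != "through_origin")
      stop("attenuation correction is defined for through-origin fits")
    ve <- if (length(x_error_var) == 1L) rep(x_error_var, n) else
      as.numeric(x_error_var)
    if (length(ve) != n)
      stop("'x_error_var' must have length 1 or length(de1)")
    if (sum(x^2) - sum(ve) <= 0)
      stop("x_error_var too large: corrected denominator not positive")
    # bootstrap resamples the per-point error-variance estimates too
    slope_fun <- function(i) sum(x[i] * y[i]) / (sum(x[i]^2) - sum(ve[i]))
    slope <- slope_fun(seq_len(n)); intercept <- 0
    df <- n - 1L
    ci <- "bootstrap"
    x_error_var <- mean(ve)
  } else if (mode == "through_origin") {
    fit <- stats::lm(y ~ 0 + x)
    slope <- unname(stats::coef(fit)); intercept <- 0
    df <- n - 1L
    slope_fun <- function(i) sum(x[i] * y[i]) / sum(x[i]^2)
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2]); intercept <-
      unname(stats::coef(fit)[1])
    df <- n - 2L
    slope_fun <- function(i) stats::cov(x[i], y[i]) / stats::var(x[i])
  }
  res <- y - (intercept + slope * x)
  residual_sd <- sqrt(sum(res^2) / df)
  if (ci == "t") {
    se <- if (mode == "through_origin") residual_sd / sqrt(sum(x^2)) else
      residual_sd / sqrt(sum((x - mean(x))^2))
    hw <- stats::qt(1 - (1 - conf_level) / 2, df) * se
    ci_slope <- c(slope - hw, slope + hw)
  } else {
    set.seed(as.integer(seed))
    bs <- vapply(seq_len(n_boot), function(b)
      slope_fun(sample.int(n, n, replace = TRUE)), 0)
    ci_slope <- unname(stats::quantile(bs, c((1 - conf_level) / 2,
                                             1 - (1 - conf_level) / 2),
                                       na.rm = TRUE))
  }
  structure(list(slope = slope, intercept = intercept, ci = ci_slope,
                 conf_level = conf_level, n = n, residual_sd = residual_sd,
                 df = df, mode = mode, ci_method = ci,
                 x_error_var = if (corrected) x_error_var else NULL,
                 de1 = x, de2 = y, call = match.call()),
            class = "epistasis_fit")
}

#' @export
print.epistasis_fit <- function(x, ...) {
  cat(sprintf("%s regression of log2 DE2 on log2 DE1 (n = %d)\n",
              if (x$mode == "through_origin") "Through-origin" else
                "Free-intercept", x$n))
  if (!is.null(x$x_error_var))
    cat(sprintf("  attenuation-corrected (DE1 error variance %.4g)\n",
                x$x_error_var))
  cat(sprintf("  slope %.3f, %d%% CI [%.3f, %.3f] (%s)\n", x$slope,
              round(100 * x$conf_level), x$ci[1], x$ci[2], x$ci_method))
  if (x$mode == "free_intercept")
    cat(sprintf("  intercept %.3f\n", x$intercept))
  cat("  (slope 1 = no epistasis; slope < 1 = TTP-phosphorylation-mediated)\n")
  invisible(x)
}

#' @export
coef.epistasis_fit <- function(object, ...) {
  if (object$mode == "free_intercept")
    c(intercept = object$intercept, slope = object$slope)
  else c(slope = object$slope)
}

#' @export
confint.epistasis_fit <- function(object, parm = "slope", level = NULL,
                                  ...) {
  if (!is.null(level) && level != object$conf_level)
    stop("refit with the desired 'conf_level' to change the CI level")
  m <- matrix(object$ci, 1, dimnames = list("slope", c("lower", "upper")))
  m
}

#' @export
predict.epistasis_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$de1 else
    if (is.list(newdata)) newdata$de1 else as.numeric(newdata)
  object$intercept + object$slope * x
}

#' @export
residuals.epistasis_fit <- function(object, ...) {
  object$de2 - predict(object)
}

#' @export
simulate.epistasis_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  out <- as.data.frame(replicate(nsim,
    mu + stats::rnorm(object$n, 0, object$residual_sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.epistasis_fit <- function(object, ...) {
  se <- if (object$ci_method == "t")
    (object$ci[2] - object$ci[1]) /
      (2 * stats::qt(1 - (1 - object$conf_level) / 2, object$df)) else NA
  structure(list(fit = object, se = se,
                 null_excluded = object$ci[2] < 1 || object$ci[1] > 1),
            class = "summary.epistasis_fit")
}

#' @export
print.summary.epistasis_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SD %.3f; null slope 1 %s the %d%% CI\n",
              x$fit$residual_sd,
              if (x$null_excluded) "excluded from" else "inside",
              round(100 * x$fit$conf_level)))
  invisible(x)
}

#' @export
plot.epistasis_fit <- function(x, ...) {
  .plot_de(x$de1, x$de2, tier = NULL, fit = x, ...)
}

.plot_de <- function(de1, de2, tier = NULL, fit = NULL, ...) {
  cols <- if (is.null(tier)) "grey40" else
    c(ns = "grey75", significant = "grey40",
      highly_significant = "black")[as.character(tier)]
  lim <- range(c(de1, de2, 0))
  graphics::plot(de1, de2, pch = 16, col = cols, xlim = lim, ylim = lim,
                 xlab = expression(log[2] ~ DE1), asp = 1,
                 ylab = expression(log[2] ~ DE2), ...)
  graphics::abline(0, 1, lty = 1)                      # null DE1 = DE2
  if (!is.null(fit))
    graphics::abline(fit$intercept, fit$slope, lty = 3) # best fit
  invisible(NULL)
}

#' Full epistasis analysis of a four-genotype expression experiment
#'
#' Computes per-transcript DE1 (Dusp1KO/WT, Zfp36 wild-type background)
#' and DE2 (DoubleMut/Zfp36aa), tests DE1 = DE2 per transcript
#' ([pairwise_ratio_test()]), assigns significance tiers and fits the
#' global through-origin regression of DE2 on DE1
#' ([fit_epistasis_regression()]).
#'
#' With `correct_attenuation = TRUE` the sampling variance of DE1 is
#' estimated from the WT and Dusp1KO replicate variances (pooled across
#' transcripts) and the errors-in-variables-corrected slope is fitted;
#' this is the appropriate estimator when testing the global null
#' slope = 1, which the naive fit is biased against.
#'
#' @inheritParams compute_de
#' @param probes optional character vector restricting the analysis
#'   (e.g. significantly overexpressed transcripts).
#' @param error_model per-transcript error model, see
#'   [pairwise_ratio_test()].
#' @param mode,conf_level,n_boot,seed passed to
#'   [fit_epistasis_regression()].
#' @param correct_attenuation logical; fit the attenuation-corrected
#'   slope (default FALSE, matching the published naive fit).
#' @return object of class `epistasis_result`: list with `table` (data
#'   frame: probe, de1_log2, de2_log2, p_diff, tier, degenerate), `fit`
#'   (`epistasis_fit`), `error_model`, and `de1_error_var`.
#' @export
epistasis_analysis <- function(log2_matrix, design, timepoint = NULL,
                               probes = NULL,
                               error_model = c("pairwise", "groupwise"),
                               mode = "through_origin",
                               correct_attenuation = FALSE,
                               conf_level = 0.95, n_boot = 2000,
                               seed = 1L) {
  error_model <- match.arg(error_model)
  if (!is.null(probes)) log2_matrix <- log2_matrix[probes, , drop = FALSE]
  wt <- .lps_group(log2_matrix, design, "WT", timepoint)
  ko <- .lps_group(log2_matrix, design, "Dusp1KO", timepoint)
  zf <- .lps_group(log2_matrix, design, "Zfp36aa", timepoint)
  db <- .lps_group(log2_matrix, design, "DoubleMut", timepoint)
  de1 <- rowMeans(ko) - rowMeans(wt)
  de2 <- rowMeans(db) - rowMeans(zf)
  pd <- .p_diff_vec(wt, ko, zf, db, error_model)
  tab <- data.frame(probe = rownames(log2_matrix), de1_log2 = de1,
                    de2_log2 = de2, p_diff = pd$p,
                    tier = classify_tiers(pd$p),
                    degenerate = pd$degenerate, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  rv <- function(m) rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L)
  ve <- rv(wt) / ncol(wt) + rv(ko) / ncol(ko)  # per-probe var of DE1
  fit <- fit_epistasis_regression(de1, de2, mode = mode,
                                  conf_level = conf_level,
                                  x_error_var = if (correct_attenuation) ve
                                  else NULL,
                                  n_boot = n_boot, seed = seed)
  structure(list(table = tab, fit = fit, error_model = error_model,
                 de1_error_var = mean(ve), timepoint = timepoint),
            class = "epistasis_result")
}

#' @export
print.epistasis_result <- function(x, ...) {
  cat(sprintf("Epistasis analysis of %d transcripts (error model: %s)\n",
              nrow(x$table), x$error_model))
  print(table(tier = x$table$tier))
  print(x$fit)
  invisible(x)
}

#' @export
summary.epistasis_result <- function(object, ...) {
  summary(object$fit)
}

#' @export
plot.epistasis_result <- function(x, ...) {
  .plot_de(x$table$de1_log2, x$table$de2_log2, tier = x$table$tier,
           fit = x$fit, ...)
}
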