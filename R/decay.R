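#' Relative expression by the delta-delta-Ct method
#'
#' Standard qPCR relative quantification against a reference gene and a
#' calibrator sample:
#' \deqn{2^{-\left[(Ct_{t,s} - Ct_{r,s}) - (Ct_{t,c} - Ct_{r,c})\right]}}
#' where t = target gene, r = reference gene (e.g. Gapdh), s = sample,
#' c = calibrator. Vectorized over its arguments.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene
#'   in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of target and
#'   reference gene in the calibrator sample.
#' @return relative expression (linear scale; calibrator = 1).
#' @examples
#' ddct(25, 20, 27, 20)  # 4: target is 2 cycles earlier than calibrator
#' @export
ddct <- function(ct_target_sample, ct_ref_sample, ct_target_calibrator,
                 ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
           ct_ref_calibrator)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("Ct values must be positive and finite")
  dct_sample <- ct_target_sample - ct_ref_sample
  dct_cal <- ct_target_calibrator - ct_ref_calibrator
  2^-(dct_sample - dct_cal)
}

#' Fit first-order mRNA decay to a transcription-shutoff chase
#'
#' Estimates the decay rate constant k (per hour) and half-life
#' \eqn{t_{1/2} = \ln 2 / k} from a chase time course (values as percent
#' of the time-zero level, after reference-gene and t0 normalization).
#'
#' `model = "log_linear"` (default) is unweighted OLS of ln(value) on
#' time — appropriate under multiplicative measurement error and stable
#' on the 4-6 point series typical of actinomycin-D chases; k is minus
#' the slope with its regression SE. `model = "plateau"` fits
#' \eqn{y = p + (100 - p) e^{-kt}} by Levenberg-Marquardt nonlinear
#' least squares with the plateau bounded to [0, 100).
#'
#' A fitted k <= 0 means no measurable decay: the half-life is reported
#' as `Inf` with `no_decay = TRUE` rather than an error.
#'
#' @param series a `decay_series` data frame (columns `time_h`, `value`;
#'   see [simulate_decay_series()]), or a numeric vector of times if
#'   `value` is given separately.
#' @param value numeric values when `series` is a time vector.
#' @param model `"log_linear"` or `"plateau"`.
#' @return object of class `decay_fit`: list with `k`, `half_life`,
#'   `se_k`, `r_squared`, `plateau` (NA for log-linear), `no_decay`,
#'   `model`, `gene`, `genotype` and the data.
#' @examples
#' fit_decay(simulate_decay_series(1, c(0, 1, 2), 0))$half_life  # 1
#' @export
fit_decay <- function(series, value = NULL,
                      model = c("log_linear", "plateau")) {
  model <- match.arg(model)
  if (is.data.frame(series)) {
    tt <- series$time_h; v <- series$value
    gene <- attr(series, "gene"); genotype <- attr(series, "genotype")
  } else {
    tt <- as.numeric(series); v <- as.numeric(value)
    gene <- NA_character_; genotype <- NA_character_
  }
  if (length(tt) < 3L) stop("need >= 3 timepoints")
  if (any(!is.finite(v)) || any(v <= 0))
    stop("chase values must be positive")
  plateau <- NA_real_
  if (model == "log_linear") {
    fit <- stats::lm(log(v) ~ tt)
    k <- -unname(stats::coef(fit)[2])
    # OLS slope SE computed directly (vcov would warn on exact fits)
    s2 <- sum(stats::residuals(fit)^2) / (length(v) - 2L)
    se_k <- sqrt(s2 / sum((tt - mean(tt))^2))
    lv <- log(v)
    sstot <- sum((lv - mean(lv))^2)
    r2 <- if (sstot > 0) 1 - sum(stats::residuals(fit)^2) / sstot else
      NA_real_  # flat series: explained variance undefined
    amplitude <- exp(unname(stats::coef(fit)[1]))
    pred <- exp(stats::fitted(fit))
  } else {
    k0 <- max(-unname(stats::coef(stats::lm(log(v) ~ tt))[2]), 1e-3)
    fit <- minpack.lm::nlsLM(v ~ p + (100 - p) * exp(-k * tt),
                             start = list(p = 0, k = k0),
                             lower = c(p = 0, k = -10),
                             upper = c(p = 99.99, k = Inf))
    cf <- stats::coef(fit)
    k <- unname(cf["k"]); plateau <- unname(cf["p"])
    se_k <- unname(sqrt(diag(stats::vcov(fit)))["k"])
    pred <- stats::fitted(fit)
    amplitude <- 100
    r2 <- 1 - sum((v - pred)^2) / sum((v - mean(v))^2)
  }
  no_decay <- k <= 1e-10  # slope within numerical noise of zero
  structure(list(k = k, half_life = if (no_decay) Inf else log(2) / k,
                 se_k = se_k, r_squared = r2, plateau = plateau,
                 amplitude = amplitude,
                 no_decay = no_decay, model = model, gene = gene,
                 genotype = genotype, time_h = tt, value = v,
                 fitted = pred),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$gene, x$genotype)), collapse = " / ")
  cat(sprintf("mRNA decay fit%s (%s)\n",
              if (nzchar(lab)) paste0(" [", lab, "]") else "", x$model))
  if (x$no_decay) {
    cat("  no measurable decay (fitted k <= 0); half-life infinite\n")
  } else {
    cat(sprintf("  k = %.3f /h (SE %.3f); t1/2 = %.3g h; R^2 = %.3f\n",
                x$k, x$se_k, x$half_life, x$r_squared))
  }
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(k = object$k,
    if (object$model == "plateau") c(plateau = object$plateau))
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$time_h else
    if (is.list(newdata)) newdata$time_h else as.numeric(newdata)
  p <- if (is.na(object$plateau)) 0 else object$plateau
  p + (object$amplitude - p) * exp(-object$k * tt)
}

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$time_h, x$value, log = "y", pch = 16,
                 xlab = "time after transcription shutoff (h)",
                 ylab = "mRNA remaining (% of t0)", ...)
  tg <- seq(min(x$time_h), max(x$time_h), length.out = 100)
  graphics::lines(tg, predict(x, tg), lty = 2)
  invisible(NULL)
}

#' Compare two fitted mRNA half-lives
#'
#' Ratio of half-lives and a two-sided z-test on the difference of the
#' decay rate constants (k is the directly fitted, approximately
#' Gaussian parameter; half-life is its reciprocal transform). An
#' infinite half-life on one side gives a ratio of 0 or Inf; both
#' infinite is undefined.
#'
#' @param fit_a,fit_b `decay_fit` objects.
#' @return list with `ratio` (half_life_a / half_life_b), `z`,
#'   `p_value`.
#' @export
compare_half_lives <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "decay_fit"), inherits(fit_b, "decay_fit"))
  if (fit_a$no_decay && fit_b$no_decay)
    stop("both half-lives infinite: ratio undefined")
  ratio <- fit_a$half_life / fit_b$half_life
  z <- (fit_a$k - fit_b$k) / sqrt(fit_a$se_k^2 + fit_b$se_k^2)
  list(ratio = ratio, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Read a chase time-course CSV
#'
#' Expected columns: `series_id`, `genotype`, `gene`, `time_h`, `value`.
#'
#' @param path CSV path.
#' @return list of `decay_series` data frames, named by `series_id`.
#' @export
read_chase_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "genotype", "gene", "time_h", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("chase CSV missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(d, d$series_id), function(s) {
    s <- s[order(s$time_h), ]
    out <- data.frame(time_h = s$time_h, value = s$value)
    attr(out, "gene") <- s$gene[1]
    attr(out, "genotype") <- s$genotype[1]
    class(out) <- c("decay_series", "data.frame")
    out
  })
}
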