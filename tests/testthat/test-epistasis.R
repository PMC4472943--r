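des4 <- toy_design()

test_that("DE is the difference of LPS log2 replicate means", {
  m <- toy_matrix(des4, list(
    p1 = list("WT.LPS" = c(8, 8, 8), "Dusp1KO.LPS" = c(9, 9, 9),
              "Zfp36aa.LPS" = c(8, 8, 8), "DoubleMut.LPS" = c(8.5, 8.5, 8.5),
              "WT.untreated" = c(5, 5, 5), "Dusp1KO.untreated" = c(5, 5, 5),
              "Zfp36aa.untreated" = c(5, 5, 5),
              "DoubleMut.untreated" = c(5, 5, 5)),
    p2 = list("WT.LPS" = c(8.0, 8.2, 8.4), "Dusp1KO.LPS" = c(9.0, 9.2, 9.4),
              "Zfp36aa.LPS" = c(7, 7, 7), "DoubleMut.LPS" = c(7, 7, 7),
              "WT.untreated" = c(5, 5, 5), "Dusp1KO.untreated" = c(5, 5, 5),
              "Zfp36aa.untreated" = c(5, 5, 5),
              "DoubleMut.untreated" = c(5, 5, 5))))
  de1 <- compute_de(m, des4, "zfp36_wt")
  de2 <- compute_de(m, des4, "zfp36_aa")
  expect_equal(unname(de1), c(1.0, 1.0))
  expect_equal(unname(de2), c(0.5, 0.0))
  # untreated samples never enter the DE computation
  m2 <- m
  unt <- des4$sample_id[des4$treatment == "untreated"]
  m2[, unt] <- m2[, unt] + 100
  expect_equal(compute_de(m2, des4, "zfp36_wt"), de1)
  expect_error(compute_de(m, des4[des4$genotype != "Dusp1KO", ], "zfp36_wt"),
               "Dusp1KO")
})

test_that("DE equals the mean of all pairwise replicate log-ratios", {
  set.seed(81)
  wt <- rnorm(3, 8); ko <- rnorm(3, 9)
  expect_equal(mean(ko) - mean(wt), mean(outer(ko, wt, "-")))
})

test_that("pairwise ratio test matches the explicit Welch oracle", {
  wt <- c(8, 8.1, 7.9); ko <- c(9, 9.2, 8.8)
  zf <- c(8, 8.1, 7.9); db <- c(8.1, 8.0, 8.2)
  res <- pairwise_ratio_test(wt, ko, zf, db)
  o <- welch_oracle(as.vector(outer(ko, wt, "-")),
                    as.vector(outer(db, zf, "-")))
  expect_equal(res$p_value, o$p, tolerance = 1e-9)
  expect_equal(res$t, o$t, tolerance = 1e-9)
  expect_equal(res$df, o$df, tolerance = 1e-9)
  expect_false(res$degenerate)
})

test_that("degenerate replicate sets are handled without fake zeros", {
  # identical ratio samples -> p = 1
  r <- pairwise_ratio_test(c(8, 8, 8), c(9, 9, 9), c(7, 7, 7), c(8, 8, 8))
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  # complete separation with zero spread -> p at the floor, flagged
  r2 <- pairwise_ratio_test(c(8, 8, 8), c(8, 8, 8), c(7, 7, 7), c(8, 8, 8))
  expect_equal(r2$p_value, .Machine$double.xmin)
  expect_true(r2$degenerate)
})

test_that("vectorized p-values agree with the scalar test for both models", {
  set.seed(82)
  sim <- simulate_experiment(sim_params(n_genes = 30, seed = 82))
  lg <- log2(sim$expression)
  d <- sim$design
  g <- function(gt) lg[, d$sample_id[d$genotype == gt & d$treatment == "LPS"],
                       drop = FALSE]
  for (model in c("pairwise", "groupwise")) {
    res <- epistasis_analysis(lg, d, error_model = model)
    for (i in c(1, 7, 30)) {
      sc <- pairwise_ratio_test(g("WT")[i, ], g("Dusp1KO")[i, ],
                                g("Zfp36aa")[i, ], g("DoubleMut")[i, ],
                                error_model = model)
      expect_equal(res$table$p_diff[i], sc$p_value, tolerance = 1e-12)
      expect_equal(res$table$de1_log2[i], sc$de1, tolerance = 1e-12)
    }
  }
})

test_that("significance tiers follow the p < 0.01 / p < 0.0001 cuts", {
  tiers <- classify_tiers(c(0.5, 0.01, 0.005, 1e-4, 1e-6))
  expect_equal(as.character(tiers),
               c("ns", "ns", "significant", "significant",
                 "highly_significant"))
  expect_error(classify_tiers(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("through-origin regression reproduces exact slopes and CIs", {
  x <- seq(0.2, 2, length.out = 10)
  f1 <- fit_epistasis_regression(x, x)
  expect_equal(unname(coef(f1)), 1.0)
  expect_true(confint(f1)[1] <= 1 && confint(f1)[2] >= 1)
  f2 <- fit_epistasis_regression(x, 0.5 * x)
  expect_equal(unname(coef(f2)), 0.5)
  expect_equal(unname(diff(confint(f2)[1, ])), 0)
  expect_equal(f2$slope, sum(x * 0.5 * x) / sum(x^2))  # sum xy / sum x^2
  expect_error(fit_epistasis_regression(rep(0, 5), 1:5), "zero")
  expect_error(fit_epistasis_regression(1:2, 1:2), "3")
})

test_that("free-intercept mode is ordinary least squares", {
  set.seed(83)
  x <- rnorm(20); y <- 0.3 + 0.7 * x + rnorm(20, 0, 0.1)
  f <- fit_epistasis_regression(x, y, mode = "free_intercept")
  ols <- lm(y ~ x)
  expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 1e-12)
  expect_equal(unname(confint(f)["slope", ]),
               unname(confint(ols)["x", ]), tolerance = 1e-9)
})

test_that("regression is symmetric under sign flip and point permutation", {
  set.seed(84)
  x <- rnorm(30, 1); y <- 0.6 * x + rnorm(30, 0, 0.1)
  f <- fit_epistasis_regression(x, y)
  expect_equal(fit_epistasis_regression(-x, -y)$slope, f$slope)
  p <- sample(30)
  expect_equal(fit_epistasis_regression(x[p], y[p])$slope, f$slope)
})

test_that("bootstrap CI is seeded and close to the analytic interval", {
  set.seed(85)
  x <- rnorm(200, 1, 0.5); y <- 0.6 * x + rnorm(200, 0, 0.2)
  fb1 <- fit_epistasis_regression(x, y, ci = "bootstrap", seed = 9)
  fb2 <- fit_epistasis_regression(x, y, ci = "bootstrap", seed = 9)
  expect_identical(fb1$ci, fb2$ci)
  ft <- fit_epistasis_regression(x, y)
  expect_equal(fb1$ci, ft$ci, tolerance = 0.05)
})

test_that("fit methods are mutually consistent", {
  x <- seq(0.1, 1, length.out = 12)
  set.seed(86)
  y <- 0.5 * x + rnorm(12, 0, 0.05)
  f <- fit_epistasis_regression(x, y)
  expect_equal(predict(f, c(0, 2)), f$slope * c(0, 2))
  expect_equal(residuals(f), y - predict(f))
  s <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(s), c(12, 2))
  expect_output(print(f), "Through-origin")
  expect_output(print(summary(f)), "residual SD")
})

test_that("DE1 recovers the planted DUSP1 effect within sampling bounds", {
  p <- sim_params(n_genes = 1000, frac_induced = 1,
                  frac_dusp1_responsive = 1, seed = 87)
  sim <- simulate_experiment(p)
  de1 <- compute_de(log2(sim$expression), sim$design, "zfp36_wt")
  bound <- 3 * p$noise_sd_log2 * sqrt(2 / p$n_replicates)
  expect_gte(mean(abs(de1 - sim$truth$delta) < bound), 0.99)
})

test_that("the slope estimates the delta^2-weighted mean attenuation", {
  hits <- 0
  for (s in 1:10) {
    p <- sim_params(n_genes = 600, frac_induced = 1,
                    frac_dusp1_responsive = 1, ttp_zero_prob = 0,
                    ttp_beta_shape1 = 4.5, ttp_beta_shape2 = 5.5,
                    seed = 900 + s)
    sim <- simulate_experiment(p)
    res <- epistasis_analysis(log2(sim$expression), sim$design)
    truth <- with(sim$truth, sum(delta^2 * (1 - phi)) / sum(delta^2))
    if (abs(res$fit$slope - truth) < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("attenuation-corrected slope needs a sane error variance", {
  x <- seq(0.2, 2, length.out = 10)
  expect_error(fit_epistasis_regression(x, x, x_error_var = 10),
               "x_error_var")
  f <- fit_epistasis_regression(x, x, x_error_var = 1e-6, seed = 2)
  expect_equal(f$slope, 1, tolerance = 1e-3)
  expect_equal(f$ci_method, "bootstrap")
})

test_that("epistasis_analysis assembles a consistent result object", {
  sim <- simulate_experiment(sim_params(n_genes = 40, seed = 88))
  lg <- log2(sim$expression)
  res <- epistasis_analysis(lg, sim$design, probes = rownames(lg)[1:20])
  expect_s3_class(res, "epistasis_result")
  expect_equal(nrow(res$table), 20)
  expect_equal(res$fit$n, 20)
  expect_true(all(levels(res$table$tier) ==
                    c("ns", "significant", "highly_significant")))
  expect_equal(unname(res$table$de1_log2),
               unname(compute_de(lg, sim$design, "zfp36_wt")[1:20]))
  expect_output(print(res), "Epistasis analysis")
})
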