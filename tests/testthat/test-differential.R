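test_that("two-way ANOVA matches the sums-of-squares oracle and aov", {
  des <- toy_design(genotypes = c("WT", "Dusp1KO"))
  # near-degenerate interaction toy: one cell shifted by 3, tiny jitter
  jit <- c(-0.01, 0, 0.01)
  cells <- list(p1 = list("WT.untreated" = 10 + jit, "WT.LPS" = 10 + jit,
                          "Dusp1KO.untreated" = 10 + jit,
                          "Dusp1KO.LPS" = 13 + jit))
  m <- toy_matrix(des, cells)
  an <- anova_two_way(m, des)
  o <- ss_oracle(m[1, des$sample_id], des$genotype, des$treatment)
  expect_equal(an$F_interaction, o$F_int, tolerance = 1e-6)
  expect_equal(an$F_genotype, o$F_g, tolerance = 1e-6)
  expect_equal(an$F_treatment, o$F_t, tolerance = 1e-6)

  # random probes, all four genotypes, cross-checked against stats::aov
  set.seed(71)
  des4 <- toy_design()
  m4 <- matrix(rnorm(5 * nrow(des4), 8, 1), 5,
               dimnames = list(paste0("p", 1:5), des4$sample_id))
  an4 <- anova_two_way(m4, des4)
  for (i in 1:5) {
    fit <- aov(m4[i, des4$sample_id] ~ factor(des4$genotype) *
                 factor(des4$treatment))
    tab <- summary(fit)[[1]]
    expect_equal(an4$F_genotype[i], tab$`F value`[1], tolerance = 1e-9)
    expect_equal(an4$F_treatment[i], tab$`F value`[2], tolerance = 1e-9)
    expect_equal(an4$F_interaction[i], tab$`F value`[3], tolerance = 1e-9)
  }
})

test_that("contrast t equals the pooled-variance hand formula", {
  des <- toy_design(genotypes = c("WT", "Dusp1KO"))
  m <- toy_matrix(des, list(
    p1 = list("WT.LPS" = c(9.0, 9.1, 8.9), "WT.untreated" = c(8.0, 8.1, 7.9),
              "Dusp1KO.LPS" = c(9.5, 9.4, 9.6),
              "Dusp1KO.untreated" = c(8.2, 8.0, 8.1))))
  an <- anova_two_way(m, des)
  o <- ss_oracle(m[1, des$sample_id], des$genotype, des$treatment)
  d <- mean(c(9.0, 9.1, 8.9)) - mean(c(8.0, 8.1, 7.9))
  t_hand <- d / sqrt(o$mse * 2 / 3)
  expect_equal(an$diff_induction, d, tolerance = 1e-9)
  expect_equal(an$p_induction, 2 * pt(-abs(t_hand), o$df_e),
               tolerance = 1e-9)
})

test_that("null probes give uniform contrast p-values and F near its mean", {
  set.seed(72)
  des <- toy_design(genotypes = c("WT", "Dusp1KO"))
  m <- matrix(rnorm(2000 * nrow(des), 8, 0.5), 2000,
              dimnames = list(sprintf("p%04d", 1:2000), des$sample_id))
  an <- anova_two_way(m, des)
  expect_lt(abs(mean(an$p_induction) - 0.5), 0.03)
  expect_lt(abs(mean(an$p_induction < 0.05) - 0.05), 0.02)
  # E[F] for a null F(df1, df_e) variate is df_e / (df_e - 2); the mean of
  # a few thousand heavy-tailed F(1, 8) draws still wanders by ~0.05-0.2
  df_e <- attr(an, "df")[["residual"]]
  expect_lt(abs(mean(an$F_interaction) - df_e / (df_e - 2)), 0.25)
})

test_that("zero residual variance is flagged untestable, not p = 0", {
  des <- toy_design(genotypes = c("WT", "Dusp1KO"))
  m <- toy_matrix(des, list(
    p1 = list("WT.untreated" = c(8, 8, 8), "WT.LPS" = c(9, 9, 9),
              "Dusp1KO.untreated" = c(8, 8, 8),
              "Dusp1KO.LPS" = c(10, 10, 10))))
  an <- anova_two_way(m, des)
  expect_true(an$untestable)
  expect_true(is.na(an$p_induction))
})

test_that("ANOVA F is invariant to replicate relabeling", {
  set.seed(73)
  des <- toy_design(genotypes = c("WT", "Dusp1KO"))
  m <- matrix(rnorm(3 * nrow(des), 8, 1), 3,
              dimnames = list(c("a", "b", "c"), des$sample_id))
  an1 <- anova_two_way(m, des)
  des2 <- des[order(des$genotype, des$treatment, -des$replicate), ]
  an2 <- anova_two_way(m, des2)
  expect_equal(an1$F_interaction, an2$F_interaction, tolerance = 1e-12)
})

test_that("BH q-values equal the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(74)
  for (i in 1:50) {
    p <- runif(sample(3:80, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
})

test_that("induction summary counts match hand enumeration", {
  # hand-assigned folds and flags for ten probes
  r <- data.frame(
    probe = paste0("p", 1:10),
    fold_wt_lps = c(0.5, 1.2, 2, 4, 4, 6, 6, 12, 15, 20),
    induced =     c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                    TRUE, TRUE),
    up_in_ko =    c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE,
                    TRUE, FALSE),
    down_in_ko =  c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                    FALSE, TRUE))
  s <- summarize_induction(r)
  # >1: induced p2,p3,p4,p6,p7,p8,p9,p10 (8); up p3,p4,p7,p9 (4); down p6,p10
  expect_equal(s$n_induced, c(8, 6, 5, 3))
  expect_equal(s$n_up, c(4, 3, 2, 1))
  expect_equal(s$n_down, c(2, 2, 2, 1))
  expect_equal(s$pct_up, c(50, 50, 40, 33))
  # counts are monotone non-increasing in the threshold
  expect_true(all(diff(s$n_induced) <= 0))
  # no induced probes -> zeros, not NaN
  r0 <- r; r0$induced <- FALSE
  s0 <- summarize_induction(r0)
  expect_equal(s0$n_induced, rep(0, 4))
  expect_equal(s0$pct_up, rep(0, 4))
  # single threshold -> single row
  expect_equal(nrow(summarize_induction(r, fold_thresholds = 1)), 1)
})

test_that("induction pipeline recovers planted induction on simulated data", {
  p <- sim_params(n_genes = 300, frac_induced = 0.3,
                  induction_log2_mean = 3, induction_log2_sd = 0.5,
                  seed = 75)
  sim <- simulate_experiment(p)
  ir <- induction_results(log2_transform(sim$expression, 0), sim$design)
  truth <- sim$truth
  # strong planted inductions are called; non-induced genes rarely are
  strong <- truth$induced & truth$lambda > 2
  expect_gt(mean(ir$induced[strong]), 0.95)
  expect_lt(mean(ir$induced[!truth$induced]), 0.05)
  # Dusp1KO overexpression corresponds to planted delta > 0
  up <- truth$dusp1_responsive & truth$delta > 0.8
  expect_gt(mean(ir$up_in_ko[up]), 0.8)
})
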