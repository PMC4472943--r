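#' Per-probe two-way fixed-effects ANOVA with pairwise contrasts
#'
#' Fits the balanced two-way genotype x treatment ANOVA independently to
#' every probe of a log2 expression matrix, via the closed-form
#' sums-of-squares decomposition (vectorized across probes, the way
#' row-wise array statistics are usually computed). Pairwise contrasts
#' between cell means are tested with t statistics using the pooled
#' residual variance of the full model, df = N - (number of cells).
#'
#' Probes whose residual variance is exactly zero cannot be tested and
#' are flagged `untestable` (their p-values are `NA`, never 0).
#'
#' @param log2_matrix numeric matrix of log2 intensities (probes x
#'   samples).
#' @param design sample design data frame; only samples whose genotype
#'   appears in `genotypes` (and matching `timepoint`, if given) enter
#'   the model.
#' @param genotypes genotype levels to include (default all present).
#' @param timepoint optional timepoint label to subset on (datasets from
#'   different LPS durations are analyzed separately).
#' @param contrasts named list of contrasts, each
#'   `list(a = c(genotype, treatment), b = c(genotype, treatment))`,
#'   tested as cell-mean differences a - b. Default: LPS vs untreated in
#'   WT (`induction`), and Dusp1KO vs WT under LPS (`ko_vs_wt_lps`).
#' @return data frame (one row per probe) with F and p for the genotype
#'   and treatment main effects and their interaction, per-contrast log2
#'   differences and p-values (`diff_<name>`, `p_<name>`), and an
#'   `untestable` flag. Attribute `df` records the ANOVA degrees of
#'   freedom.
#' @export
anova_two_way <- function(log2_matrix, design, genotypes = NULL,
                          timepoint = NULL,
                          contrasts = list(
                            induction = list(a = c("WT", "LPS"),
                                             b = c("WT", "untreated")),
                            ko_vs_wt_lps = list(a = c("Dusp1KO", "LPS"),
                                                b = c("WT", "LPS")))) {
  sel <- rep(TRUE, nrow(design))
  if (!is.null(genotypes)) sel <- sel & design$genotype %in% genotypes
  if (!is.null(timepoint)) sel <- sel & design$timepoint == timepoint
  design <- design[sel, , drop = FALSE]
  x <- log2_matrix[, design$sample_id, drop = FALSE]

  gf <- factor(design$genotype)
  tf <- factor(design$treatment)
  a <- nlevels(gf); b <- nlevels(tf)
  if (a < 2L || b < 2L)
    stop("two-way ANOVA needs at least two levels of each factor")
  cell <- interaction(gf, tf, drop = FALSE)
  ncell <- table(cell)
  if (any(ncell == 0L)) stop("empty genotype x treatment cell")
  if (length(unique(ncell)) != 1L)
    stop("unbalanced design: all cells must have the same replicate count")
  n <- unname(ncell[1]); N <- ncol(x)

  # cell means (probes x cells), via group indicator matrix
  ind <- stats::model.matrix(~ 0 + cell)
  cellmean <- x %*% ind / n                        # probes x (a*b)
  gmean <- x %*% stats::model.matrix(~ 0 + gf) / (b * n)
  tmean <- x %*% stats::model.matrix(~ 0 + tf) / (a * n)
  grand <- rowMeans(x)

  ss_a <- b * n * rowSums((gmean - grand)^2)
  ss_b <- a * n * rowSums((tmean - grand)^2)
  # interaction: cell mean minus additive prediction
  # interaction() levels vary the first factor fastest
  lev <- levels(cell)
  gi <- rep(seq_len(a), b)
  ti <- rep(seq_len(b), each = a)
  addpred <- gmean[, gi, drop = FALSE] + tmean[, ti, drop = FALSE] - grand
  ss_ab <- n * rowSums((cellmean - addpred)^2)
  fitted <- cellmean[, as.integer(cell), drop = FALSE]
  ss_e <- rowSums((x - fitted)^2)

  df_a <- a - 1L; df_b <- b - 1L; df_ab <- df_a * df_b; df_e <- N - a * b
  mse <- ss_e / df_e
  untestable <- mse <= 0 | !is.finite(mse)
  fp <- function(ss, df) {
    f <- (ss / df) / mse
    f[untestable] <- NA_real_
    list(F = f, p = stats::pf(f, df, df_e, lower.tail = FALSE))
  }
  ra <- fp(ss_a, df_a); rb <- fp(ss_b, df_b); rab <- fp(ss_ab, df_ab)

  out <- data.frame(probe = rownames(x),
                    F_genotype = ra$F, p_genotype = ra$p,
                    F_treatment = rb$F, p_treatment = rb$p,
                    F_interaction = rab$F, p_interaction = rab$p,
                    stringsAsFactors = FALSE)
  for (nm in names(contrasts)) {
    cc <- contrasts[[nm]]
    ia <- match(paste(cc$a[1], cc$a[2], sep = "."), lev)
    ib <- match(paste(cc$b[1], cc$b[2], sep = "."), lev)
    if (is.na(ia) || is.na(ib))
      stop(sprintf("contrast '%s' references a missing cell", nm))
    d <- cellmean[, ia] - cellmean[, ib]
    tstat <- d / sqrt(mse * 2 / n)
    p <- 2 * stats::pt(-abs(tstat), df_e)
    p[untestable] <- NA_real_
    out[[paste0("diff_", nm)]] <- d
    out[[paste0("p_", nm)]] <- p
  }
  out$untestable <- untestable
  attr(out, "df") <- c(genotype = df_a, treatment = df_b,
                       interaction = df_ab, residual = df_e)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' Converts p-values to BH step-up false-discovery-rate q-values,
#' \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}} m\, p_{(j)}/j} clipped at 1,
#' preserving input order. `NA` p-values propagate to `NA` q-values and
#' do not count toward `m`.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-probe LPS induction and Dusp1KO dysregulation calls
#'
#' Runs the WT/Dusp1KO two-way ANOVA ([anova_two_way()]), converts the
#' log2 contrast differences to linear fold changes (ratios of group
#' geometric means) and applies BH FDR per contrast. A probe is called
#' LPS-induced when its WT LPS/untreated fold exceeds 1 with q below the
#' cutoff, and up-/down-regulated in Dusp1KO when the LPS-treated
#' Dusp1KO/WT contrast is significant in the corresponding direction.
#'
#' @inheritParams anova_two_way
#' @param q_cutoff FDR significance gate (default 0.05).
#' @return data frame of class `induction_result`: per probe the linear
#'   folds `fold_wt_lps` (LPS/untreated in WT) and `fold_ko_vs_wt`
#'   (Dusp1KO/WT under LPS), their p- and q-values, and logical flags
#'   `induced`, `up_in_ko`, `down_in_ko`.
#' @export
induction_results <- function(log2_matrix, design, timepoint = NULL,
                              q_cutoff = 0.05) {
  an <- anova_two_way(log2_matrix, design, genotypes = c("WT", "Dusp1KO"),
                      timepoint = timepoint)
  out <- data.frame(probe = an$probe,
                    fold_wt_lps = 2^an$diff_induction,
                    p_induction = an$p_induction,
                    q_induction = bh_fdr(an$p_induction),
                    fold_ko_vs_wt = 2^an$diff_ko_vs_wt_lps,
                    p_ko_vs_wt = an$p_ko_vs_wt_lps,
                    q_ko_vs_wt = bh_fdr(an$p_ko_vs_wt_lps),
                    stringsAsFactors = FALSE)
  out$induced <- !is.na(out$q_induction) & out$fold_wt_lps > 1 &
    out$q_induction < q_cutoff
  sig_ko <- !is.na(out$q_ko_vs_wt) & out$q_ko_vs_wt < q_cutoff
  out$up_in_ko <- sig_ko & out$fold_ko_vs_wt > 1
  out$down_in_ko <- sig_ko & out$fold_ko_vs_wt < 1
  class(out) <- c("induction_result", "data.frame")
  out
}

#' Tabulate LPS-induced transcripts dysregulated in Dusp1KO
#'
#' Builds the genome-wide dysregulation summary: for each fold-change
#' threshold, the number of significantly LPS-induced transcripts whose
#' WT fold exceeds the threshold, and among them the number (and integer
#' percentage) significantly up- or down-regulated in Dusp1KO
#' macrophages.
#'
#' @param results an `induction_result` from [induction_results()].
#' @param fold_thresholds linear fold-change thresholds; the conventional
#'   rows are all induced (>1), >3, >5 and >10-fold.
#' @return data frame with columns `threshold`, `n_induced`, `n_up`,
#'   `pct_up`, `n_down`, `pct_down`. Counts are monotone non-increasing
#'   in the threshold.
#' @export
summarize_induction <- function(results, fold_thresholds = c(1, 3, 5, 10)) {
  rows <- lapply(fold_thresholds, function(th) {
    ind <- results$induced & results$fold_wt_lps > th
    n <- sum(ind)
    up <- sum(ind & results$up_in_ko)
    dn <- sum(ind & results$down_in_ko)
    data.frame(threshold = th, n_induced = n,
               n_up = up, pct_up = if (n) round(100 * up / n) else 0,
               n_down = dn, pct_down = if (n) round(100 * dn / n) else 0)
  })
  do.call(rbind, rows)
}
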