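# Independent oracles and small fixture builders used across the suite.

# Brute-force BH step-up: q_i = min_{j: p_(j) >= p_(i)} m p_(j) / rank_j,
# clipped at 1 (direct transcription of the definition, O(n^2)).
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[ps >= ps[i]] / which(ps >= ps[i]))), 0)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Naive position-by-position motif scan (overlapping, U/T-equivalent).
motif_naive <- function(sequence, motif = "UAUUUAU") {
  s <- chartr("U", "T", toupper(sequence))
  m <- chartr("U", "T", toupper(motif))
  k <- nchar(m)
  if (nchar(s) < k) return(integer(0))
  hits <- vapply(seq_len(nchar(s) - k + 1),
                 function(i) substr(s, i, i + k - 1) == m, TRUE)
  which(hits)
}

# Brute-force balanced two-way ANOVA sums of squares for a single probe.
ss_oracle <- function(v, g, t) {
  g <- factor(g); t <- factor(t)
  a <- nlevels(g); b <- nlevels(t)
  n <- length(v) / (a * b)
  grand <- mean(v)
  mg <- tapply(v, g, mean); mt <- tapply(v, t, mean)
  mc <- tapply(v, interaction(g, t), mean)
  ss_a <- b * n * sum((mg - grand)^2)
  ss_b <- a * n * sum((mt - grand)^2)
  cellof <- interaction(g, t)
  ss_e <- sum((v - mc[as.character(cellof)])^2)
  ss_tot <- sum((v - grand)^2)
  ss_ab <- ss_tot - ss_a - ss_b - ss_e
  df_e <- length(v) - a * b
  mse <- ss_e / df_e
  list(F_g = (ss_a / (a - 1)) / mse, F_t = (ss_b / (b - 1)) / mse,
       F_int = (ss_ab / ((a - 1) * (b - 1))) / mse, mse = mse, df_e = df_e)
}

# Textbook Welch two-sample t-test (explicit formulas).
welch_oracle <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  tt <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# Design for a factorial toy experiment.
toy_design <- function(genotypes = c("WT", "Dusp1KO", "Zfp36aa",
                                     "DoubleMut"),
                       treatments = c("untreated", "LPS"), n_rep = 3,
                       timepoint = "1h") {
  d <- expand.grid(replicate = seq_len(n_rep), treatment = treatments,
                   genotype = genotypes, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$timepoint <- timepoint
  d$sample_id <- sprintf("%s_%s_%s_r%d", d$genotype, d$treatment,
                         d$timepoint, d$replicate)
  d[, c("sample_id", "genotype", "treatment", "timepoint", "replicate")]
}

# Matrix of per-probe replicate values: `cells` is a list, one element per
# probe, each a named list "<genotype>.<treatment>" -> replicate vector.
toy_matrix <- function(design, cells) {
  m <- matrix(NA_real_, length(cells), nrow(design),
              dimnames = list(names(cells), design$sample_id))
  for (i in seq_along(cells)) {
    for (key in names(cells[[i]])) {
      gt <- strsplit(key, ".", fixed = TRUE)[[1]]
      sel <- design$genotype == gt[1] & design$treatment == gt[2]
      m[i, design$sample_id[sel]] <- cells[[i]][[key]]
    }
  }
  m
}
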