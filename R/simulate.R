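#' Simulation parameters for the factorial expression experiment
#'
#' Constructs and validates the parameter set driving
#' [simulate_experiment()]. The generator emulates a four-genotype
#' (WT, Dusp1KO, Zfp36aa, DoubleMut) by two-treatment (untreated, LPS)
#' bone-marrow macrophage experiment with replicate arrays, on the model
#'
#' \deqn{\log_2 I_{gs} = \mu_g + \mathrm{LPS}\cdot\lambda_g +
#'   \mathrm{effects}_{g,\mathrm{genotype}} + \varepsilon,\qquad
#'   \varepsilon \sim N(0, \sigma^2)}
#'
#' Per-gene generative parameters: baseline \eqn{\mu}, LPS induction
#' \eqn{\lambda} (log2), DUSP1 effect \eqn{\delta} (log2 overexpression in
#' Dusp1KO under LPS), TTP-mediated fraction \eqn{\phi} (the part of
#' \eqn{\delta} that requires phosphorylatable TTP and is therefore lost
#' in the Zfp36aa background), and Zfp36aa main effect \eqn{\zeta}
#' (underexpression of direct TTP targets). The DoubleMut LPS mean
#' combines the attenuated DUSP1 effect \eqn{(1-\phi)\delta} with
#' \eqn{\zeta}. Replicate noise is log-normal (Gaussian in log2 space).
#'
#' \eqn{\phi} is drawn from a mixture: a point mass at 0 (TTP-independent
#' genes) plus a Beta distribution, so both fully TTP-dependent and
#' TTP-independent regulation exist among DUSP1-responsive genes.
#'
#' @param n_genes number of genes (probes).
#' @param frac_induced fraction of genes LPS-induced in WT.
#' @param induction_log2_mean,induction_log2_sd distribution of
#'   \eqn{\lambda} for induced genes.
#' @param frac_dusp1_responsive fraction of induced genes with a DUSP1
#'   effect.
#' @param dusp1_effect_log2_mean,dusp1_effect_log2_sd distribution of
#'   \eqn{\delta} for DUSP1-responsive genes.
#' @param ttp_zero_prob probability that \eqn{\phi = 0} exactly.
#' @param ttp_beta_shape1,ttp_beta_shape2 Beta parameters for the
#'   continuous part of \eqn{\phi}.
#' @param zfp36aa_effect_log2 \eqn{\zeta}, log2 main effect applied to
#'   direct TTP targets in Zfp36aa backgrounds (negative =
#'   underexpression).
#' @param baseline_log2_mean,baseline_log2_sd distribution of \eqn{\mu}.
#' @param noise_sd_log2 replicate noise SD \eqn{\sigma} in log2 units.
#' @param n_replicates replicates per genotype/treatment cell.
#' @param timepoint label attached to the design (default "1h").
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return an object of class `sim_params` (a validated list).
#' @seealso [simulate_experiment()]
#' @export
sim_params <- function(n_genes = 1000,
                       frac_induced = 0.2,
                       induction_log2_mean = 2,
                       induction_log2_sd = 1,
                       frac_dusp1_responsive = 0.5,
                       dusp1_effect_log2_mean = 1,
                       dusp1_effect_log2_sd = 0.5,
                       ttp_zero_prob = 0.3,
                       ttp_beta_shape1 = 2,
                       ttp_beta_shape2 = 2,
                       zfp36aa_effect_log2 = -0.5,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 2,
                       noise_sd_log2 = 0.2,
                       n_replicates = 3,
                       timepoint = "1h",
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), frac_induced = frac_induced,
            induction_log2_mean = induction_log2_mean,
            induction_log2_sd = induction_log2_sd,
            frac_dusp1_responsive = frac_dusp1_responsive,
            dusp1_effect_log2_mean = dusp1_effect_log2_mean,
            dusp1_effect_log2_sd = dusp1_effect_log2_sd,
            ttp_zero_prob = ttp_zero_prob,
            ttp_beta_shape1 = ttp_beta_shape1,
            ttp_beta_shape2 = ttp_beta_shape2,
            zfp36aa_effect_log2 = zfp36aa_effect_log2,
            baseline_log2_mean = baseline_log2_mean,
            baseline_log2_sd = baseline_log2_sd,
            noise_sd_log2 = noise_sd_log2,
            n_replicates = as.integer(n_replicates),
            timepoint = as.character(timepoint), seed = as.integer(seed))
  for (f in c("frac_induced", "frac_dusp1_responsive", "ttp_zero_prob")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single value in [0, 1]", f))
  }
  if (p$n_genes < 1L) stop("'n_genes' must be >= 1")
  if (!is.finite(p$noise_sd_log2) || p$noise_sd_log2 < 0)
    stop("'noise_sd_log2' must be >= 0")
  if (p$n_replicates < 2L) stop("'n_replicates' must be >= 2")
  for (f in c("induction_log2_sd", "dusp1_effect_log2_sd", "baseline_log2_sd"))
    if (p[[f]] < 0) stop(sprintf("'%s' must be >= 0", f))
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (factorial expression experiment)\n")
  cat(sprintf("  %d genes x 4 genotypes x 2 treatments x %d replicates\n",
              x$n_genes, x$n_replicates))
  cat(sprintf("  induced: %.0f%%; DUSP1-responsive among induced: %.0f%%\n",
              100 * x$frac_induced, 100 * x$frac_dusp1_responsive))
  cat(sprintf("  noise sd (log2): %.3g; seed: %d\n", x$noise_sd_log2, x$seed))
  invisible(x)
}

.genotypes <- c("WT", "Dusp1KO", "Zfp36aa", "DoubleMut")
.treatments <- c("untreated", "LPS")

#' Simulate a four-genotype factorial expression experiment
#'
#' Draws per-gene generative parameters, builds the group means of the
#' model described in [sim_params()], adds log-normal replicate noise and
#' returns linear-scale intensities together with the sample design and
#' the ground-truth table.
#'
#' Group means in log2 space (LPS samples): WT \eqn{\mu+\lambda};
#' Dusp1KO \eqn{\mu+\lambda+\delta}; Zfp36aa \eqn{\mu+\lambda+\zeta};
#' DoubleMut \eqn{\mu+\lambda+\zeta+(1-\phi)\delta}. \eqn{\zeta} is
#' applied only to genes flagged as direct TTP targets (those with
#' \eqn{\phi > 0}). Untreated samples share the baseline \eqn{\mu}
#' across genotypes.
#'
#' @param params a [sim_params()] object.
#' @return list with components `expression` (numeric matrix, genes x
#'   samples, linear intensities), `design` (data frame: sample_id,
#'   genotype, treatment, timepoint, replicate) and `truth` (data frame
#'   of per-gene generative parameters and flags). The expected log2
#'   effect of Dusp1 deletion in the Zfp36aa background is
#'   `(1 - truth$phi) * truth$delta` by construction.
#' @examples
#' sim <- simulate_experiment(sim_params(n_genes = 50, seed = 7))
#' dim(sim$expression)  # 50 x 24
#' @export
simulate_experiment <- function(params) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  p <- params
  set.seed(p$seed)
  ng <- p$n_genes

  mu <- rnorm(ng, p$baseline_log2_mean, p$baseline_log2_sd)
  induced <- runif(ng) < p$frac_induced
  lambda <- ifelse(induced,
                   rnorm(ng, p$induction_log2_mean, p$induction_log2_sd), 0)
  responsive <- induced & (runif(ng) < p$frac_dusp1_responsive)
  delta <- ifelse(responsive,
                  rnorm(ng, p$dusp1_effect_log2_mean, p$dusp1_effect_log2_sd),
                  0)
  phi <- ifelse(runif(ng) < p$ttp_zero_prob, 0,
                rbeta(ng, p$ttp_beta_shape1, p$ttp_beta_shape2))
  phi[!responsive] <- 0
  direct_ttp <- responsive & phi > 0
  zeta <- ifelse(direct_ttp, p$zfp36aa_effect_log2, 0)

  design <- expand.grid(replicate = seq_len(p$n_replicates),
                        treatment = .treatments, genotype = .genotypes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("genotype", "treatment", "replicate")]
  design$timepoint <- p$timepoint
  design$sample_id <- sprintf("%s_%s_%s_r%d", design$genotype,
                              design$treatment, design$timepoint,
                              design$replicate)
  design <- design[, c("sample_id", "genotype", "treatment", "timepoint",
                       "replicate")]

  # log2 group mean for each design row (genes x samples)
  m <- matrix(mu, ng, nrow(design))
  lps <- design$treatment == "LPS"
  m[, lps] <- m[, lps] + lambda
  for (j in which(lps)) {
    g <- design$genotype[j]
    if (g == "Dusp1KO") m[, j] <- m[, j] + delta
    if (g == "Zfp36aa") m[, j] <- m[, j] + zeta
    if (g == "DoubleMut") m[, j] <- m[, j] + zeta + (1 - phi) * delta
  }
  noise <- matrix(rnorm(length(m), 0, p$noise_sd_log2), ng)
  expr <- 2^(m + noise)
  rownames(expr) <- sprintf("gene_%04d", seq_len(ng))
  colnames(expr) <- design$sample_id

  truth <- data.frame(gene = rownames(expr), mu = mu, lambda = lambda,
                      delta = delta, phi = phi, zeta = zeta,
                      induced = induced, dusp1_responsive = responsive,
                      direct_ttp_target = direct_ttp,
                      noise_sd_log2 = p$noise_sd_log2,
                      stringsAsFactors = FALSE)
  list(expression = expr, design = design, truth = truth, params = p)
}

#' Simulate a transcription-shutoff decay series
#'
#' First-order decay sampled at given chase timepoints, normalized to 100
#' at time zero before multiplicative (log-normal) measurement noise is
#' applied; with `noise_sd_log2 = 0` the series is exactly
#' \eqn{100 \cdot 2^{-t/t_{1/2}}}.
#'
#' @param half_life true half-life in hours (> 0).
#' @param timepoints chase sampling times in hours; must include 0.
#' @param noise_sd_log2 log2-scale measurement noise SD.
#' @param seed integer seed.
#' @param gene,genotype optional labels carried into the result.
#' @return data frame of class `decay_series` with columns `time_h`,
#'   `value` and attributes `gene`, `genotype`, `half_life`.
#' @examples
#' simulate_decay_series(1, c(0, 1, 2), 0)$value  # 100 50 25
#' @export
simulate_decay_series <- function(half_life, timepoints = c(0, 0.25, 0.5,
                                                            0.75, 1, 1.5),
                                  noise_sd_log2 = 0.1, seed = 1L,
                                  gene = NA_character_,
                                  genotype = NA_character_) {
  if (!is.numeric(half_life) || length(half_life) != 1L ||
      !is.finite(half_life) || half_life <= 0)
    stop("'half_life' must be a single positive number")
  if (!0 %in% timepoints) stop("'timepoints' must include 0")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("'timepoints' must be strictly increasing")
  set.seed(as.integer(seed))
  v <- 100 * 2^(-timepoints / half_life) *
    2^rnorm(length(timepoints), 0, noise_sd_log2)
  out <- data.frame(time_h = timepoints, value = v)
  attr(out, "gene") <- gene
  attr(out, "genotype") <- genotype
  attr(out, "half_life") <- half_life
  class(out) <- c("decay_series", "data.frame")
  out
}

#' Simulate a 3' UTR with a known number of ARE motifs
#'
#' Generates a uniform-random RNA sequence of the requested length with
#' exactly `n_motifs` planted, non-overlapping copies of the consensus
#' TTP binding heptamer UAUUUAU and no accidental additional matches.
#' The finished sequence is re-scanned and regenerated until the motif
#' count is exact, so the planted count is guaranteed.
#'
#' @param length sequence length in nucleotides (>= 7 * n_motifs).
#' @param n_motifs number of motif copies to plant (>= 0).
#' @param seed integer seed.
#' @param motif motif to plant (RNA alphabet).
#' @return a single character string (RNA alphabet, upper case).
#' @examples
#' u <- simulate_utr(60, 2, seed = 3)
#' scan_are(u)$count  # 2
#' @export
simulate_utr <- function(length, n_motifs, seed = 1L, motif = "UAUUUAU") {
  length <- as.integer(length); n_motifs <- as.integer(n_motifs)
  k <- nchar(motif)
  if (n_motifs < 0) stop("'n_motifs' must be >= 0")
  if (length < k * n_motifs)
    stop(sprintf("'length' must be >= %d for %d motif(s)", k * n_motifs,
                 n_motifs))
  set.seed(as.integer(seed))
  alph <- c("A", "C", "G", "U")
  mot <- strsplit(motif, "")[[1]]
  for (try in 1:10000) {
    s <- sample(alph, length, replace = TRUE)
    if (n_motifs > 0) {
      # non-overlapping starts: r_i distinct in 1..(L - nk + n),
      # s_i = r_i + (i-1)(k-1) guarantees s_{i+1} >= s_i + k
      r <- sort(sample.int(length - n_motifs * k + n_motifs, n_motifs))
      starts <- r + (seq_len(n_motifs) - 1L) * (k - 1L)
      for (st in starts) s[st:(st + k - 1)] <- mot
    }
    seqc <- paste(s, collapse = "")
    if (scan_are(seqc, motif = motif)$count == n_motifs) return(seqc)
  }
  stop("failed to generate a sequence with the exact motif count")
}

#' Simulate expression profiles with planted cluster archetypes
#'
#' Builds row profiles (e.g. per-genotype relative log2 expression
#' tracks) as copies of archetype rows plus Gaussian noise, for testing
#' profile clustering against a known partition.
#'
#' @param n_probes total number of probes; assigned to archetypes as
#'   evenly as possible.
#' @param archetypes numeric matrix, one row per archetype. The default
#'   encodes four regulatory patterns over relative-expression tracks
#'   (WT, Dusp1KO, Zfp36aa, DoubleMut): TTP-independent up-regulation in
#'   both Dusp1-null backgrounds; fully TTP-phosphorylation-dependent
#'   up-regulation of a direct TTP target (up in Dusp1KO, down in both
#'   Zfp36aa backgrounds); down-regulation in the Dusp1-null backgrounds;
#'   and Zfp36aa-driven up-regulation independent of Dusp1. The patterns
#'   are chosen with low pairwise profile correlation, since a
#'   correlation-distance recovery oracle is only informative when the
#'   planted classes are geometrically separable.
#' @param noise_sd per-entry Gaussian noise SD.
#' @param seed integer seed.
#' @return list with `profiles` (matrix n_probes x tracks) and `labels`
#'   (integer archetype of each row).
#' @export
simulate_profiles <- function(n_probes = 200,
                              archetypes = rbind(
                                c(0, 1.5, 0, 1.5),
                                c(0, 1.5, -1.5, -1.5),
                                c(0, -1.5, 0, -1.5),
                                c(0, 0, 1.5, 1.5)),
                              noise_sd = 0.2, seed = 1L) {
  set.seed(as.integer(seed))
  k <- nrow(archetypes)
  labels <- rep(seq_len(k), length.out = n_probes)
  prof <- archetypes[labels, , drop = FALSE] +
    matrix(rnorm(n_probes * ncol(archetypes), 0, noise_sd), n_probes)
  rownames(prof) <- sprintf("probe_%03d", seq_len(n_probes))
  colnames(prof) <- colnames(archetypes)
  list(profiles = prof, labels = labels)
}
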