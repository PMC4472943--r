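#' Low-intensity probe filter
#'
#' Removes weakly expressed probes: a probe is kept only if, in at least
#' one qualifying genotype/treatment group, at least
#' `min_passing_replicates` replicate intensities strictly exceed
#' `threshold`. The defaults reproduce the conventional microarray rule
#' of requiring a linear processed intensity above 100 in at least two of
#' three replicates of LPS-treated wild-type or Dusp1-null macrophages.
#' "Exceed" is strict: replicates exactly at the threshold do not count.
#'
#' @param expression numeric matrix of linear intensities
#'   (probes x samples, column names = sample ids).
#' @param design sample design data frame (see [read_expression_matrix()]).
#' @param threshold linear intensity threshold (default 100).
#' @param min_passing_replicates replicates that must exceed it
#'   (default 2).
#' @param qualifying_groups data frame with columns `genotype` and
#'   `treatment` (optionally `timepoint`) naming the groups in which the
#'   rule is evaluated; default LPS-treated WT and LPS-treated Dusp1KO.
#' @return logical keep-mask, one element per probe, named by probe id.
#' @export
filter_low_intensity <- function(expression, design, threshold = 100,
                                 min_passing_replicates = 2,
                                 qualifying_groups = data.frame(
                                   genotype = c("WT", "Dusp1KO"),
                                   treatment = "LPS")) {
  stopifnot(threshold > 0)
  keep <- rep(FALSE, nrow(expression))
  found <- FALSE
  for (i in seq_len(nrow(qualifying_groups))) {
    sel <- design$genotype == qualifying_groups$genotype[i] &
      design$treatment == qualifying_groups$treatment[i]
    if ("timepoint" %in% names(qualifying_groups))
      sel <- sel & design$timepoint == qualifying_groups$timepoint[i]
    if (!any(sel)) next
    found <- TRUE
    sub <- expression[, design$sample_id[sel], drop = FALSE]
    keep <- keep | rowSums(sub > threshold) >= min_passing_replicates
  }
  if (!found)
    stop("no qualifying group present in the design")
  names(keep) <- rownames(expression)
  keep
}

#' Replicate-dispersion outlier filter
#'
#' Removes probes with aberrant outlying replicate values: a probe is
#' filtered out if in any replicate group (genotype x treatment x
#' timepoint) the sample standard deviation (n-1 denominator) exceeds the
#' group mean. Groups of a single sample cannot be assessed and are
#' skipped with a warning.
#'
#' @inheritParams filter_low_intensity
#' @return logical keep-mask per probe (TRUE = kept).
#' @export
filter_outlier_dispersion <- function(expression, design) {
  groups <- interaction(design$genotype, design$treatment, design$timepoint,
                        drop = TRUE)
  keep <- rep(TRUE, nrow(expression))
  for (g in levels(groups)) {
    ids <- design$sample_id[groups == g]
    if (length(ids) < 2L) {
      warning(sprintf("replicate group '%s' has a single sample; skipped", g))
      next
    }
    sub <- expression[, ids, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- sqrt(rowSums((sub - mu)^2) / (ncol(sub) - 1L))
    keep <- keep & sdv <= mu
  }
  names(keep) <- rownames(expression)
  keep
}

#' Log2-transform an intensity matrix
#'
#' @param expression numeric matrix of non-negative linear intensities.
#' @param pseudocount added before taking log2 (default 1), so zero maps
#'   to zero.
#' @return matrix of log2(intensity + pseudocount).
#' @export
log2_transform <- function(expression, pseudocount = 1) {
  if (any(expression < 0, na.rm = TRUE))
    stop("negative intensities are not allowed")
  log2(expression + pseudocount)
}
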