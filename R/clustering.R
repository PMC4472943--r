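#' Per-genotype relative expression tracks
#'
#' Builds the matrix clustered in the heat-map analyses: per-genotype
#' mean log2 expression of LPS-treated samples, relative to LPS-treated
#' wild type.
#'
#' @inheritParams compute_de
#' @param reference genotype used as the zero track (default `"WT"`).
#' @return numeric matrix (probes x genotypes) of relative log2 means.
#' @export
relative_expression_tracks <- function(log2_matrix, design,
                                       timepoint = NULL,
                                       reference = "WT") {
  genos <- unique(design$genotype)
  tracks <- vapply(genos, function(g)
    rowMeans(.lps_group(log2_matrix, design, g, timepoint)),
    numeric(nrow(log2_matrix)))
  tracks - tracks[, reference]
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of probe profiles using one minus the
#' Pearson correlation between row-standardized profiles as distance and
#' average linkage, cut to exactly `k` clusters — the conventional
#' choices for expression heat-map clustering. Rows with zero variance
#' have no defined correlation; they are assigned to the nearest cluster
#' centroid by Euclidean distance, with a warning.
#'
#' @param profiles numeric matrix (probes x tracks), e.g. from
#'   [relative_expression_tracks()].
#' @param k number of clusters (>= 1, <= number of probes).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param metric `"pearson"` (1 - correlation on standardized rows,
#'   default) or `"euclidean"`.
#' @param standardize center and scale rows before clustering (default
#'   TRUE; ignored for `metric = "euclidean"`).
#' @return object of class `cluster_result`: list with `labels` (integer
#'   cluster per probe, named), `tree` (the `hclust` object), `k`,
#'   `metric`, `linkage`.
#' @export
cluster_genes <- function(profiles, k, linkage = "average",
                          metric = c("pearson", "euclidean"),
                          standardize = TRUE) {
  metric <- match.arg(metric)
  if (nrow(profiles) < k) stop("fewer probes than clusters")
  if (ncol(profiles) < 2L) stop("need >= 2 tracks")
  sds <- apply(profiles, 1, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  use <- if (metric == "pearson") !constant else rep(TRUE, nrow(profiles))
  if (metric == "pearson" && any(constant))
    warning(sprintf("%d constant row(s) assigned by Euclidean fallback",
                    sum(constant)))
  if (sum(use) < k) stop("too few non-constant probes for k clusters")
  sub <- profiles[use, , drop = FALSE]
  if (metric == "pearson") {
    z <- if (standardize) t(scale(t(sub))) else sub
    d <- stats::as.dist(1 - stats::cor(t(z)))
  } else {
    d <- stats::dist(sub)
  }
  tree <- stats::hclust(d, method = linkage)
  lab_sub <- stats::cutree(tree, k = k)
  labels <- integer(nrow(profiles))
  names(labels) <- rownames(profiles)
  labels[use] <- lab_sub
  if (any(!use)) {
    centroids <- vapply(seq_len(k), function(cl)
      colMeans(sub[lab_sub == cl, , drop = FALSE]), numeric(ncol(profiles)))
    for (i in which(!use)) {
      dd <- colSums((centroids - profiles[i, ])^2)
      labels[i] <- which.min(dd)
    }
  }
  structure(list(labels = labels, tree = tree, k = k, metric = metric,
                 linkage = linkage), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Hierarchical clustering: %d probes, k = %d (%s linkage, %s)\n",
              length(x$labels), x$k, x$linkage, x$metric))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Box-and-whisker summaries of clusters
#'
#' Per-cluster, per-track summary of expression profiles: median,
#' quartiles (linear-interpolation quantiles, type 7), whisker bounds by
#' the 1.5 x IQR rule (most extreme data points inside the fences), and
#' cluster size.
#'
#' @param result a [cluster_genes()] result.
#' @param profiles the matrix that was clustered (probes x tracks).
#' @return data frame with columns `cluster`, `track`, `n`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`.
#' @export
summarize_clusters <- function(result, profiles) {
  ks <- sort(unique(result$labels))
  if (any(tabulate(result$labels, nbins = result$k) == 0L))
    stop("empty cluster")
  tracks <- colnames(profiles)
  if (is.null(tracks)) tracks <- paste0("track_", seq_len(ncol(profiles)))
  rows <- list()
  for (cl in ks) {
    sub <- profiles[result$labels == cl, , drop = FALSE]
    for (j in seq_along(tracks)) {
      v <- sub[, j]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      lo <- min(v[v >= q[1] - 1.5 * iqr])
      hi <- max(v[v <= q[3] + 1.5 * iqr])
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cl, track = tracks[j], n = nrow(sub),
                   median = q[2], q1 = q[1], q3 = q[3],
                   whisker_low = lo, whisker_high = hi,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
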