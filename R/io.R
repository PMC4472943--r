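#' Read an expression matrix and its sample design
#'
#' Reads the pipeline's standard plain-text pair: a tab-delimited matrix
#' (first column `probe_id`, remaining columns one per sample, linear
#' intensities) and a tab-delimited design table with columns
#' `sample_id`, `genotype`, `treatment`, `timepoint`, `replicate`.
#' Columns of the returned matrix follow the design's sample order.
#' Missing intensities may be encoded as `NA`.
#'
#' @param matrix_path path to the expression TSV.
#' @param design_path path to the design TSV.
#' @return list with `expression` (numeric matrix, probes x samples) and
#'   `design` (data frame).
#' @export
read_expression_matrix <- function(matrix_path, design_path) {
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "treatment", "timepoint", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  key <- interaction(design$genotype, design$treatment, design$timepoint,
                     design$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated (genotype, treatment, timepoint, replicate) ",
         "combination in design")

  raw <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (names(raw)[1] != "probe_id")
    stop("first column of the matrix must be 'probe_id'")
  probes <- as.character(raw[[1]])
  if (anyDuplicated(probes))
    stop("duplicated probe_id: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad))
        stop(sprintf("non-numeric intensity at row %d, column '%s': '%s'",
                     bad[1], names(vals)[j], v[bad[1]]))
      vals[[j]] <- num
    }
  }
  extra <- setdiff(names(vals), design$sample_id)
  absent <- setdiff(design$sample_id, names(vals))
  if (length(extra) || length(absent))
    stop("matrix/design sample mismatch",
         if (length(extra)) paste0("; in matrix only: ",
                                   paste(extra, collapse = ", ")) else "",
         if (length(absent)) paste0("; in design only: ",
                                    paste(absent, collapse = ", ")) else "")
  m <- as.matrix(vals)[, design$sample_id, drop = FALSE]
  rownames(m) <- probes
  if (any(m < 0, na.rm = TRUE)) stop("negative intensities in matrix")
  list(expression = m, design = design)
}

#' Write an expression matrix and design as tab-delimited text
#'
#' Inverse of [read_expression_matrix()]; values are written with 12+
#' significant digits so a write/read round trip preserves them.
#'
#' @param expression numeric matrix (probes x samples).
#' @param design design data frame.
#' @param matrix_path,design_path output paths.
#' @export
write_expression_matrix <- function(expression, design, matrix_path,
                                    design_path) {
  df <- data.frame(probe_id = rownames(expression),
                   format(expression, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = matrix_path, design = design_path))
}

#' Write pipeline result tables and a JSON run summary
#'
#' Writes one CSV per supplied result table and a single
#' `run_summary.json` capturing parameters, seed, counts and (if an
#' epistasis result is present) the regression slope and CI. Output is
#' deterministic: fixed column order, fixed file names.
#'
#' @param results named list; recognized elements are `filter_mask`
#'   (logical vector), `anova` (data frame), `induction` (data frame),
#'   `induction_summary` (data frame), `epistasis`
#'   (`epistasis_result`), `clusters` (`cluster_result`),
#'   `cluster_summary` (data frame), `decay_fits` (list of `decay_fit`),
#'   `motif_hits` (data frame from [scan_are_fasta()]). Unrecognized
#'   data frames are written as `<name>.csv`.
#' @param out_dir output directory (created if absent).
#' @param params optional parameter list echoed into the JSON summary.
#' @param seed optional seed echoed into the JSON summary.
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, out_dir, params = NULL, seed = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }
  summary_json <- list(parameters = params, seed = seed)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (nm == "filter_mask") {
      wcsv(data.frame(probe_id = names(x), kept = unname(x)), "filter_mask")
      summary_json$n_probes <- length(x)
      summary_json$n_kept <- sum(x)
    } else if (nm == "epistasis" && inherits(x, "epistasis_result")) {
      wcsv(x$table, "epistasis")
      summary_json$regression <- list(
        slope = x$fit$slope, ci = x$fit$ci, mode = x$fit$mode,
        n = x$fit$n, error_model = x$error_model)
      summary_json$tier_counts <- as.list(table(x$table$tier))
    } else if (nm == "clusters" && inherits(x, "cluster_result")) {
      wcsv(data.frame(probe_id = names(x$labels),
                      cluster = unname(x$labels)), "clusters")
      wcsv(data.frame(step = seq_len(nrow(x$tree$merge)),
                      merge1 = x$tree$merge[, 1],
                      merge2 = x$tree$merge[, 2],
                      height = x$tree$height), "cluster_tree")
    } else if (nm == "decay_fits") {
      wcsv(do.call(rbind, lapply(x, function(f)
        data.frame(gene = f$gene, genotype = f$genotype, k = f$k,
                   half_life = f$half_life, se_k = f$se_k,
                   r_squared = f$r_squared, no_decay = f$no_decay,
                   stringsAsFactors = FALSE))), "decay_fits")
    } else if (is.data.frame(x)) {
      wcsv(x, nm)
    }
  }
  jp <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary_json, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths[[length(paths) + 1L]] <- jp
  invisible(unlist(paths))
}
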