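#' Scan a 3' UTR sequence for the consensus TTP binding ARE
#'
#' Reports every occurrence of the AU-rich element consensus heptamer
#' UAUUUAU (or another motif) in a nucleotide sequence. Overlapping
#' matches are counted: TTP biology involves the nonamer UUAUUUAUU built
#' from overlapping heptamers, and AREs cluster. T and U are treated as
#' equivalent; `N` never matches; scanning is single-stranded (mRNA
#' sense).
#'
#' @param sequence a single nucleotide string over A/C/G/T/U/N, case
#'   insensitive. A length-1 [Biostrings::DNAStringSet] /
#'   [Biostrings::RNAStringSet] element is also accepted via
#'   `as.character`.
#' @param motif motif to search for (default the TTP heptamer; set to
#'   `"UUAUUUAUU"` for the stricter nonamer consensus).
#' @param id optional sequence identifier carried into the result.
#' @return object of class `motif_hits`: list with `id`, `motif`,
#'   `positions` (1-based start positions, strictly increasing) and
#'   `count`.
#' @examples
#' scan_are("UAUUUAUUUAU")$positions  # 1 5 (overlapping)
#' scan_are("TATTTAT")$count          # 1; DNA alphabet accepted
#' @export
scan_are <- function(sequence, motif = "UAUUUAU", id = NA_character_) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single nucleotide string")
  up <- toupper(sequence)
  bad <- regexpr("[^ACGTUN]", up)
  if (bad > 0)
    stop(sprintf("illegal character '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  dna <- chartr("U", "T", up)
  motif_dna <- chartr("U", "T", toupper(motif))
  positions <- if (nchar(dna) < nchar(motif_dna)) integer(0) else
    Biostrings::start(Biostrings::matchPattern(motif_dna,
                                               Biostrings::DNAString(dna)))
  structure(list(id = id, motif = toupper(motif),
                 positions = as.integer(positions),
                 count = length(positions)),
            class = "motif_hits")
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("ARE scan%s: motif %s, %d match(es)%s\n",
              if (is.na(x$id)) "" else paste0(" [", x$id, "]"),
              x$motif, x$count,
              if (x$count) paste0(" at ", paste(x$positions, collapse = ", "))
              else ""))
  invisible(x)
}

#' Scan every sequence of a FASTA file for ARE motifs
#'
#' @param path path to a FASTA file of 3' UTR sequences (DNA or RNA
#'   alphabet).
#' @param motif motif passed to [scan_are()].
#' @return data frame with one row per match (columns `seq_id`, `motif`,
#'   `position`) plus a `counts` attribute (named integer vector, one
#'   entry per sequence, including zero-match sequences).
#' @export
scan_are_fasta <- function(path, motif = "UAUUUAU") {
  seqs <- Biostrings::readBStringSet(path)
  hits <- lapply(seq_along(seqs), function(i)
    scan_are(as.character(seqs[[i]]), motif = motif, id = names(seqs)[i]))
  counts <- vapply(hits, `[[`, integer(1), "count")
  names(counts) <- names(seqs)
  out <- do.call(rbind, lapply(hits, function(h)
    if (h$count == 0) NULL else
      data.frame(seq_id = h$id, motif = h$motif, position = h$positions,
                 stringsAsFactors = FALSE)))
  if (is.null(out))
    out <- data.frame(seq_id = character(0), motif = character(0),
                      position = integer(0), stringsAsFactors = FALSE)
  attr(out, "counts") <- counts
  out
}
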