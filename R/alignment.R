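# Multiple-sequence-alignment ingestion and the per-position evolutionary
# conservation score (ECS): the fraction of alignment rows (including the
# reference row itself) carrying the reference residue at each reference
# position. Columns where the reference row has a gap define no position;
# gaps in non-reference rows count as mismatches.

#' Read an aligned FASTA file
#'
#' @param path FASTA file with at least two rows of equal aligned length.
#' @param ref_id identifier of the reference row (first whitespace-delimited
#'   token of the FASTA header). Defaults to the first row.
#' @return An object of class `msa_alignment`: list with `rows` (named
#'   character vector of gapped sequences, upper case), `ref_id`, and
#'   `n_total` (number of rows).
#' @export
read_alignment <- function(path, ref_id = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 2L) {
    stop("alignment must contain at least 2 sequences", call. = FALSE)
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: row lengths ",
         paste(sort(unique(widths)), collapse = ", "),
         " differ", call. = FALSE)
  }
  rows <- toupper(as.character(seqs))
  names(rows) <- ids
  if (is.null(ref_id)) ref_id <- ids[1L]
  if (!ref_id %in% ids) {
    stop("reference id '", ref_id, "' not found in alignment", call. = FALSE)
  }
  structure(list(rows = rows, ref_id = ref_id, n_total = length(rows)),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("Alignment:", x$n_total, "rows x", nchar(x$rows[[1L]]),
      "columns; reference:", x$ref_id, "\n")
  invisible(x)
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$rows), ""))
}

#' Evolutionary conservation score per reference position
#'
#' For each ungapped reference position `i`, computes
#' `ECS(i) = N_identical(i) / N_total`, where `N_identical(i)` counts the
#' alignment rows (the reference row included) whose residue in that column
#' equals the reference residue, and `N_total` is the number of rows. Gap
#' characters in non-reference rows count as mismatches.
#'
#' @param aln an `msa_alignment` from [read_alignment()].
#' @return Data frame with columns `position` (1-based ungapped reference
#'   coordinate), `ref_aa` (one-letter), `ecs` (in `(0, 1]`).
#' @export
compute_ecs <- function(aln) {
  stopifnot(inherits(aln, "msa_alignment"))
  mat <- alignment_matrix(aln)
  ref <- mat[match(aln$ref_id, names(aln$rows)), ]
  gap <- ref %in% c("-", ".")
  cols <- which(!gap)
  n_identical <- vapply(cols, function(j) sum(mat[, j] == ref[j]),
                        integer(1))
  data.frame(position = seq_along(cols),
             ref_aa = ref[cols],
             ecs = n_identical / aln$n_total,
             stringsAsFactors = FALSE)
}

#' Write a per-position conservation profile to CSV
#'
#' @param profile data frame from [compute_ecs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ecs <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
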