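# Curation of pathogenic / benign / VUS variant sets from ClinVar-style and
# population-database-style tables. All filters operate on plain data frames
# with one row per variant record; the identity key within one gene is
# (position, wt_aa, mut_aa).

VARIANT_COLUMNS <- c("gene", "hgvs_p", "significance", "n_submissions",
                     "in_1000g", "in_esp", "source", "consequence")

#' Read a variant table (CSV or TSV)
#'
#' Reads a delimited variant table with columns `gene`, `hgvs_p`,
#' `significance`, `n_submissions`, `in_1000g`, `in_esp`, `source` and
#' optionally `consequence`, parses the HGVS protein notation into
#' `wt_aa` / `position` / `mut_aa`, and derives `consequence` from the
#' notation when the column is absent.
#'
#' @param path path to a `.csv` or `.tsv`/`.txt` file. Booleans are
#'   `true`/`false` (case-insensitive).
#' @return A data frame of variant records.
#' @export
read_variant_table <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(VARIANT_COLUMNS, "consequence"), names(df))
  if (length(missing_cols)) {
    stop("variant table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("in_1000g", "in_esp")) {
    if (is.character(df[[col]])) {
      df[[col]] <- tolower(df[[col]]) %in% c("true", "t", "1", "yes")
    }
  }
  as_variant_records(df)
}

#' Attach parsed HGVS fields to a variant data frame
#'
#' @param df data frame with at least `hgvs_p`; `consequence` is derived
#'   from the notation when missing.
#' @return The data frame with `wt_aa`, `position`, `mut_aa` columns added.
#' @export
as_variant_records <- function(df) {
  parsed <- lapply(df$hgvs_p, parse_hgvs_protein)
  df$wt_aa <- vapply(parsed, `[[`, character(1), "wt_aa")
  df$position <- vapply(parsed, `[[`, integer(1), "position")
  df$mut_aa <- vapply(parsed, `[[`, character(1), "mut_aa")
  if (is.null(df$consequence) || all(is.na(df$consequence))) {
    df$consequence <- vapply(parsed, `[[`, character(1), "consequence")
  }
  if (is.null(df$n_submissions)) df$n_submissions <- NA_integer_
  df
}

variant_key <- function(df) {
  paste(df$position, df$wt_aa, df$mut_aa, sep = "|")
}

sort_variants <- function(df) {
  df <- df[order(df$position, df$mut_aa), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Curate the pathogenic variant set
#'
#' Keeps missense records asserted pathogenic, discards records with
#' conflicting interpretation, and discards records backed by a single
#' submission. The filter is idempotent and its output is sorted by
#' position and mutant residue.
#'
#' @param records data frame of variant records (see [as_variant_records()]).
#' @return Filtered, sorted data frame.
#' @export
curate_pathogenic <- function(records) {
  keep <- records$consequence == "missense" &
    records$significance == "pathogenic" &
    !is.na(records$n_submissions) & records$n_submissions >= 2
  sort_variants(records[keep, , drop = FALSE])
}

#' Curate the benign (non-pathogenic) variant set
#'
#' Two arms are combined. The ClinVar-style arm keeps missense records
#' labelled benign or likely benign (conflicting interpretations are
#' excluded by the label filter). The population arm keeps missense records
#' observed in the 1000 Genomes panel (`in_1000g = TRUE`) and absent from
#' the ESP disease-cohort panel (`in_esp = FALSE`). The two arms are merged
#' and deduplicated on the (position, wt_aa, mut_aa) identity key.
#'
#' @param clinvar data frame of ClinVar-style records.
#' @param population data frame of population-database records carrying
#'   `in_1000g` and `in_esp` flags.
#' @return Deduplicated union of the two accepted arms, sorted.
#' @export
curate_benign <- function(clinvar, population) {
  cv_keep <- clinvar$consequence == "missense" &
    clinvar$significance %in% c("benign", "likely_benign")
  cv <- clinvar[cv_keep, , drop = FALSE]
  pop_keep <- population$consequence == "missense" &
    population$in_1000g & !population$in_esp
  pop <- population[pop_keep, , drop = FALSE]
  shared <- intersect(names(cv), names(pop))
  merged <- rbind(cv[, shared, drop = FALSE], pop[, shared, drop = FALSE])
  merged <- merged[!duplicated(variant_key(merged)), , drop = FALSE]
  sort_variants(merged)
}

#' Curate the VUS set
#'
#' Keeps missense records of uncertain significance whose position falls in
#' the residue span resolved in the reference crystal structure; synonymous
#' and stop records are excluded.
#'
#' @param records data frame of variant records.
#' @param structure_range length-2 numeric, `c(min_pos, max_pos)` of the
#'   structurally resolved span.
#' @return Filtered, sorted data frame.
#' @export
curate_vus <- function(records, structure_range = c(1L, 854L)) {
  stopifnot(length(structure_range) == 2L,
            structure_range[1] <= structure_range[2])
  keep <- records$consequence == "missense" &
    records$significance == "uncertain" &
    records$position >= structure_range[1] &
    records$position <= structure_range[2]
  sort_variants(records[keep, , drop = FALSE])
}

#' Run all curation arms and enforce pairwise disjointness
#'
#' Applies [curate_pathogenic()], [curate_benign()] and [curate_vus()], then
#' removes any identity appearing in both the pathogenic and the benign set
#' from both (a controversial interpretation), and removes curated
#' pathogenic/benign identities from the VUS set.
#'
#' @param clinvar,population,vus input record data frames.
#' @param structure_range passed to [curate_vus()].
#' @return A list with elements `pathogenic`, `benign`, `vus` (class
#'   `curated_dataset`).
#' @export
curate_all <- function(clinvar, population, vus,
                       structure_range = c(1L, 854L)) {
  path <- curate_pathogenic(clinvar)
  ben <- curate_benign(clinvar, population)
  vus_set <- curate_vus(vus, structure_range)
  both <- intersect(variant_key(path), variant_key(ben))
  path <- path[!variant_key(path) %in% both, , drop = FALSE]
  ben <- ben[!variant_key(ben) %in% both, , drop = FALSE]
  labelled <- c(variant_key(path), variant_key(ben))
  vus_set <- vus_set[!variant_key(vus_set) %in% labelled, , drop = FALSE]
  structure(list(pathogenic = sort_variants(path),
                 benign = sort_variants(ben),
                 vus = sort_variants(vus_set)),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("Curated variant dataset:\n")
  cat("  pathogenic:", nrow(x$pathogenic), "\n")
  cat("  benign:    ", nrow(x$benign), "\n")
  cat("  vus:       ", nrow(x$vus), "\n")
  invisible(x)
}

#' Write curated sets to a single CSV with a `class` column
#'
#' @param curated a `curated_dataset` from [curate_all()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curated <- function(curated, path) {
  stopifnot(inherits(curated, "curated_dataset"))
  out <- do.call(rbind, lapply(names(curated), function(cl) {
    df <- curated[[cl]]
    if (!nrow(df)) return(NULL)
    df$class <- cl
    df
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
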