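#' @keywords internal
"_PACKAGE"

# Canonical amino-acid code tables. Internal canonical form is three-letter.
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")
names(AA1) <- AA3

#' Normalize an amino-acid code to the canonical three-letter form
#'
#' Accepts one-letter codes (`"G"`), three-letter codes in any case
#' (`"Gly"`, `"GLY"`), and the stop/synonymous markers `"Ter"`, `"*"`,
#' `"X"` (stop, canonicalized to `"Ter"`) and `"="` (synonymous marker,
#' returned as-is).
#'
#' @param code character scalar, a residue code.
#' @return Three-letter residue code, `"Ter"` or `"="`.
#' @export
#' @examples
#' aa_canonical("G")     # "Gly"
#' aa_canonical("ARG")   # "Arg"
aa_canonical <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  if (code == "=") return("=")
  if (toupper(code) %in% c("TER", "*", "X")) return("Ter")
  if (nchar(code) == 1L) {
    hit <- match(toupper(code), AA1)
    if (is.na(hit)) {
      stop("unknown one-letter amino-acid code: '", code, "'", call. = FALSE)
    }
    return(AA3[hit])
  }
  hit <- match(toupper(code), toupper(AA3))
  if (is.na(hit)) {
    stop("unknown amino-acid code: '", code, "'", call. = FALSE)
  }
  AA3[hit]
}

is_standard_aa <- function(code) {
  !inherits(tryCatch(aa_canonical(code), error = function(e) e), "error") &&
    aa_canonical(code) %in% AA3
}

#' Parse a protein-level HGVS substitution
#'
#' Parses strings such as `"p.Ala272Val"` into the wild-type residue,
#' 1-based protein position, and mutant residue. Mixed one-/three-letter
#' forms (`"p.G162Arg"`) are accepted; both codes are normalized to the
#' three-letter set. Stop gains are returned with `mut_aa = "Ter"` and
#' synonymous markers (`"="` or identical residues) with the wild-type
#' residue repeated.
#'
#' @param s character scalar starting with `"p."`.
#' @return A list with elements `wt_aa`, `position` (integer), `mut_aa`,
#'   and `consequence` (one of `"missense"`, `"synonymous"`, `"stop"`).
#' @export
#' @examples
#' parse_hgvs_protein("p.Ala272Val")
#' parse_hgvs_protein("p.G162Arg")
parse_hgvs_protein <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!startsWith(s, "p.")) {
    stop("malformed HGVS protein string '", s, "': must begin with 'p.'",
         call. = FALSE)
  }
  body <- substring(s, 3L)
  m <- regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3}|\\*|=)$", body)
  parts <- regmatches(body, m)[[1L]]
  if (length(parts) != 4L) {
    stop("malformed HGVS protein string '", s,
         "': cannot split '", body, "' into residue/position/residue",
         call. = FALSE)
  }
  wt <- tryCatch(aa_canonical(parts[2L]), error = function(e) {
    stop("malformed HGVS protein string '", s, "': bad wild-type token '",
         parts[2L], "'", call. = FALSE)
  })
  pos <- as.integer(parts[3L])
  if (is.na(pos) || pos < 1L) {
    stop("malformed HGVS protein string '", s, "': bad position token '",
         parts[3L], "'", call. = FALSE)
  }
  mut <- tryCatch(aa_canonical(parts[4L]), error = function(e) {
    stop("malformed HGVS protein string '", s, "': bad mutant token '",
         parts[4L], "'", call. = FALSE)
  })
  if (!wt %in% AA3) {
    stop("malformed HGVS protein string '", s,
         "': wild-type residue must be a standard amino acid", call. = FALSE)
  }
  consequence <-
    if (mut == "Ter") "stop"
    else if (mut == "=" || mut == wt) "synonymous"
    else "missense"
  if (mut == "=") mut <- wt
  list(wt_aa = wt, position = pos, mut_aa = mut, consequence = consequence)
}

#' Format a substitution back to HGVS protein notation
#'
#' Inverse of [parse_hgvs_protein()] on its canonical output.
#'
#' @param wt_aa,mut_aa residue codes (any accepted form).
#' @param position 1-based protein position.
#' @return Character scalar, e.g. `"p.Ala272Val"`.
#' @export
format_hgvs_protein <- function(wt_aa, position, mut_aa) {
  paste0("p.", aa_canonical(wt_aa), as.integer(position), aa_canonical(mut_aa))
}
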