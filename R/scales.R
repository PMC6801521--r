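# Residue property scales used by the property-distance and residue-delta
# features. The hydrophobicity column is the Fauchere-Pliska (1983)
# octanol/water side-chain transfer free-energy scale (kcal/mol); volumes
# are the Zamyatnin (1972) residue volumes (cubic Angstrom); charge is +1
# for Arg/Lys, -1 for Asp/Glu and 0 otherwise (histidine neutral); polarity
# is the standard polar/nonpolar partition. Any user scale with the same
# columns can be supplied instead.

.default_scales <- data.frame(
  residue = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val"),
  hydrophobicity = c(0.31, -1.01, -0.60, -0.77, 1.54, -0.22, -0.64, 0.00,
                     0.13, 1.80, 1.70, -0.99, 1.23, 1.79, 0.72, -0.04, 0.26,
                     2.25, 0.96, 1.22),
  charge = c(0L, 1L, 0L, -1L, 0L, 0L, -1L, 0L, 0L,
             0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
  volume = c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1, 153.2,
             166.7, 166.7, 168.6, 162.9, 189.9, 112.7, 89.0, 116.1, 227.8,
             193.6, 140.0),
  polarity = c("nonpolar", "polar", "polar", "polar", "polar", "polar",
               "polar", "nonpolar", "polar", "nonpolar", "nonpolar",
               "polar", "nonpolar", "nonpolar", "nonpolar", "polar",
               "polar", "nonpolar", "polar", "nonpolar"),
  stringsAsFactors = FALSE
)

#' Default residue property scales
#'
#' Returns the packaged scale table: one row per standard residue with
#' `hydrophobicity` (side-chain octanol/water transfer free energy,
#' kcal/mol), `charge` (+1 Arg/Lys, -1 Asp/Glu, else 0), `volume`
#' (residue volume, cubic Angstrom) and `polarity`
#' (`"polar"`/`"nonpolar"`).
#'
#' @return Data frame with 20 rows.
#' @export
default_property_scales <- function() {
  .default_scales
}

#' Read a user-supplied property scale table
#'
#' @param path CSV with columns `residue`, `hydrophobicity`, `charge`,
#'   `volume`, `polarity`; residues in any accepted code form.
#' @return Validated scale data frame (residues canonicalized).
#' @export
read_property_scales <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "hydrophobicity", "charge", "volume", "polarity")
  if (!all(need %in% names(df))) {
    stop("scale file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$residue <- vapply(df$residue, aa_canonical, character(1))
  missing <- setdiff(AA3, df$residue)
  if (length(missing)) {
    stop("scale file lacks residue(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- df$residue[df$charge == 1L & !df$residue %in% c("Arg", "Lys")]
  bad <- c(bad, df$residue[df$charge == -1L & !df$residue %in% c("Asp", "Glu")])
  if (length(bad)) {
    stop("unexpected nonzero charge for residue(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

scale_lookup <- function(residue, column, scales) {
  res <- aa_canonical(residue)
  if (!res %in% AA3) {
    stop("nonstandard residue: '", residue, "'", call. = FALSE)
  }
  scales[[column]][match(res, scales$residue)]
}

#' Property distance between wild-type and mutant residue
#'
#' Euclidean distance in the two-dimensional (hydrophobicity, charge)
#' property plane:
#' `sqrt((H(wt) - H(mut))^2 + (Q(wt) - Q(mut))^2)`.
#' Symmetric and non-negative; zero for identical residues.
#'
#' @param wt,mut residue codes (one- or three-letter).
#' @param scales scale table, see [default_property_scales()].
#' @return Non-negative numeric scalar.
#' @export
#' @examples
#' property_distance("Arg", "Asp")  # charge term alone contributes 2
property_distance <- function(wt, mut, scales = default_property_scales()) {
  dh <- scale_lookup(wt, "hydrophobicity", scales) -
    scale_lookup(mut, "hydrophobicity", scales)
  dq <- scale_lookup(wt, "charge", scales) -
    scale_lookup(mut, "charge", scales)
  sqrt(dh^2 + dq^2)
}

#' Size, charge and polarity changes upon mutation
#'
#' @param wt,mut residue codes.
#' @param scales scale table.
#' @return List with `size_change` (volume(mut) - volume(wt), cubic
#'   Angstrom), `charge_change` (integer), and `polarity_change` (1 if the
#'   polar/nonpolar class differs, else 0).
#' @export
residue_deltas <- function(wt, mut, scales = default_property_scales()) {
  list(
    size_change = scale_lookup(mut, "volume", scales) -
      scale_lookup(wt, "volume", scales),
    charge_change = as.integer(scale_lookup(mut, "charge", scales) -
                                 scale_lookup(wt, "charge", scales)),
    polarity_change = as.integer(scale_lookup(mut, "polarity", scales) !=
                                   scale_lookup(wt, "polarity", scales))
  )
}
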