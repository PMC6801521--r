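# Published reference values shipped with the package (defined in code so
# the package carries no binary data files).

#' Reported single-feature AUC values for the MSH2 benchmark
#'
#' Oriented ROC-AUC values reported for the 22 candidate features on the
#' curated MSH2 pathogenic/benign discrimination task, used to reproduce
#' the feature-screening step from printed values alone.
#'
#' @format Data frame with columns `feature` (names as in
#'   [FEATURE_NAMES]) and `auc`.
#' @export
msh2_reference_auc <- data.frame(
  feature = c("folding_ddg", "binding_dddg", "ecs", "avg_rmsd",
              "rmsd_change", "rmsf_mut", "rmsf_wt", "rmsf_change",
              "cum_rmsf_mut", "cum_rmsf_wt", "cum_rmsf_change",
              "hbond_mut", "hbond_wt", "hbond_change", "bfactor_wt",
              "rsasa_mut", "rsasa_wt", "rsasa_change",
              "property_distance", "size_change", "charge_change",
              "polarity_change"),
  auc = c(0.77, 0.53, 0.81, 0.80,
          0.65, 0.69, 0.80, 0.73,
          0.57, 0.61, 0.55,
          0.54, 0.52, 0.52, 0.69,
          0.69, 0.72, 0.50,
          0.70, 0.70, 0.54,
          0.70),
  stringsAsFactors = FALSE
)

#' Reported feature values for the four clinical MSH2 VUS
#'
#' The classifier features of the four breast-cancer-cohort VUS
#' (p.Tyr43Cys, p.Ala272Val, p.Asn547Ser, p.Met592Val): folding free-energy
#' change (kcal/mol), evolutionary conservation score, and RMSF of the
#' wild-type residue (Angstrom). Used as query rows when classifying the
#' VUS against a trained model.
#'
#' @format Data frame with columns `hgvs_p`, `folding_ddg`, `ecs`,
#'   `rmsf_wt`.
#' @export
msh2_vus_features <- data.frame(
  hgvs_p = c("p.Tyr43Cys", "p.Ala272Val", "p.Asn547Ser", "p.Met592Val"),
  folding_ddg = c(-1.228, -0.788, -0.260, -1.286),
  ecs = c(0.767, 0.877, 0.863, 0.575),
  rmsf_wt = c(4.559, 1.966, 5.725, 1.876),
  stringsAsFactors = FALSE
)
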