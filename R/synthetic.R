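# Seeded synthetic-data generators. These stand in for the study inputs
# that cannot be redistributed or recomputed at desk scale: molecular
# dynamics trajectories, stability-webserver ddG values, and database
# extracts. The class-conditional feature-table generator encodes the
# published summary statistics of the curated MSH2 pathogenic/benign sets
# as exact per-bin quotas, and couples the three classifier features
# within each variant so that the joint class structure (not just the
# marginals) matches the reported discrimination behaviour.

runif1 <- function(n, lo, hi) stats::runif(n, lo, hi)

#' Default class-conditional quota specification
#'
#' Describes the synthetic pathogenic (n = 34) and benign (n = 41) classes
#' as archetype blocks. Each block fixes a count and uniform supports for
#' the three classifier features (ECS, |folding ddG| in kcal/mol, RMSF of
#' the wild-type residue in Angstrom). The marginal bin counts implied by
#' the blocks are exact: 15/34 pathogenic ECS > 0.9, 14 pathogenic ECS in
#' \[0.8, 0.9\], 31/34 pathogenic RMSF in \[1, 2\] Angstrom, no pathogenic
#' |ddG| below 0.5 kcal/mol, 14/41 benign |ddG| at most 0.5 kcal/mol, 4/41
#' benign ECS > 0.9, and at most 10% of benign RMSF below 2 Angstrom.
#' Additional elements fix the pathogenic rSASA quota (20/34 below 0.1) and
#' the B-factor cluster (80-85 square Angstrom).
#'
#' @return A list with elements `pathogenic`, `benign` (archetype data
#'   frames), `rsasa` and `bfactor` supports.
#' @export
default_class_spec <- function() {
  arch <- function(n, ecs_lo, ecs_hi, ddg_lo, ddg_hi, rmsf_lo, rmsf_hi) {
    data.frame(n = n, ecs_lo = ecs_lo, ecs_hi = ecs_hi,
               ddg_lo = ddg_lo, ddg_hi = ddg_hi,
               rmsf_lo = rmsf_lo, rmsf_hi = rmsf_hi)
  }
  list(
    pathogenic = rbind(
      # conserved core: high ECS, destabilizing, rigid site
      arch(10, 0.905, 1.000, 1.10, 3.0, 1.00, 1.90),
      arch(9, 0.800, 0.900, 1.10, 3.0, 1.00, 1.90),
      # moderate ddG exceptions, still conserved and rigid
      arch(2, 0.905, 1.000, 0.55, 1.0, 1.00, 1.90),
      arch(5, 0.800, 0.900, 0.55, 1.0, 1.00, 1.90),
      # low-conservation exceptions, strongly destabilizing and rigid
      arch(5, 0.550, 0.795, 1.05, 1.8, 1.45, 2.00),
      # flexible-site exceptions, very conserved and strongly destabilizing
      arch(3, 0.950, 1.000, 2.01, 3.0, 2.05, 4.00)
    ),
    benign = rbind(
      # conserved but neutral and flexible
      arch(4, 0.905, 1.000, 0.05, 0.50, 3.00, 6.00),
      arch(10, 0.800, 0.900, 0.05, 0.50, 3.00, 6.00),
      # rigid-site exceptions: unconserved and near-neutral
      arch(4, 0.300, 0.400, 0.55, 0.78, 1.00, 1.45),
      # moderately destabilizing exceptions: unconserved and flexible
      arch(10, 0.300, 0.700, 1.01, 1.50, 4.00, 6.00),
      # unconserved bulk
      arch(13, 0.300, 0.750, 0.51, 0.80, 3.40, 6.00)
    ),
    rsasa = list(n_buried = 20L, buried = c(0.01, 0.095),
                 exposed = c(0.10, 0.80), benign = c(0.00, 0.80)),
    bfactor = list(pathogenic = c(80, 85), benign = c(65, 115)),
    avg_rmsd = list(pathogenic = c(8.5, 14), benign = c(5.5, 9))
  )
}

# filler features: class-independent apart from a modest location offset
# targeting a mid-range oriented AUC (never calibrated per feature)
filler_specs <- function() {
  f <- function(target_auc, mean, sd, dir = 1, transform = "none") {
    list(target_auc = target_auc, mean = mean, sd = sd, dir = dir,
         transform = transform)
  }
  list(
    binding_dddg = f(0.53, 0, 0.40),
    rmsd_change = f(0.65, 0.5, 1.20),
    rmsf_mut = f(0.69, 3.0, 1.20, transform = "pos"),
    rmsf_change = f(0.70, 0, 1.50, dir = -1),
    cum_rmsf_mut = f(0.57, 28, 7, transform = "pos"),
    cum_rmsf_wt = f(0.61, 25, 7, dir = -1, transform = "pos"),
    cum_rmsf_change = f(0.55, 0, 6),
    hbond_mut = f(0.54, 2.2, 1.1, transform = "count"),
    hbond_wt = f(0.52, 2.4, 1.1, transform = "count"),
    hbond_change = f(0.52, 0, 1.0, transform = "round"),
    rsasa_mut = f(0.69, 0.35, 0.22, dir = -1, transform = "unit"),
    rsasa_change = f(0.50, 0, 0.12),
    property_distance = f(0.70, 1.3, 0.8, transform = "pos"),
    size_change = f(0.70, 0, 55),
    charge_change = f(0.54, 0, 0.9, transform = "charge")
  )
}

draw_filler <- function(spec, n_path, n_ben) {
  delta <- spec$sd * sqrt(2) * stats::qnorm(spec$target_auc) * spec$dir
  v <- c(stats::rnorm(n_path, spec$mean + delta, spec$sd),
         stats::rnorm(n_ben, spec$mean, spec$sd))
  switch(spec$transform,
         none = v,
         pos = pmax(v, 0.2),
         unit = pmin(pmax(v, 0), 1),
         count = pmax(round(v), 0),
         round = round(v),
         charge = pmin(pmax(round(v), -2), 2))
}

draw_block <- function(blocks) {
  lapply(c(ecs = "ecs", ddg = "ddg", rmsf = "rmsf"), function(feat) {
    unlist(lapply(seq_len(nrow(blocks)), function(i) {
      runif1(blocks$n[i], blocks[[paste0(feat, "_lo")]][i],
             blocks[[paste0(feat, "_hi")]][i])
    }))
  })
}

random_variant_ids <- function(n, positions = 5:850) {
  pos <- sort(sample(positions, n))
  wt <- sample(AA3, n, replace = TRUE)
  mut <- vapply(wt, function(w) sample(setdiff(AA3, w), 1L), character(1))
  data.frame(gene = "MSH2",
             hgvs_p = paste0("p.", wt, pos, mut),
             wt_aa = wt, position = pos, mut_aa = mut,
             stringsAsFactors = FALSE)
}

#' Generate the class-conditional synthetic feature table
#'
#' Draws 34 pathogenic and 41 benign variants with all 22 feature columns.
#' The three classifier features follow the archetype blocks of the spec
#' (exact per-bin quotas, uniform within bins, jointly coupled per
#' variant); `folding_ddg` receives a random sign; rSASA and B-factor
#' quotas are exact; the remaining features are near-class-independent
#' draws with modest offsets. Deterministic under `seed`.
#'
#' @param seed integer seed.
#' @param spec quota specification, see [default_class_spec()].
#' @return A `feature_table` data frame: identity columns, `class`
#'   (pathogenic/benign), and the 22 columns of [FEATURE_NAMES].
#' @export
generate_feature_table <- function(seed = 1L, spec = default_class_spec()) {
  n_path <- sum(spec$pathogenic$n)
  n_ben <- sum(spec$benign$n)
  if (n_path != 34L || n_ben != 41L) {
    stop("quota specification must allocate 34 pathogenic and 41 benign ",
         "rows; got ", n_path, " + ", n_ben, call. = FALSE)
  }
  with_seed(seed, {
    ids <- random_variant_ids(n_path + n_ben)
    ids <- ids[sample(nrow(ids)), , drop = FALSE]
    p <- draw_block(spec$pathogenic)
    b <- draw_block(spec$benign)
    rs <- spec$rsasa
    rsasa_path <- sample(c(runif1(rs$n_buried, rs$buried[1], rs$buried[2]),
                           runif1(n_path - rs$n_buried,
                                  rs$exposed[1], rs$exposed[2])))
    df <- data.frame(
      class = rep(c("pathogenic", "benign"), c(n_path, n_ben)),
      folding_ddg = c(p$ddg, b$ddg) * sample(c(-1, 1), n_path + n_ben,
                                             replace = TRUE),
      ecs = c(p$ecs, b$ecs),
      rmsf_wt = c(p$rmsf, b$rmsf),
      avg_rmsd = c(runif1(n_path, spec$avg_rmsd$pathogenic[1],
                          spec$avg_rmsd$pathogenic[2]),
                   runif1(n_ben, spec$avg_rmsd$benign[1],
                          spec$avg_rmsd$benign[2])),
      rsasa_wt = c(rsasa_path,
                   runif1(n_ben, rs$benign[1], rs$benign[2])),
      bfactor_wt = c(runif1(n_path, spec$bfactor$pathogenic[1],
                            spec$bfactor$pathogenic[2]),
                     runif1(n_ben, spec$bfactor$benign[1],
                            spec$bfactor$benign[2])),
      stringsAsFactors = FALSE)
    for (nm in names(filler_specs())) {
      df[[nm]] <- draw_filler(filler_specs()[[nm]], n_path, n_ben)
    }
    df$polarity_change <- c(stats::rbinom(n_path, 1, 0.7),
                            stats::rbinom(n_ben, 1, 0.3))
    # shuffle pathogenic draws within class so archetypes are not ordered
    out <- cbind(ids, df)
    out <- out[order(out$position), , drop = FALSE]
    rownames(out) <- NULL
    out <- out[, c(names(ids), "class", FEATURE_NAMES)]
    class(out) <- c("feature_table", "data.frame")
    out
  })
}

#' Generate an alignment realizing a target conservation profile
#'
#' Builds an ungapped alignment of `n_rows` sequences whose computed ECS at
#' each position equals the nearest attainable fraction `k / n_rows` (with
#' `k >= 1`, since the reference row always matches itself).
#'
#' @param n_rows number of alignment rows (default 73).
#' @param length number of positions (ignored when `target_ecs` is given).
#' @param target_ecs numeric vector of per-position targets in `(0, 1]`;
#'   default: uniform random targets.
#' @param seed integer seed.
#' @param path optional FASTA output path.
#' @return An `msa_alignment` (reference row id `"ref"`); written to `path`
#'   when given.
#' @export
generate_msa <- function(n_rows = 73L, length = 50L, target_ecs = NULL,
                         seed = 1L, path = NULL) {
  with_seed(seed, {
    if (is.null(target_ecs)) target_ecs <- stats::runif(length, 0.3, 1)
    L <- base::length(target_ecs)
    mat <- matrix("", nrow = n_rows, ncol = L)
    ref <- sample(AA1, L, replace = TRUE)
    for (j in seq_len(L)) {
      k <- max(1L, min(n_rows, round(target_ecs[j] * n_rows)))
      match_rows <- c(1L, sample(2:n_rows, k - 1L))
      mat[, j] <- vapply(seq_len(n_rows), function(r) {
        if (r %in% match_rows) ref[j] else sample(setdiff(AA1, ref[j]), 1L)
      }, character(1))
    }
    rows <- apply(mat, 1, paste, collapse = "")
    names(rows) <- c("ref", paste0("sp", seq_len(n_rows - 1L)))
    aln <- structure(list(rows = rows, ref_id = "ref", n_total = n_rows),
                     class = "msa_alignment")
    if (!is.null(path)) {
      Biostrings::writeXStringSet(Biostrings::BStringSet(rows), path)
    }
    aln
  })
}

# idealized alpha-helix C-alpha trace (radius 2.3 A, rise 1.5 A/residue,
# 100 degrees/residue) -- non-collinear by construction
helix_trace <- function(n_residues) {
  i <- seq_len(n_residues) - 1L
  ang <- i * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
}

#' Generate a toy peptide structure (PDB)
#'
#' Writes an idealized-geometry glycine peptide with one backbone
#' N/CA/C/O unit per residue. Residues listed in `buried` are surrounded
#' by a spherical cage of carbon atoms (chain `X`) so that their relative
#' solvent accessibility downstream is small; others stay fully exposed.
#' Per-residue B-factors can be planned exactly.
#'
#' @param n_residues number of residues.
#' @param buried integer vector of residue numbers to enclose.
#' @param bfactors numeric vector (length `n_residues`) of B-factors
#'   applied to every atom of each residue; default 20.
#' @param spacing inter-residue spacing, Angstrom (default 12: residues do
#'   not shield one another).
#' @param seed integer seed (cage orientation).
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
generate_toy_structure <- function(n_residues, buried = integer(0),
                                   bfactors = rep(20, n_residues),
                                   spacing = 12, seed = 1L,
                                   path = tempfile(fileext = ".pdb")) {
  stopifnot(n_residues >= 1L, length(bfactors) == n_residues)
  with_seed(seed, {
    unit <- rbind(N = c(0, 1.33, 0), CA = c(0, 0, 0),
                  C = c(1.52, 0, 0), O = c(2.1, 1.0, 0))
    rows <- list()
    for (r in seq_len(n_residues)) {
      base <- c((r - 1) * spacing, 0, 0)
      for (a in rownames(unit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chain = "A", resnum = r, resname = "GLY", atom_name = a,
          element = substr(a, 1, 1),
          x = unit[a, 1] + base[1], y = unit[a, 2] + base[2],
          z = unit[a, 3] + base[3], b = bfactors[r])
      }
      if (r %in% buried) {
        cage <- sphere_points(80) * 4.6
        centroid <- colMeans(unit) + base
        for (q in seq_len(nrow(cage))) {
          rows[[length(rows) + 1L]] <- data.frame(
            chain = "X", resnum = 1000L + 100L * r + q, resname = "CAG",
            atom_name = "C", element = "C",
            x = cage[q, 1] + centroid[1], y = cage[q, 2] + centroid[2],
            z = cage[q, 3] + centroid[3], b = 0)
        }
      }
    }
    at <- do.call(rbind, rows)
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(at)),
                     resno = at$resnum, resid = at$resname,
                     eleno = seq_len(nrow(at)), elety = at$atom_name,
                     chain = at$chain, b = at$b, elesy = at$element)
  })
  invisible(path)
}

#' Generate a synthetic trajectory with known per-residue fluctuations
#'
#' Writes a multi-model PDB of a C-alpha helix trace jittered frame-by-frame
#' with isotropic Gaussian noise of per-coordinate standard deviation
#' `rmsf_targets / sqrt(3)`, so the downstream per-residue RMSF converges to
#' `rmsf_targets` as the number of frames grows.
#'
#' @param n_frames number of frames (>= 10).
#' @param rmsf_targets numeric vector of target RMSF values (Angstrom), one
#'   per residue.
#' @param seed integer seed.
#' @param path output multi-model PDB path.
#' @return `path`, invisibly.
#' @export
generate_trajectory <- function(n_frames, rmsf_targets, seed = 1L,
                                path = tempfile(fileext = ".pdb")) {
  stopifnot(n_frames >= 10L)
  n_res <- length(rmsf_targets)
  base <- helix_trace(n_res)
  sigma <- rmsf_targets / sqrt(3)
  with_seed(seed, {
    xyz <- matrix(NA_real_, nrow = n_frames, ncol = 3L * n_res)
    for (f in seq_len(n_frames)) {
      jitter <- matrix(stats::rnorm(3L * n_res, 0, rep(sigma, each = 3L)),
                       ncol = 3L, byrow = TRUE)
      xyz[f, ] <- as.numeric(t(base + jitter))
    }
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = rep("ATOM", n_res),
                     resno = seq_len(n_res),
                     resid = rep("ALA", n_res),
                     eleno = seq_len(n_res),
                     elety = rep("CA", n_res),
                     chain = rep("A", n_res),
                     b = rep(0, n_res),
                     elesy = rep("C", n_res))
  })
  invisible(path)
}

fixture_record <- function(ids, significance, n_submissions = 3L,
                           in_1000g = FALSE, in_esp = FALSE,
                           source = "clinvar", consequence = NULL) {
  n <- nrow(ids)
  df <- ids
  df$significance <- significance
  df$n_submissions <- n_submissions
  df$in_1000g <- in_1000g
  df$in_esp <- in_esp
  df$source <- source
  if (!is.null(consequence)) df$consequence <- consequence else {
    df$consequence <- vapply(df$hgvs_p, function(s)
      parse_hgvs_protein(s)$consequence, character(1))
  }
  df
}

#' Generate a ClinVar-like curation fixture
#'
#' Produces three record tables — a ClinVar-style table, a population
#' (EXAC/1000G/ESP-style) table, and a clinical VUS table — engineered so
#' that every curation filter branch is exercised by at least one record
#' and the curated arm sizes come out at 34 pathogenic, 41 benign (20
#' ClinVar-arm + 26 population-arm with 5 shared identities) and 4 VUS
#' (from 7 candidates: one beyond the resolved structure span, one
#' synonymous, one stop).
#'
#' @param seed integer seed (default 0).
#' @param out_dir optional directory; when given, writes `clinvar.csv`,
#'   `population.csv`, `vus.csv`.
#' @return List of data frames `clinvar`, `population`, `vus`.
#' @export
generate_clinvar_fixture <- function(seed = 0L, out_dir = NULL) {
  with_seed(seed, {
    ids <- random_variant_ids(34 + 3 + 2 + 2 + 20 + 1 + 21 + 3 + 3,
                              positions = 5:850)
    ids <- ids[sample(nrow(ids)), , drop = FALSE]
    take <- function(n) {
      out <- ids[seq_len(n), , drop = FALSE]
      ids <<- ids[-seq_len(n), , drop = FALSE]
      out
    }
    path_ok <- fixture_record(take(34), "pathogenic",
                              n_submissions = sample(2:9, 34, replace = TRUE))
    path_single <- fixture_record(take(3), "pathogenic", n_submissions = 1L)
    conflicting <- fixture_record(take(2), "conflicting")
    likely_path <- fixture_record(take(2), "likely_pathogenic")
    benign_cv <- fixture_record(take(20),
                                sample(rep(c("benign", "likely_benign"),
                                           c(12, 8))))
    stop_rec <- take(1)
    stop_rec$hgvs_p <- sub("[A-Za-z]{3}$", "Ter", stop_rec$hgvs_p)
    stop_rec$mut_aa <- "Ter"
    benign_stop <- fixture_record(stop_rec, "benign", consequence = "stop")
    clinvar <- rbind(path_ok, path_single, conflicting, likely_path,
                     benign_cv, benign_stop)

    shared <- benign_cv[sample(20, 5), , drop = FALSE]
    pop_new <- take(21)
    pop_ok <- fixture_record(rbind(shared[, names(pop_new)], pop_new),
                             "uncertain", in_1000g = TRUE, in_esp = FALSE,
                             source = "exac")
    pop_not1000g <- fixture_record(take(3), "uncertain",
                                   in_1000g = FALSE, in_esp = FALSE,
                                   source = "exac")
    pop_esp <- fixture_record(take(3), "uncertain",
                              in_1000g = TRUE, in_esp = TRUE,
                              source = "exac")
    population <- rbind(pop_ok, pop_not1000g, pop_esp)

    vus_ids <- data.frame(
      gene = "MSH2",
      hgvs_p = c("p.Tyr43Cys", "p.Ala272Val", "p.Asn547Ser", "p.Met592Val",
                 "p.Thr934Met", "p.Cys31=", "p.Arg100Ter"),
      stringsAsFactors = FALSE)
    vus_ids <- as_variant_records(vus_ids)
    vus <- fixture_record(vus_ids[, c("gene", "hgvs_p", "wt_aa", "position",
                                      "mut_aa")],
                          "uncertain", n_submissions = 1L, source = "study")
    rownames(clinvar) <- rownames(population) <- rownames(vus) <- NULL
    out <- list(clinvar = clinvar, population = population, vus = vus)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(out)) {
        utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    out
  })
}
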