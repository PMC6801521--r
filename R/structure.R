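# Structure-derived features: B-factor extraction, Shrake-Rupley solvent
# accessible surface area with a deterministic spiral point set, relative
# SASA against the same residue extracted alone, and geometric hydrogen-bond
# counting with a 3.5 Angstrom / 60 degree criterion.

# van der Waals radii (Angstrom) by element
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90)

#' Read a PDB structure into a flat atom table
#'
#' Wraps [bio3d::read.pdb()] and returns a `structure_model`: a data frame
#' of atoms (`chain`, `resnum`, `resname`, `atom_name`, `element`, `x`,
#' `y`, `z`, `b_factor`) plus the per-chain resolved residue range.
#' Alternate locations other than the first are dropped; duplicate
#' (chain, resnum, atom_name) keys are an error.
#'
#' @param path PDB file.
#' @return Object of class `structure_model`: list with `atoms` (data
#'   frame) and `resolved_range` (data frame `chain`, `min_pos`, `max_pos`).
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  coords <- suppressWarnings(cbind(
    as.numeric(substr(lines[rec], 31, 38)),
    as.numeric(substr(lines[rec], 39, 46)),
    as.numeric(substr(lines[rec], 47, 54))))
  if (any(!is.finite(coords))) {
    bad <- which(rec)[which(rowSums(!is.finite(coords)) > 0)[1L]]
    stop("unreadable coordinate record at line ", bad, " of ", path,
         call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("A", "1")
  at <- at[keep, , drop = FALSE]
  element <- toupper(at$elesy)
  no_elem <- is.na(element) | element == ""
  element[no_elem] <- substr(gsub("[^A-Za-z].*$", "",
                                  gsub("^[0-9]", "", at$elety[no_elem])),
                             1, 1)
  atoms <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                      resnum = at$resno,
                      resname = at$resid,
                      atom_name = at$elety,
                      element = toupper(element),
                      x = at$x, y = at$y, z = at$z,
                      b_factor = at$b,
                      stringsAsFactors = FALSE)
  key <- paste(atoms$chain, atoms$resnum, atoms$atom_name)
  if (anyDuplicated(key)) {
    stop("duplicate atom key in ", path, ": ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  rng <- do.call(rbind, lapply(split(atoms$resnum, atoms$chain), range))
  resolved_range <- data.frame(chain = rownames(rng),
                               min_pos = rng[, 1], max_pos = rng[, 2],
                               stringsAsFactors = FALSE)
  rownames(resolved_range) <- NULL
  structure(list(atoms = atoms, resolved_range = resolved_range),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure model:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resnum))), "residues,",
      nrow(x$resolved_range), "chain(s)\n")
  invisible(x)
}

residue_atoms <- function(model, chain, resnum) {
  sel <- model$atoms$chain == chain & model$atoms$resnum == resnum
  model$atoms[sel, , drop = FALSE]
}

#' Extract the C-alpha B-factor of a residue
#'
#' @param model a `structure_model`.
#' @param chain,resnum residue address.
#' @return Numeric B-factor (squared Angstrom).
#' @export
bfactor_ca <- function(model, chain, resnum) {
  res <- residue_atoms(model, chain, resnum)
  if (!nrow(res)) {
    stop("residue ", chain, ":", resnum, " not present in structure",
         call. = FALSE)
  }
  ca <- res[res$atom_name == "CA", , drop = FALSE]
  if (!nrow(ca)) {
    stop("residue ", chain, ":", resnum, " has no C-alpha atom",
         call. = FALSE)
  }
  ca$b_factor[1L]
}

# Deterministic, nearly uniform unit-sphere point set (golden-section
# spiral). Fixed for a given n, so SASA values are reproducible.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

atom_radii <- function(elements) {
  r <- VDW_RADII[elements]
  if (anyNA(r)) {
    stop("unknown element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  unname(r)
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Rolling-probe point-sampling SASA: each atom's solvent sphere of radius
#' `r_vdw + probe_radius` is sampled with a fixed spiral point set; a point
#' is accessible when it lies outside every other atom's solvent sphere.
#' Deterministic given `n_points`.
#'
#' @param model a `structure_model`.
#' @param probe_radius solvent probe radius, Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom.
#' @return Data frame `chain`, `resnum`, `resname`, `sasa` (squared
#'   Angstrom), one row per residue.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960) {
  atoms <- model$atoms
  stopifnot(nrow(atoms) >= 1L)
  radii <- atom_radii(atoms$element) + probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  atom_sasa <- numeric(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    ri <- radii[i]
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (radii + ri)^2 & seq_along(d2) != i)
    surf <- pts * ri + rep(xyz[i, ], each = n_points)
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        # strictly interior points are buried; points exactly on a
        # neighbour's surface (coincident spheres) are credited to the
        # lower-indexed atom so shared surface is counted once
        buried <- dj2 < radii[j]^2 - 1e-9
        if (j < i) buried <- buried | dj2 < radii[j]^2 + 1e-9
        acc <- acc & !buried
      }
      frac <- sum(acc) / n_points
    } else {
      frac <- 1
    }
    atom_sasa[i] <- frac * 4 * pi * ri^2
  }
  agg <- stats::aggregate(atom_sasa,
                          by = list(chain = atoms$chain,
                                    resnum = atoms$resnum),
                          FUN = sum)
  names(agg)[3] <- "sasa"
  first <- !duplicated(paste(atoms$chain, atoms$resnum))
  resname <- atoms$resname[first]
  names(resname) <- paste(atoms$chain[first], atoms$resnum[first])
  agg$resname <- resname[paste(agg$chain, agg$resnum)]
  agg <- agg[order(agg$chain, agg$resnum),
             c("chain", "resnum", "resname", "sasa")]
  rownames(agg) <- NULL
  agg
}

#' Relative solvent accessible surface area of one residue
#'
#' `rSASA(i) = SASA(i) / SASA_max(i)`, where the numerator is the residue's
#' SASA in the full structural context and the denominator is obtained by
#' running the identical SASA algorithm on the residue's atoms extracted
#' alone. An isolated single-residue model therefore has rSASA exactly 1.
#'
#' @inheritParams bfactor_ca
#' @param probe_radius,n_points as in [compute_sasa()].
#' @return Numeric in `[0, 1]` up to sampling tolerance.
#' @export
compute_rsasa <- function(model, chain, resnum,
                          probe_radius = 1.4, n_points = 960) {
  res <- residue_atoms(model, chain, resnum)
  if (!nrow(res)) {
    stop("residue ", chain, ":", resnum, " not present in structure",
         call. = FALSE)
  }
  ctx <- compute_sasa(model, probe_radius, n_points)
  num <- ctx$sasa[ctx$chain == chain & ctx$resnum == resnum]
  alone <- structure(list(atoms = res, resolved_range = NULL),
                     class = "structure_model")
  den <- compute_sasa(alone, probe_radius, n_points)$sasa
  if (den <= 0) {
    stop("degenerate geometry: isolated-residue SASA is zero for ",
         chain, ":", resnum, call. = FALSE)
  }
  num / den
}

# Donor and acceptor heavy atoms of the standard residues (N/O chemistry).
# Backbone N is a donor for every residue except proline; backbone O (and
# OXT) accepts everywhere.
hb_donor_atoms <- function(resname, atom_name) {
  side <- switch(resname,
    ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
    HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
    TRP = "NE1", TYR = "OH", character(0))
  bb <- if (identical(resname, "PRO")) character(0) else "N"
  atom_name %in% c(bb, side)
}

hb_acceptor_atoms <- function(resname, atom_name) {
  side <- switch(resname,
    ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1",
    GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), SER = "OG",
    THR = "OG1", TYR = "OH", character(0))
  atom_name %in% c("O", "OXT", side)
}

# Idealized hydrogen position for a donor heavy atom: 1.0 Angstrom from the
# donor, pointing away from the mean direction of its covalently bonded
# heavy-atom neighbours (within 1.8 Angstrom). Falls back to the
# donor->acceptor direction when the donor has no bonded neighbour. If the
# model carries explicit hydrogens bonded to the donor (within 1.25
# Angstrom), those are used instead.
donor_hydrogens <- function(atoms, d_idx, a_xyz) {
  dx <- c(atoms$x[d_idx], atoms$y[d_idx], atoms$z[d_idx])
  hyd <- which(atoms$element == "H")
  if (length(hyd)) {
    hxyz <- as.matrix(atoms[hyd, c("x", "y", "z")])
    d2 <- colSums((t(hxyz) - dx)^2)
    bonded <- hyd[d2 <= 1.25^2]
    if (length(bonded)) {
      return(as.matrix(atoms[bonded, c("x", "y", "z")]))
    }
  }
  heavy <- which(atoms$element != "H" & seq_len(nrow(atoms)) != d_idx)
  dir <- NULL
  if (length(heavy)) {
    nxyz <- as.matrix(atoms[heavy, c("x", "y", "z")])
    d2 <- colSums((t(nxyz) - dx)^2)
    nb <- heavy[d2 <= 1.8^2]
    if (length(nb)) {
      units <- t(vapply(nb, function(j) {
        v <- c(atoms$x[j], atoms$y[j], atoms$z[j]) - dx
        v / sqrt(sum(v^2))
      }, numeric(3)))
      m <- colMeans(units)
      if (sqrt(sum(m^2)) > 1e-6) dir <- -m / sqrt(sum(m^2))
    }
  }
  if (is.null(dir)) {
    v <- a_xyz - dx
    dir <- v / sqrt(sum(v^2))
  }
  matrix(dx + dir, nrow = 1)
}

hb_pair_ok <- function(atoms, d_idx, a_idx, distance_cutoff, angle_cutoff) {
  dx <- c(atoms$x[d_idx], atoms$y[d_idx], atoms$z[d_idx])
  ax <- c(atoms$x[a_idx], atoms$y[a_idx], atoms$z[a_idx])
  if (sum((dx - ax)^2) > distance_cutoff^2) return(FALSE)
  hs <- donor_hydrogens(atoms, d_idx, ax)
  for (r in seq_len(nrow(hs))) {
    h <- hs[r, ]
    v1 <- dx - h
    v2 <- ax - h
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    if (180 - ang <= angle_cutoff) return(TRUE)  # deviation from linearity
  }
  FALSE
}

#' Hydrogen-bond counts for one residue
#'
#' Counts donor-acceptor heavy-atom pairs between the given residue and the
#' rest of the model satisfying a geometric criterion: donor-acceptor
#' distance at most `distance_cutoff` and donor-hydrogen-acceptor deviation
#' from linearity at most `angle_cutoff` degrees. Hydrogens are taken from
#' the model when present, otherwise placed by idealized geometry. Pairs
#' within one residue are not counted. Each qualifying pair contributes once
#' to `n_donor` (residue's donor atom) or `n_acceptor` (residue's acceptor
#' atom); `n_total = n_acceptor + n_donor`.
#'
#' @inheritParams bfactor_ca
#' @param distance_cutoff heavy-atom distance cutoff, Angstrom.
#' @param angle_cutoff maximum deviation from linearity, degrees.
#' @return List with `n_acceptor`, `n_donor`, `n_total` (integers).
#' @export
count_hbonds <- function(model, chain, resnum,
                         distance_cutoff = 3.5, angle_cutoff = 60) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0, angle_cutoff < 180)
  atoms <- model$atoms
  in_res <- atoms$chain == chain & atoms$resnum == resnum
  if (!any(in_res)) {
    stop("residue ", chain, ":", resnum, " not present in structure",
         call. = FALSE)
  }
  is_donor <- mapply(hb_donor_atoms, atoms$resname, atoms$atom_name)
  is_acc <- mapply(hb_acceptor_atoms, atoms$resname, atoms$atom_name)
  n_donor <- 0L
  for (d in which(is_donor & in_res)) {
    for (a in which(is_acc & !in_res)) {
      if (hb_pair_ok(atoms, d, a, distance_cutoff, angle_cutoff)) {
        n_donor <- n_donor + 1L
      }
    }
  }
  n_acceptor <- 0L
  for (a in which(is_acc & in_res)) {
    for (d in which(is_donor & !in_res)) {
      if (hb_pair_ok(atoms, d, a, distance_cutoff, angle_cutoff)) {
        n_acceptor <- n_acceptor + 1L
      }
    }
  }
  list(n_acceptor = n_acceptor, n_donor = n_donor,
       n_total = n_acceptor + n_donor)
}

#' Per-residue structural feature table
#'
#' Convenience wrapper computing, for every residue of one chain, the
#' C-alpha B-factor, SASA, rSASA and hydrogen-bond counts.
#'
#' @param model a `structure_model`.
#' @param chain chain identifier.
#' @param probe_radius,n_points SASA parameters.
#' @param distance_cutoff,angle_cutoff H-bond criteria.
#' @return Data frame with one row per residue.
#' @export
structure_features <- function(model, chain = "A",
                               probe_radius = 1.4, n_points = 960,
                               distance_cutoff = 3.5, angle_cutoff = 60) {
  atoms <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  resnums <- sort(unique(atoms$resnum))
  ctx <- compute_sasa(model, probe_radius, n_points)
  rows <- lapply(resnums, function(rn) {
    res <- residue_atoms(model, chain, rn)
    alone <- structure(list(atoms = res), class = "structure_model")
    den <- compute_sasa(alone, probe_radius, n_points)$sasa
    num <- ctx$sasa[ctx$chain == chain & ctx$resnum == rn]
    hb <- count_hbonds(model, chain, rn, distance_cutoff, angle_cutoff)
    bf <- tryCatch(bfactor_ca(model, chain, rn),
                   error = function(e) NA_real_)
    data.frame(chain = chain, resnum = rn, resname = res$resname[1L],
               bfactor_ca = bf, sasa = num, rsasa = num / den,
               n_hbond_acceptor = hb$n_acceptor,
               n_hbond_donor = hb$n_donor,
               n_hbond_total = hb$n_total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
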