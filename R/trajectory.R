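# Trajectory statistics: least-squares (Kabsch) superposition, per-frame
# C-alpha RMSD, per-residue RMSF about the mean structure, and the
# 11-residue cumulative RMSF window.

#' Read a multi-model PDB as a trajectory
#'
#' Each MODEL block becomes one frame. Atom ordering must be consistent
#' across models; a model with a deviating atom count is reported by index.
#' By default only C-alpha atoms are retained.
#'
#' @param path multi-model PDB file.
#' @param selection atom-name filter (default `"CA"`); `NULL` keeps all
#'   atoms.
#' @return Object of class `trajectory`: list with `atom_meta` (data frame
#'   `chain`, `resnum`, `atom_name`), `coords` (array frames x atoms x 3),
#'   and `selection`.
#' @export
read_trajectory <- function(path, selection = "CA") {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) >= 2L) {
    ends <- grep("^ENDMDL", lines)
    counts <- vapply(seq_along(model_starts), function(i) {
      seg <- lines[model_starts[i]:ends[i]]
      sum(grepl("^(ATOM  |HETATM)", seg))
    }, integer(1))
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1L])[1L]
      stop("model ", bad, " has ", counts[bad],
           " atoms; expected ", counts[1L], call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3
  keep <- if (is.null(selection)) seq_len(n_atoms) else {
    which(at$elety %in% selection)
  }
  if (!length(keep)) {
    stop("selection '", paste(selection, collapse = ","),
         "' matches no atoms", call. = FALSE)
  }
  coords <- array(NA_real_, dim = c(n_frames, length(keep), 3))
  for (f in seq_len(n_frames)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[f, , ] <- m[keep, , drop = FALSE]
  }
  meta <- data.frame(chain = ifelse(is.na(at$chain[keep]), "A",
                                    at$chain[keep]),
                     resnum = at$resno[keep],
                     atom_name = at$elety[keep],
                     stringsAsFactors = FALSE)
  structure(list(atom_meta = meta, coords = coords, selection = selection),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[1], "frames x", dim(x$coords)[2],
      "atoms (selection:",
      if (is.null(x$selection)) "all" else x$selection, ")\n")
  invisible(x)
}

frame_coords <- function(traj, f) {
  matrix(traj$coords[f, , ], ncol = 3)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference`.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3,
#'   non-collinear.
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3), `rmsd_after`, and `fitted` (transformed mobile
#'   coordinates).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (nrow(mobile) < 3L) {
    stop("superposition needs at least 3 atoms", call. = FALSE)
  }
  cm <- colMeans(mobile); cr <- colMeans(reference)
  pm <- sweep(mobile, 2, cm); pr <- sweep(reference, 2, cr)
  if (svd(pr)$d[2] < 1e-8 * max(1, svd(pr)$d[1])) {
    stop("degenerate (collinear) reference geometry", call. = FALSE)
  }
  h <- t(pm) %*% pr
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- pm %*% t(rot)
  fitted <- sweep(fitted, 2, cr, `+`)
  rmsd_after <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% t(rot)),
       rmsd_after = rmsd_after, fitted = fitted)
}

raw_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame and average RMSD of a trajectory against a reference
#'
#' Each frame is (optionally) superposed onto the reference before the
#' RMSD is taken; the average over frames is the "average RMSD of all
#' protein structures" summary statistic.
#'
#' @param traj a `trajectory`.
#' @param reference n x 3 matrix or frame index (default: frame 1).
#' @param fit superpose each frame first (default `TRUE`).
#' @return List with `per_frame` (numeric vector, Angstrom) and `average`.
#' @export
trajectory_rmsd <- function(traj, reference = 1L, fit = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  if (nrow(ref) != dim(traj$coords)[2]) {
    stop("reference atom count (", nrow(ref),
         ") does not match trajectory selection (", dim(traj$coords)[2], ")",
         call. = FALSE)
  }
  per_frame <- vapply(seq_len(dim(traj$coords)[1]), function(f) {
    fr <- frame_coords(traj, f)
    if (fit) superpose(fr, ref)$rmsd_after else raw_rmsd(fr, ref)
  }, numeric(1))
  list(per_frame = per_frame, average = mean(per_frame))
}

#' Per-residue RMSF profile with 11-residue cumulative window
#'
#' Frames are superposed onto the first frame, the mean structure is
#' computed, frames are re-superposed onto that mean (one iteration), and
#' `RMSF(p) = sqrt(mean_f |x_f(p) - xbar(p)|^2)` is taken per C-alpha. The
#' cumulative column sums the RMSF over the 11-residue window `[p-5, p+5]`,
#' truncated at chain termini.
#'
#' @param traj a `trajectory` with at least 2 frames.
#' @param fit superpose frames before computing fluctuations (default
#'   `TRUE`; disable for pre-aligned synthetic trajectories).
#' @param skip_frames number of leading frames to discard (default 0).
#' @return Object of class `rmsf_profile`: data frame with `position`,
#'   `rmsf` (Angstrom), `cum_rmsf_11` (Angstrom).
#' @export
compute_rmsf <- function(traj, fit = TRUE, skip_frames = 0L) {
  stopifnot(inherits(traj, "trajectory"))
  n_frames <- dim(traj$coords)[1]
  use <- seq_len(n_frames)
  if (skip_frames > 0L) use <- use[-seq_len(skip_frames)]
  if (length(use) < 2L) {
    stop("RMSF needs at least 2 frames after skipping", call. = FALSE)
  }
  frames <- lapply(use, function(f) frame_coords(traj, f))
  if (fit) {
    frames <- lapply(frames, function(fr) superpose(fr, frames[[1L]])$fitted)
    mean_str <- Reduce(`+`, frames) / length(frames)
    frames <- lapply(frames, function(fr) superpose(fr, mean_str)$fitted)
  }
  mean_str <- Reduce(`+`, frames) / length(frames)
  sq <- Reduce(`+`, lapply(frames, function(fr) rowSums((fr - mean_str)^2)))
  rmsf <- sqrt(sq / length(frames))
  prof <- data.frame(position = traj$atom_meta$resnum, rmsf = rmsf)
  prof <- prof[order(prof$position), , drop = FALSE]
  rownames(prof) <- NULL
  prof$cum_rmsf_11 <- vapply(prof$position, function(p) {
    sum(prof$rmsf[prof$position >= p - 5 & prof$position <= p + 5])
  }, numeric(1))
  class(prof) <- c("rmsf_profile", "data.frame")
  prof
}

#' Cumulative RMSF over the 11-residue window centred on a position
#'
#' Sums the per-residue RMSF over `[position - 5, position + 5]`, truncated
#' at the profiled range.
#'
#' @param profile an `rmsf_profile` from [compute_rmsf()].
#' @param position residue position within the profiled range.
#' @return Numeric (Angstrom).
#' @export
cumulative_rmsf <- function(profile, position) {
  stopifnot(inherits(profile, "rmsf_profile"))
  if (!position %in% profile$position) {
    stop("position ", position, " outside profiled range", call. = FALSE)
  }
  sum(profile$rmsf[profile$position >= position - 5 &
                     profile$position <= position + 5])
}
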