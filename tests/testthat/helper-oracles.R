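# Independent oracles and small fixture builders shared across test files.
# Each oracle is written as a direct, unoptimized restatement of the
# definition it checks, separate from the package implementation.

# all-pairs Mann-Whitney AUC, ties counted one half
auc_oracle <- function(values, labels) {
  pos <- values[labels == "pathogenic"]
  neg <- values[labels == "benign"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# brute-force KNN over standardized features, majority vote with
# inverse-distance tie-break (loop form)
knn_oracle <- function(train_x, labels, query, k) {
  d <- numeric(nrow(train_x))
  for (i in seq_len(nrow(train_x))) {
    d[i] <- sqrt(sum((train_x[i, ] - query)^2))
  }
  nb <- order(d)[seq_len(k)]
  tab <- table(labels[nb])
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  w <- tapply(1 / pmax(d[nb], 1e-12), labels[nb], sum)
  names(w)[which.max(w)]
}

# Horn's closed-form quaternion superposition (independent of the
# SVD-based implementation); returns the minimized RMSD only
quaternion_rmsd <- function(mobile, reference) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  m <- t(p) %*% q
  nmat <- rbind(
    c(m[1,1] + m[2,2] + m[3,3], m[2,3] - m[3,2], m[3,1] - m[1,3],
      m[1,2] - m[2,1]),
    c(m[2,3] - m[3,2], m[1,1] - m[2,2] - m[3,3], m[1,2] + m[2,1],
      m[3,1] + m[1,3]),
    c(m[3,1] - m[1,3], m[1,2] + m[2,1], -m[1,1] + m[2,2] - m[3,3],
      m[2,3] + m[3,2]),
    c(m[1,2] - m[2,1], m[3,1] + m[1,3], m[2,3] + m[3,2],
      -m[1,1] - m[2,2] + m[3,3]))
  ev <- eigen(nmat, symmetric = TRUE)
  qv <- ev$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  rot <- rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  fitted <- p %*% t(rot)
  sqrt(mean(rowSums((fitted - q)^2)))
}

# one frame of a trajectory as an n x 3 matrix
get_frame <- function(traj, f) {
  matrix(traj$coords[f, , ], ncol = 3)
}

# random proper rotation matrix
random_rotation <- function() {
  qr_out <- qr(matrix(stats::rnorm(9), 3))
  r <- qr.Q(qr_out)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# structure_model built directly from an atom data frame
make_model <- function(atoms) {
  structure(list(atoms = atoms), class = "structure_model")
}

# two glycine backbone units; the second residue's amide N can donate to
# the first residue's carbonyl O across a gap of `no_distance` Angstrom
make_hbond_pair <- function(no_distance = 2.9) {
  atoms <- data.frame(
    chain = "A", resnum = c(1, 1, 1, 1, 2, 2, 2, 2),
    resname = "GLY",
    atom_name = c("N", "CA", "C", "O", "N", "CA", "C", "O"),
    element = c("N", "C", "C", "O", "N", "C", "C", "O"),
    x = c(no_distance + 5, no_distance + 6, no_distance + 7, no_distance,
          0, -1.45, -2.5, -3.5),
    y = c(10, 10, 10, 0, 0, 0, 1.0, 2.0),
    z = 0, b_factor = 0,
    stringsAsFactors = FALSE)
  make_model(atoms)
}

# variant record data frame from minimal field vectors
make_records <- function(hgvs, significance,
                         n_submissions = 3L, in_1000g = FALSE,
                         in_esp = FALSE, source = "clinvar",
                         consequence = NULL) {
  df <- data.frame(gene = "MSH2", hgvs_p = hgvs,
                   significance = significance,
                   n_submissions = n_submissions,
                   in_1000g = in_1000g, in_esp = in_esp,
                   source = source, stringsAsFactors = FALSE)
  if (!is.null(consequence)) df$consequence <- consequence
  as_variant_records(df)
}

expected_vus_calls <- c("benign", "pathogenic", "benign", "pathogenic")
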