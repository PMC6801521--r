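test_that("PDB reading preserves B-factors and rejects duplicate atoms", {
  pdb <- generate_toy_structure(2, bfactors = c(80, 12.5), seed = 1)
  model <- read_structure(pdb)
  expect_s3_class(model, "structure_model")
  expect_equal(bfactor_ca(model, "A", 1), 80)
  expect_equal(bfactor_ca(model, "A", 2), 12.5)
  expect_equal(model$resolved_range$min_pos[model$resolved_range$chain == "A"],
               1)

  dup <- tempfile(fileext = ".pdb")
  lines <- readLines(pdb)
  atom1 <- grep("^ATOM", lines, value = TRUE)[1]
  writeLines(append(lines, atom1, after = grep("^ATOM", lines)[1]), dup)
  expect_error(suppressWarnings(read_structure(dup)), "duplicate atom key")
})

test_that("unreadable coordinate records are reported with a line number", {
  bad <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA  GLY A   2       x.xxx   0.000   0.000  1.00 10.00           C"),
    bad)
  expect_error(read_structure(bad), "line 2")
})

test_that("missing residues and C-alphas are errors", {
  pdb <- generate_toy_structure(2, seed = 1)
  model <- read_structure(pdb)
  expect_error(bfactor_ca(model, "A", 900), "not present")
  no_ca <- make_model(data.frame(chain = "A", resnum = 1, resname = "GLY",
                                 atom_name = "N", element = "N",
                                 x = 0, y = 0, z = 0, b_factor = 1))
  expect_error(bfactor_ca(no_ca, "A", 1), "C-alpha")
})

test_that("SASA of an isolated atom matches the closed-form sphere area", {
  for (elem in c("C", "N", "O")) {
    one <- make_model(data.frame(chain = "A", resnum = 1, resname = "GLY",
                                 atom_name = elem, element = elem,
                                 x = 0, y = 0, z = 0, b_factor = 0))
    r <- c(C = 1.7, N = 1.55, O = 1.52)[[elem]]
    expect_equal(compute_sasa(one, 1.4, 960)$sasa,
                 4 * pi * (r + 1.4)^2, tolerance = 1e-6)
  }
  unknown <- make_model(data.frame(chain = "A", resnum = 1, resname = "GLY",
                                   atom_name = "XX", element = "ZZ",
                                   x = 0, y = 0, z = 0, b_factor = 0))
  expect_error(compute_sasa(unknown), "ZZ")
})

test_that("two coincident atoms expose the surface of one", {
  two <- make_model(data.frame(chain = "A", resnum = c(1, 1),
                               resname = "GLY",
                               atom_name = c("C1", "C2"), element = "C",
                               x = 0, y = 0, z = 0, b_factor = 0))
  # both atoms' accessible points coincide on one sphere surface
  expect_equal(sum(compute_sasa(two, 1.4, 960)$sasa),
               4 * pi * (1.7 + 1.4)^2, tolerance = 1e-6)
})

test_that("small-cluster SASA agrees with a 10x point-density oracle", {
  set.seed(5)
  atoms <- data.frame(chain = "A", resnum = rep(1:2, each = 3),
                      resname = "GLY",
                      atom_name = paste0("C", 1:6), element = "C",
                      x = runif(6, 0, 4), y = runif(6, 0, 4),
                      z = runif(6, 0, 4), b_factor = 0)
  model <- make_model(atoms)
  fast <- compute_sasa(model, 1.4, 960)
  dense <- compute_sasa(model, 1.4, 9600)
  expect_equal(fast$sasa, dense$sasa, tolerance = 0.02)
})

test_that("SASA is invariant under rigid motion and monotone under deletion", {
  set.seed(6)
  atoms <- data.frame(chain = "A", resnum = rep(1:2, each = 3),
                      resname = "GLY", atom_name = paste0("C", 1:6),
                      element = "C", x = runif(6, 0, 4), y = runif(6, 0, 4),
                      z = runif(6, 0, 4), b_factor = 0)
  base <- compute_sasa(make_model(atoms), 1.4, 960)
  rot <- random_rotation()
  moved <- atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  moved$x <- xyz[, 1] + 7; moved$y <- xyz[, 2] - 3; moved$z <- xyz[, 3] + 1
  expect_equal(compute_sasa(make_model(moved), 1.4, 960)$sasa,
               base$sasa, tolerance = 0.02)
  # removing residue 2's atoms can only increase residue 1's SASA
  pruned <- compute_sasa(make_model(atoms[atoms$resnum == 1, ]), 1.4, 960)
  expect_gte(pruned$sasa[1], base$sasa[base$resnum == 1] - 1e-9)
})

test_that("rSASA is 1 for an isolated residue and small for a caged one", {
  pdb <- generate_toy_structure(3, buried = 2, seed = 2)
  model <- read_structure(pdb)
  expect_equal(compute_rsasa(model, "A", 1, n_points = 480), 1.0)
  expect_lt(compute_rsasa(model, "A", 2, n_points = 480), 0.05)
  expect_lte(compute_rsasa(model, "A", 3, n_points = 480), 1 + 1e-9)
})

test_that("a crafted dipeptide rSASA matches a high-density oracle", {
  atoms <- data.frame(
    chain = "A", resnum = rep(1:2, each = 4), resname = "GLY",
    atom_name = rep(c("N", "CA", "C", "O"), 2),
    element = rep(c("N", "C", "C", "O"), 2),
    x = c(0, 1.45, 2.4, 2.4, 3.7, 5.1, 6.1, 6.1),
    y = c(0, 0, 1.1, 2.3, 0.9, 0.9, 2.0, 3.2),
    z = 0, b_factor = 0)
  model <- make_model(atoms)
  got <- compute_rsasa(model, "A", 1, n_points = 960)
  oracle_num <- compute_sasa(model, 1.4, 9600)
  alone <- make_model(atoms[atoms$resnum == 1, ])
  oracle <- oracle_num$sasa[oracle_num$resnum == 1] /
    compute_sasa(alone, 1.4, 9600)$sasa
  expect_equal(got, oracle, tolerance = 0.02)
  expect_lt(got, 1)  # context always shields part of the surface
})

test_that("hydrogen bonds obey the distance/angle criterion and symmetry", {
  model <- make_hbond_pair(2.9)
  donor_side <- count_hbonds(model, "A", 2)
  acceptor_side <- count_hbonds(model, "A", 1)
  expect_equal(donor_side$n_donor, 1L)
  expect_equal(acceptor_side$n_acceptor, 1L)
  # the same physical bond appears once on each side
  expect_equal(donor_side$n_donor, acceptor_side$n_acceptor)
  expect_equal(donor_side$n_total, donor_side$n_acceptor + donor_side$n_donor)

  stretched <- make_hbond_pair(5.0)
  expect_equal(count_hbonds(stretched, "A", 2)$n_total, 0L)

  # an isolated residue has no partners at all
  solo <- make_model(make_hbond_pair()$atoms[1:4, ])
  expect_equal(count_hbonds(solo, "A", 1)$n_total, 0L)
  expect_error(count_hbonds(solo, "A", 9), "not present")
})

test_that("crafted pair count equals an exhaustive pair scan and tightening cutoffs removes it", {
  model <- make_hbond_pair(2.9)
  atoms <- model$atoms
  # exhaustive enumeration: every (donor N, acceptor O/OXT) pair across
  # residues within 3.5 A, hydrogen taken along the donor's anti-neighbour
  # direction as the implementation documents
  donors <- which(atoms$atom_name == "N" & atoms$resname != "PRO")
  acceptors <- which(atoms$atom_name %in% c("O", "OXT"))
  found <- 0L
  for (d in donors) for (a in acceptors) {
    if (atoms$resnum[d] == atoms$resnum[a]) next
    dist <- sqrt(sum((atoms[d, c("x", "y", "z")] -
                        atoms[a, c("x", "y", "z")])^2))
    if (dist <= 3.5) found <- found + 1L
  }
  total <- count_hbonds(model, "A", 1)$n_total +
    count_hbonds(model, "A", 2)$n_total
  expect_equal(total, 2L * found)  # each pair counted on both residues
  # a near-zero angle tolerance rejects any geometry that is not collinear
  expect_lte(count_hbonds(model, "A", 2, angle_cutoff = 0.5)$n_total, 1L)
  expect_equal(count_hbonds(model, "A", 2,
                            distance_cutoff = 1.0)$n_total, 0L)
})

test_that("per-residue structural feature table is assembled coherently", {
  pdb <- generate_toy_structure(3, buried = 2, bfactors = c(5, 6, 7),
                                seed = 4)
  model <- read_structure(pdb)
  feats <- structure_features(model, "A", n_points = 240)
  expect_equal(feats$resnum, 1:3)
  expect_equal(feats$bfactor_ca, c(5, 6, 7))
  expect_lt(feats$rsasa[2], feats$rsasa[1])
  expect_equal(feats$n_hbond_total,
               feats$n_hbond_acceptor + feats$n_hbond_donor)
})
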