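# Fixtures are built in code: hand-placed atom tables with known geometry,
# plus small seeded corpora shared between tests.

# Atom table with explicit coordinates; one row per (name, element,
# residue_name, residue_seq, x, y, z, het) entry.
make_atoms <- function(..., structure_id = "toy") {
  rows <- list(...)
  tibble::tibble(
    structure_id = structure_id,
    serial = seq_along(rows),
    atom_name = vapply(rows, function(r) r$name, ""),
    element = vapply(rows, function(r) r$element, ""),
    residue_name = vapply(rows, function(r) r$res, ""),
    chain = "A",
    residue_seq = vapply(rows, function(r) r$seq, 1L),
    x = vapply(rows, function(r) r$xyz[1], 1),
    y = vapply(rows, function(r) r$xyz[2], 1),
    z = vapply(rows, function(r) r$xyz[3], 1),
    het = vapply(rows, function(r) isTRUE(r$het), TRUE),
    occupancy = 1
  )
}

atom <- function(name, element, res, seq, xyz, het = FALSE) {
  list(name = name, element = element, res = res, seq = as.integer(seq),
    xyz = xyz, het = het)
}

# Metal at origin; His closest heavy atom at 9.0 A, second atom beyond.
toy_his_structure <- function() {
  make_atoms(
    atom("CB", "C", "HIS", 1, c(9, 0, 0)),
    atom("CG", "C", "HIS", 1, c(9.5, 0, 0)),
    atom("MG", "MG", "MG", 2, c(0, 0, 0), het = TRUE)
  )
}

# Metal at origin; His@9, His@4, Lys@6 along orthogonal axes (one heavy
# atom each), giving hand-computable composition and geometry.
toy_three_residue_structure <- function() {
  make_atoms(
    atom("CB", "C", "HIS", 1, c(9, 0, 0)),
    atom("CB", "C", "HIS", 2, c(0, 4, 0)),
    atom("CB", "C", "LYS", 3, c(0, 0, 6)),
    atom("MG", "MG", "MG", 4, c(0, 0, 0), het = TRUE)
  )
}

# Rotation by `angle` about the z axis followed by translation.
rigid_transform <- function(atoms, angle = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(
    c(cos(angle), sin(angle), 0, -sin(angle), cos(angle), 0, 0, 0, 1),
    3, 3
  )
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

# 2-D two-class toy with hand-computed scatter:
# class1 = {(0,0),(2,0),(1,1)}, class2 = class1 shifted by (0,2).
# mu1 = (1, 1/3), mu2 = (1, 7/3), S1 = S2 = [[2,0],[0,2/3]],
# S_P = [[4,0],[0,4/3]], S_B = [[0,0],[0,4]].
toy_2d_features <- function() {
  tibble::tibble(
    label = rep(c("MG", "MN"), each = 3),
    f1 = c(0, 2, 1, 0, 2, 1),
    f2 = c(0, 0, 1, 2, 2, 3)
  )
}

# 1-D separation lifted into 25 dimensions: feature 1 carries the class,
# the rest are constant, so leave-one-out must be perfect.
separable_features <- function(n_per_class = 10) {
  p <- 25
  X <- matrix(0.5, 2 * n_per_class, p)
  X[, 1] <- rep(c(0, 10), each = n_per_class) +
    rep(seq(-0.4, 0.4, length.out = n_per_class), 2)
  colnames(X) <- feature_names()
  dplyr::bind_cols(
    tibble::tibble(label = rep(c("MG", "MN"), each = n_per_class)),
    tibble::as_tibble(X)
  )
}
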