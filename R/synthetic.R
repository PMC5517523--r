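#' Generate a synthetic corpus of metal-site structures
#'
#' Builds toy protein-like structures, each carrying exactly one divalent
#' metal heteroatom (MG or MN) at the origin surrounded by a shell of
#' amino-acid residues, emulating a balanced two-class corpus of
#' metal-bound crystal structures. Residue types are drawn from a
#' background distribution reweighted per class, so that by default
#' histidine is enriched around Mn-like sites and lysine around Mg-like
#' sites — the compositional asymmetry a site classifier should detect.
#' Each residue is a small cluster of 3-5 heavy atoms whose anchor atom is
#' placed at a distance drawn uniformly between `min_dist` and `radius`
#' from the metal, exercising the any-heavy-atom neighbourhood rule; full
#' side-chain realism is out of scope.
#'
#' @param n_per_class Structures per class (class balance is exact).
#' @param residues_per_site Integer range (length 2) of residues per
#'   structure; each structure draws uniformly from it.
#' @param enrichment Fold-enrichment factor `k` applied to the favoured
#'   residue of each class (default 3; `k = 1` removes the class signal).
#' @param enriched Named character vector mapping class to its enriched
#'   residue (default `c(MG = "LYS", MN = "HIS")`).
#' @param radius Placement shell radius in Angstrom (> 2).
#' @param min_dist Minimum metal-to-anchor distance (default 1.5 A, about
#'   the shortest plausible contact).
#' @param background `"uniform"` over the 20 amino acids, or a named
#'   probability vector over three-letter codes.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration and seed.
#' @return An atom tibble in [read_pdb()] layout covering all
#'   `2 * n_per_class` structures; `structure_id` is `"synth_MG_0001"`
#'   etc., and the metal element doubles as the true class label.
#' @examples
#' atoms <- generate_site_structures(n_per_class = 3, seed = 42)
#' dplyr::count(atoms[atoms$het, ], element)
#' @export
generate_site_structures <- function(n_per_class = 10,
                                     residues_per_site = c(8, 14),
                                     enrichment = 3,
                                     enriched = c(MG = "LYS", MN = "HIS"),
                                     radius = 10, min_dist = 1.5,
                                     background = "uniform",
                                     seed = NULL) {
  stopifnot(n_per_class >= 1, length(residues_per_site) == 2,
    residues_per_site[1] >= 1,
    residues_per_site[2] >= residues_per_site[1],
    all(enrichment > 0), radius > 2, min_dist > 0, min_dist < radius)
  if (identical(background, "uniform")) {
    bg <- setNames(rep(1 / 20, 20), AA20)
  } else {
    stopifnot(is.numeric(background), !is.null(names(background)),
      all(names(background) %in% AA20))
    bg <- setNames(rep(0, 20), AA20)
    bg[names(background)] <- background
    bg <- bg / sum(bg)
  }
  classes <- names(enriched)
  # crude feasibility check: shell volume vs excluded volume per residue
  max_res <- residues_per_site[2]
  shell_vol <- 4 / 3 * pi * (radius^3 - min_dist^3)
  if (max_res * 4 / 3 * pi * 1.0^3 > shell_vol) {
    abort("infeasible geometry: too many residues for the shell volume")
  }

  with_seed_maybe(seed, {
    purrr::map(classes, function(cl) {
      w <- bg
      w[enriched[[cl]]] <- w[enriched[[cl]]] * enrichment
      w <- w / sum(w)
      purrr::map(seq_len(n_per_class), function(i) {
        one_synthetic_structure(
          structure_id = sprintf("synth_%s_%04d", cl, i),
          metal = cl, weights = w,
          n_res = sample(seq(residues_per_site[1], residues_per_site[2]), 1),
          radius = radius, min_dist = min_dist
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
}

# Heavy-atom offsets (A) of the small residue fragment placed at each
# anchor: a backbone-like triad plus up to two side-chain-like atoms.
RESIDUE_FRAGMENT <- rbind(
  c(0, 0, 0),
  c(1.46, 0, 0),
  c(2.0, 1.4, 0),
  c(-0.8, 1.2, 0.6),
  c(2.9, 1.5, 1.2)
)
FRAGMENT_NAMES <- c("CA", "C", "O", "CB", "CG")

one_synthetic_structure <- function(structure_id, metal, weights, n_res,
                                    radius, min_dist) {
  res_types <- sample(AA20, n_res, replace = TRUE, prob = weights)
  n_atoms_per <- sample(3:5, n_res, replace = TRUE)
  total <- sum(n_atoms_per) + 1L
  xyz <- matrix(0, total, 3)
  at_name <- character(total)
  res_name <- character(total)
  res_seq <- integer(total)
  pos <- 1L
  for (r in seq_len(n_res)) {
    d <- runif(1, min_dist, radius)
    anchor <- d * random_unit_vector()
    na <- n_atoms_per[r]
    # random rotation of the fragment so geometry varies between residues
    R <- random_rotation()
    frag <- RESIDUE_FRAGMENT[seq_len(na), , drop = FALSE] %*% t(R)
    idx <- pos:(pos + na - 1L)
    xyz[idx, ] <- sweep(frag, 2, anchor, "+")
    at_name[idx] <- FRAGMENT_NAMES[seq_len(na)]
    res_name[idx] <- res_types[r]
    res_seq[idx] <- r
    pos <- pos + na
  }
  at_name[total] <- metal
  res_name[total] <- metal
  res_seq[total] <- n_res + 1L
  tibble::tibble(
    structure_id = structure_id,
    serial = seq_len(total),
    atom_name = at_name,
    element = c(substr(at_name[-total], 1, 1), metal),
    residue_name = res_name,
    chain = "A",
    residue_seq = res_seq,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    het = c(rep(FALSE, total - 1L), TRUE),
    occupancy = 1
  )
}

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) {
      return(v / n)
    }
  }
}

# Uniform random rotation via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a two-class Gaussian feature corpus with a planted direction
#'
#' Draws balanced multivariate Gaussian samples sharing one covariance,
#' with class means at \eqn{\mp \Delta/2} along a planted unit direction
#' (the second listed class sits at \eqn{+\Delta/2}, so it projects
#' higher, matching the discriminant's sign convention). With identity
#' covariance the Bayes-optimal accuracy is \eqn{\Phi(\Delta/2)}, which
#' makes these corpora exact calibration instruments for the classifier.
#'
#' @param n_per_class Samples per class (>= 2).
#' @param p Dimension (default 25; when 25, columns take the names of
#'   [feature_names()]).
#' @param delta Mean separation \eqn{\Delta} along the planted direction.
#' @param direction Optional unit p-vector; default: random direction.
#' @param covariance Shared covariance matrix (default identity); must be
#'   symmetric positive definite.
#' @param classes Pair of labels (default `c("MG", "MN")`).
#' @param seed Integer seed.
#' @return List with `features` (tibble: `site_id`, `label`, p feature
#'   columns) and `direction` (the planted unit vector).
#' @examples
#' corpus <- generate_gaussian_corpus(n_per_class = 100, delta = 2, seed = 9)
#' fit <- fit_lda(corpus$features)
#' abs(sum(fit$w * corpus$direction)) # close to 1
#' @export
generate_gaussian_corpus <- function(n_per_class, p = 25, delta = 2,
                                     direction = NULL, covariance = NULL,
                                     classes = c("MG", "MN"), seed = NULL) {
  stopifnot(n_per_class >= 2, p >= 2, delta >= 0, length(classes) == 2)
  if (!is.null(covariance)) {
    stopifnot(is.matrix(covariance), nrow(covariance) == p,
      isSymmetric(covariance, tol = 1e-10))
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) abort("covariance must be positive definite")
  } else {
    covariance <- diag(p)
  }
  with_seed_maybe(seed, {
    v <- direction %||% {
      z <- rnorm(p)
      z / sqrt(sum(z^2))
    }
    stopifnot(length(v) == p)
    v <- v / sqrt(sum(v^2))
    X1 <- MASS::mvrnorm(n_per_class, mu = -delta / 2 * v, Sigma = covariance)
    X2 <- MASS::mvrnorm(n_per_class, mu = +delta / 2 * v, Sigma = covariance)
    X <- rbind(X1, X2)
    colnames(X) <- if (p == 25) feature_names() else paste0("V", seq_len(p))
    features <- dplyr::bind_cols(
      tibble::tibble(
        site_id = sprintf("g_%s_%04d",
          rep(classes, each = n_per_class), rep(seq_len(n_per_class), 2)
        ),
        label = rep(classes, each = n_per_class)
      ),
      tibble::as_tibble(X)
    )
    list(features = features, direction = v)
  })
}
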