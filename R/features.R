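#' The 25-feature schema of a metal site
#'
#' Returns the fixed, ordered names of the site descriptor: counts of the
#' 20 standard amino acids within the neighbourhood radius (alphabetical by
#' three-letter code), followed by five geometric descriptors of the
#' neighbourhood — residue count, mean and minimum residue-to-metal
#' distance, and mean and maximum pairwise distance between residue
#' representative points (all distances in Angstrom).
#'
#' The schema is versioned (`"metallosite-25/1"`); users with an
#' alternative attribute table can swap in their own ordering by building
#' the feature tibble directly, as every downstream routine takes the
#' columns it is given.
#'
#' @return Character vector of length 25.
#' @export
feature_names <- function() {
  c(
    AA20,
    "n_residues",
    "mean_residue_to_site_distance",
    "mean_pairwise_residue_distance",
    "min_residue_to_site_distance",
    "max_pairwise_residue_distance"
  )
}

FEATURE_SCHEMA_VERSION <- "metallosite-25/1"

#' Compute the 25-dimensional descriptor of metal sites
#'
#' Tallies the residue composition of each site's neighbourhood and its
#' geometry into one row per site. An empty neighbourhood yields all-zero
#' features by convention. Residues with an unrecognised three-letter code
#' are dropped with a warning (they cannot be tallied into the fixed
#' composition schema).
#'
#' @param sites Site tibble from [find_metal_sites()].
#' @return A tibble with columns `site_id`, `label` (the metal element),
#'   and the 25 feature columns of [feature_names()].
#' @examples
#' atoms <- generate_site_structures(n_per_class = 2, seed = 7)
#' sites <- find_metal_sites(atoms)
#' compute_features(sites)
#' @export
compute_features <- function(sites) {
  stopifnot(is.data.frame(sites), "neighborhood" %in% names(sites))
  rows <- purrr::map2(
    sites$neighborhood, sites$radius,
    function(nb, radius) feature_row(nb)
  )
  feats <- dplyr::bind_rows(rows)
  if (nrow(sites) == 0) {
    feats <- tibble::as_tibble(
      setNames(rep(list(double()), 25), feature_names())
    )
  }
  dplyr::bind_cols(
    tibble::tibble(site_id = sites$site_id, label = sites$metal),
    feats
  )
}

feature_row <- function(nb) {
  unknown <- !(nb$residue_name %in% AA20)
  if (any(unknown)) {
    warn(paste0(
      "dropping ", sum(unknown), " neighbourhood residue(s) with ",
      "unrecognised code(s): ",
      paste(unique(nb$residue_name[unknown]), collapse = ", ")
    ))
    nb <- nb[!unknown, ]
  }
  counts <- as.numeric(table(factor(nb$residue_name, levels = AA20)))
  n <- nrow(nb)
  if (n == 0) {
    geo <- c(0, 0, 0, 0, 0)
  } else {
    pw <- if (n >= 2) {
      stats::dist(as.matrix(nb[, c("rx", "ry", "rz")]))
    } else {
      0
    }
    geo <- c(n, mean(nb$dist), mean(pw), min(nb$dist), max(pw))
  }
  tibble::as_tibble(as.list(setNames(c(counts, geo), feature_names())))
}

#' Extract a labelled feature matrix from structures
#'
#' The batch path from parsed structures to the analysis-ready feature
#' table: locates metal sites in every structure and computes each site's
#' descriptor, one row per site, labelled by the metal element and ordered
#' by `structure_id` then metal serial.
#'
#' @param atoms Atom tibble (possibly many structures), or a character
#'   vector of PDB file paths.
#' @param elements,radius,mode Passed to [find_metal_sites()].
#' @param on_error For file input: `"stop"` (default) re-raises a per-file
#'   parse error naming the file; `"continue"` skips unreadable files with
#'   a warning.
#' @return A labelled feature tibble as from [compute_features()].
#' @export
extract_features <- function(atoms, elements = c("MG", "MN"), radius = 10,
                             mode = "heavy", on_error = c("stop", "continue")) {
  on_error <- match.arg(on_error)
  if (is.character(atoms)) {
    parsed <- purrr::map(atoms, function(f) {
      tryCatch(read_pdb(f), error = function(e) {
        if (on_error == "stop") {
          abort(paste0("failed to parse '", f, "': ", conditionMessage(e)))
        }
        warn(paste0("skipping '", f, "': ", conditionMessage(e)))
        NULL
      })
    })
    atoms <- dplyr::bind_rows(purrr::compact(parsed))
    if (nrow(atoms) == 0) {
      return(compute_features(find_metal_sites(
        tibble::tibble(
          structure_id = character(), serial = integer(),
          atom_name = character(), element = character(),
          residue_name = character(), chain = character(),
          residue_seq = integer(), x = double(), y = double(), z = double(),
          het = logical(), occupancy = double()
        ),
        elements, radius
      )))
    }
  }
  sites <- find_metal_sites(atoms, elements = elements, radius = radius,
    mode = mode)
  compute_features(sites)
}

#' Read and write feature matrices as tab-delimited text
#'
#' The on-disk interchange format: a header row of `site_id`, `label` and
#' the 25 feature names, one data row per site. Round-trips losslessly.
#'
#' @param features Labelled feature tibble.
#' @param file Path.
#' @return `write_feature_matrix()` returns `file` invisibly;
#'   `read_feature_matrix()` returns the tibble.
#' @export
write_feature_matrix <- function(features, file) {
  readr::write_tsv(features, file)
  invisible(file)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(file) {
  readr::read_tsv(
    file,
    col_types = readr::cols(
      site_id = readr::col_character(),
      label = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}
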