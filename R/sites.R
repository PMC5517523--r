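#' Locate divalent-metal cofactor sites and their residue neighbourhoods
#'
#' Scans the heteroatoms of an atom table for metal ions and collects, for
#' each metal, the amino-acid residues lying within `radius` Angstrom. A
#' residue joins the neighbourhood when any of its heavy (non-hydrogen)
#' atoms is within the radius; its representative distance is the minimum
#' heavy-atom distance to the metal. Only the 20 standard amino acids
#' count: waters, nucleotides and other heteroatoms are never neighbours.
#'
#' @param atoms Atom tibble from [read_pdb()]; may contain several
#'   `structure_id`s.
#' @param elements Metal element symbols to look for (upper case).
#' @param radius Neighbourhood radius in Angstrom (> 0). The default 10 A
#'   is the shell conventionally used to describe a metallo-site's
#'   first and second coordination environment.
#' @param mode `"heavy"` (default): residue membership and representative
#'   point from the closest heavy atom. `"calpha"`: both taken from the
#'   C-alpha atom only.
#'
#' @return A tibble with one row per metal heteroatom found: `site_id`
#'   (`structure_id` + metal serial), `structure_id`, `serial`, `metal`,
#'   `x`, `y`, `z`, `radius`, `n_residues`, and a `neighborhood`
#'   list-column of per-residue tibbles (`chain`, `residue_seq`,
#'   `residue_name`, `dist` in Angstrom, and representative coordinates
#'   `rx`, `ry`, `rz`). Structures without matching metals contribute no
#'   rows.
#' @examples
#' atoms <- generate_site_structures(n_per_class = 1, seed = 1)
#' find_metal_sites(atoms)
#' @export
find_metal_sites <- function(atoms, elements = c("MG", "MN"), radius = 10,
                             mode = c("heavy", "calpha")) {
  stopifnot(is.data.frame(atoms), radius > 0, length(elements) > 0)
  mode <- match.arg(mode)
  elements <- toupper(elements)

  metals <- atoms |>
    dplyr::filter(.data$het, .data$element %in% elements |
      .data$residue_name %in% elements)

  empty <- tibble::tibble(
    site_id = character(), structure_id = character(), serial = integer(),
    metal = character(), x = double(), y = double(), z = double(),
    radius = double(), n_residues = integer(), neighborhood = list()
  )
  if (nrow(metals) == 0) {
    return(empty)
  }

  cand <- atoms |>
    dplyr::filter(.data$residue_name %in% AA20, !heavy_excluded(.data$element,
      .data$atom_name))
  if (mode == "calpha") {
    cand <- dplyr::filter(cand, .data$atom_name == "CA")
  }

  metals <- dplyr::arrange(metals, .data$structure_id, .data$serial)
  cand_by <- split(cand, cand$structure_id)
  rows <- purrr::pmap(
    list(
      metals$structure_id, metals$serial,
      ifelse(metals$element %in% elements, metals$element,
        metals$residue_name
      ),
      metals$x, metals$y, metals$z
    ),
    function(sid, serial, metal, mx, my, mz) {
      res <- cand_by[[sid]]
      nb <- residue_neighborhood(res, c(mx, my, mz), radius)
      tibble::tibble(
        site_id = paste(sid, serial, sep = "_"),
        structure_id = sid, serial = as.integer(serial),
        metal = toupper(metal), x = mx, y = my, z = mz,
        radius = radius, n_residues = nrow(nb), neighborhood = list(nb)
      )
    }
  )
  dplyr::bind_rows(rows)
}

# Hydrogens/deuteriums are ignored when measuring residue-to-metal distance.
heavy_excluded <- function(element, atom_name) {
  element %in% c("H", "D") | grepl("^[0-9]*H", atom_name)
}

# Per-residue minimum distance from `pos` among this structure's candidate
# atoms, keeping the coordinates of the realising atom as representative.
residue_neighborhood <- function(res_atoms, pos, radius) {
  empty <- tibble::tibble(
    chain = character(), residue_seq = integer(), residue_name = character(),
    dist = double(), rx = double(), ry = double(), rz = double()
  )
  if (is.null(res_atoms) || nrow(res_atoms) == 0) {
    return(empty)
  }
  d <- sqrt((res_atoms$x - pos[1])^2 + (res_atoms$y - pos[2])^2 +
    (res_atoms$z - pos[3])^2)
  key <- paste(res_atoms$chain, res_atoms$residue_seq, res_atoms$residue_name)
  ord <- order(d)
  first <- ord[!duplicated(key[ord])] # row of each residue's closest atom
  keep <- first[d[first] <= radius]
  keep <- keep[order(res_atoms$chain[keep], res_atoms$residue_seq[keep])]
  tibble::tibble(
    chain = res_atoms$chain[keep],
    residue_seq = as.integer(res_atoms$residue_seq[keep]),
    residue_name = res_atoms$residue_name[keep],
    dist = d[keep],
    rx = res_atoms$x[keep], ry = res_atoms$y[keep], rz = res_atoms$z[keep]
  )
}

#' Distances between metal cofactor positions
#'
#' With a site table alone, returns every unordered pair of sites and the
#' Euclidean distance between their metal positions — the measurement used
#' to characterise two-metal active sites (e.g. the ~7.5 A inter-cofactor
#' separation in the T7 primase active site). With `site_a`/`site_b` given,
#' returns the single scalar distance.
#'
#' @param sites Site tibble from [find_metal_sites()] (>= 2 rows for the
#'   pairwise form).
#' @param site_a,site_b Optional `site_id`s selecting one pair.
#' @return A tibble (`site_a`, `site_b`, `distance`) or a single numeric
#'   distance in Angstrom.
#' @examples
#' s <- tibble::tibble(
#'   site_id = c("a", "b"), x = c(0, 3), y = c(0, 4), z = c(0, 0)
#' )
#' inter_metal_distance(s, "a", "b") # 5
#' @export
inter_metal_distance <- function(sites, site_a = NULL, site_b = NULL) {
  stopifnot(is.data.frame(sites), all(is.finite(sites$x)),
    all(is.finite(sites$y)), all(is.finite(sites$z)))
  if (!is.null(site_a) || !is.null(site_b)) {
    a <- sites[match(site_a, sites$site_id), ]
    b <- sites[match(site_b, sites$site_id), ]
    if (nrow(a) != 1 || nrow(b) != 1 || anyNA(a$x) || anyNA(b$x)) {
      abort("site_a/site_b must each match one site_id")
    }
    return(sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
  }
  if (nrow(sites) < 2) {
    return(tibble::tibble(
      site_a = character(), site_b = character(), distance = double()
    ))
  }
  pairs <- utils::combn(seq_len(nrow(sites)), 2)
  tibble::tibble(
    site_a = sites$site_id[pairs[1, ]],
    site_b = sites$site_id[pairs[2, ]],
    distance = sqrt(
      (sites$x[pairs[1, ]] - sites$x[pairs[2, ]])^2 +
        (sites$y[pairs[1, ]] - sites$y[pairs[2, ]])^2 +
        (sites$z[pairs[1, ]] - sites$z[pairs[2, ]])^2
    )
  )
}

#' Export metal sites as tab-delimited text
#'
#' @param sites Site tibble from [find_metal_sites()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_sites <- function(sites, file) {
  sites |>
    dplyr::select(
      "site_id", "metal", "x", "y", "z",
      n_residues = "n_residues"
    ) |>
    readr::write_tsv(file)
  invisible(file)
}
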