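# Metal coordination-site analysis: coordination-sphere extraction, donor
# chemistry classification, carboxyl/imidazole motif matching, structure-set
# census, and coordination-geometry metrics (tau4).

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

WATER_RESNAMES <- c("HOH", "WAT")

#' Classify a coordinating atom by donor chemistry
#'
#' Pure table lookup on (residue name, atom name):
#' Asp `OD1`/`OD2` and Glu `OE1`/`OE2` are carboxylate oxygens; His
#' `ND1`/`NE2` are imidazole nitrogens; the backbone `O` of any standard
#' amino acid is a backbone carbonyl oxygen; the `O` of `HOH`/`WAT` is a
#' water oxygen; everything else (including unknown residues) is `"other"`.
#'
#' @param resname 3-letter residue code(s).
#' @param name PDB atom name(s).
#' @return Character vector over
#'   `c("carboxylate_O", "imidazole_N", "backbone_carbonyl_O", "water_O",
#'   "other")`.
#' @export
classify_ligand <- function(resname, name) {
  resname <- toupper(trimws(resname))
  name <- toupper(trimws(name))
  out <- rep("other", length(resname))
  out[resname == "ASP" & name %in% c("OD1", "OD2")] <- "carboxylate_O"
  out[resname == "GLU" & name %in% c("OE1", "OE2")] <- "carboxylate_O"
  out[resname == "HIS" & name %in% c("ND1", "NE2")] <- "imidazole_N"
  out[resname %in% STANDARD_AA & name == "O"] <- "backbone_carbonyl_O"
  out[resname %in% WATER_RESNAMES & name == "O"] <- "water_O"
  out
}

#' Extract metal coordination spheres from a structure
#'
#' One `metal_site` per atom whose element is in `metals`; its ligands are
#' all non-metal, non-hydrogen atoms within `cutoff` of the metal, sorted by
#' distance and classified with [classify_ligand()].
#'
#' @param structure a structure.
#' @param metals element symbols treated as metals (e.g. `c("Cd", "Zn")`).
#' @param cutoff metal-donor distance cutoff, Angstrom (default 3.0).
#' @param source_id identifier recorded on each site (defaults to empty).
#' @return List of `metal_site` objects (empty if the structure has no
#'   metals); each has `metal` (atom row), `ligands` (data.frame with the
#'   atom fields plus `distance` and `ligand_class`) and `source_structure`.
#' @export
extract_sites <- function(structure, metals = "Cd", cutoff = 3.0,
                          source_id = "") {
  stopifnot(inherits(structure, "structure"))
  if (!is_scalar_number(cutoff) || cutoff <= 0) {
    stop_ionprobe("cutoff must be positive")
  }
  metals <- normalize_element(metals)
  at <- structure$atoms
  el <- normalize_element(at$element)
  metal_rows <- which(el %in% metals)
  candidate <- which(!(el %in% metals) & el != "H")
  out <- list()
  xyz <- coords_matrix(structure)
  for (m in metal_rows) {
    dvec <- sqrt(colSums((t(xyz[candidate, , drop = FALSE]) - xyz[m, ])^2))
    keep <- which(dvec <= cutoff)
    lig <- at[candidate[keep], , drop = FALSE]
    lig$distance <- dvec[keep]
    lig$ligand_class <- classify_ligand(lig$resname, lig$name)
    lig <- lig[order(lig$distance), , drop = FALSE]
    rownames(lig) <- NULL
    site <- list(metal = at[m, , drop = FALSE], ligands = lig,
                 source_structure = source_id)
    class(site) <- "metal_site"
    out[[length(out) + 1L]] <- site
  }
  out
}

#' @export
print.metal_site <- function(x, ...) {
  cat(sprintf("<metal_site> %s (serial %d)%s, %d ligand(s)\n",
              x$metal$element, x$metal$serial,
              if (nzchar(x$source_structure))
                paste0(" in ", x$source_structure) else "",
              nrow(x$ligands)))
  if (nrow(x$ligands) > 0L) {
    for (i in seq_len(nrow(x$ligands))) {
      l <- x$ligands[i, ]
      cat(sprintf("  %s %d %s  %.2f A  [%s]\n", l$resname, l$resid, l$name,
                  l$distance, l$ligand_class))
    }
  }
  invisible(x)
}

#' Define a metal-binding motif
#'
#' Residue-level counting: a residue contributing one or more carboxylate
#' oxygens counts as one carboxyl; a histidine contributing one or more
#' imidazole nitrogens counts as one imidazole. `NA` leaves a category
#' unconstrained. With `allow_other = FALSE`, any ligand outside the motif's
#' categories (water excluded when the water count is unconstrained) fails
#' the match.
#'
#' @param carboxyl exact number of Asp/Glu carboxyl residues, or `NA`.
#' @param imidazole exact number of His imidazole residues, or `NA`.
#' @param backbone_min minimum number of backbone carbonyl oxygens
#'   (0 = unconstrained).
#' @param water exact number of water oxygens, or `NA` (unconstrained).
#' @param allow_other allow ligands outside the above categories.
#' @return A `motif_spec`.
#' @export
motif_spec <- function(carboxyl = NA_integer_, imidazole = NA_integer_,
                       backbone_min = 0L, water = NA_integer_,
                       allow_other = TRUE) {
  obj <- list(carboxyl = carboxyl, imidazole = imidazole,
              backbone_min = as.integer(backbone_min), water = water,
              allow_other = isTRUE(allow_other))
  class(obj) <- "motif_spec"
  obj
}

#' UNG-like motif: exactly one Asp/Glu carboxyl and one His imidazole
#' @export
#' @rdname motif_spec
motif_ung_like <- function() {
  motif_spec(carboxyl = 1L, imidazole = 1L, allow_other = TRUE)
}

#' Strict active-site motif: one carboxyl, one imidazole, at least one
#' backbone carbonyl oxygen, water unconstrained, no other donors
#' @export
#' @rdname motif_spec
motif_exact_site <- function() {
  motif_spec(carboxyl = 1L, imidazole = 1L, backbone_min = 1L,
             allow_other = FALSE)
}

#' Match a coordination sphere against a motif
#'
#' @param site a `metal_site`.
#' @param spec a [motif_spec()].
#' @return `TRUE` if the site matches.
#' @export
match_motif <- function(site, spec = motif_ung_like()) {
  stopifnot(inherits(site, "metal_site"), inherits(spec, "motif_spec"))
  lig <- site$ligands
  if (nrow(lig) == 0L) {
    n_carboxyl <- 0L; n_imidazole <- 0L; n_backbone <- 0L; n_water <- 0L
    n_other <- 0L
  } else {
    res_key <- paste(lig$chain, lig$resid, lig$resname)
    n_carboxyl <- length(unique(res_key[lig$ligand_class == "carboxylate_O"]))
    n_imidazole <- length(unique(res_key[lig$ligand_class == "imidazole_N"]))
    n_backbone <- sum(lig$ligand_class == "backbone_carbonyl_O")
    n_water <- sum(lig$ligand_class == "water_O")
    n_other <- sum(lig$ligand_class == "other")
  }
  if (!is.na(spec$carboxyl) && n_carboxyl != spec$carboxyl) return(FALSE)
  if (!is.na(spec$imidazole) && n_imidazole != spec$imidazole) return(FALSE)
  if (n_backbone < spec$backbone_min) return(FALSE)
  if (!is.na(spec$water) && n_water != spec$water) return(FALSE)
  if (!spec$allow_other) {
    if (n_other > 0L) return(FALSE)
    if (!is.na(spec$water) && n_water != spec$water) return(FALSE)
  }
  TRUE
}

#' Motif census over a structure set
#'
#' Runs [extract_sites()] and [match_motif()] over every structure and
#' tallies per metal element: structures containing the metal, sites, motif
#' matches, and the match percentage (100 * matches / sites; `NA` when a
#' metal has no sites).
#'
#' @param structures list of structures (optionally named; names are used as
#'   source identifiers).
#' @param metals element symbols to scan for.
#' @param spec a [motif_spec()].
#' @param cutoff coordination cutoff, Angstrom.
#' @return A `census_result` data.frame with columns `metal`,
#'   `n_structures`, `n_sites`, `n_matches`, `percent_matches`, ordered by
#'   element symbol.
#' @export
census <- function(structures, metals = "Cd", spec = motif_ung_like(),
                   cutoff = 3.0) {
  if (inherits(structures, "structure")) structures <- list(structures)
  if (length(structures) < 1L) stop_ionprobe("need at least one structure")
  metals <- sort(normalize_element(metals))
  ids <- names(structures) %||% rep("", length(structures))
  tall <- list()
  for (i in seq_along(structures)) {
    id <- if (nzchar(ids[i])) ids[i] else sprintf("structure_%d", i)
    sites <- extract_sites(structures[[i]], metals = metals, cutoff = cutoff,
                           source_id = id)
    for (s in sites) {
      tall[[length(tall) + 1L]] <- data.frame(
        metal = normalize_element(s$metal$element),
        structure = id,
        match = match_motif(s, spec),
        stringsAsFactors = FALSE)
    }
  }
  tally <- if (length(tall) > 0L) do.call(rbind, tall)
  else data.frame(metal = character(0), structure = character(0),
                  match = logical(0))
  out <- data.frame(metal = metals, n_structures = NA_integer_,
                    n_sites = NA_integer_, n_matches = NA_integer_,
                    percent_matches = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(metals)) {
    sub <- tally[tally$metal == metals[j], , drop = FALSE]
    out$n_structures[j] <- length(unique(sub$structure))
    out$n_sites[j] <- nrow(sub)
    out$n_matches[j] <- sum(sub$match)
    out$percent_matches[j] <- if (nrow(sub) > 0L)
      100 * sum(sub$match) / nrow(sub) else NA_real_
  }
  class(out) <- c("census_result", "data.frame")
  out
}

#' Coordination geometry of a metal site
#'
#' Reports metal-ligand distances, all pairwise ligand-metal-ligand angles,
#' the mean absolute deviation of those angles from the ideal tetrahedral
#' angle (109.47 degrees), and the four-coordinate geometry index
#' \deqn{\tau_4 = \frac{360 - (\beta + \gamma)}{360 - 2\theta_t}}
#' where \eqn{\beta \ge \gamma} are the two largest angles and
#' \eqn{\theta_t = \arccos(-1/3)}. \eqn{\tau_4} is 1 for an ideal
#' tetrahedron and 0 for square planar; values above 1 are possible for
#' distorted inputs and are reported as computed. With fewer than four
#' ligands \eqn{\tau_4} is `NA`.
#'
#' @param site a `metal_site` with at least 2 ligands.
#' @return A `geometry_report`: list with `coordination_number`,
#'   `distances`, `angles` (degrees), `mean_abs_dev_from_109_47`, `tau4`.
#' @export
coordination_geometry <- function(site) {
  stopifnot(inherits(site, "metal_site"))
  lig <- site$ligands
  n <- nrow(lig)
  if (n < 2L) stop_ionprobe("geometry needs at least 2 ligands")
  m <- as.numeric(site$metal[1, c("x", "y", "z")])
  vecs <- sweep(as.matrix(lig[, c("x", "y", "z")]), 2L, m)
  norms <- sqrt(rowSums(vecs^2))
  unit <- vecs / norms
  pairs <- utils::combn(n, 2L)
  angles <- apply(pairs, 2L, function(p) {
    cosang <- sum(unit[p[1L], ] * unit[p[2L], ])
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  })
  tau4 <- if (n >= 4L) {
    two <- sort(angles, decreasing = TRUE)[1:2]
    (360 - sum(two)) / TAU4_DENOM
  } else NA_real_
  out <- list(coordination_number = n,
              distances = lig$distance,
              angles = angles,
              mean_abs_dev_from_109_47 = mean(abs(angles -
                                                    TETRAHEDRAL_ANGLE)),
              tau4 = tau4)
  class(out) <- "geometry_report"
  out
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("<geometry_report> CN %d, tau4 %s\n", x$coordination_number,
              if (is.na(x$tau4)) "NA" else sprintf("%.3f", x$tau4)))
  cat(sprintf("  distances (A): %s\n",
              paste(sprintf("%.2f", x$distances), collapse = ", ")))
  cat(sprintf("  mean |angle - 109.47|: %.2f deg\n",
              x$mean_abs_dev_from_109_47))
  invisible(x)
}
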