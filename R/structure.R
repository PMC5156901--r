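# Containers for static structures and coordinate ensembles.
#
# A `structure` holds an atom table (one row per atom) plus an optional
# periodic box; an `ensemble` holds one shared atom roster and a
# n_atoms x 3 x n_frames coordinate array. Coordinates are Cartesian
# Angstroms, residue numbering is 1-based PDB numbering.

#' Construct a molecular structure
#'
#' @param atoms data.frame with columns `serial` (positive integer, unique),
#'   `name` (PDB atom name, e.g. `"OD1"`), `element` (element symbol),
#'   `resname` (3-letter residue code), `resid` (integer residue number),
#'   `chain` (single character), `x`, `y`, `z` (Angstrom), and logical
#'   `hetero`.
#' @param box optional numeric length-3 vector of box edge lengths (Angstrom),
#'   all positive.
#' @return An object of class `"structure"`.
#' @export
new_structure <- function(atoms, box = NULL) {
  required <- c("serial", "name", "element", "resname", "resid",
                "chain", "x", "y", "z", "hetero")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop_ionprobe("atom table missing columns: ",
                  paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$serial)) {
    dup <- atoms$serial[duplicated(atoms$serial)][1L]
    stop_ionprobe("duplicate atom serial: ", dup)
  }
  if (any(!nzchar(atoms$element))) {
    stop_ionprobe("empty element symbol in atom table")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop_ionprobe("non-finite atom coordinates")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0)) {
      stop_ionprobe("box must be 3 positive edge lengths (Angstrom)")
    }
  }
  rownames(atoms) <- NULL
  obj <- list(atoms = atoms, box = box)
  class(obj) <- "structure"
  obj
}

#' @export
print.structure <- function(x, ...) {
  cat(sprintf("<structure> %d atoms, %d residues%s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              if (is.null(x$box)) "" else
                sprintf(", box %.2f x %.2f x %.2f A",
                        x$box[1], x$box[2], x$box[3])))
  het <- sum(x$atoms$hetero)
  if (het > 0L) cat(sprintf("  hetero atoms: %d\n", het))
  invisible(x)
}

coords_matrix <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Construct a coordinate ensemble
#'
#' @param atoms shared atom roster (see [new_structure()]); coordinate columns
#'   are ignored in favour of `coords`.
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`.
#' @param frame_interval optional time between frames, ns (metadata only).
#' @param box optional shared periodic box, Angstrom.
#' @return An object of class `"ensemble"`.
#' @export
new_ensemble <- function(atoms, coords, frame_interval = NULL, box = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop_ionprobe("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(atoms)) {
    stop_ionprobe("coords first dimension must match atom count")
  }
  if (dim(coords)[3] < 1L) stop_ionprobe("ensemble needs at least one frame")
  if (!all(is.finite(coords))) stop_ionprobe("non-finite coordinates in ensemble")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  obj <- list(atoms = atoms, coords = coords,
              frame_interval = frame_interval, box = box)
  class(obj) <- "ensemble"
  obj
}

#' Number of frames in an ensemble
#' @param ensemble an [new_ensemble()] object.
#' @export
n_frames <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble"))
  dim(ensemble$coords)[3]
}

#' Extract one frame of an ensemble as a structure
#' @param ensemble an ensemble.
#' @param i frame index (1-based).
#' @export
get_frame <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "ensemble"))
  nf <- n_frames(ensemble)
  if (i < 1L || i > nf) stop_ionprobe("frame index ", i, " out of range 1..", nf)
  atoms <- ensemble$atoms
  atoms$x <- ensemble$coords[, 1, i]
  atoms$y <- ensemble$coords[, 2, i]
  atoms$z <- ensemble$coords[, 3, i]
  new_structure(atoms, box = ensemble$box)
}

#' Build an ensemble from a list of structures sharing one atom roster
#' @param frames list of `structure` objects.
#' @param frame_interval optional time per frame, ns.
#' @export
ensemble_from_frames <- function(frames, frame_interval = NULL) {
  if (length(frames) < 1L) stop_ionprobe("ensemble needs at least one frame")
  ref <- frames[[1L]]$atoms
  coords <- array(NA_real_, dim = c(nrow(ref), 3, length(frames)))
  for (i in seq_along(frames)) {
    at <- frames[[i]]$atoms
    if (nrow(at) != nrow(ref)) {
      stop_ionprobe("frame ", i, " has ", nrow(at),
                    " atoms; expected ", nrow(ref))
    }
    if (!identical(at$name, ref$name) || !identical(at$resname, ref$resname)) {
      stop_ionprobe("frame ", i, " atom roster differs from frame 1")
    }
    coords[, , i] <- as.matrix(at[, c("x", "y", "z")])
  }
  new_ensemble(ref, coords, frame_interval = frame_interval,
               box = frames[[1L]]$box)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames x %d atoms%s\n",
              n_frames(x), nrow(x$atoms),
              if (is.null(x$frame_interval)) "" else
                sprintf(", %g ns/frame", x$frame_interval)))
  invisible(x)
}
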