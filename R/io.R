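# PDB (v3.3 fixed-width) and multi-frame XYZ readers/writers.
#
# Deliberately strict dialect: insertion codes are rejected, altloc other
# than blank/'A' is dropped with a warning, malformed records fail with the
# offending line number. This keeps parsing deterministic.

# Two-letter element symbols recognised when the element column is absent
# and the atom is a HETATM (metals and common hetero species).
TWO_LETTER_ELEMENTS <- c(
  "CD", "ZN", "NI", "PB", "MG", "MN", "FE", "CU", "CO", "CA", "NA", "CL",
  "BR", "HG", "SE", "MO", "AL", "AS", "AU", "AG", "PT", "SR", "CS", "BA",
  "RB", "LI", "TL", "SI"
)

normalize_element <- function(sym) {
  sym <- toupper(trimws(sym))
  ifelse(nchar(sym) == 2L,
         paste0(substr(sym, 1, 1), tolower(substr(sym, 2, 2))),
         sym)
}

guess_element <- function(name, hetero) {
  stripped <- toupper(gsub("[0-9' ]", "", name))
  if (!nzchar(stripped)) return("")
  two <- substr(stripped, 1, 2)
  if (hetero && two %in% TWO_LETTER_ELEMENTS) return(normalize_element(two))
  substr(stripped, 1, 1)
}

parse_pdb_atom_lines <- function(lines, line_numbers) {
  n <- length(lines)
  field <- function(l, from, to) substr(l, from, to)
  num_or_stop <- function(txt, what, ln) {
    v <- suppressWarnings(as.numeric(txt))
    if (any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1L]
      stop_ionprobe("PDB parse error at line ", ln[bad],
                    ": bad ", what, " field '", trimws(txt[bad]), "'")
    }
    v
  }
  icode <- field(lines, 27, 27)
  bad_icode <- which(!(icode %in% c("", " ")))
  if (length(bad_icode) > 0L) {
    stop_ionprobe("PDB parse error at line ", line_numbers[bad_icode[1L]],
                  ": insertion codes are not supported")
  }
  altloc <- field(lines, 17, 17)
  drop <- !(altloc %in% c("", " ", "A"))
  if (any(drop)) {
    warning(sum(drop), " atom(s) with altloc other than blank/'A' dropped",
            call. = FALSE)
    lines <- lines[!drop]
    line_numbers <- line_numbers[!drop]
    if (length(lines) == 0L) {
      return(data.frame(serial = integer(), name = character(),
                        element = character(), resname = character(),
                        resid = integer(), chain = character(),
                        x = numeric(), y = numeric(), z = numeric(),
                        hetero = logical(), stringsAsFactors = FALSE))
    }
  }
  hetero <- startsWith(lines, "HETATM")
  serial <- num_or_stop(field(lines, 7, 11), "serial", line_numbers)
  resid <- num_or_stop(field(lines, 23, 26), "residue number", line_numbers)
  atoms <- data.frame(
    serial = as.integer(serial),
    name = trimws(field(lines, 13, 16)),
    element = trimws(field(lines, 77, 78)),
    resname = trimws(field(lines, 18, 20)),
    resid = as.integer(resid),
    chain = field(lines, 22, 22),
    x = num_or_stop(field(lines, 31, 38), "x coordinate", line_numbers),
    y = num_or_stop(field(lines, 39, 46), "y coordinate", line_numbers),
    z = num_or_stop(field(lines, 47, 54), "z coordinate", line_numbers),
    hetero = hetero,
    stringsAsFactors = FALSE
  )
  need <- !nzchar(atoms$element)
  if (any(need)) {
    atoms$element[need] <- mapply(guess_element, atoms$name[need],
                                  atoms$hetero[need], USE.NAMES = FALSE)
  }
  atoms$element <- normalize_element(atoms$element)
  if (anyDuplicated(atoms$serial)) {
    i <- which(duplicated(atoms$serial))[1L]
    stop_ionprobe("PDB parse error at line ", line_numbers[i],
                  ": duplicate atom serial ", atoms$serial[i])
  }
  atoms
}

parse_cryst1 <- function(line) {
  abc <- suppressWarnings(as.numeric(c(substr(line, 7, 15),
                                       substr(line, 16, 24),
                                       substr(line, 25, 33))))
  if (any(!is.finite(abc)) || any(abc <= 0)) return(NULL)
  abc
}

#' Read a PDB structure
#'
#' Parses `ATOM`/`HETATM` records from a PDB v3.3 fixed-width file. The box
#' is taken from `CRYST1` if present. Files with multiple models are read up
#' to the first `ENDMDL`; use [read_trajectory()] for multi-model files.
#' Insertion codes are rejected; alternate locations other than blank/`'A'`
#' are dropped with a warning.
#'
#' @param path path to a PDB file.
#' @param format file format; only `"pdb"` is supported.
#' @return A [new_structure()] object.
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop_ionprobe("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop_ionprobe("empty file: ", path)
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm) > 0L) lines <- lines[seq_len(endm[1L] - 1L)]
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  if (!any(is_atom)) stop_ionprobe("no ATOM/HETATM records in ", path)
  atoms <- parse_pdb_atom_lines(lines[is_atom], which(is_atom))
  box <- NULL
  cr <- which(startsWith(lines, "CRYST1"))
  if (length(cr) > 0L) box <- parse_cryst1(lines[cr[1L]])
  new_structure(atoms, box = box)
}

#' Read a coordinate trajectory
#'
#' Supported carriers: multi-frame XYZ (count line, comment line, then
#' `element x y z` per atom) and multi-model PDB (`MODEL`/`ENDMDL` pairs).
#' All frames must share one atom roster; a mismatch fails naming the frame.
#'
#' @param path trajectory file path.
#' @param format `"auto"` (by extension), `"xyz"` or `"pdb"`.
#' @param frame_interval optional time between frames, ns (metadata only).
#' @return A [new_ensemble()] object.
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "pdb"),
                            frame_interval = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ionprobe("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  if (format == "xyz") read_xyz_trajectory(path, frame_interval)
  else read_pdb_trajectory(path, frame_interval)
}

read_xyz_trajectory <- function(path, frame_interval = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > 1 & lines == "" &
                     seq_along(lines) == length(lines))]  # tolerate final blank
  if (length(lines) == 0L) stop_ionprobe("empty file: ", path)
  frames <- list()
  i <- 1L
  frame_idx <- 0L
  n_expect <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    frame_idx <- frame_idx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0L) {
      stop_ionprobe("XYZ parse error at line ", i, " (frame ", frame_idx,
                    "): expected atom count, got '", trimws(lines[i]), "'")
    }
    if (is.null(n_expect)) n_expect <- n
    if (n != n_expect) {
      stop_ionprobe("XYZ frame ", frame_idx, " has ", n,
                    " atoms; expected ", n_expect)
    }
    if (i + 1L + n > length(lines)) {
      stop_ionprobe("XYZ frame ", frame_idx, " truncated: expected ", n,
                    " atom lines")
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(toks, length, 0L) < 4L)
    if (length(bad) > 0L) {
      stop_ionprobe("XYZ parse error at line ", i + 1L + bad[1L],
                    ": expected 'element x y z'")
    }
    el <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(t) {
      v <- suppressWarnings(as.numeric(t[2:4]))
      v
    }, numeric(3)))
    if (any(!is.finite(xyz))) {
      stop_ionprobe("XYZ parse error in frame ", frame_idx,
                    ": non-numeric coordinate")
    }
    frames[[frame_idx]] <- list(element = normalize_element(el), xyz = xyz)
    i <- i + 2L + n
    while (i <= length(lines) && !nzchar(trimws(lines[i])) &&
           i == length(lines)) i <- i + 1L
  }
  if (frame_idx == 0L) stop_ionprobe("no frames in ", path)
  ref <- frames[[1L]]
  for (k in seq_along(frames)) {
    if (!identical(frames[[k]]$element, ref$element)) {
      stop_ionprobe("XYZ frame ", k, " atom roster differs from frame 1")
    }
  }
  atoms <- data.frame(
    serial = seq_len(n_expect),
    name = ref$element,
    element = ref$element,
    resname = "UNK",
    resid = seq_len(n_expect),
    chain = "A",
    x = ref$xyz[, 1], y = ref$xyz[, 2], z = ref$xyz[, 3],
    hetero = FALSE,
    stringsAsFactors = FALSE
  )
  coords <- array(NA_real_, dim = c(n_expect, 3, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]$xyz
  new_ensemble(atoms, coords, frame_interval = frame_interval)
}

read_pdb_trajectory <- function(path, frame_interval = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop_ionprobe("empty file: ", path)
  model_starts <- which(startsWith(lines, "MODEL"))
  box <- NULL
  cr <- which(startsWith(lines, "CRYST1"))
  if (length(cr) > 0L) box <- parse_cryst1(lines[cr[1L]])
  if (length(model_starts) == 0L) {
    s <- read_structure(path)
    return(new_ensemble(s$atoms, array(coords_matrix(s),
                                       dim = c(nrow(s$atoms), 3, 1)),
                        frame_interval = frame_interval, box = s$box))
  }
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) != length(model_starts)) {
    stop_ionprobe("unbalanced MODEL/ENDMDL records in ", path)
  }
  frames <- vector("list", length(model_starts))
  for (k in seq_along(model_starts)) {
    rng <- (model_starts[k] + 1L):(model_ends[k] - 1L)
    is_atom <- startsWith(lines[rng], "ATOM  ") |
      startsWith(lines[rng], "HETATM")
    if (!any(is_atom)) stop_ionprobe("PDB model ", k, " has no atoms")
    frames[[k]] <- parse_pdb_atom_lines(lines[rng][is_atom], rng[is_atom])
  }
  ref <- frames[[1L]]
  coords <- array(NA_real_, dim = c(nrow(ref), 3, length(frames)))
  for (k in seq_along(frames)) {
    at <- frames[[k]]
    if (nrow(at) != nrow(ref)) {
      stop_ionprobe("PDB frame ", k, " has ", nrow(at),
                    " atoms; expected ", nrow(ref))
    }
    if (!identical(at$name, ref$name)) {
      stop_ionprobe("PDB frame ", k, " atom roster differs from frame 1")
    }
    coords[, , k] <- as.matrix(at[, c("x", "y", "z")])
  }
  new_ensemble(ref, coords, frame_interval = frame_interval, box = box)
}

format_pdb_atom <- function(at) {
  rec <- ifelse(at$hetero, "HETATM", "ATOM  ")
  # PDB atom-name column convention: names of length < 4 start in column 14
  name <- ifelse(nchar(at$name) >= 4L, substr(at$name, 1, 4),
                 sprintf(" %-3s", at$name))
  el <- toupper(at$element)
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, at$serial, name, at$resname, at$chain, at$resid,
          at$x, at$y, at$z, 1.0, 0.0, el)
}

#' Write a structure as PDB
#' @param structure a [new_structure()] object.
#' @param path output path.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "structure"))
  lines <- character(0)
  if (!is.null(structure$box)) {
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      structure$box[1], structure$box[2], structure$box[3], 90, 90, 90))
  }
  lines <- c(lines, format_pdb_atom(structure$atoms), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write an ensemble as multi-frame XYZ or multi-model PDB
#' @param ensemble an ensemble.
#' @param path output path.
#' @param format `"xyz"` or `"pdb"`.
#' @export
write_trajectory <- function(ensemble, path, format = c("xyz", "pdb")) {
  stopifnot(inherits(ensemble, "ensemble"))
  format <- match.arg(format)
  nf <- n_frames(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    n <- nrow(ensemble$atoms)
    el <- toupper(ensemble$atoms$element)
    for (k in seq_len(nf)) {
      writeLines(c(as.character(n), sprintf("frame %d", k)), con)
      writeLines(sprintf("%-2s %17.10f %17.10f %17.10f", el,
                         ensemble$coords[, 1, k],
                         ensemble$coords[, 2, k],
                         ensemble$coords[, 3, k]), con)
    }
  } else {
    if (!is.null(ensemble$box)) {
      writeLines(sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        ensemble$box[1], ensemble$box[2], ensemble$box[3], 90, 90, 90), con)
    }
    for (k in seq_len(nf)) {
      at <- ensemble$atoms
      at$x <- ensemble$coords[, 1, k]
      at$y <- ensemble$coords[, 2, k]
      at$z <- ensemble$coords[, 3, k]
      writeLines(sprintf("MODEL %8d", k), con)
      writeLines(format_pdb_atom(at), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}
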