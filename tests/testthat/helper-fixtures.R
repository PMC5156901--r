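# Text fixtures built in code. pdb_line() formats PDB v3.3 fixed-width
# records independently of the package's own writer so parser tests have an
# independent oracle for the file layout.

pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     record = "ATOM", element = "", altloc = " ",
                     icode = " ") {
  name_field <- if (nchar(name) >= 4L) substr(name, 1, 4)
  else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, altloc, resname, chain, resid, icode,
          x, y, z, 1.0, 0.0, element)
}

# A 3-residue peptide (N, CA, C, O per residue) with an optional Cd HETATM.
peptide_pdb_lines <- function(with_cd = FALSE) {
  lines <- character(0)
  serial <- 0L
  for (r in 1:3) {
    for (nm in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      lines <- c(lines, pdb_line(serial, nm, "ALA", "A", r,
                                 x = r * 3.8, y = serial * 0.5, z = 0,
                                 element = substr(nm, 1, 1)))
    }
  }
  if (with_cd) {
    lines <- c(lines, pdb_line(serial + 1L, "CD", "CD", "A", 90,
                               x = 1, y = 2, z = 3, record = "HETATM",
                               element = "CD"))
  }
  c(lines, "END")
}

write_tmp_lines <- function(lines, ext = ".pdb") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Alpha-carbon-only chain of n residues (resid 1..n), one CA per residue.
ca_chain_structure <- function(n) {
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", element = "C", resname = "ALA",
    resid = seq_len(n), chain = "A",
    x = seq_len(n) * 3.8, y = 0, z = 0, hetero = FALSE,
    stringsAsFactors = FALSE)
  new_structure(atoms)
}

# Metal site built directly (no generator): metal at origin plus donor atoms
# at given positions.
manual_site_structure <- function(donors) {
  atoms <- data.frame(serial = 1L, name = "CD", element = "Cd",
                      resname = "CD", resid = 1L, chain = "A",
                      x = 0, y = 0, z = 0, hetero = TRUE,
                      stringsAsFactors = FALSE)
  for (i in seq_along(donors)) {
    d <- donors[[i]]
    atoms <- rbind(atoms, data.frame(
      serial = i + 1L, name = d$name, element = d$element %||% "O",
      resname = d$resname, resid = d$resid %||% (i + 1L), chain = "A",
      x = d$pos[1], y = d$pos[2], z = d$pos[3],
      hetero = isTRUE(d$hetero), stringsAsFactors = FALSE))
  }
  new_structure(atoms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tetrahedral_unit_vectors <- function() {
  matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1) / sqrt(3),
         ncol = 3, byrow = TRUE)
}
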