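# Atom selection mini-language.
#
# Grammar: clause ("and" clause)*
#   clause := name=V[,V...] | resname=V[,V...] | element=V[,V...]
#           | chain=V[,V...] | resid N | resid A..B | resid=N | resid=A..B
#           | hetero | hetero=true | hetero=false
# Ranges are inclusive on both ends. Matching of names/resnames/elements is
# case-insensitive; syntax errors report the character position.

parse_selection <- function(query) {
  if (!is.character(query) || length(query) != 1L || !nzchar(trimws(query))) {
    stop_ionprobe("selection query must be a non-empty string")
  }
  m <- gregexpr("[^[:space:]]+", query)[[1L]]
  tokens <- regmatches(query, gregexpr("[^[:space:]]+", query))[[1L]]
  positions <- as.integer(m)
  clauses <- list()
  i <- 1L
  expect_clause <- TRUE
  while (i <= length(tokens)) {
    tok <- tokens[i]
    pos <- positions[i]
    if (tolower(tok) == "and") {
      if (expect_clause) {
        stop_ionprobe("selection syntax error at position ", pos,
                      ": unexpected 'and'")
      }
      expect_clause <- TRUE
      i <- i + 1L
      next
    }
    if (!expect_clause) {
      stop_ionprobe("selection syntax error at position ", pos,
                    ": expected 'and', got '", tok, "'")
    }
    lowered <- tolower(tok)
    if (lowered == "hetero") {
      clauses[[length(clauses) + 1L]] <- list(key = "hetero", value = TRUE)
    } else if (grepl("^hetero=", lowered)) {
      val <- sub("^hetero=", "", lowered)
      if (!val %in% c("true", "false")) {
        stop_ionprobe("selection syntax error at position ", pos,
                      ": hetero takes true/false")
      }
      clauses[[length(clauses) + 1L]] <-
        list(key = "hetero", value = identical(val, "true"))
    } else if (lowered == "resid" && i < length(tokens)) {
      clauses[[length(clauses) + 1L]] <-
        parse_resid_clause(tokens[i + 1L], positions[i + 1L])
      i <- i + 1L
    } else if (grepl("^resid=", lowered)) {
      clauses[[length(clauses) + 1L]] <-
        parse_resid_clause(sub("^[Rr][Ee][Ss][Ii][Dd]=", "", tok), pos)
    } else if (grepl("^(name|resname|element|chain)=", lowered)) {
      key <- sub("=.*$", "", lowered)
      val <- sub("^[^=]*=", "", tok)
      if (!nzchar(val)) {
        stop_ionprobe("selection syntax error at position ", pos,
                      ": empty value for ", key)
      }
      clauses[[length(clauses) + 1L]] <-
        list(key = key, value = toupper(strsplit(val, ",")[[1L]]))
    } else {
      stop_ionprobe("selection syntax error at position ", pos,
                    ": unrecognized clause '", tok, "'")
    }
    expect_clause <- FALSE
    i <- i + 1L
  }
  if (expect_clause) {
    stop_ionprobe("selection syntax error: query ends after 'and'")
  }
  clauses
}

parse_resid_clause <- function(tok, pos) {
  if (grepl("^-?[0-9]+\\.\\.-?[0-9]+$", tok)) {
    parts <- as.integer(strsplit(tok, "\\.\\.")[[1L]])
    if (parts[1L] > parts[2L]) {
      stop_ionprobe("selection syntax error at position ", pos,
                    ": descending resid range ", tok)
    }
    list(key = "resid", value = c(parts[1L], parts[2L]))
  } else if (grepl("^-?[0-9]+$", tok)) {
    v <- as.integer(tok)
    list(key = "resid", value = c(v, v))
  } else {
    stop_ionprobe("selection syntax error at position ", pos,
                  ": expected resid number or A..B range, got '", tok, "'")
  }
}

#' Select atoms by query
#'
#' Evaluates a selection expression against a structure's or ensemble's atom
#' roster and returns the matching atom indices in roster order. Supported
#' clauses: `name=`, `resname=`, `element=`, `chain=` (comma-separated
#' alternatives), `resid N` / `resid A..B` (inclusive), and `hetero` /
#' `hetero=false`, combined with `and`.
#'
#' @param x a `structure` or `ensemble`.
#' @param query selection expression, e.g. `"resid 5..219 and name=CA"`.
#' @return Integer vector of atom indices (possibly empty), in roster order.
#' @examples
#' \dontrun{
#' select_atoms(s, "name=CA")
#' select_atoms(s, "element=Cd and hetero")
#' }
#' @export
select_atoms <- function(x, query) {
  atoms <- if (inherits(x, "ensemble") || inherits(x, "structure")) x$atoms
  else stop_ionprobe("select_atoms needs a structure or ensemble")
  clauses <- parse_selection(query)
  keep <- rep(TRUE, nrow(atoms))
  for (cl in clauses) {
    keep <- keep & switch(
      cl$key,
      name = toupper(atoms$name) %in% cl$value,
      resname = toupper(atoms$resname) %in% cl$value,
      element = toupper(atoms$element) %in% cl$value,
      chain = toupper(atoms$chain) %in% cl$value,
      resid = atoms$resid >= cl$value[1L] & atoms$resid <= cl$value[2L],
      hetero = atoms$hetero == cl$value
    )
  }
  which(keep)
}
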