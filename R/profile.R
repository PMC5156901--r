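# Binned 1-D profiles (g(r), free energies, PMFs, displacement curves).
#
# A profile is a strictly increasing grid of bin centers with one value per
# grid point, an optional per-point spread (standard deviation), and free-form
# metadata. CSV serialization stores metadata as a single JSON comment line so
# round trips are lossless.

#' Construct a profile
#'
#' @param grid strictly increasing numeric bin-center values (Angstrom or
#'   unitless).
#' @param values numeric, one per grid point.
#' @param spread optional per-point standard deviation (same length).
#' @param meta named list of free-form metadata (units, bin width, counts...).
#' @param subclass optional S3 subclass tag (e.g. `"rdf_profile"`).
#' @return An object of class `"profile"`.
#' @export
new_profile <- function(grid, values, spread = NULL, meta = list(),
                        subclass = NULL) {
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  if (length(grid) != length(values)) {
    stop_ionprobe("grid and values must have the same length")
  }
  if (length(grid) == 0L) stop_ionprobe("profile must have at least one point")
  if (any(!is.finite(grid))) stop_ionprobe("profile grid must be finite")
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop_ionprobe("profile grid must be strictly increasing")
  }
  if (!is.null(spread)) {
    spread <- as.numeric(spread)
    if (length(spread) != length(grid)) {
      stop_ionprobe("spread must match grid length")
    }
    if (any(is.finite(spread) & spread < 0)) {
      stop_ionprobe("spread must be non-negative")
    }
  }
  obj <- list(grid = grid, values = values, spread = spread,
              meta = as.list(meta))
  class(obj) <- c(subclass, "profile")
  obj
}

#' @export
print.profile <- function(x, ...) {
  cat(sprintf("<%s> %d points, grid [%g, %g]\n",
              class(x)[1L], length(x$grid), min(x$grid), max(x$grid)))
  if (length(x$meta) > 0L) {
    keys <- names(x$meta)
    cat("  meta:", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.profile <- function(x, ...) {
  data.frame(grid = x$grid, value = x$values,
             spread = if (is.null(x$spread)) NA_real_ else x$spread)
}

#' Write a profile to CSV or JSON
#'
#' CSV layout: a `# meta: {...}` JSON comment line, then a
#' `grid,value,spread` header and one row per point (empty spread column when
#' absent). Numbers are written with 17 significant digits so
#' `read_profile(write_profile(p))` reproduces `p` exactly.
#'
#' @param profile a [new_profile()] object.
#' @param path output path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @export
write_profile <- function(profile, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(profile, "profile"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  if (format == "json") {
    payload <- list(grid = profile$grid, values = profile$values,
                    spread = profile$spread, meta = profile$meta,
                    class = class(profile))
    # I(17) = 17 significant digits: doubles survive the round trip exactly
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
  } else {
    fmt <- function(v) sprintf("%.17g", v)
    spread_col <- if (is.null(profile$spread)) rep("", length(profile$grid))
    else fmt(profile$spread)
    meta_line <- sprintf("# meta: %s", as.character(jsonlite::toJSON(
      c(profile$meta, list(.class = class(profile))),
      auto_unbox = TRUE, digits = I(17), null = "null")))
    lines <- c(meta_line, "grid,value,spread",
               paste(fmt(profile$grid), fmt(profile$values), spread_col,
                     sep = ","))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a profile written by [write_profile()]
#' @param path input path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A `profile` object (subclass restored from metadata).
#' @export
read_profile <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ionprobe("file not found: ", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  if (format == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    cls <- payload$class %||% "profile"
    meta <- payload$meta %||% list()
    spread <- payload$spread
    if (length(spread) == 0L) spread <- NULL
    return(new_profile(payload$grid, payload$values, spread = spread,
                       meta = as.list(meta),
                       subclass = setdiff(cls, "profile")))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop_ionprobe("empty profile file: ", path)
  meta <- list()
  cls <- character(0)
  meta_lines <- grep("^# meta:", lines, value = TRUE)
  if (length(meta_lines) > 0L) {
    meta <- jsonlite::fromJSON(sub("^# meta:\\s*", "", meta_lines[1L]),
                               simplifyVector = TRUE)
    cls <- meta$.class %||% character(0)
    meta$.class <- NULL
  }
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2L || !identical(trimws(body[1L]), "grid,value,spread")) {
    stop_ionprobe("profile CSV must start with header grid,value,spread")
  }
  rows <- strsplit(body[-1L], ",")
  grid <- as.numeric(vapply(rows, `[`, "", 1L))
  values <- as.numeric(vapply(rows, `[`, "", 2L))
  spread_chr <- vapply(rows, function(r) if (length(r) >= 3L) r[3L] else "", "")
  spread <- if (all(!nzchar(spread_chr))) NULL else as.numeric(spread_chr)
  new_profile(grid, values, spread = spread, meta = as.list(meta),
              subclass = setdiff(cls, "profile"))
}
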