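# Ion localization: per-frame ion-to-site distances, radial distribution
# function g(r), and Boltzmann inversion to a free-energy profile.

#' Track per-frame ion-to-reference distances
#'
#' For each ion selected by `ion_query`, computes one distance per frame to
#' the reference selection: the minimum over reference atoms
#' (`reducer = "min"`) or the distance to the unweighted centroid of the
#' reference atoms (`reducer = "centroid"`).
#'
#' @param ensemble a coordinate ensemble.
#' @param ion_query selection expression for the ions (see [select_atoms()]).
#' @param reference_query selection expression for the reference site.
#' @param reducer `"min"` or `"centroid"`.
#' @return A list of `distance_series` objects, one per ion; each is a
#'   data.frame with columns `frame` and `distance` (Angstrom) plus
#'   attributes `ion_id` (atom serial) and `reducer`.
#' @export
track_distances <- function(ensemble, ion_query, reference_query,
                            reducer = c("min", "centroid")) {
  stopifnot(inherits(ensemble, "ensemble"))
  reducer <- match.arg(reducer)
  ion_idx <- select_atoms(ensemble, ion_query)
  ref_idx <- select_atoms(ensemble, reference_query)
  if (length(ion_idx) == 0L) stop_ionprobe("ion selection is empty")
  if (length(ref_idx) == 0L) stop_ionprobe("reference selection is empty")
  nf <- n_frames(ensemble)
  out <- vector("list", length(ion_idx))
  for (j in seq_along(ion_idx)) {
    ii <- ion_idx[j]
    d <- numeric(nf)
    for (f in seq_len(nf)) {
      ion <- ensemble$coords[ii, , f]
      ref <- ensemble$coords[ref_idx, , f, drop = FALSE][, , 1, drop = TRUE]
      if (length(ref_idx) == 1L) ref <- matrix(ref, nrow = 1L)
      if (reducer == "centroid") {
        cen <- colMeans(ref)
        d[f] <- sqrt(sum((ion - cen)^2))
      } else {
        diffs <- sweep(ref, 2L, ion)
        d[f] <- sqrt(min(rowSums(diffs^2)))
      }
    }
    ds <- data.frame(frame = seq_len(nf), distance = d)
    attr(ds, "ion_id") <- ensemble$atoms$serial[ii]
    attr(ds, "reducer") <- reducer
    class(ds) <- c("distance_series", "data.frame")
    out[[j]] <- ds
  }
  out
}

#' Radial distribution function from distance series
#'
#' Histograms all (frame, ion) distance observations into half-open bins
#' `[left, right)` of width `bin_width` up to `r_max` and normalizes by the
#' ideal-gas shell expectation:
#' \deqn{g(r_i) = \frac{\langle n_i \rangle}{\rho \, 4 \pi r_i^2 \, \Delta r}}
#' with bulk density \eqn{\rho = n_\mathrm{ions} / V_\mathrm{box}}, bin center
#' \eqn{r_i}, and \eqn{\langle n_i \rangle} the mean per-frame count in bin
#' \eqn{i}. The full box volume is used for \eqn{\rho} with no excluded-volume
#' correction (a known bias near a solute surface; only relative peak
#' structure should be interpreted there).
#'
#' @param series_set list of distance series from [track_distances()] (one
#'   per ion, equal frame counts).
#' @param bin_width bin width, Angstrom (default 0.25).
#' @param r_max histogram range, Angstrom (default 20).
#' @param box_volume box volume, Angstrom^3, used for the bulk density.
#' @return An `rdf_profile` (a [new_profile()] subclass); `meta` carries
#'   `bin_width`, `n_frames`, `n_ions`, `bulk_density` and `raw_counts`.
#' @export
compute_rdf <- function(series_set, bin_width = 0.25, r_max = 20,
                        box_volume) {
  if (inherits(series_set, "distance_series")) series_set <- list(series_set)
  if (!is_scalar_number(bin_width) || bin_width <= 0) {
    stop_ionprobe("bin_width must be a positive number")
  }
  if (!is_scalar_number(r_max) || r_max <= bin_width) {
    stop_ionprobe("r_max must exceed bin_width")
  }
  if (!is_scalar_number(box_volume) || box_volume <= 0) {
    stop_ionprobe("box_volume must be positive")
  }
  n_ions <- length(series_set)
  if (n_ions == 0L) stop_ionprobe("no ions: empty series set")
  nf <- nrow(series_set[[1L]])
  if (nf == 0L) stop_ionprobe("no frames in distance series")
  for (s in series_set) {
    if (nrow(s) != nf) stop_ionprobe("distance series differ in frame count")
  }
  d <- unlist(lapply(series_set, function(s) s$distance), use.names = FALSE)
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_ionprobe("distances must be finite and non-negative")
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max - 1e-12) edges <- c(edges, r_max)
  n_bins <- length(edges) - 1L
  # half-open [left, right): findInterval with left-closed intervals
  idx <- findInterval(d, edges, rightmost.closed = FALSE, left.open = FALSE)
  idx <- idx[idx >= 1L & idx <= n_bins & d < r_max]
  counts <- tabulate(idx, nbins = n_bins)
  centers <- (edges[-length(edges)] + edges[-1L]) / 2
  rho <- n_ions / box_volume
  shell <- 4 * pi * centers^2 * diff(edges)
  g <- (counts / nf) / (rho * shell)
  new_profile(centers, g,
              meta = list(bin_width = bin_width, r_max = r_max,
                          n_frames = nf, n_ions = n_ions,
                          bulk_density = rho, raw_counts = counts,
                          units = "grid:A, value:g(r)"),
              subclass = "rdf_profile")
}

#' Boltzmann inversion of a radial distribution function
#'
#' Converts g(r) to a free-energy profile
#' \eqn{F(r) = -k_B T \ln g(r)} (kcal/mol), dropping bins with zero
#' occupancy from the grid and shifting so the minimum of F is zero.
#'
#' @param rdf an `rdf_profile` (or any profile of non-negative values).
#' @param temperature temperature, K.
#' @return A `free_energy_profile` profile, kcal/mol.
#' @export
boltzmann_invert <- function(rdf, temperature = 300) {
  stopifnot(inherits(rdf, "profile"))
  kT <- kbt(temperature)
  g <- rdf$values
  if (any(g < 0)) stop_ionprobe("g(r) must be non-negative")
  keep <- g > 0
  if (!any(keep)) stop_ionprobe("all bins empty: cannot invert")
  f <- -kT * log(g[keep])
  f <- f - min(f)
  new_profile(rdf$grid[keep], f,
              meta = list(temperature = temperature,
                          source = "boltzmann_inversion",
                          n_masked_bins = sum(!keep),
                          units = "grid:A, value:kcal/mol"),
              subclass = "free_energy_profile")
}
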