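# Stiff-spring steered-pull analysis: work accumulation along a moving
# harmonic restraint, PMF estimation across replicates (mean work, second
# cumulant, Jarzynski exponential average), barrier detection, and profile
# correlation.

#' Constant-velocity pull schedule
#'
#' Describes a stiff-spring pull: a harmonic restraint whose target moves as
#' \eqn{\lambda(t) = \mathrm{start} + v t}. Two spring conventions are
#' supported: `"amber"` with \eqn{U = k(x-\lambda)^2} (the restraint form
#' used by AMBER's steered-MD implementation) and `"half"` with
#' \eqn{U = \tfrac{1}{2} k (x-\lambda)^2}.
#'
#' @param start_position pull start, Angstrom.
#' @param pull_distance total pull length, Angstrom (> 0).
#' @param velocity pull velocity, Angstrom/ns (> 0).
#' @param spring_constant k, kcal mol^-1 A^-2 (> 0); default 20.
#' @param spring_convention `"amber"` or `"half"`.
#' @param time_step sampling interval of the position series, ns.
#' @return A `pull_schedule` object.
#' @export
pull_schedule <- function(start_position = 0, pull_distance, velocity,
                          spring_constant = 20,
                          spring_convention = c("amber", "half"),
                          time_step = 0.01) {
  spring_convention <- match.arg(spring_convention)
  if (!is_scalar_number(pull_distance) || pull_distance <= 0) {
    stop_ionprobe("pull_distance must be > 0")
  }
  if (!is_scalar_number(velocity) || velocity <= 0) {
    stop_ionprobe("velocity must be > 0")
  }
  if (!is_scalar_number(spring_constant) || spring_constant <= 0) {
    stop_ionprobe("spring_constant must be > 0")
  }
  if (!is_scalar_number(time_step) || time_step <= 0) {
    stop_ionprobe("time_step must be > 0")
  }
  obj <- list(start_position = start_position, pull_distance = pull_distance,
              velocity = velocity, spring_constant = spring_constant,
              spring_convention = spring_convention, time_step = time_step)
  class(obj) <- "pull_schedule"
  obj
}

#' Duration of a pull schedule
#' @param schedule a [pull_schedule()].
#' @return Duration in ns (`pull_distance / velocity`).
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "pull_schedule"))
  schedule$pull_distance / schedule$velocity
}

# Stiffness of dU/d(lambda) per unit (lambda - x): 2k (amber) or k (half).
spring_gradient_factor <- function(schedule) {
  switch(schedule$spring_convention, amber = 2, half = 1) *
    schedule$spring_constant
}

schedule_lambda_grid <- function(schedule) {
  n_steps <- round(schedule_duration(schedule) / schedule$time_step)
  schedule$start_position +
    schedule$velocity * schedule$time_step * (0:n_steps)
}

#' Accumulate nonequilibrium work along a pull
#'
#' Integrates \eqn{dW = (\partial U / \partial \lambda) \, v \, dt} by the
#' trapezoid rule over the target trajectory
#' \eqn{\lambda(t) = \mathrm{start} + vt}, with
#' \eqn{\partial U/\partial\lambda = 2k(\lambda - x)} (amber convention) or
#' \eqn{k(\lambda - x)} (half convention).
#'
#' @param positions particle reaction-coordinate series sampled at
#'   `schedule$time_step`, one value per target grid point.
#' @param schedule a [pull_schedule()].
#' @param replicate_id integer tag stored on the result.
#' @param stride keep every `stride`-th grid point in the output (the
#'   integration itself always runs at full resolution); the first point is
#'   always kept.
#' @return A `work_series`: data.frame with columns `lambda` (Angstrom) and
#'   `work` (kcal/mol, `work[1] = 0`), attribute `replicate_id`.
#' @export
accumulate_work <- function(positions, schedule, replicate_id = 1L,
                            stride = 1L) {
  stopifnot(inherits(schedule, "pull_schedule"))
  lambda <- schedule_lambda_grid(schedule)
  if (length(positions) < length(lambda)) {
    stop_ionprobe("position series has ", length(positions),
                  " samples; schedule needs ", length(lambda))
  }
  positions <- positions[seq_along(lambda)]
  grad <- spring_gradient_factor(schedule) * (lambda - positions)
  dl <- diff(lambda)
  increments <- (grad[-length(grad)] + grad[-1L]) / 2 * dl
  work <- c(0, cumsum(increments))
  keep <- unique(c(seq(1L, length(lambda), by = max(1L, as.integer(stride))),
                   length(lambda)))
  ws <- data.frame(lambda = lambda[keep], work = work[keep])
  attr(ws, "replicate_id") <- as.integer(replicate_id)
  class(ws) <- c("work_series", "data.frame")
  ws
}

#' Estimate a potential of mean force from replicate work series
#'
#' Combines replicate work profiles sharing one target grid into a PMF:
#' \describe{
#'   \item{`mean_work`}{\eqn{F = \langle W \rangle} — the stiff-spring,
#'     slow-pulling approximation (default; robust at small replicate
#'     counts).}
#'   \item{`cumulant2`}{\eqn{F = \langle W \rangle -
#'     \mathrm{var}(W) / (2 k_B T)} — second-order cumulant expansion of the
#'     Jarzynski average, exact for Gaussian work distributions.}
#'   \item{`jarzynski_exp`}{\eqn{F = -k_B T \ln \langle e^{-W/k_B T}\rangle},
#'     evaluated with a log-sum-exp so large work values do not underflow.}
#' }
#' The profile is shifted so \eqn{F = 0} at the grid start, and the spread is
#' the per-point inter-replicate standard deviation of the work.
#'
#' @param works list of `work_series` (shared `lambda` grid).
#' @param temperature temperature, K.
#' @param estimator `"mean_work"`, `"cumulant2"` or `"jarzynski_exp"`.
#' @return A `pmf_profile` (profile subclass) in kcal/mol.
#' @export
estimate_pmf <- function(works, temperature = 300,
                         estimator = c("mean_work", "cumulant2",
                                       "jarzynski_exp")) {
  estimator <- match.arg(estimator)
  if (inherits(works, "work_series")) works <- list(works)
  if (length(works) < 1L) stop_ionprobe("need at least one work series")
  grid <- works[[1L]]$lambda
  for (w in works[-1L]) {
    if (length(w$lambda) != length(grid) ||
        max(abs(w$lambda - grid)) > 1e-9) {
      stop_ionprobe("work series must share one lambda grid")
    }
  }
  W <- vapply(works, function(w) w$work, numeric(length(grid)))
  W <- matrix(W, nrow = length(grid))
  R <- ncol(W)
  kT <- kbt(temperature)
  mean_w <- rowMeans(W)
  var_w <- if (R > 1L) apply(W, 1L, stats::var) else rep(0, length(grid))
  if (R == 1L && estimator == "cumulant2") {
    warning("cumulant2 with a single replicate: variance taken as 0",
            call. = FALSE)
  }
  f <- switch(
    estimator,
    mean_work = mean_w,
    cumulant2 = mean_w - var_w / (2 * kT),
    jarzynski_exp = {
      A <- -W / kT
      m <- apply(A, 1L, max)
      -kT * (m + log(rowMeans(exp(A - m))))
    }
  )
  f <- f - f[1L]
  spread <- if (R > 1L) apply(W, 1L, stats::sd) else rep(0, length(grid))
  new_profile(grid, f, spread = spread,
              meta = list(estimator = estimator, n_replicates = R,
                          temperature = temperature,
                          units = "grid:A, value:kcal/mol"),
              subclass = "pmf_profile")
}

#' Detect barriers/peaks in a profile
#'
#' Smooths the profile with a centered moving average (window shrinks at the
#' edges), scans the smoothed curve for local extrema, and reports those with
#' topographic prominence at or above `min_prominence`. Reported positions are
#' taken at the extremal unsmoothed grid point within the smoothing window of
#' each smoothed extremum; the height of a maximum is measured relative to
#' the lowest point between it and the previous reported maximum (or the
#' grid start).
#'
#' @param profile a profile (PMF, RDF, ...).
#' @param kind `"maxima"` or `"minima"`.
#' @param smooth_window moving-average window, bins (default 5).
#' @param min_prominence minimum prominence to report, profile units
#'   (default 1, the PMF default in kcal/mol; lower it for RDF peaks).
#' @return A `barrier_set`: data.frame with columns `position`, `value`,
#'   `height` (relative to the preceding minimum) and `prominence`, ordered
#'   by position. Empty for constant or strictly monotone profiles.
#' @export
detect_extrema <- function(profile, kind = c("maxima", "minima"),
                           smooth_window = 5L, min_prominence = 1) {
  stopifnot(inherits(profile, "profile"))
  kind <- match.arg(kind)
  v <- profile$values
  n <- length(v)
  if (n <= smooth_window) {
    stop_ionprobe("profile length must exceed the smoothing window")
  }
  sgn <- if (kind == "maxima") 1 else -1
  y_raw <- sgn * v
  half <- max(0L, (as.integer(smooth_window) - 1L) %/% 2L)
  y <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(y_raw[lo:hi])
  }, 0)
  empty <- data.frame(position = numeric(0), value = numeric(0),
                      height = numeric(0), prominence = numeric(0))
  class(empty) <- c("barrier_set", "data.frame")
  if (max(y) - min(y) < .Machine$double.eps * 100) return(empty)
  peaks <- integer(0)
  for (i in 2:(n - 1L)) {
    if (y[i] > y[i - 1L] && y[i] >= y[i + 1L]) peaks <- c(peaks, i)
  }
  if (length(peaks) == 0L) return(empty)
  # topographic prominence on the smoothed curve
  prom <- vapply(peaks, function(p) {
    left_min <- y[p]
    i <- p
    while (i > 1L && y[i - 1L] <= y[p]) {
      i <- i - 1L
      left_min <- min(left_min, y[i])
    }
    if (i == 1L && y[1L] <= y[p]) left_min <- min(left_min, y[1L])
    left_base <- if (i == 1L) min(y[1:p]) else left_min
    right_min <- y[p]
    i <- p
    while (i < n && y[i + 1L] <= y[p]) {
      i <- i + 1L
      right_min <- min(right_min, y[i])
    }
    right_base <- if (i == n) min(y[p:n]) else right_min
    y[p] - max(left_base, right_base)
  }, 0)
  keep <- which(prom >= min_prominence)
  if (length(keep) == 0L) return(empty)
  peaks <- peaks[keep]
  prom <- prom[keep]
  # refine each position to the extremal unsmoothed point near the peak
  pos_idx <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(y_raw[lo:hi]) - 1L
  }, 0L)
  prev <- 1L
  height <- numeric(length(pos_idx))
  for (j in seq_along(pos_idx)) {
    seg <- y_raw[prev:pos_idx[j]]
    height[j] <- y_raw[pos_idx[j]] - min(seg)
    prev <- pos_idx[j]
  }
  out <- data.frame(position = profile$grid[pos_idx],
                    value = v[pos_idx],
                    height = height,
                    prominence = prom)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("barrier_set", "data.frame")
  out
}

#' Squared correlation between two profiles
#'
#' Re-bins both profiles to the coarser grid restricted to their overlapping
#' range by linear interpolation, then returns the squared Pearson
#' correlation of the paired values. With `mode = "invert_a_first"`, profile
#' `a` (an RDF) is first Boltzmann-inverted at `temperature`, so the
#' comparison is free energy against free energy; zero-occupancy bins are
#' dropped pairwise.
#'
#' @param a,b profiles.
#' @param mode `"raw"` or `"invert_a_first"`.
#' @param temperature temperature (K) for the inversion.
#' @return r^2 (scalar in `[0, 1]`).
#' @export
correlate_profiles <- function(a, b, mode = c("raw", "invert_a_first"),
                               temperature = 300) {
  stopifnot(inherits(a, "profile"), inherits(b, "profile"))
  mode <- match.arg(mode)
  if (mode == "invert_a_first") a <- boltzmann_invert(a, temperature)
  lo <- max(min(a$grid), min(b$grid))
  hi <- min(max(a$grid), max(b$grid))
  if (!(hi > lo)) stop_ionprobe("profiles do not overlap")
  a_in <- a$grid >= lo & a$grid <= hi
  b_in <- b$grid >= lo & b$grid <= hi
  coarse <- if (sum(a_in) <= sum(b_in)) a else b
  fine <- if (sum(a_in) <= sum(b_in)) b else a
  grid <- coarse$grid[coarse$grid >= lo & coarse$grid <= hi]
  cv <- coarse$values[coarse$grid >= lo & coarse$grid <= hi]
  fv <- stats::approx(fine$grid, fine$values, xout = grid, rule = 1)$y
  ok <- is.finite(cv) & is.finite(fv)
  if (sum(ok) < 3L) stop_ionprobe("fewer than 3 common finite points")
  x <- cv[ok]; y <- fv[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ionprobe("degenerate profile: zero variance in overlap")
  }
  as.numeric(stats::cor(x, y))^2
}
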