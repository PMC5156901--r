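# Seeded synthetic-data generators with known ground truth: ideal-gas ion
# clouds, Boltzmann-distributed ions in a radial potential, overdamped
# Langevin stiff-spring pulls, planted-mode pseudo-protein ensembles, and
# metal-site PDB fixtures. Every generator returns the data together with
# the ground truth it was built from, so recovery tests never re-derive
# truth from the data.

#' Radial potential specification
#'
#' @param form `"harmonic"` (\eqn{U = k (r - r_0)^2}), `"double_well"`
#'   (\eqn{U = h ((\frac{r - c}{w})^2 - 1)^2} with minima at `r1`, `r2`,
#'   center \eqn{c = (r_1+r_2)/2}, half-width \eqn{w = (r_2-r_1)/2}, barrier
#'   height `h` at the center), or `"table"` (piecewise-linear interpolation
#'   of `table_r`, `table_u`).
#' @param k harmonic force constant, kcal mol^-1 A^-2 (> 0).
#' @param r0 harmonic minimum, Angstrom.
#' @param height double-well barrier height h, kcal/mol (> 0).
#' @param r1,r2 double-well minima, Angstrom (`r1 < r2`).
#' @param table_r,table_u tabulated potential (strictly increasing r).
#' @param temperature temperature, K.
#' @return A `radial_potential` object.
#' @export
radial_potential <- function(form = c("harmonic", "double_well", "table"),
                             k = 1, r0 = 5, height = 5, r1 = 3, r2 = 7,
                             table_r = NULL, table_u = NULL,
                             temperature = 300) {
  form <- match.arg(form)
  if (form == "harmonic" && (!is_scalar_number(k) || k <= 0)) {
    stop_ionprobe("harmonic k must be > 0")
  }
  if (form == "double_well") {
    if (!is_scalar_number(height) || height <= 0) {
      stop_ionprobe("double-well height must be > 0")
    }
    if (!(r1 < r2)) stop_ionprobe("double-well requires r1 < r2")
  }
  if (form == "table") {
    if (is.null(table_r) || is.null(table_u) ||
        length(table_r) != length(table_u) || any(diff(table_r) <= 0)) {
      stop_ionprobe("table form needs matching table_r/table_u with strictly increasing r")
    }
  }
  obj <- list(form = form, k = k, r0 = r0, height = height, r1 = r1, r2 = r2,
              table_r = table_r, table_u = table_u,
              temperature = temperature)
  class(obj) <- "radial_potential"
  obj
}

#' Evaluate a radial potential
#' @param potential a [radial_potential()].
#' @param r radii (Angstrom).
#' @return Potential energy, kcal/mol.
#' @export
potential_energy <- function(potential, r) {
  stopifnot(inherits(potential, "radial_potential"))
  switch(potential$form,
         harmonic = potential$k * (r - potential$r0)^2,
         double_well = {
           cc <- (potential$r1 + potential$r2) / 2
           w <- (potential$r2 - potential$r1) / 2
           potential$height * (((r - cc) / w)^2 - 1)^2
         },
         table = stats::approx(potential$table_r, potential$table_u,
                               xout = r, rule = 2)$y)
}

potential_force <- function(potential, r) {
  # -dU/dr; analytic where possible, central difference for tables
  switch(potential$form,
         harmonic = -2 * potential$k * (r - potential$r0),
         double_well = {
           cc <- (potential$r1 + potential$r2) / 2
           w <- (potential$r2 - potential$r1) / 2
           u <- (r - cc) / w
           -4 * potential$height / w * u * (u^2 - 1)
         },
         table = {
           h <- 1e-4
           -(potential_energy(potential, r + h) -
               potential_energy(potential, r - h)) / (2 * h)
         })
}

ion_cloud_roster <- function(n_ions, reference) {
  ref <- data.frame(serial = 1L, name = "OD1", element = "O",
                    resname = "ASP", resid = 1L, chain = "A",
                    x = reference[1], y = reference[2], z = reference[3],
                    hetero = FALSE, stringsAsFactors = FALSE)
  if (n_ions == 0L) return(ref)
  ions <- data.frame(serial = 1L + seq_len(n_ions), name = "CD",
                     element = "Cd", resname = "CD",
                     resid = 1L + seq_len(n_ions), chain = "B",
                     x = 0, y = 0, z = 0, hetero = TRUE,
                     stringsAsFactors = FALSE)
  rbind(ref, ions)
}

#' Ideal-gas ion cloud (RDF null model)
#'
#' Ions i.i.d. uniform in a cubic (or orthorhombic) box, per frame; a single
#' reference atom (Asp OD1) sits at the box center. Deterministic under
#' `seed`.
#'
#' @param n_ions ions per frame (0 allowed).
#' @param n_frames number of frames.
#' @param box numeric length-1 or length-3 box edge lengths, Angstrom.
#' @param seed RNG seed.
#' @return List with `ensemble` and `truth` (box, density).
#' @export
gen_ideal_gas <- function(n_ions, n_frames, box, seed = 1L) {
  box <- rep(as.numeric(box), length.out = 3L)
  if (any(box <= 0)) stop_ionprobe("box edges must be positive")
  set.seed(seed)
  roster <- ion_cloud_roster(n_ions, box / 2)
  coords <- array(0, dim = c(nrow(roster), 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1, , f] <- box / 2
    if (n_ions > 0L) {
      coords[1L + seq_len(n_ions), , f] <-
        cbind(stats::runif(n_ions, 0, box[1]),
              stats::runif(n_ions, 0, box[2]),
              stats::runif(n_ions, 0, box[3]))
    }
  }
  ens <- new_ensemble(roster, coords, box = box)
  list(ensemble = ens,
       truth = list(box = box, n_ions = n_ions,
                    density = n_ions / prod(box)))
}

#' Boltzmann-distributed ions in a radial potential
#'
#' Metropolis sampling of the radius under
#' \eqn{p(r) \propto r^2 e^{-U(r)/k_B T}} (the 3-D volume element included),
#' with uniform angles. One ion per frame plus the reference atom at
#' `reference`. Defaults: Gaussian proposal sd 0.3 Angstrom, 1000-step
#' burn-in, 10x thinning. A warning is raised when the acceptance rate falls
#' outside [0.1, 0.9].
#'
#' @param potential a [radial_potential()] (bounded below on the sampled
#'   range; its `temperature` sets \eqn{k_B T}).
#' @param reference 3-vector, Angstrom.
#' @param n_samples number of retained samples (= frames).
#' @param seed RNG seed.
#' @param proposal_sd,thin,burn_in Metropolis controls.
#' @param r_init starting radius (default: potential minimum region, 5 A).
#' @return List with `ensemble`, `truth` (the potential), and
#'   `acceptance_rate`.
#' @export
gen_boltzmann_ions <- function(potential, reference = c(0, 0, 0),
                               n_samples = 2000L, seed = 1L,
                               proposal_sd = 0.3, thin = 10L,
                               burn_in = 1000L, r_init = NULL) {
  stopifnot(inherits(potential, "radial_potential"))
  kT <- kbt(potential$temperature)
  set.seed(seed)
  log_target <- function(r) {
    ifelse(r > 0, 2 * log(r) - potential_energy(potential, r) / kT, -Inf)
  }
  r <- r_init %||% switch(potential$form, harmonic = potential$r0,
                          double_well = potential$r1, 5)
  n_steps <- burn_in + n_samples * thin
  samples <- numeric(n_samples)
  n_acc <- 0L
  kept <- 0L
  lt <- log_target(r)
  for (i in seq_len(n_steps)) {
    prop <- r + stats::rnorm(1L, 0, proposal_sd)
    lt_prop <- log_target(prop)
    if (is.finite(lt_prop) && log(stats::runif(1L)) < lt_prop - lt) {
      r <- prop
      lt <- lt_prop
      n_acc <- n_acc + 1L
    }
    if (i > burn_in && (i - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      samples[kept] <- r
    }
  }
  acc <- n_acc / n_steps
  if (acc < 0.1 || acc > 0.9) {
    warning(sprintf("Metropolis acceptance rate %.2f outside [0.1, 0.9]",
                    acc), call. = FALSE)
  }
  # uniform directions on the sphere
  u <- stats::runif(n_samples, -1, 1)
  phi <- stats::runif(n_samples, 0, 2 * pi)
  st <- sqrt(1 - u^2)
  dirs <- cbind(st * cos(phi), st * sin(phi), u)
  roster <- ion_cloud_roster(1L, reference)
  coords <- array(0, dim = c(2L, 3, n_samples))
  for (f in seq_len(n_samples)) {
    coords[1, , f] <- reference
    coords[2, , f] <- reference + samples[f] * dirs[f, ]
  }
  list(ensemble = new_ensemble(roster, coords),
       truth = list(potential = potential, radii = samples),
       acceptance_rate = acc)
}

#' Synthetic stiff-spring pulls by overdamped Langevin dynamics
#'
#' Simulates replicates of a constant-velocity pull over a 1-D radial
#' potential with the overdamped update
#' \deqn{x \leftarrow x + (-U'(x) - \partial U_\mathrm{spring}/\partial x)
#'   \Delta t / \gamma + \sqrt{2 k_B T \Delta t / \gamma}\, \eta}
#' and accumulates work with [accumulate_work()]. The scheme requires
#' \eqn{k_\mathrm{eff} \Delta t / \gamma < 0.1} (checked; the error suggests
#' a suitable time step).
#'
#' @param schedule a [pull_schedule()].
#' @param potential a [radial_potential()].
#' @param friction gamma, kcal mol^-1 ns A^-2 (default 50).
#' @param temperature temperature, K.
#' @param n_replicates number of independent pulls.
#' @param seed RNG seed.
#' @param x_init starting particle position (default: schedule start).
#' @param stride thinning of the reported work grid (see
#'   [accumulate_work()]).
#' @return List with `works` (list of `work_series`), `positions` (matrix,
#'   steps x replicates), and `truth` (the potential and schedule).
#' @export
gen_smd_pulls <- function(schedule, potential, friction = 50,
                          temperature = 300, n_replicates = 4L, seed = 1L,
                          x_init = NULL, stride = 1L) {
  stopifnot(inherits(schedule, "pull_schedule"),
            inherits(potential, "radial_potential"))
  if (!is_scalar_number(friction) || friction <= 0) {
    stop_ionprobe("friction must be > 0")
  }
  if (n_replicates < 1L) stop_ionprobe("need at least one replicate")
  k_eff <- spring_gradient_factor(schedule)
  dt <- schedule$time_step
  if (k_eff * dt / friction >= 0.1) {
    stop_ionprobe(sprintf(
      "unstable integration: k*dt/gamma = %.3f >= 0.1; use time_step < %.4g ns",
      k_eff * dt / friction, 0.1 * friction / k_eff))
  }
  set.seed(seed)
  lambda <- schedule_lambda_grid(schedule)
  n_steps <- length(lambda)
  x <- rep(x_init %||% schedule$start_position, n_replicates)
  kT <- kbt(temperature)
  noise_scale <- sqrt(2 * kT * dt / friction)
  positions <- matrix(NA_real_, nrow = n_steps, ncol = n_replicates)
  positions[1L, ] <- x
  for (i in 2:n_steps) {
    f_pot <- potential_force(potential, x)
    f_spring <- k_eff * (lambda[i - 1L] - x)
    x <- x + (f_pot + f_spring) * dt / friction +
      noise_scale * stats::rnorm(n_replicates)
    positions[i, ] <- x
  }
  works <- lapply(seq_len(n_replicates), function(r) {
    accumulate_work(positions[, r], schedule, replicate_id = r,
                    stride = stride)
  })
  list(works = works, positions = positions,
       truth = list(potential = potential, schedule = schedule,
                    friction = friction, temperature = temperature))
}

#' Planted-mode specification for synthetic ensembles
#'
#' @param sampler `"gaussian"` (amplitude sd `sd`, Angstrom) or
#'   `"double_well"` (amplitude distributed as
#'   \eqn{\propto e^{-U(q)/k_B T}} with
#'   \eqn{U(q) = h((q/w)^2 - 1)^2}: modes at \eqn{\pm w}).
#' @param sd Gaussian amplitude sd, Angstrom.
#' @param height,width double-well barrier height (kcal/mol) and minima
#'   position w (Angstrom).
#' @param temperature temperature (K) for the double-well sampler.
#' @param direction optional 3N unit vector; `NULL` draws a random seeded
#'   direction.
#' @return A `mode_spec`.
#' @export
mode_spec <- function(sampler = c("gaussian", "double_well"), sd = 1,
                      height = 1.2, width = 2, temperature = 300,
                      direction = NULL) {
  sampler <- match.arg(sampler)
  obj <- list(sampler = sampler, sd = sd, height = height, width = width,
              temperature = temperature, direction = direction)
  class(obj) <- "mode_spec"
  obj
}

sample_mode_amplitudes <- function(spec, n) {
  if (spec$sampler == "gaussian") return(stats::rnorm(n, 0, spec$sd))
  kT <- kbt(spec$temperature)
  u_fun <- function(q) spec$height * ((q / spec$width)^2 - 1)^2
  q <- spec$width
  burn_in <- 1000L
  thin <- 10L
  out <- numeric(n)
  e <- u_fun(q)
  prop_sd <- spec$width
  kept <- 0L
  for (i in seq_len(burn_in + n * thin)) {
    prop <- q + stats::rnorm(1L, 0, prop_sd)
    e_prop <- u_fun(prop)
    if (log(stats::runif(1L)) < (e - e_prop) / kT) {
      q <- prop
      e <- e_prop
    }
    if (i > burn_in && (i - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      out[kept] <- q
    }
  }
  out
}

random_rotation_matrix <- function() {
  repeat {
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_dec <- qr(M)
    Q <- qr.Q(qr_dec)
    Q <- Q %*% diag(sign(diag(qr.R(qr_dec))))
    if (det(Q) > 0) return(Q)
  }
}

#' Pseudo-protein ensemble with planted covariance modes
#'
#' Places `n_atoms` pseudo alpha-carbons on a helix-like curve (3.8 Angstrom
#' spacing), then displaces each frame along the planted mode directions
#' (orthonormalized internally) with amplitudes drawn from each mode's
#' sampler, plus isotropic per-atom Gaussian noise. With
#' `rigid_jitter = TRUE`, a random rigid-body rotation/translation is
#' applied per frame (to be removed again by [align_ensemble()]).
#'
#' @param n_atoms number of pseudo-atoms (>= 4).
#' @param modes list of [mode_spec()] objects.
#' @param n_frames number of frames.
#' @param noise_sd isotropic per-atom-coordinate noise sd, Angstrom
#'   (default 0.1, i.e. 0.01 A^2 variance).
#' @param rigid_jitter apply a random rigid transform per frame.
#' @param internal_modes orthogonalize mode directions against the base
#'   geometry's rigid-body subspace (3 translations + 3 infinitesimal
#'   rotations) so planted modes are purely internal and survive
#'   superposition unchanged (default `TRUE`).
#' @param seed RNG seed.
#' @return List with `ensemble` and `truth` (base coordinates, orthonormal
#'   mode direction matrix 3N x M, per-frame amplitudes, noise sd).
#' @export
gen_mode_ensemble <- function(n_atoms, modes, n_frames, noise_sd = 0.1,
                              rigid_jitter = FALSE, internal_modes = TRUE,
                              seed = 1L) {
  if (n_atoms < 4L) stop_ionprobe("need at least 4 atoms")
  if (inherits(modes, "mode_spec")) modes <- list(modes)
  set.seed(seed)
  n3 <- 3L * n_atoms
  # helix-like backbone: radius 2.3 A, rise 1.5 A, 100 degrees per residue
  idx <- seq_len(n_atoms)
  theta <- idx * 100 * pi / 180
  base <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * idx)
  rigid_basis <- NULL
  if (internal_modes) {
    cen <- sweep(base, 2L, colMeans(base))
    rigid <- matrix(0, nrow = n3, ncol = 6L)
    for (ax in 1:3) {
      tr <- matrix(0, n_atoms, 3); tr[, ax] <- 1
      rigid[, ax] <- as.vector(t(tr))
      omega <- c(0, 0, 0); omega[ax] <- 1
      rot <- t(apply(cen, 1L, function(p)
        c(omega[2] * p[3] - omega[3] * p[2],
          omega[3] * p[1] - omega[1] * p[3],
          omega[1] * p[2] - omega[2] * p[1])))
      rigid[, 3L + ax] <- as.vector(t(rot))
    }
    rigid_basis <- qr.Q(qr(rigid))
  }
  directions <- matrix(0, nrow = n3, ncol = length(modes))
  for (m in seq_along(modes)) {
    v <- modes[[m]]$direction %||% stats::rnorm(n3)
    if (length(v) != n3) stop_ionprobe("mode direction must have length 3N")
    if (!is.null(rigid_basis)) {
      v <- v - rigid_basis %*% crossprod(rigid_basis, v)
    }
    if (m > 1L) {
      prev <- directions[, seq_len(m - 1L), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stop_ionprobe("mode directions are linearly dependent")
    directions[, m] <- v / nv
  }
  amplitudes <- vapply(modes, sample_mode_amplitudes, numeric(n_frames),
                       n = n_frames)
  amplitudes <- matrix(amplitudes, nrow = n_frames)
  coords <- array(NA_real_, dim = c(n_atoms, 3, n_frames))
  base_flat <- as.vector(t(base))
  for (f in seq_len(n_frames)) {
    flat <- base_flat + directions %*% amplitudes[f, ] +
      stats::rnorm(n3, 0, noise_sd)
    xyz <- matrix(flat, ncol = 3L, byrow = TRUE)
    if (rigid_jitter) {
      R <- random_rotation_matrix()
      shift <- stats::rnorm(3L, 0, 5)
      xyz <- sweep(xyz %*% R, 2L, shift, `+`)
    }
    coords[, , f] <- xyz
  }
  atoms <- data.frame(serial = idx, name = "CA", element = "C",
                      resname = "ALA", resid = idx, chain = "A",
                      x = base[, 1], y = base[, 2], z = base[, 3],
                      hetero = FALSE, stringsAsFactors = FALSE)
  list(ensemble = new_ensemble(atoms, coords),
       truth = list(base = base, directions = directions,
                    amplitudes = amplitudes, noise_sd = noise_sd,
                    modes = modes))
}

TETRAHEDRAL_VERTICES <- matrix(c(1, 1, 1,
                                 1, -1, -1,
                                 -1, 1, -1,
                                 -1, -1, 1) / sqrt(3), ncol = 3,
                               byrow = TRUE)

SQUARE_PLANAR_VERTICES <- matrix(c(1, 0, 0,
                                   -1, 0, 0,
                                   0, 1, 0,
                                   0, -1, 0), ncol = 3, byrow = TRUE)

#' Metal-site structure fixtures
#'
#' Builds one structure per site specification: the metal at the origin and
#' donor atoms placed at prescribed distances on prescribed geometry
#' vertices (randomly rotated as a whole, which preserves all angles).
#' Ligand tokens use the [classify_ligand()] vocabulary as
#' `"RESNAME:ATOM"`; a token like `"ASP:OD1+OD2"` places both atoms on the
#' same residue (bidentate, second atom offset ~0.8 Angstrom from the
#' first).
#'
#' @param spec_list list of site specs; each a list with `metal` (element),
#'   `ligands` (character tokens), `distances` (recycled to the ligand
#'   count), `geometry` (`"tetrahedral"`, `"square_planar"`, or an n x 3
#'   matrix of unit vectors), and optionally `expected_match` (logical
#'   ground-truth label carried into `truth`).
#' @param seed RNG seed (site orientations).
#' @return List with `structures` (list of structures, named site_1..n) and
#'   `truth` (data.frame: site, metal, n_ligand_tokens, expected_match).
#' @export
gen_metal_fixtures <- function(spec_list, seed = 1L) {
  set.seed(seed)
  structures <- list()
  truth <- list()
  for (s in seq_along(spec_list)) {
    sp <- spec_list[[s]]
    metal <- sp$metal %||% "Cd"
    ligands <- sp$ligands
    if (is.null(ligands) || length(ligands) == 0L) {
      stop_ionprobe("site ", s, ": no ligand tokens")
    }
    n_lig <- length(ligands)
    dists <- rep(sp$distances %||% 2.2, length.out = n_lig)
    geom <- sp$geometry %||% "tetrahedral"
    vertices <- if (is.matrix(geom)) geom
    else switch(geom,
                tetrahedral = TETRAHEDRAL_VERTICES,
                square_planar = SQUARE_PLANAR_VERTICES,
                stop_ionprobe("site ", s, ": unknown geometry '", geom, "'"))
    if (n_lig > nrow(vertices)) {
      stop_ionprobe("site ", s, ": ", n_lig, " ligands but geometry has ",
                    nrow(vertices), " vertices")
    }
    R <- random_rotation_matrix()
    vertices <- vertices %*% R
    atoms <- data.frame(serial = 1L, name = toupper(metal),
                        element = metal, resname = toupper(metal),
                        resid = 1L, chain = "A", x = 0, y = 0, z = 0,
                        hetero = TRUE, stringsAsFactors = FALSE)
    serial <- 1L
    for (j in seq_len(n_lig)) {
      tok <- strsplit(ligands[j], ":", fixed = TRUE)[[1L]]
      if (length(tok) != 2L) {
        stop_ionprobe("site ", s, ": bad ligand token '", ligands[j],
                      "' (want RESNAME:ATOM)")
      }
      resname <- toupper(tok[1L])
      atom_names <- strsplit(tok[2L], "+", fixed = TRUE)[[1L]]
      if (!(resname %in% c(STANDARD_AA, WATER_RESNAMES))) {
        stop_ionprobe("site ", s, ": unknown residue '", resname, "'")
      }
      pos <- vertices[j, ] * dists[j]
      for (a in seq_along(atom_names)) {
        serial <- serial + 1L
        p <- pos
        if (a > 1L) {
          # second donor of a bidentate group: offset along a tangent so it
          # stays at a comparable metal distance
          tangent <- vertices[(j %% nrow(vertices)) + 1L, ]
          tangent <- tangent - sum(tangent * vertices[j, ]) * vertices[j, ]
          tangent <- tangent / sqrt(sum(tangent^2))
          p <- pos + 0.8 * tangent
        }
        atoms <- rbind(atoms, data.frame(
          serial = serial, name = toupper(atom_names[a]),
          element = substr(toupper(atom_names[a]), 1, 1),
          resname = resname, resid = 1L + j, chain = "A",
          x = p[1], y = p[2], z = p[3],
          hetero = resname %in% WATER_RESNAMES,
          stringsAsFactors = FALSE))
      }
    }
    id <- sprintf("site_%d", s)
    structures[[id]] <- new_structure(atoms)
    truth[[s]] <- data.frame(site = id, metal = metal,
                             n_ligand_tokens = n_lig,
                             expected_match = sp$expected_match %||% NA,
                             stringsAsFactors = FALSE)
  }
  list(structures = structures, truth = do.call(rbind, truth))
}

#' Ten-site census fixture set with three UNG-like sites by construction
#'
#' Convenience wrapper around [gen_metal_fixtures()]: ten Cd sites of which
#' exactly three match the UNG-like motif (one Asp/Glu carboxyl plus one His
#' imidazole); the rest violate the exact-count rule in different ways (two
#' imidazoles, two carboxyls, missing partner, all-water, non-table donors).
#'
#' @param seed RNG seed.
#' @return As [gen_metal_fixtures()].
#' @export
ung_like_fixture_set <- function(seed = 1L) {
  specs <- list(
    list(ligands = c("ASP:OD1", "HIS:ND1", "PRO:O", "HOH:O"),
         expected_match = TRUE),
    list(ligands = c("GLU:OE1", "HIS:NE2", "HOH:O", "HOH:O"),
         expected_match = TRUE),
    list(ligands = c("ASP:OD1+OD2", "HIS:ND1", "GLY:O"),
         expected_match = TRUE),
    list(ligands = c("ASP:OD1", "HIS:ND1", "HIS:NE2", "HOH:O"),
         expected_match = FALSE),
    list(ligands = c("ASP:OD1", "GLU:OE1", "HIS:ND1", "HOH:O"),
         expected_match = FALSE),
    list(ligands = c("ASP:OD1", "HOH:O", "HOH:O", "HOH:O"),
         expected_match = FALSE),
    list(ligands = c("HIS:ND1", "HOH:O", "HOH:O", "HOH:O"),
         expected_match = FALSE),
    list(ligands = c("HOH:O", "HOH:O", "HOH:O", "HOH:O"),
         expected_match = FALSE),
    list(ligands = c("LYS:NZ", "ASP:OD1", "HOH:O", "HOH:O"),
         expected_match = FALSE),
    list(ligands = c("CYS:SG", "HIS:ND1", "HOH:O", "HOH:O"),
         expected_match = FALSE)
  )
  specs <- lapply(specs, function(sp) {
    sp$metal <- "Cd"
    sp$geometry <- "tetrahedral"
    sp$distances <- 2.2
    sp
  })
  gen_metal_fixtures(specs, seed = seed)
}
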