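# Generator contracts: determinism under seeds, distributional ground truth,
# integrator stability, and fixture labelling.

test_that("all generators are bit-reproducible under a fixed seed", {
  g1 <- gen_ideal_gas(10, 20, 30, seed = 5)
  g2 <- gen_ideal_gas(10, 20, 30, seed = 5)
  expect_identical(g1$ensemble$coords, g2$ensemble$coords)

  pot <- radial_potential("harmonic", k = 2, r0 = 5)
  b1 <- gen_boltzmann_ions(pot, n_samples = 200, seed = 5)
  b2 <- gen_boltzmann_ions(pot, n_samples = 200, seed = 5)
  expect_identical(b1$ensemble$coords, b2$ensemble$coords)

  sch <- pull_schedule(0, 1, 0.1, 20, time_step = 0.01)
  p1 <- gen_smd_pulls(sch, pot, friction = 50, n_replicates = 2, seed = 5)
  p2 <- gen_smd_pulls(sch, pot, friction = 50, n_replicates = 2, seed = 5)
  expect_identical(p1$positions, p2$positions)

  m1 <- gen_mode_ensemble(10, mode_spec("gaussian", sd = 1), 50, seed = 5)
  m2 <- gen_mode_ensemble(10, mode_spec("gaussian", sd = 1), 50, seed = 5)
  expect_identical(m1$ensemble$coords, m2$ensemble$coords)

  f1 <- ung_like_fixture_set(seed = 5)
  f2 <- ung_like_fixture_set(seed = 5)
  expect_identical(f1$structures$site_1$atoms, f2$structures$site_1$atoms)
})

test_that("ideal-gas ions have uniform-box moments", {
  box <- 30
  sim <- gen_ideal_gas(n_ions = 50, n_frames = 100, box = box, seed = 9)
  ions <- sim$ensemble$atoms$hetero
  n <- sum(ions) * n_frames(sim$ensemble)
  se <- box / sqrt(12) / sqrt(n)
  for (ax in 1:3) {
    m <- mean(sim$ensemble$coords[ions, ax, ])
    expect_lt(abs(m - box / 2), 3 * se)
  }
  empty <- gen_ideal_gas(0, 3, 30, seed = 1)
  expect_equal(nrow(empty$ensemble$atoms), 1L)  # reference only
})

test_that("Boltzmann radial sampler matches the quadrature mean radius", {
  pot <- radial_potential("harmonic", k = 2, r0 = 5, temperature = 300)
  kT <- 0.0019872041 * 300
  dens <- function(r) r^2 * exp(-potential_energy(pot, r) / kT)
  Z <- integrate(dens, 0, 20)$value
  mean_r <- integrate(function(r) r * dens(r), 0, 20)$value / Z
  var_r <- integrate(function(r) (r - mean_r)^2 * dens(r), 0, 20)$value / Z

  sim <- gen_boltzmann_ions(pot, n_samples = 2000, seed = 12)
  r <- sim$truth$radii
  # thinned Metropolis samples still carry some autocorrelation; allow a
  # conservative factor on the nominal standard error
  se <- sqrt(var_r / length(r)) * 3
  expect_lt(abs(mean(r) - mean_r), 3 * se)
  expect_gt(sim$acceptance_rate, 0.1)
  expect_lt(sim$acceptance_rate, 0.9)

  # near-zero temperature concentrates samples at the minimum
  cold <- radial_potential("harmonic", k = 2, r0 = 5, temperature = 5)
  csim <- suppressWarnings(gen_boltzmann_ions(cold, n_samples = 300,
                                              seed = 3))
  expect_lt(abs(mean(csim$truth$radii) - 5), 0.2)
  expect_lt(sd(csim$truth$radii), 0.2)

  # different seeds: different chains, same distribution
  simB <- gen_boltzmann_ions(pot, n_samples = 2000, seed = 13)
  expect_false(identical(sim$truth$radii, simB$truth$radii))
  expect_lt(abs(mean(simB$truth$radii) - mean_r), 3 * se)
})

test_that("Langevin pulls obey the stiff-spring and reversible limits", {
  flat <- radial_potential("table", table_r = c(0, 100),
                           table_u = c(0, 0))
  # zero temperature, stiff spring: the particle tracks the target
  sch <- pull_schedule(0, 2, 0.05, spring_constant = 20, time_step = 0.002)
  cold <- gen_smd_pulls(sch, flat, friction = 2, temperature = 1e-9,
                        n_replicates = 1, seed = 2)
  lag <- abs(cold$positions[nrow(cold$positions), 1] - 2)
  expect_lt(lag, 0.05)
  expect_lt(abs(cold$works[[1]]$work[length(cold$works[[1]]$work)]), 0.5)

  # quasi-reversible pull across a flat landscape: mean work near zero
  slow <- pull_schedule(0, 2, 0.02, spring_constant = 20, time_step = 0.01)
  sim <- gen_smd_pulls(slow, flat, friction = 5, temperature = 300,
                       n_replicates = 8, seed = 4)
  final_w <- vapply(sim$works, function(w) w$work[length(w$work)], 0)
  expect_lt(abs(mean(final_w)), 0.5)

  # instability is caught with a suggested time step
  bad <- pull_schedule(0, 1, 0.1, spring_constant = 20, time_step = 0.5)
  expect_error(gen_smd_pulls(bad, flat, friction = 10), "time_step")
})

test_that("slower pulling reduces the PMF error against the planted truth", {
  pot <- radial_potential("harmonic", k = 1, r0 = 3, temperature = 300)
  rmse_at <- function(v) {
    sch <- pull_schedule(1, 4, v, spring_constant = 20, time_step = 0.02)
    sim <- gen_smd_pulls(sch, pot, friction = 50, n_replicates = 8,
                         seed = 6, stride = max(1L, round(0.25 / (v * 0.02))))
    pmf <- estimate_pmf(sim$works, 300, "mean_work")
    truth <- potential_energy(pot, pmf$grid)
    truth <- truth - truth[1]
    sqrt(mean((pmf$values - truth)^2))
  }
  expect_lt(rmse_at(0.01), rmse_at(0.16))
})

test_that("planted double-well modes flow through to the modality verdict", {
  sim <- gen_mode_ensemble(30, mode_spec("double_well", height = 1.2,
                                         width = 2),
                           n_frames = 1000, noise_sd = 0.1,
                           rigid_jitter = TRUE, seed = 15)
  al <- align_ensemble(sim$ensemble, 1:30)
  model <- build_pca(al, 1:30)
  verdict <- classify_modality(project_frames(al, model, 1))
  expect_equal(verdict$verdict, "anharmonic")

  gsim <- gen_mode_ensemble(30, mode_spec("gaussian", sd = 2),
                            n_frames = 1000, noise_sd = 0.1,
                            rigid_jitter = TRUE, seed = 16)
  gal <- align_ensemble(gsim$ensemble, 1:30)
  gmodel <- build_pca(gal, 1:30)
  gverdict <- classify_modality(project_frames(gal, gmodel, 1))
  expect_equal(gverdict$verdict, "harmonic")

  expect_error(gen_mode_ensemble(3, mode_spec("gaussian"), 10), "4 atoms")
})

test_that("mode directions are orthonormal and internal", {
  sim <- gen_mode_ensemble(20, list(mode_spec("gaussian", sd = 1),
                                    mode_spec("gaussian", sd = 0.5)),
                           n_frames = 10, seed = 20)
  D <- sim$truth$directions
  expect_equal(crossprod(D), diag(2), tolerance = 1e-8)
  # internal modes carry no net translation
  for (m in 1:2) {
    comp <- matrix(D[, m], ncol = 3, byrow = TRUE)
    expect_equal(colSums(comp), c(0, 0, 0), tolerance = 1e-8)
  }
})

test_that("metal fixture generation validates its tokens", {
  expect_error(gen_metal_fixtures(list(list(ligands = "NOPE"))), "token")
  expect_error(gen_metal_fixtures(list(list(ligands = "ZZZ:O1"))),
               "unknown residue")
  expect_error(gen_metal_fixtures(list(list(ligands = rep("HOH:O", 5),
                                            geometry = "tetrahedral"))),
               "vertices")
  expect_error(gen_metal_fixtures(list(list(ligands = "HOH:O",
                                            geometry = "banana"))),
               "unknown geometry")
})
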