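# Superposition, covariance PCA, projections, modality classification, and
# displacement-versus-distance binning.

test_that("superposition removes planted rigid-body transforms exactly", {
  set.seed(21)
  base <- gen_mode_ensemble(20, mode_spec("gaussian", sd = 0),
                            n_frames = 1, noise_sd = 0, seed = 1)$ensemble
  ref_xyz <- base$coords[, , 1]
  nf <- 12L
  coords <- array(NA_real_, dim = c(20, 3, nf))
  for (f in seq_len(nf)) {
    M <- matrix(rnorm(9), 3, 3)
    qr_d <- qr(M)
    R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    coords[, , f] <- sweep(ref_xyz %*% R, 2, rnorm(3, sd = 4), `+`)
  }
  ens <- new_ensemble(base$atoms, coords)
  al <- align_ensemble(ens, 1:20)
  mean_xyz <- apply(al$coords, c(1, 2), mean)
  rmsd <- vapply(seq_len(nf), function(f) {
    sqrt(mean(rowSums((al$coords[, , f] - mean_xyz)^2)))
  }, 0)
  expect_lt(max(rmsd), 1e-6)
})

test_that("superposition agrees with an independent rigid-fit oracle", {
  skip_if_not_installed("bio3d")
  set.seed(3)
  sim <- gen_mode_ensemble(15, mode_spec("gaussian", sd = 1),
                           n_frames = 2, noise_sd = 0.05, seed = 8)
  a <- sim$ensemble$coords[, , 1]
  b <- sim$ensemble$coords[, , 2]
  inds <- seq_len(45)
  fit <- bio3d::fit.xyz(fixed = as.vector(t(a)),
                        mobile = matrix(as.vector(t(b)), nrow = 1),
                        fixed.inds = inds, mobile.inds = inds)
  oracle_rmsd <- sqrt(mean((fit - as.vector(t(a)))^2) * 3)
  ens <- new_ensemble(sim$ensemble$atoms,
                      array(c(a, b), dim = c(15, 3, 2)))
  al <- align_ensemble(ens, 1:15)
  ours <- sqrt(mean(rowSums((al$coords[, , 2] - al$coords[, , 1])^2)))
  expect_equal(ours, oracle_rmsd, tolerance = 1e-4)
})

test_that("alignment rejects collinear selections and centers single frames", {
  atoms <- data.frame(serial = 1:5, name = "CA", element = "C",
                      resname = "ALA", resid = 1:5, chain = "A",
                      x = 1:5, y = 0, z = 0, hetero = FALSE)
  line <- new_ensemble(atoms, array(rep(cbind(1:5, 0, 0), 2),
                                    dim = c(5, 3, 2)))
  expect_error(align_ensemble(line, 1:5), "collinear")

  one <- gen_mode_ensemble(10, mode_spec("gaussian", sd = 1),
                           n_frames = 1, seed = 2)$ensemble
  al <- align_ensemble(one, 1:10)
  expect_equal(colMeans(al$coords[, , 1]), c(0, 0, 0), tolerance = 1e-9)
})

test_that("PCA recovers a planted mode's variance and direction", {
  sim <- gen_mode_ensemble(50, mode_spec("gaussian", sd = 2),
                           n_frames = 2000, noise_sd = 0.1,
                           rigid_jitter = FALSE, seed = 11)
  al <- align_ensemble(sim$ensemble, 1:50)
  model <- build_pca(al, 1:50)
  expect_equal(model$eigenvalues[1], 4, tolerance = 0.1)
  planted <- sim$truth$directions[, 1]
  expect_gt(abs(sum(model$eigenvectors[, 1] * planted)), 0.99)
  # eigenvalue sum equals the covariance trace (total variance)
  X <- t(vapply(seq_len(n_frames(al)),
                function(f) as.vector(t(al$coords[, , f])), numeric(150)))
  expect_equal(sum(model$eigenvalues), sum(apply(X, 2, var)),
               tolerance = 1e-8)
})

test_that("degenerate ensembles give zero spectra and errors", {
  sim <- gen_mode_ensemble(10, mode_spec("gaussian", sd = 0),
                           n_frames = 5, noise_sd = 0, seed = 2)
  model <- build_pca(sim$ensemble, 1:10)
  expect_true(all(model$eigenvalues == 0))
  one_frame <- gen_mode_ensemble(10, mode_spec("gaussian", sd = 1),
                                 n_frames = 1, seed = 2)$ensemble
  expect_error(build_pca(one_frame, 1:10), "at least 2 frames")
})

test_that("component counts for a variance fraction follow the spectrum", {
  fake <- structure(list(selection = 1:2, mean_coords = rep(0, 6),
                         eigenvalues = c(4, 3, 2, 1),
                         eigenvectors = diag(4), n_frames = 10),
                    class = "pca_model")
  expect_equal(n_components_for_fraction(fake, 0.9), 3L)
  expect_equal(n_components_for_fraction(fake, 0.4), 1L)
  expect_equal(n_components_for_fraction(fake, 1.0), 4L)
  fake$eigenvalues <- c(5, 0, 0, 0)
  expect_equal(n_components_for_fraction(fake, 0.999), 1L)
  expect_error(n_components_for_fraction(fake, 0), "fraction")
  expect_error(n_components_for_fraction(fake, 1.5), "fraction")

  # planted spectrum built so 13 components reach 90%: geometric head plus
  # a flat tail; verified here against the cumulative-sum oracle
  head <- 0.9 * 0.82^(0:12) / sum(0.82^(0:12))
  tail <- rep(0.1 / 20, 20)
  spectrum <- c(head, tail)
  expect_equal(which(cumsum(spectrum) / sum(spectrum) >= 0.9)[1], 13L)
  fake13 <- structure(list(eigenvalues = spectrum), class = "pca_model")
  expect_equal(n_components_for_fraction(fake13, 0.9), 13L)
})

test_that("projections are exact inner products with the eigenvectors", {
  sim <- gen_mode_ensemble(20, mode_spec("gaussian", sd = 1.5),
                           n_frames = 300, noise_sd = 0.1, seed = 5)
  al <- align_ensemble(sim$ensemble, 1:20)
  model <- build_pca(al, 1:20)

  # frame equal to the mean structure projects to zero everywhere
  mean_xyz <- matrix(model$mean_coords, ncol = 3, byrow = TRUE)
  ens_mean <- new_ensemble(al$atoms, array(mean_xyz, dim = c(20, 3, 1)))
  for (j in c(1, 2, 10)) {
    expect_equal(as.numeric(project_frames(ens_mean, model, j)), 0,
                 tolerance = 1e-9)
  }

  # frame = mean + 2.5 * e_j lands at 2.5 on j and 0 elsewhere
  j <- 2L
  shifted <- model$mean_coords + 2.5 * model$eigenvectors[, j]
  ens_sh <- new_ensemble(al$atoms,
                         array(matrix(shifted, ncol = 3, byrow = TRUE),
                               dim = c(20, 3, 1)))
  expect_equal(as.numeric(project_frames(ens_sh, model, j)), 2.5,
               tolerance = 1e-9)
  expect_equal(as.numeric(project_frames(ens_sh, model, 1L)), 0,
               tolerance = 1e-9)
  expect_error(project_frames(ens_sh, model, 100L), "out of range")

  # on the training ensemble: projection variance = eigenvalue, and
  # projections on different components are uncorrelated
  p1 <- as.numeric(project_frames(al, model, 1))
  p2 <- as.numeric(project_frames(al, model, 2))
  expect_equal(var(p1), model$eigenvalues[1], tolerance = 1e-10)
  expect_equal(var(p2), model$eigenvalues[2], tolerance = 1e-10)
  expect_lt(abs(cor(p1, p2)), 1e-8)
})

test_that("PCA eigenvalues are invariant to a rigid pre-transform", {
  sim <- gen_mode_ensemble(25, mode_spec("gaussian", sd = 1),
                           n_frames = 200, noise_sd = 0.1, seed = 9)
  al <- align_ensemble(sim$ensemble, 1:25)
  m1 <- build_pca(al, 1:25)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  rot <- sim$ensemble
  for (f in seq_len(n_frames(rot))) {
    rot$coords[, , f] <- sweep(rot$coords[, , f] %*% R, 2,
                               c(3, -2, 8), `+`)
  }
  m2 <- build_pca(align_ensemble(rot, 1:25), 1:25)
  expect_equal(m2$eigenvalues[1:10], m1$eigenvalues[1:10],
               tolerance = 1e-6)
})

test_that("modality classification separates Gaussian from bimodal series", {
  set.seed(1)
  null_series <- rnorm(5000)
  r_null <- classify_modality(null_series)
  expect_equal(r_null$verdict, "harmonic")
  expect_equal(r_null$n_modes_fit, 1L)

  set.seed(2)
  bimodal <- c(rnorm(2500, -2, 0.5), rnorm(2500, 2, 0.5))
  r_bi <- classify_modality(bimodal)
  expect_equal(r_bi$verdict, "anharmonic")
  expect_equal(sort(r_bi$component_means), c(-2, 2), tolerance = 0.1)
  expect_true(all(r_bi$weights >= 0.2))

  expect_error(classify_modality(rep(1, 500)), "zero variance")
  expect_error(classify_modality(rnorm(50)), "at least 200")
})

test_that("displacement-versus-distance binning reproduces a scripted step", {
  sim <- gen_mode_ensemble(20, mode_spec("gaussian", sd = 1),
                           n_frames = 200, noise_sd = 0.05, seed = 4)
  al <- align_ensemble(sim$ensemble, 1:20)
  model <- build_pca(al, 1:20)

  # forward model: displacement is a step function of distance
  nf <- 400L
  d <- seq(2, 12, length.out = nf)
  disp <- ifelse(d < 7, -1.5, 2.0)
  coords <- array(NA_real_, dim = c(20, 3, nf))
  for (f in seq_len(nf)) {
    flat <- model$mean_coords + disp[f] * model$eigenvectors[, 1]
    coords[, , f] <- matrix(flat, ncol = 3, byrow = TRUE)
  }
  pull <- new_ensemble(al$atoms, coords)
  prof <- project_vs_distance(pull, model, 1, d, bin_width = 0.5)
  low <- prof$grid < 6.5
  high <- prof$grid > 7.5
  expect_equal(unique(round(prof$values[low], 6)), -1.5)
  expect_equal(unique(round(prof$values[high], 6)), 2.0)

  # constant displacement gives a flat profile at that constant
  flat_prof <- project_vs_distance(pull, model, 2, d, bin_width = 0.5)
  expect_equal(max(abs(flat_prof$values)), 0, tolerance = 1e-9)

  expect_error(project_vs_distance(pull, model, 1, d[-1]), "frames")
})
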