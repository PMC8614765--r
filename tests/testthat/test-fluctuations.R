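# Superposition, block MSF, per-residue profiles, radius of gyration and the
# sigma^2(P,T) surface. The independent oracle is Horn's quaternion method
# (helper-fixtures.R); the package uses Kabsch SVD.

ref_coords <- function(n = 8, seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 5), ncol = 3)
}

test_that("superpose removes exact rigid-body transforms", {
  coords <- ref_coords()
  atoms <- make_atoms(coords)
  ref <- structure_frame(atoms)
  R <- random_rotation(2)
  moved <- sweep(coords %*% t(R), 2, c(3, -7, 11), "+")
  fr <- structure_frame(make_atoms(moved))
  out <- superpose(fr, ref, selection = "all")
  expect_equal(frame_coords(out), coords, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(attr(out, "rmsd"), 1e-8)
})

test_that("superpose matches the quaternion oracle on noisy structures", {
  coords <- ref_coords(10, seed = 3)
  set.seed(4)
  noisy <- coords + matrix(rnorm(30, sd = 0.6), ncol = 3)
  R <- random_rotation(5)
  mob <- sweep(noisy %*% t(R), 2, c(1, 2, 3), "+")
  ref <- structure_frame(make_atoms(coords))
  fr <- structure_frame(make_atoms(mob))
  out <- superpose(fr, ref, selection = "all")
  expect_equal(attr(out, "rmsd"), horn_rmsd(mob, coords), tolerance = 1e-9)
  expect_equal(frame_coords(out), horn_apply(mob, coords), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("superposition needs at least 3 selected atoms", {
  fr <- structure_frame(make_atoms(matrix(rnorm(6), ncol = 3)))
  expect_error(superpose(fr, fr, selection = "all"), "at least 3")
})

test_that("constant trajectory has exactly zero MSF", {
  coords <- ref_coords()
  atoms <- make_atoms(coords)
  tr <- make_traj(atoms, replicate(10, coords, simplify = FALSE))
  st <- block_msf(tr, selection = "all", block_length = 10)
  expect_equal(st$mean, 0)
  expect_equal(st$sd, 0)
})

test_that("MSF is invariant under per-frame rigid-body transforms", {
  coords <- ref_coords(12, seed = 6)
  atoms <- make_atoms(coords)
  set.seed(7)
  frames <- lapply(1:20, function(i) coords + matrix(rnorm(36, sd = 0.3),
                                                     ncol = 3))
  tr <- make_traj(atoms, frames)
  st0 <- block_msf(tr, selection = "all", block_length = 20)

  moved <- lapply(seq_along(frames), function(i) {
    R <- random_rotation(100 + i)
    sweep(frames[[i]] %*% t(R), 2, rnorm(3, sd = 50), "+")
  })
  trm <- make_traj(atoms, moved)
  stm <- block_msf(trm, selection = "all", block_length = 20)
  expect_equal(stm$mean, st0$mean, tolerance = 1e-8)

  # in particular, a rigid-body-only trajectory has (numerically) zero MSF
  rigid <- lapply(1:10, function(i) {
    R <- random_rotation(200 + i)
    sweep(coords %*% t(R), 2, rnorm(3, sd = 20), "+")
  })
  str <- block_msf(make_traj(atoms, rigid), selection = "all",
                   block_length = 10)
  expect_lt(str$mean, 1e-12)
})

test_that("block MSF equals an independent two-pass oracle implementation", {
  coords <- ref_coords(6, seed = 8)
  atoms <- make_atoms(coords)
  set.seed(9)
  frames <- lapply(1:10, function(i) coords + matrix(rnorm(18, sd = 0.4),
                                                     ncol = 3))
  tr <- make_traj(atoms, frames)
  st <- block_msf(tr, selection = "all", block_length = 10)

  # oracle: same protocol, Horn superposition instead of Kabsch
  s1 <- lapply(frames, horn_apply, ref = frames[[1]])
  avg1 <- Reduce("+", s1) / length(s1)
  s2 <- lapply(frames, horn_apply, ref = avg1)
  avg2 <- Reduce("+", s2) / length(s2)
  per_atom <- Reduce("+", lapply(s2, function(m) (m - avg2)^2)) /
    (length(s2) - 1)
  oracle <- mean(rowSums(per_atom))
  expect_equal(st$mean, oracle, tolerance = 1e-9)
})

test_that("block MSF recovers a known stationary variance", {
  pars <- params_deep()
  target <- qha_forward(pars, 1, 240)
  trs <- gen_qha_trajectories(qha_gen_spec(pars,
                                           grid = data.frame(P = 1, T = 240),
                                           n_atoms = 2000,
                                           frames_per_run = 100, seed = 10))
  st <- block_msf(trs[[1]], selection = "all", block_length = 100)
  se_rel <- sqrt(2 / (3 * 2000 * 99))
  # superposition absorbs ~3/(3N) of the variance; negligible at N = 2000
  expect_lt(abs(st$mean - target) / target, 3 * se_rel + 2 / 2000)
})

test_that("trailing partial blocks are discarded, never padded", {
  coords <- ref_coords(4, seed = 11)
  atoms <- make_atoms(coords)
  frames <- replicate(15, coords, simplify = FALSE)
  tr <- make_traj(atoms, frames) # dt = 1 ps, 15 frames
  st <- block_msf(tr, selection = "all", block_length = 10)
  expect_equal(st$n_blocks, 1)
  expect_error(block_msf(tr, selection = "all", block_length = 20),
               "shorter than one block")
})

test_that("per-residue CA profile resolves scripted mobility differences", {
  # enough non-collinear atoms that the rigid-body fit absorbs little of the
  # one mobile residue's excess variance
  n_res <- 24
  set.seed(12)
  coords <- matrix(runif(3 * n_res, -15, 15), ncol = 3)
  resnum <- c(1, 2, 3, 66, 66.5, 67, 67 + seq_len(n_res - 6))
  atoms <- make_atoms(coords, name = "CA", resnum = resnum)
  sds <- rep(0.2, n_res)
  sds[5] <- 0.2 * sqrt(2) # residue 66.5 has 2x MSF
  nf <- 4000
  frames <- lapply(seq_len(nf), function(i) {
    coords + matrix(rnorm(3 * n_res, sd = rep(sds, 3)), ncol = 3)
  })
  prof <- ca_msf(make_traj(atoms, frames))
  expect_equal(nrow(prof), n_res)
  # ordering by consensus key puts 66.5 between 66 and 67
  expect_equal(prof$reslabel[1:6], c("1", "2", "3", "66", "66.5", "67"))
  ratio <- prof$msf[5] / mean(prof$msf[-5])
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("ca_msf warns about residues lacking a C-alpha", {
  atoms <- make_atoms(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0), c(15, 0, 0)),
                      name = c("CA", "CB", "CA", "CA"),
                      resnum = c(1, 2, 3, 4))
  tr <- make_traj(atoms, replicate(5, matrix(rnorm(12), ncol = 3),
                                   simplify = FALSE))
  expect_warning(prof <- ca_msf(tr), "lack a C-alpha")
  expect_equal(prof$resnum, c(1, 3, 4))
})

test_that("radius of gyration matches closed forms and is rigid-invariant", {
  # two equal-mass atoms 2 A apart: Rg = 1.0 A
  atoms2 <- make_atoms(rbind(c(0, 0, 0), c(2, 0, 0)))
  tr2 <- make_traj(atoms2, list(frame_coords(structure_frame(atoms2))))
  expect_equal(radius_of_gyration(tr2, block_length = 1)$mean, 1.0)

  # unit-cube corners: Rg = sqrt(3)/2 * edge
  corners <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  atoms8 <- make_atoms(corners)
  tr8 <- make_traj(atoms8, list(corners))
  expect_equal(radius_of_gyration(tr8, block_length = 1)$mean, sqrt(3))

  # invariance under rotation + translation
  R <- random_rotation(13)
  moved <- sweep(corners %*% t(R), 2, c(5, 6, 7), "+")
  trm <- make_traj(atoms8, list(moved))
  expect_equal(radius_of_gyration(trm, block_length = 1)$mean, sqrt(3))

  # single atom: zero
  tr1 <- make_traj(make_atoms(matrix(1, 1, 3)), list(matrix(1, 1, 3)))
  expect_equal(radius_of_gyration(tr1, block_length = 1)$mean, 0)

  # mass weighting shifts Rg toward the heavy atom
  atomsw <- make_atoms(rbind(c(0, 0, 0), c(2, 0, 0)), element = c("C", "H"))
  trw <- make_traj(atomsw, list(frame_coords(structure_frame(atomsw))),
                   sampling_interval = 1)
  rg_w <- radius_of_gyration(trw, block_length = 1, selection = "all")$mean
  rg_g <- radius_of_gyration(trw, block_length = 1, selection = "all",
                             mass_weighted = FALSE)$mean
  expect_equal(rg_g, 1.0)
  expect_lt(rg_w, 1.0)
})

test_that("grid_sigma2 partitions 1 ns at 1 ps into exactly 100 intervals", {
  pars <- params_deep()
  trs <- gen_qha_trajectories(qha_gen_spec(pars,
                                           grid = data.frame(P = 1, T = 240),
                                           n_atoms = 10,
                                           frames_per_run = 1000,
                                           interval = 1, seed = 14))
  surf <- grid_sigma2(trs, interval = 10)
  expect_equal(attr(surf, "n_intervals"), 100)
  expect_equal(nrow(surf$points), 1)
  expect_equal(surf$points$P, 1)
  expect_equal(surf$points$T, 240)
})

test_that("grid_sigma2 flags constant trajectories as invalid for fitting", {
  coords <- ref_coords(5, seed = 15)
  atoms <- make_atoms(coords)
  tr <- make_traj(atoms, replicate(20, coords, simplify = FALSE))
  expect_warning(surf <- grid_sigma2(list(tr), interval = 10,
                                     selection = "all"),
                 "invalid for QHA")
  expect_equal(surf$points$sigma2, 0)
  expect_error(fit_stage1(surf), "nonpositive sigma2")
})

test_that("fluctuation_surface rejects duplicate grid points", {
  pts <- data.frame(P = c(1, 1), T = c(240, 240), sigma2 = c(0.1, 0.2))
  expect_error(fluctuation_surface(pts), "duplicate")
})
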