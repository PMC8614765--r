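# Grid voxelization, flood-fill classification, Monte Carlo volume
# refinement, tracking and merge detection.

# cache expensive shell analyses across tests in this file
.void_cache <- new.env(parent = emptyenv())
shell_snapshot <- function(hole = 0, params = void_params()) {
  key <- paste0("h", hole, "_s", params$seed, "_m", params$mc_per_A3)
  if (is.null(.void_cache[[key]])) {
    fr <- gen_shell_structure(shell_spec(6, hole_diameter = hole))
    .void_cache[[key]] <- analyze_voids(fr, params)
  }
  .void_cache[[key]]
}
largest <- function(snap) {
  snap$components[which.max(snap$components$volume), ]
}

test_that("voxelization matches a brute-force occupancy oracle", {
  fr <- make_frame(rbind(c(0, 0, 0), c(4.2, 1.3, -2.0)), name = "C",
                   element = "C")
  params <- void_params(search_grid = 1.0, probe_radius = 1.1)
  grid <- voxelize(fr, params)
  centers <- piezotraj:::.cell_centers(grid, seq_len(prod(grid$dim)))
  coords <- frame_coords(fr)
  want <- rep(FALSE, nrow(centers))
  for (a in seq_len(nrow(coords))) {
    d2 <- rowSums(sweep(centers, 2, coords[a, ])^2)
    want <- want | d2 <= (fr$atoms$vdw[a] + params$probe_radius)^2
  }
  expect_equal(grid$occupied, want)
  # two isolated atoms: no cavities, no enclosed clefts
  snap <- classify_voids(grid, params, frame = fr, refine = FALSE)
  expect_equal(sum(snap$components$class == "cavity"), 0)
})

test_that("component labelling agrees with a min-label propagation oracle", {
  set.seed(41)
  dim <- c(12L, 12L, 12L)
  mask <- runif(prod(dim)) < 0.25
  lab <- piezotraj:::.label_components(mask, dim)
  oracle <- minlabel_components(mask, dim)
  expect_true(same_partition(lab, oracle))
})

test_that("sealed 6 A shell yields one cavity near the analytic volume", {
  snap <- shell_snapshot(0)
  cavities <- snap$components[snap$components$class == "cavity", ]
  expect_equal(nrow(cavities), 1)
  analytic <- 4 / 3 * pi * 6^3 # 904.78 A^3
  expect_lt(abs(cavities$volume - analytic) / analytic, 0.10)
  # lining covers the shell residues
  lin <- snap$lining[[cavities$id]]
  expect_gt(length(lin), 10)
})

test_that("hole diameter controls the cavity/cleft classification", {
  # 4 A hole: probe (diameter 2.2 A) passes, interior becomes a cleft
  wide <- largest(shell_snapshot(4))
  expect_equal(wide$class, "cleft")
  # 0.5 A hole: probe cannot pass, interior stays a cavity
  narrow <- largest(shell_snapshot(0.5))
  expect_equal(narrow$class, "cavity")
  analytic <- 4 / 3 * pi * 6^3
  expect_lt(abs(narrow$volume - analytic) / analytic, 0.10)
})

test_that("refined volume tracks the analytic value on a smaller shell", {
  fr <- gen_shell_structure(shell_spec(4, atom_count_on_shell = 250))
  snap <- analyze_voids(fr)
  cav <- snap$components[snap$components$class == "cavity", ]
  expect_equal(nrow(cav), 1)
  analytic <- 4 / 3 * pi * 4^3
  expect_lt(abs(cav$volume - analytic) / analytic, 0.10)
  # refinement against the vdW surface recovers more volume than the raw
  # probe-inflated grid count
  expect_gt(cav$volume, cav$raw_volume)
})

test_that("sub-cutoff components report zero volume", {
  # tight shell around a 0.5 A interior: vdW void = 0.52 A^3 < 1 A^3.
  # A 0.3 A probe (with a matching fine search grid) still detects the
  # pocket, whose refined volume must then be zeroed by the cutoff rule.
  params <- void_params(search_grid = 0.2, probe_radius = 0.3,
                        refine_grid = 0.1, mc_per_A3 = 400,
                        envelope_radius = 1.0)
  fr <- gen_shell_structure(shell_spec(0.5, atom_count_on_shell = 120,
                                       probe_radius = 0.3))
  snap <- analyze_voids(fr, params)
  cav <- snap$components[snap$components$class == "cavity", ]
  expect_equal(nrow(cav), 1)
  expect_gt(cav$raw_volume, 0)
  expect_equal(cav$volume, 0)
})

test_that("Monte Carlo refinement is seeded and stable across seeds", {
  fr <- gen_shell_structure(shell_spec(4, atom_count_on_shell = 250))
  s1 <- analyze_voids(fr, void_params(seed = 1))
  s1b <- analyze_voids(fr, void_params(seed = 1))
  expect_identical(s1$components$volume, s1b$components$volume)
  s2 <- analyze_voids(fr, void_params(seed = 2))
  v1 <- largest(s1)$volume
  v2 <- largest(s2)$volume
  expect_false(identical(v1, v2))
  expect_lt(abs(v1 - v2) / v1, 0.02)
})

test_that("doubling MC density roughly halves the estimator variance", {
  fr <- gen_shell_structure(shell_spec(3, atom_count_on_shell = 200))
  grid <- voxelize(fr, void_params())
  vol_at <- function(mc, seed) {
    p <- void_params(mc_per_A3 = mc, seed = seed)
    snap <- classify_voids(grid, p, frame = fr, refine = FALSE)
    id <- snap$components$id[which.max(snap$components$raw_volume)]
    refine_volume(snap, id, fr, p)
  }
  seeds <- 1:16
  v_lo <- vapply(seeds, function(s) vol_at(8, s), 0)
  v_hi <- vapply(seeds, function(s) vol_at(32, s), 0)
  # 4x the points: variance ratio ~4; accept a generous [1.5, 12] window
  ratio <- var(v_lo) / var(v_hi)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 12)
})

test_that("volumes are conserved: bulk + vdW solid tile the box", {
  fr <- make_frame(rbind(c(0, 0, 0), c(10, 0, 0)), name = "C", element = "C")
  params <- void_params()
  grid <- voxelize(fr, params)
  snap <- classify_voids(grid, params, frame = fr, refine = FALSE)
  bulk_vol <- refine_volume(snap, snap$bulk_id, fr, params)
  comp_vol <- sum(vapply(snap$components$id, function(i) {
    refine_volume(snap, i, fr, params)
  }, 0))
  box_vol <- prod(grid$dim) * grid$spacing^3
  spheres <- 2 * 4 / 3 * pi * 1.7^3 # non-overlapping atoms
  expect_equal(bulk_vol + comp_vol, box_vol - spheres,
               tolerance = 0.01 * box_vol / (box_vol - spheres))
})

test_that("classification is stable under sub-grid translation", {
  fr <- gen_shell_structure(shell_spec(4, atom_count_on_shell = 250))
  atoms2 <- fr$atoms
  shift <- c(0.37, 0.21, 0.49)
  atoms2$x <- atoms2$x + shift[1]
  atoms2$y <- atoms2$y + shift[2]
  atoms2$z <- atoms2$z + shift[3]
  fr2 <- structure_frame(atoms2)
  v1 <- largest(analyze_voids(fr))
  v2 <- largest(analyze_voids(fr2))
  expect_equal(v1$class, v2$class)
  expect_lt(abs(v1$volume - v2$volume) / v1$volume, 0.05)
})

# minimal hand-built snapshot for tracking tests (no geometry needed)
fake_snapshot <- function(vols, classes, linings, t = 0) {
  n <- length(vols)
  structure(list(
    frame_time = t,
    components = data.frame(
      id = seq_len(n), class = classes, volume = vols, raw_volume = vols,
      n_cells = rep(1L, n), cx = seq_len(n) * 10, cy = numeric(n),
      cz = numeric(n), stringsAsFactors = FALSE),
    cells = rep(list(1L), n),
    lining = linings), class = "void_snapshot")
}

test_that("tracking aggregates with population RMS including absences", {
  linA <- c("A1", "A2", "A3")
  snaps <- c(
    replicate(9, fake_snapshot(17, "cavity", list(linA)), simplify = FALSE),
    list(fake_snapshot(numeric(0), character(0), list())))
  rec <- track_voids(snaps)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$label, "cavity")
  # population statistics over all 10 snapshots, zero counted for absence
  expect_equal(rec$mean, 17 * 9 / 10)
  v <- c(rep(17, 9), 0)
  expect_equal(rec$rms, sqrt(mean((v - mean(v))^2)))
  expect_equal(attr(rec, "volumes")[1, ], v)
  expect_true(is.na(attr(rec, "assignments")[1, 10]))
})

test_that("majority labelling with ties going to cleft", {
  linA <- c("A1", "A2")
  mk <- function(cls) fake_snapshot(10, cls, list(linA))
  rec1 <- track_voids(c(replicate(6, mk("cavity"), simplify = FALSE),
                        replicate(4, mk("cleft"), simplify = FALSE)))
  expect_equal(rec1$label, "cavity")
  rec2 <- track_voids(c(replicate(5, mk("cavity"), simplify = FALSE),
                        replicate(5, mk("cleft"), simplify = FALSE)))
  expect_equal(rec2$label, "cleft")
})

test_that("tracks match by lining similarity, not by volume or order", {
  linA <- c("A1", "A2", "A3", "A4")
  linB <- c("B1", "B2", "B3", "B4")
  s1 <- fake_snapshot(c(20, 5), c("cavity", "cavity"), list(linA, linB))
  # second snapshot reverses component order and perturbs linings slightly
  s2 <- fake_snapshot(c(6, 19), c("cavity", "cavity"),
                      list(c("B1", "B2", "B3", "B5"),
                           c("A1", "A2", "A3", "A5")))
  rec <- track_voids(list(s1, s2))
  expect_equal(nrow(rec), 2)
  vols <- attr(rec, "volumes")
  expect_equal(vols[1, ], c(20, 19)) # track of linA
  expect_equal(vols[2, ], c(5, 6))   # track of linB
})

test_that("merge detection: separate, merged, and pathway-to-surface", {
  # frame 1: two sealed shells far apart -> two cavity tracks
  n_pts <- 300
  shellA <- sphere_shell_atoms(c(0, 0, 0), 5, n_pts, resbase = 0)
  shellB <- sphere_shell_atoms(c(0, 0, 30), 5, n_pts, resbase = 1000)
  fr1 <- structure_frame(rbind(shellA, shellB))
  snap1 <- analyze_voids(fr1, void_params(mc_per_A3 = 8))
  expect_equal(sum(snap1$components$class == "cavity"), 2)

  # frame 2: the same two shells overlapping into a sealed peanut; each
  # keeps only atoms outside the other sphere, so the interiors connect
  d <- 7
  pA <- sphere_shell_atoms(c(0, 0, 0), 5, n_pts, resbase = 0,
                           keep = function(u) {
                             pts <- u * 5
                             (pts[, 3] - d)^2 + pts[, 1]^2 + pts[, 2]^2 >= 5.2^2
                           })
  pB <- sphere_shell_atoms(c(0, 0, d), 5, n_pts, resbase = 1000,
                           keep = function(u) {
                             pts <- sweep(u * 5, 2, c(0, 0, d), "+")
                             rowSums(pts^2) >= 5.2^2
                           })
  fr2 <- structure_frame(rbind(pA, pB))
  snap2 <- analyze_voids(fr2, void_params(mc_per_A3 = 8))

  tracks <- track_voids(list(snap1))
  # the shells' surface dimples register as small cleft tracks; the two
  # interiors are the only cavity tracks
  cav <- which(tracks$label == "cavity")
  expect_equal(length(cav), 2)
  m1 <- detect_merge(snap1, tracks, cav[1], cav[2])
  expect_false(as.logical(m1))
  m2 <- detect_merge(snap2, tracks, cav[1], cav[2])
  expect_true(as.logical(m2))
  expect_false(attr(m2, "pathway_to_surface")) # still internal (cavity)

  # frame 3: open the peanut to the solvent -> merged region is a cleft,
  # i.e. a surface-to-interior pathway
  top <- c(0, 0, d + 5)
  keep3 <- sqrt(rowSums(sweep(as.matrix(pB[, c("x", "y", "z")]), 2,
                              top)^2)) >= 2 + 1.7
  fr3 <- structure_frame(rbind(pA, pB[keep3, ]))
  snap3 <- analyze_voids(fr3, void_params(mc_per_A3 = 8))
  m3 <- detect_merge(snap3, tracks, cav[1], cav[2])
  expect_true(as.logical(m3))
  expect_true(attr(m3, "pathway_to_surface"))
})

test_that("void outputs export deterministically", {
  snap <- shell_snapshot(0)
  rec <- track_voids(list(snap, snap))
  f <- tempfile(fileext = ".tsv")
  df <- write_void_table(rec, f)
  back <- read.delim(f)
  expect_equal(back$mean, df$mean)
  expect_equal(back$label, df$label)

  pdb <- tempfile(fileext = ".pdb")
  write_void_pdb(snap, pdb)
  lines <- readLines(pdb)
  n_cells <- sum(snap$components$n_cells)
  expect_equal(sum(grepl("^HETATM", lines)), n_cells)
})
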