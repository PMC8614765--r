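# Synthetic-data generators: every input the pipeline needs can be produced
# here, so all analysis stages are testable without running molecular
# dynamics. All generators are bit-reproducible under a fixed seed.

# Run code under a fixed seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default pressure-temperature grid for quasiharmonic scans
#'
#' All combinations of P = 1, 2500, 5000, 7500, 10000 bar and
#' T = 40 to 320 K in 40 K steps (5 x 8 = 40 points).
#'
#' @return data.frame with columns `P` (bar) and `T` (K).
#' @export
default_pt_grid <- function() {
  expand.grid(P = c(1, 2500, 5000, 7500, 10000),
              T = seq(40, 320, by = 40))
}

#' Specification for quasiharmonic synthetic data
#'
#' @param params Generating [qha_params()] (must include `Tg0` and `c` so the
#'   frozen-glass branch is defined).
#' @param grid data.frame of (P, T) points; defaults to [default_pt_grid()].
#' @param n_atoms Atoms per synthetic trajectory.
#' @param frames_per_run Frames per grid-point trajectory.
#' @param interval Frame spacing (ps).
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @param corr_time Optional AR(1) correlation time (ps); 0 means positions
#'   are drawn i.i.d. per frame.
#' @return Object of class `qha_gen_spec`.
#' @export
qha_gen_spec <- function(params, grid = default_pt_grid(), n_atoms = 100,
                         frames_per_run = 1000, interval = 1, seed = 1,
                         corr_time = 0) {
  if (any(grid$T <= 0)) stop("all grid temperatures must be positive")
  if (any(grid$P < 1)) stop("all grid pressures must be >= 1 bar")
  if (n_atoms < 1) stop("n_atoms must be >= 1")
  structure(list(params = params, grid = grid, n_atoms = n_atoms,
                 frames_per_run = frames_per_run, interval = interval,
                 seed = seed, corr_time = corr_time),
            class = "qha_gen_spec")
}

#' Generate a synthetic fluctuation surface
#'
#' Evaluates the piecewise quasiharmonic forward model ([qha_forward()]:
#' liquid branch at T >= T_g(P), frozen-glass branch below) on the grid and
#' applies multiplicative Gaussian noise of the given relative standard
#' deviation (0 gives the exact model values).
#'
#' @param spec A [qha_gen_spec()].
#' @param noise_rel_sd Relative standard deviation of the multiplicative
#'   noise (>= 0).
#' @return A [fluctuation_surface()].
#' @export
gen_qha_surface <- function(spec, noise_rel_sd = 0) {
  if (noise_rel_sd < 0) stop("noise_rel_sd must be >= 0")
  mu <- qha_forward(spec$params, spec$grid$P, spec$grid$T)
  vals <- if (noise_rel_sd > 0) {
    local_seed(spec$seed,
               mu * (1 + stats::rnorm(length(mu), sd = noise_rel_sd)))
  } else {
    mu
  }
  fluctuation_surface(data.frame(P = spec$grid$P, T = spec$grid$T,
                                 sigma2 = vals),
                      P0 = spec$params$P0, T0 = spec$params$T0)
}

#' Generate harmonic-well trajectories on a P-T grid
#'
#' One trajectory per grid point. Each atom is an independent isotropic
#' Gaussian about a fixed centre with stationary mean-square displacement
#' equal to the forward-model sigma^2 at that grid point; with
#' `corr_time > 0` successive frames follow an AR(1) process with that
#' correlation time, otherwise frames are i.i.d. Applying [grid_sigma2()]
#' to these trajectories recovers the generating surface within sampling
#' error.
#'
#' @param spec A [qha_gen_spec()].
#' @return List of [trajectory()] objects, one per grid point.
#' @export
gen_qha_trajectories <- function(spec) {
  if (spec$frames_per_run < 20) {
    stop("frames_per_run must be >= 20 for interval averaging")
  }
  n <- spec$n_atoms
  # well centres on a sparse lattice so atoms never interact geometrically
  k <- ceiling(n^(1 / 3))
  centers <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k),
                                   z = seq_len(k)))[seq_len(n), , drop = FALSE] * 20
  atoms <- data.frame(
    name = "CA", element = "C", vdw = 1.70,
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    chain = "A", resnum = seq_len(n), reslabel = residue_label(seq_len(n)),
    resname = "ALA", is_heavy = TRUE, is_protein = TRUE,
    stringsAsFactors = FALSE)
  mu_flat <- as.vector(t(centers))
  nf <- spec$frames_per_run
  rho <- if (spec$corr_time > 0) exp(-spec$interval / spec$corr_time) else 0

  lapply(seq_len(nrow(spec$grid)), function(i) {
    P <- spec$grid$P[i]; T <- spec$grid$T[i]
    s2 <- qha_forward(spec$params, P, T)
    sd1 <- sqrt(s2 / 3) # per-coordinate sd so that <|dr|^2> = sigma^2
    xyz <- local_seed(spec$seed + i, {
      if (rho == 0) {
        matrix(stats::rnorm(nf * 3 * n, sd = sd1), nrow = nf)
      } else {
        eps <- matrix(stats::rnorm(nf * 3 * n, sd = sd1), nrow = nf)
        out <- eps
        fac <- sqrt(1 - rho^2)
        for (t in 2:nf) out[t, ] <- rho * out[t - 1, ] + fac * eps[t, ]
        out
      }
    })
    xyz <- sweep(xyz, 2, mu_flat, "+")
    trajectory(atoms, xyz, temperature = T, pressure = P,
               sampling_interval = spec$interval)
  })
}

#' Specification for a hollow-shell void fixture
#'
#' Atoms are placed quasi-uniformly (Fibonacci lattice) on a sphere such
#' that their vdW surfaces enclose an interior void of analytically known
#' volume (4/3 pi inner_radius^3). A hole of prescribed diameter can be
#' opened at the north pole; holes narrower than the probe diameter leave
#' the interior a cavity, wider ones turn it into a solvent-accessible cleft.
#'
#' @param inner_radius Interior void radius (Angstrom).
#' @param shell_atom_radius vdW radius of the shell atoms (Angstrom).
#' @param atom_count_on_shell Number of shell atoms.
#' @param hole_diameter Opening diameter (Angstrom); 0 = sealed.
#' @param seed Integer seed (orients the lattice).
#' @param probe_radius Probe radius (Angstrom) against which shell tightness
#'   is validated at generation time.
#' @return Object of class `shell_spec`.
#' @export
shell_spec <- function(inner_radius, shell_atom_radius = 1.7,
                       atom_count_on_shell = 400, hole_diameter = 0,
                       seed = 1, probe_radius = 1.1) {
  if (inner_radius <= probe_radius) {
    stop("inner_radius must exceed the probe radius")
  }
  structure(list(inner_radius = inner_radius,
                 shell_atom_radius = shell_atom_radius,
                 atom_count_on_shell = atom_count_on_shell,
                 hole_diameter = hole_diameter, seed = seed,
                 probe_radius = probe_radius),
            class = "shell_spec")
}

# Fibonacci sphere: n quasi-uniform unit vectors.
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a hollow atom shell with known interior volume
#'
#' @param spec A [shell_spec()].
#' @return A [structure_frame()]; the interior void volume is approximately
#'   (4/3) pi inner_radius^3.
#' @export
gen_shell_structure <- function(spec) {
  rc <- spec$inner_radius + spec$shell_atom_radius
  pts <- .fib_sphere(spec$atom_count_on_shell) * rc
  # tightness check: gaps between atom surfaces must be below the probe
  # diameter, else the "sealed" shell leaks
  nn <- vapply(seq_len(nrow(pts)), function(i) {
    d <- sqrt(rowSums(sweep(pts[-i, , drop = FALSE], 2, pts[i, ])^2))
    min(d)
  }, 0)
  gap <- max(nn) - 2 * spec$shell_atom_radius
  if (gap >= 2 * spec$probe_radius) {
    stop(sprintf("shell too sparse (max surface gap %.2f A >= probe diameter %.2f A); increase atom_count_on_shell",
                 gap, 2 * spec$probe_radius))
  }
  if (spec$hole_diameter > 0) {
    top <- c(0, 0, rc)
    cut <- spec$hole_diameter / 2 + spec$shell_atom_radius
    keep <- sqrt(rowSums(sweep(pts, 2, top)^2)) >= cut
    pts <- pts[keep, , drop = FALSE]
  }
  n <- nrow(pts)
  atoms <- data.frame(
    name = "C", element = "C", vdw = spec$shell_atom_radius,
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    chain = "A",
    resnum = ceiling(seq_len(n) / 10),
    reslabel = residue_label(ceiling(seq_len(n) / 10)),
    resname = "SHL", is_heavy = TRUE, is_protein = FALSE,
    stringsAsFactors = FALSE)
  structure_frame(atoms)
}

#' Define one scripted donor-acceptor event
#'
#' @param donor_resname,donor_resnum Donor residue identity.
#' @param acceptor_resname,acceptor_resnum Acceptor residue identity.
#' @param occupancy Target fraction of frames in bonded geometry, in `[0, 1]`.
#' @param donor_atom,donor_h Donor heavy atom and its hydrogen (default the
#'   backbone amide).
#' @param acceptor_atom Acceptor atom (default backbone carbonyl O).
#' @param chain Chain label.
#' @return List describing the event.
#' @export
hbond_event <- function(donor_resname, donor_resnum,
                        acceptor_resname, acceptor_resnum, occupancy,
                        donor_atom = "N", donor_h = "H",
                        acceptor_atom = "O", chain = "A") {
  if (occupancy < 0 || occupancy > 1) stop("occupancy must be in [0, 1]")
  list(donor_resname = donor_resname, donor_resnum = donor_resnum,
       acceptor_resname = acceptor_resname, acceptor_resnum = acceptor_resnum,
       occupancy = occupancy, donor_atom = donor_atom, donor_h = donor_h,
       acceptor_atom = acceptor_atom, chain = chain)
}

#' Generate a trajectory with prescribed hydrogen-bond occupancies
#'
#' Each scripted donor-acceptor pair is placed in ideal bonded geometry
#' (H...A = 2.0 Angstrom, D-H...A = 180 degrees) in the prescribed fraction
#' of frames (realised fraction within 1/n_frames of the target) and in
#' non-bonded geometry (H...A = 3.5 Angstrom) otherwise. Event pairs are
#' placed 50 Angstrom apart so they cannot interfere.
#'
#' @param events List of [hbond_event()]s.
#' @param n_frames Number of frames.
#' @param seed Integer seed (selects which frames are bonded).
#' @return A [trajectory()].
#' @export
gen_hbond_trajectory <- function(events, n_frames = 100, seed = 1) {
  dk <- vapply(events, function(e)
    paste(e$chain, e$donor_resnum, e$donor_atom), "")
  ak <- vapply(events, function(e)
    paste(e$chain, e$acceptor_resnum, e$acceptor_atom), "")
  dres <- vapply(events, function(e) paste(e$chain, e$donor_resnum), "")
  ares <- vapply(events, function(e) paste(e$chain, e$acceptor_resnum), "")
  if (anyDuplicated(dk) || anyDuplicated(ak) || any(dres %in% ares)) {
    stop("overlapping donor/acceptor group definitions across events")
  }

  rows <- list()
  for (i in seq_along(events)) {
    e <- events[[i]]
    y0 <- 50 * (i - 1)
    add <- function(name, element, resname, resnum, x) {
      data.frame(name = name, element = element,
                 vdw = unname(vdw_radius_table()[element]),
                 x = x, y = y0, z = 0, chain = e$chain,
                 resnum = resnum, reslabel = residue_label(resnum),
                 resname = resname, is_heavy = element != "H",
                 is_protein = resname %in% .aa3, stringsAsFactors = FALSE)
    }
    el_d <- element_from_name(e$donor_atom)
    el_a <- element_from_name(e$acceptor_atom)
    rows[[length(rows) + 1]] <- add(e$donor_atom, el_d, e$donor_resname,
                                    e$donor_resnum, 0)
    rows[[length(rows) + 1]] <- add(e$donor_h, "H", e$donor_resname,
                                    e$donor_resnum, 1)
    rows[[length(rows) + 1]] <- add(e$acceptor_atom, el_a, e$acceptor_resname,
                                    e$acceptor_resnum, 1 + 3.5)
  }
  atoms <- do.call(rbind, rows)

  base <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  xyz <- matrix(rep(base, n_frames), nrow = n_frames, byrow = TRUE)
  bonded_x <- 1 + 2.0
  local_seed(seed, {
    for (i in seq_along(events)) {
      k <- round(events[[i]]$occupancy * n_frames)
      if (k > 0) {
        frames <- sample.int(n_frames, k)
        acc_row <- 3 * i # third atom of event i
        xcol <- 3 * (acc_row - 1) + 1
        xyz[frames, xcol] <- bonded_x
      }
    }
  })
  trajectory(atoms, xyz, temperature = 279, pressure = 1,
             sampling_interval = 1)
}
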