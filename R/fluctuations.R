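# Block-averaged fluctuation statistics: mean-square fluctuations (MSF) of
# selected atoms about iteratively superposed average structures, per-residue
# C-alpha profiles, radius of gyration, and the sigma^2(P,T) surface feeding
# the quasiharmonic analysis.
#
# Superposition protocol (applies throughout): frames are superposed on the
# same atom selection that is being analysed, onto a block/interval average
# structure computed in two passes (average of frames superposed to the first
# frame, then one refinement superposition onto that average). MSF uses the
# unbiased (m - 1) variance normalisation. Trailing partial blocks/intervals
# are discarded, never padded.

#' Resolve an atom selection
#'
#' @param atoms Atom table.
#' @param selection One of the shortcuts `"all"`, `"protein"`, `"heavy"`
#'   (protein heavy atoms), `"heavy_all"` (all heavy atoms), `"ca"`; or a
#'   logical vector over atoms; or a predicate `function(atoms)`.
#' @return Logical vector over atoms.
#' @keywords internal
resolve_selection <- function(atoms, selection) {
  sel <- if (is.function(selection)) {
    selection(atoms)
  } else if (is.logical(selection)) {
    selection
  } else if (is.character(selection) && length(selection) == 1) {
    switch(selection,
           all = rep(TRUE, nrow(atoms)),
           protein = atoms$is_protein,
           heavy = atoms$is_heavy & atoms$is_protein,
           heavy_all = atoms$is_heavy,
           ca = atoms$name == "CA" & atoms$is_protein,
           stop("unknown selection shortcut: ", selection))
  } else {
    stop("selection must be a shortcut string, logical vector or predicate")
  }
  if (length(sel) != nrow(atoms)) stop("selection length mismatch")
  sel
}

# Kabsch least-squares rotation+translation of mob (N x 3) onto ref (N x 3),
# fitted over rows sel, applied to all rows.
.kabsch_apply <- function(mob, ref, sel) {
  mu_m <- colMeans(mob[sel, , drop = FALSE])
  mu_r <- colMeans(ref[sel, , drop = FALSE])
  C <- crossprod(sweep(mob[sel, , drop = FALSE], 2, mu_m),
                 sweep(ref[sel, , drop = FALSE], 2, mu_r))
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  A <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sweep(sweep(mob, 2, mu_m) %*% A, 2, mu_r, "+")
}

#' Superpose one frame onto a reference
#'
#' Least-squares optimal rigid rotation + translation of `frame` onto
#' `reference` over the given atom selection (applied to all atoms).
#'
#' @param frame,reference `structure_frame`s with identical atoms.
#' @param selection Atom selection used for the fit (see
#'   [resolve_selection()]); needs at least 3 atoms.
#' @return The transformed `structure_frame`, with an `rmsd` attribute
#'   (over the selection).
#' @export
superpose <- function(frame, reference, selection = "heavy") {
  sel <- resolve_selection(frame$atoms, selection)
  if (sum(sel) < 3) stop("superposition needs at least 3 selected atoms")
  if (nrow(frame$atoms) != nrow(reference$atoms)) {
    stop("frame and reference have different atom counts")
  }
  inds <- which(rep(sel, each = 3)) # xyz-vector indices of selected atoms
  fixed <- as.vector(t(frame_coords(reference)))
  mobile <- as.vector(t(frame_coords(frame)))
  moved <- bio3d::fit.xyz(fixed, mobile, fixed.inds = inds,
                          mobile.inds = inds)
  m <- matrix(moved, ncol = 3, byrow = TRUE)
  out <- frame
  out$atoms$x <- m[, 1]; out$atoms$y <- m[, 2]; out$atoms$z <- m[, 3]
  dev <- m[sel, , drop = FALSE] - frame_coords(reference)[sel, , drop = FALSE]
  attr(out, "rmsd") <- sqrt(mean(rowSums(dev^2)))
  out
}

# Superpose every frame of an xyz block (frames x 3N) onto the two-pass mean
# structure over selection sel (logical over atoms). Returns list(xyz, mean).
.superpose_block <- function(xyz, sel) {
  m <- nrow(xyz)
  tomat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
  ref <- tomat(xyz[1, ])
  pass <- function(target) {
    out <- xyz
    for (i in seq_len(m)) {
      out[i, ] <- as.vector(t(.kabsch_apply(tomat(xyz[i, ]), target, sel)))
    }
    out
  }
  s1 <- pass(ref)
  avg1 <- tomat(colMeans(s1))
  s2 <- pass(avg1)
  avg2 <- tomat(colMeans(s2))
  list(xyz = s2, mean = avg2)
}

# Per-atom MSF (A^2) of an xyz block about its two-pass mean structure,
# unbiased normalisation. Returns vector over the selected atoms.
.block_msf_per_atom <- function(xyz, sel) {
  m <- nrow(xyz)
  if (m < 2) return(rep(0, sum(sel)))
  sp <- .superpose_block(xyz, sel)
  mu <- as.vector(t(sp$mean))
  dev2 <- sweep(sp$xyz, 2, mu)^2
  idx <- which(rep(sel, each = 3))
  per_coord <- colSums(dev2[, idx, drop = FALSE]) / (m - 1)
  per_coord[seq(1, length(per_coord), 3)] +
    per_coord[seq(2, length(per_coord), 3)] +
    per_coord[seq(3, length(per_coord), 3)]
}

#' Construct a block statistic
#' @param values Per-block values.
#' @param block_length Block length (ps).
#' @return Object of class `block_stat` with `mean`, `sd` (sample sd over
#'   blocks, 0 for a single block), `n_blocks`, `block_length`.
#' @export
block_stat <- function(values, block_length) {
  structure(list(mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 n_blocks = length(values),
                 block_length = block_length,
                 values = values),
            class = "block_stat")
}

#' @export
print.block_stat <- function(x, ...) {
  cat(sprintf("%.6g +/- %.3g  (%d blocks of %g ps)\n",
              x$mean, x$sd, x$n_blocks, x$block_length))
  invisible(x)
}

.block_indices <- function(n_frames, frames_per_block) {
  n_blocks <- n_frames %/% frames_per_block
  if (n_blocks < 1) stop("trajectory shorter than one block/interval")
  lapply(seq_len(n_blocks), function(b) {
    ((b - 1) * frames_per_block + 1):(b * frames_per_block)
  })
}

#' Block-averaged mean-square fluctuations
#'
#' Within each block, frames are superposed onto the block-average structure
#' and the squared displacement is averaged over the selected atoms; the
#' per-block values are then averaged over blocks.
#'
#' @param traj A [trajectory()].
#' @param selection Atom selection (default protein heavy atoms).
#' @param block_length Block length (ps).
#' @return A [block_stat()] in Angstrom^2.
#' @export
block_msf <- function(traj, selection = "heavy", block_length = 10000) {
  sel <- resolve_selection(traj$atoms, selection)
  if (!any(sel)) stop("empty atom selection")
  fpb <- max(1L, as.integer(round(block_length / traj$sampling_interval)))
  blocks <- .block_indices(nrow(traj$xyz), fpb)
  vals <- vapply(blocks, function(ix) {
    mean(.block_msf_per_atom(traj$xyz[ix, , drop = FALSE], sel))
  }, 0)
  block_stat(vals, block_length)
}

#' Per-residue C-alpha mean-square fluctuation profile
#'
#' Computed over the full run with respect to the full-run average structure
#' (after C-alpha superposition). Residues lacking a C-alpha are omitted with
#' a warning. Output is ordered by the consensus numeric key, so half-integer
#' residues (e.g. 66.5) sit between their integer neighbours.
#'
#' @param traj A [trajectory()].
#' @return data.frame with columns `chain`, `resnum`, `reslabel`, `resname`,
#'   `msf` (Angstrom^2).
#' @export
ca_msf <- function(traj) {
  atoms <- traj$atoms
  sel <- resolve_selection(atoms, "ca")
  if (!any(sel)) stop("no C-alpha atoms present")
  prot_res <- unique(atoms[atoms$is_protein, c("chain", "resnum"), drop = FALSE])
  ca_res <- atoms[sel, c("chain", "resnum")]
  missing <- !paste(prot_res$chain, prot_res$resnum) %in%
    paste(ca_res$chain, ca_res$resnum)
  if (any(missing)) {
    warning(sum(missing), " residue(s) lack a C-alpha and are omitted")
  }
  per_atom <- .block_msf_per_atom(traj$xyz, sel)
  out <- data.frame(chain = atoms$chain[sel],
                    resnum = atoms$resnum[sel],
                    reslabel = atoms$reslabel[sel],
                    resname = atoms$resname[sel],
                    msf = per_atom,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resnum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Block-averaged radius of gyration
#'
#' Mass-weighted by default (standard atomic weights); set
#' `mass_weighted = FALSE` for the geometric radius.
#'
#' @param traj A [trajectory()].
#' @param block_length Block length (ps).
#' @param selection Atom selection (default all protein atoms).
#' @param mass_weighted Use atomic masses as weights.
#' @return A [block_stat()] in Angstrom.
#' @export
radius_of_gyration <- function(traj, block_length = 10000,
                               selection = "protein", mass_weighted = TRUE) {
  sel <- resolve_selection(traj$atoms, selection)
  if (!any(sel)) stop("empty atom selection")
  w <- if (mass_weighted) {
    m <- unname(.atomic_masses[traj$atoms$element[sel]])
    if (anyNA(m)) stop("no mass entry for element(s): ",
                       paste(unique(traj$atoms$element[sel][is.na(m)]),
                             collapse = ", "))
    m
  } else {
    rep(1, sum(sel))
  }
  if (sum(w) <= 0) stop("zero total mass")
  idx <- which(rep(sel, each = 3))
  rg_frame <- function(v) {
    m <- matrix(v[idx], ncol = 3, byrow = TRUE)
    cm <- colSums(m * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(m, 2, cm)^2)) / sum(w))
  }
  per_frame <- apply(traj$xyz, 1, rg_frame)
  fpb <- max(1L, as.integer(round(block_length / traj$sampling_interval)))
  blocks <- .block_indices(length(per_frame), fpb)
  block_stat(vapply(blocks, function(ix) mean(per_frame[ix]), 0), block_length)
}

#' Construct a fluctuation surface
#'
#' sigma^2(P,T) values on a pressure-temperature grid, the input of the
#' quasiharmonic fits.
#'
#' @param points data.frame with columns `P` (bar), `T` (K), `sigma2`
#'   (Angstrom^2).
#' @param P0,T0 Reference state (bar, K).
#' @return Object of class `fluctuation_surface`.
#' @export
fluctuation_surface <- function(points, P0 = 1, T0 = 279) {
  stopifnot(all(c("P", "T", "sigma2") %in% names(points)))
  if (anyDuplicated(points[, c("P", "T")])) {
    stop("duplicate (P, T) grid points in surface")
  }
  structure(list(points = points, reference_state = c(P0 = P0, T0 = T0)),
            class = "fluctuation_surface")
}

#' @export
print.fluctuation_surface <- function(x, ...) {
  cat(sprintf("fluctuation_surface: %d grid points, P in [%g, %g] bar, T in [%g, %g] K (P0 = %g, T0 = %g)\n",
              nrow(x$points), min(x$points$P), max(x$points$P),
              min(x$points$T), max(x$points$T),
              x$reference_state[["P0"]], x$reference_state[["T0"]]))
  invisible(x)
}

#' Interval-averaged fluctuation surface from a grid of trajectories
#'
#' For each trajectory: frames are partitioned into consecutive intervals of
#' `interval` ps; within each interval the MSF of the selected atoms about
#' the interval-average structure (after superposition) is computed, and the
#' per-interval values are averaged. One surface point per trajectory, at
#' its (P, T) metadata.
#'
#' @param trajs List of [trajectory()] objects with distinct (P, T).
#' @param interval Interval length (ps).
#' @param selection Atom selection (default protein heavy atoms).
#' @param P0,T0 Reference state recorded on the surface.
#' @return A [fluctuation_surface()].
#' @export
grid_sigma2 <- function(trajs, interval = 10, selection = "heavy",
                        P0 = 1, T0 = 279) {
  pts <- do.call(rbind, lapply(trajs, function(tr) {
    sel <- resolve_selection(tr$atoms, selection)
    if (!any(sel)) stop("empty atom selection")
    fpi <- as.integer(round(interval / tr$sampling_interval))
    if (fpi < 2) stop("interval shorter than two frames; MSF undefined")
    ints <- .block_indices(nrow(tr$xyz), fpi)
    vals <- vapply(ints, function(ix) {
      mean(.block_msf_per_atom(tr$xyz[ix, , drop = FALSE], sel))
    }, 0)
    data.frame(P = tr$pressure, T = tr$temperature, sigma2 = mean(vals),
               n_intervals = length(ints))
  }))
  if (any(pts$sigma2 <= 0)) {
    warning("surface contains sigma2 <= 0 (constant trajectory?); invalid for QHA fitting")
  }
  out <- fluctuation_surface(pts[, c("P", "T", "sigma2")], P0 = P0, T0 = T0)
  attr(out, "n_intervals") <- pts$n_intervals
  out
}

#' Write a per-residue MSF profile as TSV
#' @param profile Output of [ca_msf()].
#' @param path Output path.
#' @export
write_msf_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
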