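# Shared fixtures and independent oracles for the test suite.
#
# The oracles deliberately use different algorithms from the package code:
# superposition via Horn's quaternion method (package: Kabsch SVD),
# hydrogen-bond detection via an explicit triple loop (package: vectorised
# pairwise test), connected components via min-label propagation
# (package: BFS flood fill).

# ---- atom-table / frame builders --------------------------------------------

make_atoms <- function(coords, name = "CA", element = "C", resname = "ALA",
                       resnum = seq_len(nrow(coords)), chain = "A",
                       vdw = NULL) {
  n <- nrow(coords)
  name <- rep_len(name, n); element <- rep_len(element, n)
  resname <- rep_len(resname, n); chain <- rep_len(chain, n)
  resnum <- rep_len(resnum, n)
  if (is.null(vdw)) vdw <- unname(vdw_radius_table()[element])
  data.frame(name = name, element = element, vdw = rep_len(vdw, n),
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             chain = chain, resnum = resnum,
             reslabel = residue_label(resnum), resname = resname,
             is_heavy = element != "H",
             is_protein = resname %in% c("ALA", "GLY", "ASP", "TYR", "LEU",
                                         "SER", "ARG", "GLU"),
             stringsAsFactors = FALSE)
}

make_frame <- function(coords, ...) structure_frame(make_atoms(coords, ...))

# trajectory from a list of N x 3 coordinate matrices over a fixed atom table
make_traj <- function(atoms, frames, temperature = 279, pressure = 1,
                      sampling_interval = 1) {
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  trajectory(atoms, xyz, temperature = temperature, pressure = pressure,
             sampling_interval = sampling_interval)
}

# random rigid rotation matrix (seeded)
random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# ---- oracle: Horn quaternion superposition ----------------------------------

# optimal RMSD of mob onto ref (both N x 3) via the largest eigenvalue of
# Horn's 4x4 quaternion matrix
horn_rmsd <- function(mob, ref) {
  n <- nrow(mob)
  mc <- sweep(mob, 2, colMeans(mob))
  rc <- sweep(ref, 2, colMeans(ref))
  S <- crossprod(mc, rc)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    nrow = 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(mc^2) + sum(rc^2) - 2 * lam) / n
  sqrt(max(0, msd))
}

# rotation matrix of the optimal Horn superposition (mob -> ref, centred)
horn_rotation <- function(mob, ref) {
  mc <- sweep(mob, 2, colMeans(mob))
  rc <- sweep(ref, 2, colMeans(ref))
  S <- crossprod(mc, rc)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    nrow = 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# apply the Horn-optimal transform of mob onto ref to all rows of mob;
# the quaternion eigenvector encodes the rotation taking centred mobile
# coordinates onto centred reference coordinates as x' = x R^T (row vectors)
horn_apply <- function(mob, ref) {
  R <- horn_rotation(mob, ref)
  mc <- sweep(mob, 2, colMeans(mob))
  sweep(mc %*% t(R), 2, colMeans(ref), "+")
}

# ---- oracle: brute-force hydrogen-bond detection ----------------------------

# donors: data.frame(d, h, group_key); acceptors: data.frame(a, group_key);
# indices into coords (N x 3). Returns distinct (donor group, acceptor group)
# keys bonded under the strict criteria.
brute_hbond_pairs <- function(coords, donors, acceptors, dmax = 2.40,
                              amin = 130, same_res = NULL) {
  found <- character(0)
  for (i in seq_len(nrow(donors))) {
    for (j in seq_len(nrow(acceptors))) {
      if (!is.null(same_res) && same_res(donors$d[i], acceptors$a[j])) next
      H <- coords[donors$h[i], ]
      A <- coords[acceptors$a[j], ]
      D <- coords[donors$d[i], ]
      dist <- sqrt(sum((H - A)^2))
      if (dist >= dmax) next
      u <- D - H; v <- A - H
      ang <- acos(min(1, max(-1, sum(u * v) /
                               sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (ang <= amin) next
      found <- c(found, paste(donors$group_key[i], acceptors$group_key[j],
                              sep = " -> "))
    }
  }
  sort(unique(found))
}

# frame with one donor (D, H) / acceptor (A) triple at prescribed geometry:
# H at origin, D at (-1, 0, 0); A at distance `dist` from H making the given
# D-H...A angle (degrees)
make_dha_frame <- function(dist, angle) {
  th <- angle * pi / 180
  coords <- rbind(c(-1, 0, 0),                       # donor N
                  c(0, 0, 0),                        # hydrogen
                  c(dist * -cos(th), dist * sin(th), 0)) # acceptor O
  atoms <- data.frame(
    name = c("N", "H", "O"), element = c("N", "H", "O"),
    vdw = unname(vdw_radius_table()[c("N", "H", "O")]),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    chain = "A", resnum = c(1, 1, 2),
    reslabel = residue_label(c(1, 1, 2)),
    resname = c("ALA", "ALA", "GLY"),
    is_heavy = c(TRUE, FALSE, TRUE), is_protein = TRUE,
    stringsAsFactors = FALSE)
  structure_frame(atoms)
}

# ---- oracle: connected components by min-label propagation ------------------

# 26-connected components of a logical 3d mask by iterated neighbourhood
# minimum; returns an integer labelling (values arbitrary but consistent)
minlabel_components <- function(mask, dim) {
  lab <- array(ifelse(mask, seq_along(mask), Inf), dim)
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  repeat {
    nb <- array(Inf, dim)
    for (k in seq_len(nrow(offs))) {
      dx <- offs[k, 1]; dy <- offs[k, 2]; dz <- offs[k, 3]
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      zs <- max(1, 1 + dz):min(nz, nz + dz)
      nb[xs, ys, zs] <- pmin(nb[xs, ys, zs], lab[xs - dx, ys - dy, zs - dz])
    }
    new <- pmin(lab, nb)
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- as.vector(lab)
  out[!is.finite(out)] <- 0
  as.integer(match(out, sort(unique(out[out > 0]))) %.na0%
               rep(0L, length(out)))
}

# replace NA by the fallback elementwise (helper for the oracle above)
`%.na0%` <- function(a, b) ifelse(is.na(a), b, a)

# do two labelings describe the same partition of the TRUE cells?
same_partition <- function(lab1, lab2) {
  on1 <- lab1 > 0; on2 <- lab2 > 0
  if (!identical(on1, on2)) return(FALSE)
  key <- paste(lab1[on1], lab2[on1])
  length(unique(key)) == length(unique(lab1[on1])) &&
    length(unique(key)) == length(unique(lab2[on2]))
}

# ---- geometric fixtures ------------------------------------------------------

# atoms on a sphere shell around an arbitrary centre (for merge fixtures);
# keeps only points satisfying `keep(unit_vector)`
sphere_shell_atoms <- function(center, radius, n, resbase = 0,
                               keep = function(u) rep(TRUE, nrow(u))) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  u <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  u <- u[keep(u), , drop = FALSE]
  pts <- sweep(u * radius, 2, center, "+")
  resnum <- resbase + seq_len(nrow(pts))
  make_atoms(pts, name = "C", element = "C", resname = "SHL",
             resnum = resnum, vdw = 1.7)
}

# reference parameter sets used across QHA tests (high-pressure and
# shallow-water homologue rows of the fit-summary convention)
params_deep <- function() qha_params(0.148, 8.0e-3, 65e-3, Tg0 = 191,
                                     c = -0.5, P0 = 1, T0 = 279)
params_shallow <- function() qha_params(0.151, 8.1e-3, 70e-3, Tg0 = 186,
                                        c = -1.0, P0 = 1, T0 = 279)
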