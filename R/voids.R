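# Cavity and cleft volumetrics: probe-inflated occupancy grid, flood-fill
# classification of internal cavities vs solvent-accessible clefts, Monte
# Carlo volume refinement against the vdW surface, tracking across snapshots
# and merge detection.
#
# Algorithm (McVol-style re-implementation, all knobs in void_params):
#  * a cell is protein-occupied when its centre lies within
#    (vdw + probe_radius) of an atom centre (solvent-accessible convention);
#  * free cells reachable from the box boundary are bulk solvent
#    (26-connectivity throughout);
#  * the molecular envelope is the morphological closing of the occupied set
#    with a ball of envelope_radius;
#  * free components disconnected from bulk are cavities; bulk-connected
#    free cells inside the envelope form cleft components;
#  * volumes are refined on a finer grid against the bare vdW surface
#    (no probe inflation) with stratified, seeded Monte Carlo sampling in
#    boundary cells; refined volumes below min_volume report as 0.

#' Void-detection parameters
#'
#' @param search_grid Search grid spacing (Angstrom).
#' @param probe_radius Solvent probe radius (Angstrom).
#' @param refine_grid Refinement grid spacing (Angstrom).
#' @param mc_per_A3 Monte Carlo points per cubic Angstrom in boundary cells.
#' @param min_volume Volumes below this cutoff (Angstrom^3) report as 0.
#' @param envelope_radius Closing-ball radius bounding clefts (Angstrom).
#' @param seed Integer seed for the Monte Carlo sampling.
#' @param max_cells Guard on the search-grid size.
#' @return Object of class `void_params`.
#' @export
void_params <- function(search_grid = 1.0, probe_radius = 1.1,
                        refine_grid = 0.5, mc_per_A3 = 50, min_volume = 1.0,
                        envelope_radius = 4.0, seed = 1, max_cells = 2e7) {
  stopifnot(search_grid > 0, probe_radius > 0, refine_grid > 0,
            mc_per_A3 >= 1, min_volume >= 0, envelope_radius > 0)
  structure(list(search_grid = search_grid, probe_radius = probe_radius,
                 refine_grid = refine_grid, mc_per_A3 = mc_per_A3,
                 min_volume = min_volume, envelope_radius = envelope_radius,
                 seed = seed, max_cells = max_cells),
            class = "void_params")
}

# ---- grid primitives --------------------------------------------------------

.lin_to_xyz <- function(idx, dim) {
  i <- idx - 1L
  x <- i %% dim[1]
  i <- i %/% dim[1]
  y <- i %% dim[2]
  z <- i %/% dim[2]
  cbind(x + 1L, y + 1L, z + 1L)
}
.xyz_to_lin <- function(x, y, z, dim) {
  (z - 1L) * dim[1] * dim[2] + (y - 1L) * dim[1] + x
}

.offsets26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
.offsets26 <- .offsets26[rowSums(abs(.offsets26)) > 0, ]

# vectorised BFS flood fill over a logical mask from seed linear indices
.flood <- function(mask, dim, seeds) {
  reach <- logical(length(mask))
  seeds <- seeds[mask[seeds]]
  reach[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    co <- .lin_to_xyz(frontier, dim)
    nxt <- integer(0)
    for (k in seq_len(nrow(.offsets26))) {
      x <- co[, 1] + .offsets26[k, 1]
      y <- co[, 2] + .offsets26[k, 2]
      z <- co[, 3] + .offsets26[k, 3]
      ok <- x >= 1 & x <= dim[1] & y >= 1 & y <= dim[2] & z >= 1 & z <= dim[3]
      if (!any(ok)) next
      lin <- .xyz_to_lin(x[ok], y[ok], z[ok], dim)
      lin <- lin[mask[lin] & !reach[lin]]
      if (length(lin)) {
        reach[lin] <- TRUE
        nxt <- c(nxt, lin)
      }
    }
    frontier <- unique(nxt)
  }
  reach
}

# label connected components (26-conn) of a logical mask; returns integer vec
.label_components <- function(mask, dim) {
  lab <- integer(length(mask))
  cur <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    comp <- .flood(mask & lab == 0L, dim, s)
    lab[comp] <- cur
  }
  lab
}

# boundary linear indices of a grid
.boundary_cells <- function(dim) {
  arr <- array(FALSE, dim)
  arr[1, , ] <- TRUE; arr[dim[1], , ] <- TRUE
  arr[, 1, ] <- TRUE; arr[, dim[2], ] <- TRUE
  arr[, , 1] <- TRUE; arr[, , dim[3]] <- TRUE
  which(arr)
}

# dilate a logical array by a ball of radius r (grid units: spacing)
.dilate <- function(arr, dim, r, spacing) {
  m <- floor(r / spacing)
  offs <- as.matrix(expand.grid(dx = -m:m, dy = -m:m, dz = -m:m))
  offs <- offs[rowSums(offs^2) * spacing^2 <= r^2, , drop = FALSE]
  a <- array(arr, dim)
  out <- array(FALSE, dim)
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  for (k in seq_len(nrow(offs))) {
    dx <- offs[k, 1]; dy <- offs[k, 2]; dz <- offs[k, 3]
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    zs <- max(1, 1 + dz):min(nz, nz + dz)
    out[xs, ys, zs] <- out[xs, ys, zs] |
      a[xs - dx, ys - dy, zs - dz]
  }
  as.vector(out)
}

#' Voxelize a structure into a probe-inflated occupancy grid
#'
#' Axis-aligned grid with padding beyond the inflated structure extent; a
#' cell is protein-occupied when its centre lies within
#' `vdw + probe_radius` of any atom centre.
#'
#' @param frame A [structure_frame()].
#' @param params [void_params()].
#' @return Object of class `void_grid`: `origin`, `spacing`, `dim`,
#'   `occupied` (logical vector in array order).
#' @export
voxelize <- function(frame, params = void_params()) {
  atoms <- frame$atoms
  if (nrow(atoms) == 0) stop("empty frame")
  coords <- frame_coords(frame)
  rmax <- max(atoms$vdw) + params$probe_radius
  pad <- rmax + 2 * params$probe_radius + params$search_grid
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  dim <- as.integer(ceiling((hi - lo) / params$search_grid)) + 1L
  if (prod(dim) > params$max_cells) {
    stop("search grid would need ", prod(dim),
         " cells (> max_cells); use a coarser search_grid")
  }
  occ <- logical(prod(dim))
  ax <- lo[1] + (seq_len(dim[1]) - 1) * params$search_grid
  ay <- lo[2] + (seq_len(dim[2]) - 1) * params$search_grid
  az <- lo[3] + (seq_len(dim[3]) - 1) * params$search_grid
  for (a in seq_len(nrow(atoms))) {
    r <- atoms$vdw[a] + params$probe_radius
    xr <- which(abs(ax - coords[a, 1]) <= r)
    yr <- which(abs(ay - coords[a, 2]) <= r)
    zr <- which(abs(az - coords[a, 3]) <= r)
    if (!length(xr) || !length(yr) || !length(zr)) next
    d2 <- outer(outer((ax[xr] - coords[a, 1])^2,
                      (ay[yr] - coords[a, 2])^2, "+"),
                (az[zr] - coords[a, 3])^2, "+")
    hit <- which(d2 <= r^2, arr.ind = TRUE)
    if (nrow(hit)) {
      occ[.xyz_to_lin(xr[hit[, 1]], yr[hit[, 2]], zr[hit[, 3]], dim)] <- TRUE
    }
  }
  structure(list(origin = lo, spacing = params$search_grid, dim = dim,
                 occupied = occ),
            class = "void_grid")
}

.cell_centers <- function(grid, idx) {
  co <- .lin_to_xyz(idx, grid$dim)
  sweep((co - 1) * grid$spacing, 2, grid$origin, "+")
}

#' Classify free space into bulk solvent, cavities and clefts
#'
#' @param grid A [voxelize()] output.
#' @param params [void_params()].
#' @param frame The source [structure_frame()] (for lining residues and
#'   volume refinement).
#' @param refine Refine component volumes by Monte Carlo integration
#'   (see [refine_volume()]); if `FALSE`, raw grid volumes are reported.
#' @param frame_time Time stamp (ps) recorded on the snapshot.
#' @return Object of class `void_snapshot`: `components` data.frame (`id`,
#'   `class`, `volume`, `raw_volume`, `n_cells`, centroid columns), per-id
#'   cell/lining lists, plus the masks needed by [detect_merge()].
#' @export
classify_voids <- function(grid, params = void_params(), frame = NULL,
                           refine = !is.null(frame), frame_time = 0) {
  dim <- grid$dim
  free <- !grid$occupied
  bulk <- .flood(free, dim, .boundary_cells(dim))

  # molecular envelope: morphological closing of the occupied set
  dil <- .dilate(grid$occupied, dim, params$envelope_radius, grid$spacing)
  ext <- .flood(!dil, dim, .boundary_cells(dim))
  env <- !.dilate(ext, dim, params$envelope_radius, grid$spacing)

  cav_lab <- .label_components(free & !bulk, dim)
  n_cav <- max(cav_lab, 0L)
  cleft_lab <- .label_components(free & bulk & env, dim)
  n_cleft <- max(cleft_lab, 0L)

  lab <- integer(length(free))
  lab[cav_lab > 0L] <- cav_lab[cav_lab > 0L]
  lab[cleft_lab > 0L] <- n_cav + cleft_lab[cleft_lab > 0L]
  n_comp <- n_cav + n_cleft
  bulk_id <- n_comp + 1L
  lab[bulk & lab == 0L] <- bulk_id

  # assign occupied cells adjacent to labelled free cells, for volume
  # attribution up to the vdW surface (majority of labelled neighbours;
  # ties prefer components over bulk, then the lowest id)
  lab_ext <- integer(length(free))
  occ_idx <- which(grid$occupied)
  if (length(occ_idx)) {
    co <- .lin_to_xyz(occ_idx, dim)
    votes <- matrix(0L, nrow = length(occ_idx), ncol = bulk_id)
    for (k in seq_len(nrow(.offsets26))) {
      x <- co[, 1] + .offsets26[k, 1]
      y <- co[, 2] + .offsets26[k, 2]
      z <- co[, 3] + .offsets26[k, 3]
      ok <- x >= 1 & x <= dim[1] & y >= 1 & y <= dim[2] & z >= 1 & z <= dim[3]
      l <- integer(length(occ_idx))
      l[ok] <- lab[.xyz_to_lin(x[ok], y[ok], z[ok], dim)]
      has <- l > 0L
      if (any(has)) {
        votes[cbind(which(has), l[has])] <- votes[cbind(which(has), l[has])] + 1L
      }
    }
    any_vote <- rowSums(votes) > 0
    if (any(any_vote)) {
      # prefer components over bulk on ties: bulk column inspected last and
      # max.col(ties.method = "first") picks the earliest maximum
      pick <- max.col(votes[any_vote, , drop = FALSE], ties.method = "first")
      lab_ext[occ_idx[any_vote]] <- pick
    }
  }

  comp_ids <- seq_len(n_comp)
  cells <- lapply(comp_ids, function(i) which(lab == i))
  classes <- c(rep("cavity", n_cav), rep("cleft", n_cleft))
  cell_vol <- grid$spacing^3
  centroids <- t(vapply(cells, function(ix) {
    colMeans(.cell_centers(grid, ix))
  }, numeric(3)))

  lining <- vector("list", n_comp)
  if (!is.null(frame) && n_comp > 0) {
    coords <- frame_coords(frame)
    for (i in comp_ids) {
      cc <- .cell_centers(grid, cells[[i]])
      reach <- frame$atoms$vdw + params$probe_radius + params$search_grid
      near <- vapply(seq_len(nrow(coords)), function(a) {
        min(colSums((t(cc) - coords[a, ])^2)) <= reach[a]^2
      }, TRUE)
      lining[[i]] <- sort(unique(paste0(frame$atoms$chain[near],
                                        frame$atoms$reslabel[near])))
    }
  }

  snap <- structure(list(
    frame_time = frame_time,
    components = data.frame(
      id = comp_ids,
      class = classes,
      volume = vapply(cells, length, 0L) * cell_vol,
      raw_volume = vapply(cells, length, 0L) * cell_vol,
      n_cells = vapply(cells, length, 0L),
      cx = if (n_comp) centroids[, 1] else numeric(0),
      cy = if (n_comp) centroids[, 2] else numeric(0),
      cz = if (n_comp) centroids[, 3] else numeric(0),
      stringsAsFactors = FALSE),
    cells = cells,
    lining = lining,
    grid = grid,
    lab = lab,
    lab_ext = lab_ext,
    bulk_id = bulk_id,
    env = env,
    bulk = bulk),
    class = "void_snapshot")

  if (refine && !is.null(frame)) {
    for (i in comp_ids) {
      v <- refine_volume(snap, i, frame, params)
      snap$components$volume[i] <- v
    }
  } else if (n_comp > 0) {
    snap$components$volume[snap$components$volume < params$min_volume] <- 0
  }
  snap
}

#' @export
print.void_snapshot <- function(x, ...) {
  cat(sprintf("void_snapshot (t = %g ps): %d component(s)\n",
              x$frame_time, nrow(x$components)))
  if (nrow(x$components)) print(x$components, row.names = FALSE)
  invisible(x)
}

#' Refine a component volume by Monte Carlo integration
#'
#' The component's cells (plus the occupied boundary cells attributed to it)
#' are re-gridded at `refine_grid`; cells wholly outside the vdW surface
#' count fully, wholly inside count zero, and boundary cells are integrated
#' by stratified, seeded uniform Monte Carlo sampling (`mc_per_A3` points per
#' cubic Angstrom). Volumes below `min_volume` report as 0.
#'
#' @param snapshot A [classify_voids()] output.
#' @param id Component id.
#' @param frame The source [structure_frame()].
#' @param params [void_params()].
#' @return Volume in Angstrom^3.
#' @export
refine_volume <- function(snapshot, id, frame, params = void_params()) {
  grid <- snapshot$grid
  cells <- which(snapshot$lab == id | snapshot$lab_ext == id)
  if (!length(cells)) return(0)
  coords <- frame_coords(frame)
  vdw <- frame$atoms$vdw
  f <- max(1L, as.integer(round(grid$spacing / params$refine_grid)))
  h <- grid$spacing / f
  sub <- as.matrix(expand.grid(i = seq_len(f), j = seq_len(f), k = seq_len(f)))
  sub_off <- (sub - 0.5) * h - grid$spacing / 2

  base <- .cell_centers(grid, cells)
  centers <- base[rep(seq_len(nrow(base)), each = nrow(sub_off)), , drop = FALSE] +
    sub_off[rep(seq_len(nrow(sub_off)), times = nrow(base)), , drop = FALSE]

  # signed clearance of each refine-cell centre to the nearest vdW surface
  clearance <- function(pts) {
    n <- nrow(pts)
    out <- rep(Inf, n)
    chunk <- max(1L, as.integer(2e7 / nrow(coords)))
    for (s in seq(1, n, by = chunk)) {
      e <- min(n, s + chunk - 1)
      d <- sqrt(outer(rowSums(pts[s:e, , drop = FALSE]^2), rowSums(coords^2),
                      "+") - 2 * pts[s:e, , drop = FALSE] %*% t(coords))
      out[s:e] <- apply(sweep(d, 2, vdw), 1, min)
    }
    out
  }
  cl <- clearance(centers)
  half_diag <- sqrt(3) / 2 * h
  full <- cl >= half_diag
  inside <- cl <= -half_diag
  border <- !full & !inside

  vol <- sum(full) * h^3
  if (any(border)) {
    npts <- max(1L, as.integer(ceiling(params$mc_per_A3 * h^3)))
    bc <- centers[border, , drop = FALSE]
    frac <- local_seed(params$seed + 131L * id, {
      pts <- bc[rep(seq_len(nrow(bc)), each = npts), , drop = FALSE] +
        matrix(stats::runif(nrow(bc) * npts * 3, -h / 2, h / 2), ncol = 3)
      void <- clearance(pts) > 0
      colSums(matrix(void, nrow = npts)) / npts
    })
    vol <- vol + sum(frac) * h^3
  }
  if (vol < params$min_volume) 0 else vol
}

#' Analyze one structure for voids
#'
#' Convenience wrapper: [voxelize()] then [classify_voids()] with refinement.
#'
#' @inheritParams voxelize
#' @param frame_time Time stamp (ps).
#' @return A `void_snapshot`.
#' @export
analyze_voids <- function(frame, params = void_params(), frame_time = 0) {
  classify_voids(voxelize(frame, params), params, frame = frame,
                 refine = TRUE, frame_time = frame_time)
}

#' Track voids across snapshots
#'
#' Components are matched by maximum Jaccard similarity of their
#' lining-residue sets (ties broken by nearest centroid); unmatched
#' components open new tracks. A track absent from a snapshot contributes
#' volume 0 there. Mean and RMS fluctuation are over all snapshots
#' (population normalisation, zeros included); the label is the majority
#' class across snapshots, ties going to cleft (assume solvent-accessible).
#'
#' @param snapshots List of `void_snapshot`s in time order.
#' @return data.frame with one row per track: `track`, `label`, `mean`,
#'   `rms`, `n_snapshots`, plus a `volumes` matrix attribute and
#'   `assignments` attribute (per-snapshot component ids, NA when absent).
#' @export
track_voids <- function(snapshots) {
  if (!length(snapshots)) stop("need at least one snapshot")
  ns <- length(snapshots)
  tracks <- list() # each: lining (character set), centroid, classes, comp_by_snap
  vols <- list()

  jaccard <- function(a, b) {
    if (!length(a) && !length(b)) return(0)
    length(intersect(a, b)) / length(union(a, b))
  }

  for (s in seq_len(ns)) {
    snap <- snapshots[[s]]
    nc <- nrow(snap$components)
    assigned_comp <- rep(FALSE, nc)
    if (length(tracks) && nc) {
      J <- matrix(0, nrow = length(tracks), ncol = nc)
      D <- matrix(Inf, nrow = length(tracks), ncol = nc)
      for (t in seq_along(tracks)) {
        for (k in seq_len(nc)) {
          J[t, k] <- jaccard(tracks[[t]]$lining, snap$lining[[k]])
          D[t, k] <- sqrt(sum((tracks[[t]]$centroid -
                               unlist(snap$components[k, c("cx", "cy", "cz")]))^2))
        }
      }
      taken_t <- rep(FALSE, length(tracks))
      ord <- order(-J, D) # best Jaccard first, centroid distance breaks ties
      for (o in ord) {
        t <- (o - 1) %% length(tracks) + 1
        k <- (o - 1) %/% length(tracks) + 1
        if (J[t, k] <= 0 || taken_t[t] || assigned_comp[k]) next
        taken_t[t] <- TRUE
        assigned_comp[k] <- TRUE
        tracks[[t]]$lining <- union(tracks[[t]]$lining, snap$lining[[k]])
        tracks[[t]]$centroid <- unlist(snap$components[k, c("cx", "cy", "cz")])
        tracks[[t]]$classes <- c(tracks[[t]]$classes, snap$components$class[k])
        tracks[[t]]$comp_by_snap[s] <- snap$components$id[k]
        vols[[t]][s] <- snap$components$volume[k]
      }
    }
    if (nc) {
      for (k in which(!assigned_comp)) {
        tracks[[length(tracks) + 1]] <- list(
          lining = snap$lining[[k]],
          centroid = unlist(snap$components[k, c("cx", "cy", "cz")]),
          classes = snap$components$class[k],
          comp_by_snap = {
            v <- rep(NA_integer_, ns); v[s] <- snap$components$id[k]; v
          })
        vols[[length(vols) + 1]] <- {
          v <- rep(0, ns); v[s] <- snap$components$volume[k]; v
        }
      }
    }
  }

  label_of <- function(classes) {
    ncav <- sum(classes == "cavity")
    ncle <- sum(classes == "cleft")
    if (ncav > ncle) "cavity" else "cleft"
  }
  out <- data.frame(
    track = seq_along(tracks),
    label = vapply(tracks, function(t) label_of(t$classes), ""),
    mean = vapply(vols, mean, 0),
    rms = vapply(vols, function(v) sqrt(mean((v - mean(v))^2)), 0),
    n_snapshots = ns,
    stringsAsFactors = FALSE)
  attr(out, "volumes") <- do.call(rbind, vols)
  attr(out, "assignments") <- do.call(rbind, lapply(tracks,
                                                    function(t) t$comp_by_snap))
  attr(out, "lining") <- lapply(tracks, function(t) t$lining)
  out
}

#' Detect a void merge within one snapshot
#'
#' Two tracks have merged in a snapshot when the regions they map onto (by
#' maximum lining-residue Jaccard similarity) fall in one connected free
#' component there, i.e. both tracks resolve to the same component. The
#' returned flag carries a `pathway_to_surface` attribute, `TRUE` when that
#' joint component is bulk-connected (a cleft): a formerly internal cavity
#' merging with a solvent-accessible cleft forms a surface-to-interior
#' pathway.
#'
#' @param snapshot A `void_snapshot`.
#' @param tracks [track_voids()] output (its `lining` attribute supplies the
#'   track signatures), or a list of two character vectors of lining
#'   residues.
#' @param a,b Track indices.
#' @return Logical flag with attribute `pathway_to_surface`.
#' @export
detect_merge <- function(snapshot, tracks, a, b) {
  linings <- if (is.data.frame(tracks)) attr(tracks, "lining") else tracks
  jaccard <- function(x, y) {
    if (!length(x) && !length(y)) return(0)
    length(intersect(x, y)) / length(union(x, y))
  }
  best <- function(sig) {
    if (!length(snapshot$lining)) return(NA_integer_)
    j <- vapply(snapshot$lining, function(l) jaccard(sig, l), 0)
    if (max(j) <= 0) return(NA_integer_)
    which.max(j)
  }
  ca <- best(linings[[a]])
  cb <- best(linings[[b]])
  merged <- !is.na(ca) && !is.na(cb) && ca == cb
  path <- merged && snapshot$components$class[ca] == "cleft"
  structure(merged, pathway_to_surface = path)
}

#' Write a void-tracking summary table
#'
#' @param records Output of [track_voids()].
#' @param path Output TSV path.
#' @export
write_void_table <- function(records, path) {
  df <- records[, c("track", "label", "mean", "rms", "n_snapshots")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export void grid cells as a dummy-atom PDB for visualisation
#'
#' One pseudo-atom per component grid cell, component id in the residue
#' number field.
#'
#' @param snapshot A `void_snapshot`.
#' @param path Output PDB path.
#' @export
write_void_pdb <- function(snapshot, path) {
  rows <- list()
  for (i in seq_len(nrow(snapshot$components))) {
    cc <- .cell_centers(snapshot$grid, snapshot$cells[[i]])
    if (!nrow(cc)) next
    rows[[length(rows) + 1]] <- data.frame(x = cc[, 1], y = cc[, 2],
                                           z = cc[, 3], id = i)
  }
  if (!length(rows)) {
    writeLines("END", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  n <- nrow(df) # write.pdb requires per-atom vectors, no scalar recycling
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(df[, c("x", "y", "z")]))),
                   resno = df$id, resid = rep("VOI", n),
                   chain = rep("V", n), elety = rep("DU", n),
                   type = rep("HETATM", n))
  invisible(path)
}
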