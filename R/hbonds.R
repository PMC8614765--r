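# Geometric hydrogen-bond detection, equivalent-donor/acceptor merging,
# bifurcation collapse, occupancy computation and network export.
#
# A hydrogen bond is present when the donor-hydrogen-to-acceptor distance is
# strictly below the cutoff AND the D-H...A angle is strictly above the
# minimum. Chemically equivalent donors or acceptors of one residue (e.g.
# Asp OD1/OD2) are combined into groups, and bifurcated bonds (one hydrogen
# to several equivalent acceptors) count as a single event.

#' Hydrogen-bond geometric criteria
#'
#' Defaults: H...A distance < 2.40 Angstrom and D-H...A angle > 130 degrees,
#' both strict inequalities.
#'
#' @param max_h_a_distance Maximum donor-H to acceptor distance (Angstrom).
#' @param min_dha_angle Minimum D-H...A angle (degrees).
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_h_a_distance = 2.40, min_dha_angle = 130) {
  if (max_h_a_distance <= 0) stop("distance cutoff must be positive")
  if (min_dha_angle <= 0 || min_dha_angle > 180) {
    stop("angle cutoff must be in (0, 180]")
  }
  structure(list(max_h_a_distance = max_h_a_distance,
                 min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

#' Load a donor/acceptor chemistry table
#'
#' The table assigns, per residue type, the donor heavy atoms with their
#' attached hydrogens and the acceptor atoms, and groups chemically
#' equivalent atoms (column `group`). `resname = "*"` rows are backbone
#' entries applying to every protein residue. The shipped table is versioned
#' data and fully overridable; ligand/cofactor chemistry can be added by the
#' user.
#'
#' @param path CSV path; default is the table shipped with the package.
#' @return data.frame with columns `resname`, `role`, `atom`, `hydrogens`
#'   (|-separated), `group`.
#' @export
load_chemistry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hbond_chemistry.csv",
                        package = "piezotraj", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("resname", "role", "atom", "hydrogens", "group")
  if (!all(needed %in% names(tab))) {
    stop("chemistry table must have columns: ", paste(needed, collapse = ", "))
  }
  bad <- tab$role == "donor" & !nzchar(tab$hydrogens)
  if (any(bad)) {
    stop("configuration error: donor entries without attached hydrogens: ",
         paste(paste(tab$resname[bad], tab$atom[bad]), collapse = ", "))
  }
  tab
}

.title_case_res <- function(resname) {
  paste0(substr(resname, 1, 1), tolower(substr(resname, 2, nchar(resname))))
}

# Build donor (D,H) pair rows and acceptor rows for an atom table.
.hbond_sites <- function(atoms, chemistry, include_nonprotein = FALSE) {
  scope <- if (include_nonprotein) rep(TRUE, nrow(atoms)) else atoms$is_protein
  reskey <- paste(atoms$chain, atoms$resnum)

  match_rows <- function(role) {
    ch <- chemistry[chemistry$role == role, , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(ch))) {
      hit <- scope & atoms$name == ch$atom[i] &
        (if (ch$resname[i] == "*") atoms$is_protein
         else atoms$resname == ch$resname[i])
      # wildcard rows must not double-match residue-specific entries
      if (ch$resname[i] == "*") {
        specific <- ch$resname != "*" & ch$atom == ch$atom[i]
        if (any(specific)) {
          hit <- hit & !atoms$resname %in% ch$resname[specific]
        }
      }
      if (!any(hit)) next
      out[[length(out) + 1]] <- data.frame(
        idx = which(hit), group = ch$group[i],
        hydrogens = ch$hydrogens[i], stringsAsFactors = FALSE)
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }

  dn <- match_rows("donor")
  donors <- NULL
  if (!is.null(dn)) {
    rows <- list()
    for (j in seq_len(nrow(dn))) {
      d <- dn$idx[j]
      hn <- strsplit(dn$hydrogens[j], "|", fixed = TRUE)[[1]]
      hidx <- which(reskey == reskey[d] & atoms$name %in% hn)
      for (h in hidx) {
        rows[[length(rows) + 1]] <- data.frame(
          d = d, h = h, group = dn$group[j], stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) donors <- do.call(rbind, rows)
  }
  ac <- match_rows("acceptor")
  acceptors <- if (is.null(ac)) NULL else data.frame(a = ac$idx,
                                                     group = ac$group,
                                                     stringsAsFactors = FALSE)
  lab <- function(idx, group) {
    paste0(.title_case_res(atoms$resname[idx]), atoms$reslabel[idx], " ", group)
  }
  if (!is.null(donors)) {
    donors$reskey <- reskey[donors$d]
    donors$group_key <- paste(donors$reskey, donors$group)
    donors$label <- lab(donors$d, donors$group)
  }
  if (!is.null(acceptors)) {
    acceptors$reskey <- reskey[acceptors$a]
    acceptors$group_key <- paste(acceptors$reskey, acceptors$group)
    acceptors$label <- lab(acceptors$a, acceptors$group)
  }
  list(donors = donors, acceptors = acceptors)
}

# core geometric test on one coordinate set (N x 3)
.detect_core <- function(coords, sites, criteria, allow_intra = FALSE) {
  dn <- sites$donors; ac <- sites$acceptors
  empty <- data.frame(d = integer(), h = integer(), a = integer(),
                      distance = numeric(), angle = numeric(),
                      donor_group = character(), acceptor_group = character(),
                      donor_label = character(), acceptor_label = character())
  if (is.null(dn) || is.null(ac) || nrow(dn) == 0 || nrow(ac) == 0) {
    return(empty)
  }
  H <- coords[dn$h, , drop = FALSE]
  A <- coords[ac$a, , drop = FALSE]
  # pairwise squared distances H x A
  d2 <- outer(rowSums(H^2), rowSums(A^2), "+") - 2 * H %*% t(A)
  hit <- which(d2 < criteria$max_h_a_distance^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  if (!allow_intra) {
    keep <- dn$reskey[i] != ac$reskey[j]
    i <- i[keep]; j <- j[keep]
  }
  if (!length(i)) return(empty)
  D <- coords[dn$d[i], , drop = FALSE]
  Hv <- coords[dn$h[i], , drop = FALSE]
  Av <- coords[ac$a[j], , drop = FALSE]
  u <- D - Hv; v <- Av - Hv
  cosang <- rowSums(u * v) /
    (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  keep <- ang > criteria$min_dha_angle
  i <- i[keep]; j <- j[keep]; ang <- ang[keep]
  if (!length(i)) return(empty)
  data.frame(d = dn$d[i], h = dn$h[i], a = ac$a[j],
             distance = sqrt(d2[cbind(i, j)][keep]),
             angle = ang,
             donor_group = dn$group_key[i],
             acceptor_group = ac$group_key[j],
             donor_label = dn$label[i],
             acceptor_label = ac$label[j],
             stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds in one frame
#'
#' Returns every (donor atom, hydrogen, acceptor atom) triplet satisfying the
#' geometric criteria. Donor and acceptor are never in the same residue
#' unless `allow_intra = TRUE`.
#'
#' @param frame A [structure_frame()] (hydrogens must be present).
#' @param criteria [hbond_criteria()].
#' @param chemistry Donor/acceptor table from [load_chemistry()].
#' @param allow_intra Allow intra-residue pairs.
#' @param include_nonprotein Also consider non-protein residues whose types
#'   appear in the chemistry table.
#' @return data.frame of triplets with distances (Angstrom), angles
#'   (degrees) and group assignments.
#' @export
detect_hbonds_frame <- function(frame, criteria = hbond_criteria(),
                                chemistry = load_chemistry(),
                                allow_intra = FALSE,
                                include_nonprotein = FALSE) {
  sites <- .hbond_sites(frame$atoms, chemistry, include_nonprotein)
  .detect_core(frame_coords(frame), sites, criteria, allow_intra)
}

#' Collapse raw triplets to group-pair events
#'
#' Triplets are mapped to (donor group, acceptor group) pairs; duplicates --
#' bifurcated bonds or equivalent-atom multiplicity -- collapse to one event
#' per pair.
#'
#' @param raw Triplet data.frame from [detect_hbonds_frame()].
#' @return data.frame with one row per distinct
#'   (donor group, acceptor group) pair.
#' @export
collapse_events <- function(raw) {
  if (nrow(raw) == 0) {
    return(data.frame(donor_group = character(), acceptor_group = character(),
                      donor_label = character(), acceptor_label = character()))
  }
  key <- paste(raw$donor_group, raw$acceptor_group, sep = " -> ")
  first <- !duplicated(key)
  out <- raw[first, c("donor_group", "acceptor_group",
                      "donor_label", "acceptor_label"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# iterate detection over all frames, returning a list of collapsed event
# data.frames (shared site tables built once)
.events_per_frame <- function(traj, criteria, chemistry, allow_intra,
                              include_nonprotein) {
  sites <- .hbond_sites(traj$atoms, chemistry, include_nonprotein)
  lapply(seq_len(nrow(traj$xyz)), function(i) {
    coords <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
    collapse_events(.detect_core(coords, sites, criteria, allow_intra))
  })
}

#' Hydrogen-bond occupancies over a trajectory
#'
#' Per (donor group, acceptor group) pair, the fraction of frames with at
#' least one event. The full list is returned; thresholding happens only at
#' export ([export_network()]).
#'
#' @inheritParams detect_hbonds_frame
#' @param traj A [trajectory()].
#' @return data.frame with columns `donor_label`, `acceptor_label`,
#'   `occupancy`, `n_frames`, ordered by occupancy (descending) then labels.
#' @export
hbond_occupancy <- function(traj, criteria = hbond_criteria(),
                            chemistry = load_chemistry(),
                            allow_intra = FALSE, include_nonprotein = FALSE) {
  evs <- .events_per_frame(traj, criteria, chemistry, allow_intra,
                           include_nonprotein)
  nf <- length(evs)
  all_ev <- do.call(rbind, evs)
  if (is.null(all_ev) || nrow(all_ev) == 0) {
    return(data.frame(donor_label = character(), acceptor_label = character(),
                      occupancy = numeric(), n_frames = integer()))
  }
  key <- paste(all_ev$donor_group, all_ev$acceptor_group, sep = " -> ")
  counts <- table(key)
  first <- all_ev[!duplicated(key), , drop = FALSE]
  ord_key <- paste(first$donor_group, first$acceptor_group, sep = " -> ")
  out <- data.frame(donor_label = first$donor_label,
                    acceptor_label = first$acceptor_label,
                    occupancy = as.numeric(counts[ord_key]) / nf,
                    n_frames = nf,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occupancy, out$donor_label, out$acceptor_label), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Block-averaged hydrogen-bond count per frame
#'
#' Counts distinct (donor group, acceptor group) pairs per frame (bifurcated
#' bonds count once) and block-averages the per-frame counts.
#'
#' @inheritParams hbond_occupancy
#' @param block_length Block length (ps).
#' @return A [block_stat()].
#' @export
hbond_count <- function(traj, criteria = hbond_criteria(),
                        chemistry = load_chemistry(), block_length = 10000,
                        allow_intra = FALSE, include_nonprotein = FALSE) {
  evs <- .events_per_frame(traj, criteria, chemistry, allow_intra,
                           include_nonprotein)
  per_frame <- vapply(evs, nrow, 0L)
  fpb <- max(1L, as.integer(round(block_length / traj$sampling_interval)))
  blocks <- .block_indices(length(per_frame), fpb)
  block_stat(vapply(blocks, function(ix) mean(per_frame[ix]), 0),
             block_length)
}

#' Export an occupancy network edge list
#'
#' Keeps edges with occupancy strictly greater than the threshold, in
#' deterministic (donor, acceptor) order.
#'
#' @param records Occupancy records from [hbond_occupancy()].
#' @param threshold Occupancy threshold (strict `>`).
#' @param path Optional TSV output path (header always written).
#' @return data.frame of edges (`donor`, `acceptor`, `occupancy`).
#' @export
export_network <- function(records, threshold = 0.5, path = NULL) {
  keep <- records$occupancy > threshold
  edges <- data.frame(donor = records$donor_label[keep],
                      acceptor = records$acceptor_label[keep],
                      occupancy = records$occupancy[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$donor, edges$acceptor), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  edges
}
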