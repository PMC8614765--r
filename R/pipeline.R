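# End-to-end orchestration: run the fluctuation, hydrogen-bond, void and
# quasiharmonic stages from a single config, with seeded determinism and
# provenance headers on every output.

# FNV-1a 32-bit hash of a character scalar (provenance fingerprinting).
# Kept in double arithmetic: h exceeds 2^31, so bitwXor() cannot take it
# directly (the byte xor only touches the low 8 bits), and h * prime
# exceeds 2^53, so the modular multiply is done in 16-bit halves to stay
# exact.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.config_hash <- function(config) {
  .fnv1a(paste(deparse(config), collapse = ""))
}

#' Assemble a run configuration
#'
#' Defaults mirror the standard analysis protocol: reference state P0 = 1
#' bar, T0 = 279 K; 10 ns fluctuation blocks; 10 ps quasiharmonic intervals;
#' hydrogen-bond cutoffs 2.40 Angstrom / 130 degrees; void search grid 1.0
#' Angstrom with probe 1.1 Angstrom; occupancy network threshold 0.5. All
#' are overridable; none are hard-coded downstream.
#'
#' @param ... Overrides of the defaults (see Details in the vignette).
#' @param path Optional YAML config file read before applying `...`.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(..., path = NULL) {
  defaults <- list(
    P0 = 1, T0 = 279,
    t_split = 200,
    block_length = 10000,
    interval = 10,
    hbond = list(max_h_a_distance = 2.40, min_dha_angle = 130),
    voids = list(search_grid = 1.0, probe_radius = 1.1, refine_grid = 0.5,
                 mc_per_A3 = 50, min_volume = 1.0, envelope_radius = 4.0),
    network_threshold = 0.5,
    seed = 1,
    out_dir = "."
  )
  cfg <- defaults
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

.provenance <- function(config) {
  c(sprintf("# piezotraj %s",
            as.character(utils::packageVersion("piezotraj"))),
    sprintf("# config_hash %s", .config_hash(unclass(config))),
    sprintf("# seed %s", config$seed))
}

.write_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by the pipeline (skipping provenance headers)
#' @param path File path.
#' @export
read_pipeline_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#")
}

.resolve_traj <- function(entry) {
  if (inherits(entry, "trajectory")) return(entry)
  if (is.list(entry) && !is.null(entry$pdb)) {
    if (is.null(entry$sidecar)) {
      stop("trajectory entry '", entry$label %||% entry$pdb,
           "' lacks an ensemble sidecar")
    }
    return(read_trajectory(entry$pdb, entry$sidecar))
  }
  stop("cannot resolve trajectory entry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary report: fluctuations, hydrogen bonds, radius of gyration
#'
#' One row per trajectory: block-averaged heavy-atom mean-square fluctuation,
#' hydrogen-bond count and radius of gyration, each as mean +/- sd over
#' blocks.
#'
#' @param trajectories Named list of [trajectory()] objects (or entries with
#'   `pdb` and `sidecar` paths).
#' @param config A [run_config()].
#' @param path Optional TSV output path (with provenance header).
#' @return data.frame summary.
#' @export
run_table1 <- function(trajectories, config = run_config(), path = NULL) {
  crit <- do.call(hbond_criteria, config$hbond)
  rows <- lapply(seq_along(trajectories), function(i) {
    label <- names(trajectories)[i] %||% paste0("traj", i)
    tr <- .resolve_traj(trajectories[[i]])
    msf <- tryCatch(block_msf(tr, "heavy", config$block_length),
                    error = function(e) stop("fluctuations stage: ",
                                             conditionMessage(e)))
    nhb <- tryCatch(hbond_count(tr, crit, block_length = config$block_length),
                    error = function(e) stop("hbonds stage: ",
                                             conditionMessage(e)))
    rg <- tryCatch(radius_of_gyration(tr, config$block_length),
                   error = function(e) stop("fluctuations stage: ",
                                            conditionMessage(e)))
    data.frame(system = label,
               P_bar = tr$pressure, T_K = tr$temperature,
               msf_HA_A2 = msf$mean, msf_HA_sd = msf$sd,
               N_HB = nhb$mean, N_HB_sd = nhb$sd,
               Rg_A = rg$mean, Rg_sd = rg$sd)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) .write_tsv(out, path, config)
  out
}

#' Run the quasiharmonic stage
#'
#' Either from a pressure-temperature grid of trajectories (via
#' [grid_sigma2()]) or directly from a surface (data.frame / CSV shortcut),
#' then the two-stage fit.
#'
#' @param input List of trajectories, a [fluctuation_surface()], a
#'   data.frame with `P`, `T`, `sigma2`, or a CSV/TSV path to one.
#' @param config A [run_config()].
#' @param path Optional TSV output path for the fit-summary table.
#' @return A [qha_params()] fit.
#' @export
run_qha <- function(input, config = run_config(), path = NULL) {
  surface <- if (inherits(input, "fluctuation_surface")) {
    input
  } else if (is.data.frame(input)) {
    fluctuation_surface(input, P0 = config$P0, T0 = config$T0)
  } else if (is.character(input)) {
    fluctuation_surface(utils::read.delim(input, comment.char = "#",
                                          sep = ""),
                        P0 = config$P0, T0 = config$T0)
  } else if (is.list(input)) {
    trajs <- lapply(input, .resolve_traj)
    grid_sigma2(trajs, interval = config$interval,
                P0 = config$P0, T0 = config$T0)
  } else {
    stop("unsupported QHA input")
  }
  fit <- fit_qha(surface, t_split = config$t_split,
                 P0 = config$P0, T0 = config$T0)
  if (!is.null(path)) {
    df <- write_qha_table(list(fit = fit), tempfile())
    .write_tsv(df, path, config)
  }
  fit
}

#' Run the hydrogen-bond stage
#'
#' @param traj A [trajectory()] (or resolvable entry).
#' @param config A [run_config()].
#' @param occupancy_path,network_path Optional TSV outputs.
#' @return List with `records` (occupancies) and `edges` (thresholded
#'   network).
#' @export
run_hbonds <- function(traj, config = run_config(), occupancy_path = NULL,
                       network_path = NULL) {
  tr <- .resolve_traj(traj)
  crit <- do.call(hbond_criteria, config$hbond)
  rec <- hbond_occupancy(tr, crit)
  edges <- export_network(rec, threshold = config$network_threshold)
  if (!is.null(occupancy_path)) .write_tsv(rec, occupancy_path, config)
  if (!is.null(network_path)) .write_tsv(edges, network_path, config)
  list(records = rec, edges = edges)
}

#' Run the void stage over structure snapshots
#'
#' @param frames List of [structure_frame()]s (e.g. trajectory snapshots at a
#'   fixed cadence) or a [trajectory()] plus `cadence` in ps.
#' @param config A [run_config()].
#' @param cadence Snapshot spacing (ps) when `frames` is a trajectory.
#' @param path Optional TSV output path for the tracking summary.
#' @return List with `snapshots` and `records` ([track_voids()] output).
#' @export
run_voids <- function(frames, config = run_config(), cadence = 5000,
                      path = NULL) {
  vp <- do.call(void_params, c(config$voids, list(seed = config$seed)))
  if (inherits(frames, "trajectory")) {
    step <- max(1L, as.integer(round(cadence / frames$sampling_interval)))
    idx <- seq(step, nrow(frames$xyz), by = step)
    frames <- lapply(idx, function(i) get_frame(frames, i))
  }
  snaps <- lapply(frames, function(fr) {
    analyze_voids(fr, vp, frame_time = fr$frame_time)
  })
  rec <- track_voids(snaps)
  if (!is.null(path)) {
    .write_tsv(rec[, c("track", "label", "mean", "rms", "n_snapshots")],
               path, config)
  }
  list(snapshots = snaps, records = rec)
}
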