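# Quasiharmonic analysis (QHA) of the protein potential energy landscape.
#
# Each atom is taken to sit in an effective local harmonic well created by
# its neighbours. The width of the average well, measured as the mean-square
# fluctuation sigma^2(P,T) over a pressure-temperature grid of short runs,
# follows a "liquid" branch above the glass transition:
#
#   sigma^2(P,T) = sigma0^2 * (T/T0) * [ (1 + kappa_T0 * dP) *
#                                        exp(-alpha_P0 * dT) ]^(-2/3)
#
# with dP = P - P0 (kbar internally), dT = T - T0, and a frozen-glass branch
# below T_g(P) = Tg0 - c * dP. Fitting the surface in two stages yields the
# reference well width sigma0^2, the intrinsic isobaric expansivity alpha_P0,
# the intrinsic isothermal compressibility kappa_T0, and the glass-transition
# parameters Tg0 and c.

#' Bundle quasiharmonic landscape parameters
#'
#' @param sigma0_sq Reference well width sigma0^2 (Angstrom^2).
#' @param alpha_P0 Intrinsic isobaric expansivity (1/K).
#' @param kappa_T0 Intrinsic isothermal compressibility (1/kbar).
#' @param Tg0 Glass-transition temperature at the reference pressure (K).
#' @param c Pressure coefficient of T_g, defined through
#'   `T_g(P) = Tg0 - c * dP` (K/kbar). Note that for proteins whose T_g rises
#'   with pressure `c` is negative; summary tables report `-c`.
#' @param P0,T0 Reference state (bar, K).
#' @param chi2_stage1,chi2_stage2 Reduced chi-square of the two fit stages
#'   (Angstrom^4).
#' @param se Named numeric vector of parameter standard errors.
#' @return Object of class `qha_params`.
#' @export
qha_params <- function(sigma0_sq, alpha_P0, kappa_T0, Tg0 = NA_real_,
                       c = NA_real_, P0 = 1, T0 = 279,
                       chi2_stage1 = NA_real_, chi2_stage2 = NA_real_,
                       se = NULL) {
  if (!is.na(sigma0_sq) && sigma0_sq <= 0) stop("sigma0_sq must be positive")
  if (!is.na(Tg0) && Tg0 <= 0) stop("Tg0 must be positive")
  structure(list(sigma0_sq = sigma0_sq, alpha_P0 = alpha_P0,
                 kappa_T0 = kappa_T0, Tg0 = Tg0, c = c, P0 = P0, T0 = T0,
                 chi2_stage1 = chi2_stage1, chi2_stage2 = chi2_stage2,
                 se = se),
            class = "qha_params")
}

#' @export
print.qha_params <- function(x, ...) {
  cat("Quasiharmonic landscape parameters",
      sprintf(" (reference state P0 = %g bar, T0 = %g K)\n", x$P0, x$T0))
  fmt <- function(v, s, scale = 1, digits = 4) {
    if (is.na(v)) return("  --")
    out <- format(signif(v * scale, digits))
    if (!is.null(x$se) && s %in% names(x$se) && is.finite(x$se[[s]])) {
      out <- paste0(out, " +/- ", format(signif(x$se[[s]] * scale, 2)))
    }
    out
  }
  cat("  sigma0^2 (A^2):        ", fmt(x$sigma0_sq, "sigma0_sq"), "\n")
  cat("  alpha_P,0 (10^-3/K):   ", fmt(x$alpha_P0, "alpha_P0", 1e3), "\n")
  cat("  kappa_T,0 (10^-3/kbar):", fmt(x$kappa_T0, "kappa_T0", 1e3), "\n")
  if (!is.na(x$chi2_stage1))
    cat("  reduced chi^2 stage 1 (A^4):", format(signif(x$chi2_stage1, 3)), "\n")
  if (!is.na(x$Tg0)) {
    cat("  T_g,0 (K):             ", fmt(x$Tg0, "Tg0"), "\n")
    cat("  -c (K/kbar):           ", fmt(-x$c, "c"), "\n")
  }
  if (!is.na(x$chi2_stage2))
    cat("  reduced chi^2 stage 2 (A^4):", format(signif(x$chi2_stage2, 3)), "\n")
  invisible(x)
}

.dp_kbar <- function(params, P) (P - params$P0) / 1000

#' Liquid-branch quasiharmonic fluctuation model
#'
#' Evaluates the well width sigma^2 at (P, T) on the quasiharmonic "liquid"
#' branch (valid above the glass transition).
#'
#' @param params A [qha_params()] object.
#' @param P Pressure (bar); vectorised.
#' @param T Temperature (K); vectorised.
#' @return sigma^2 in Angstrom^2.
#' @export
#' @examples
#' p <- qha_params(0.148, 8.0e-3, 65e-3)
#' forward_liquid(p, 1, 279)      # reference state: exactly sigma0^2
#' forward_liquid(p, 2500, 279)   # compressed: smaller well
forward_liquid <- function(params, P, T) {
  if (any(T <= 0)) stop("temperature must be positive")
  dP <- .dp_kbar(params, P)
  dT <- T - params$T0
  bracket <- (1 + params$kappa_T0 * dP) * exp(-params$alpha_P0 * dT)
  if (any(bracket <= 0)) {
    stop("nonpositive bracket (1 + kappa_T0*dP)*exp(-alpha_P0*dT); model domain exceeded")
  }
  params$sigma0_sq * (T / params$T0) * bracket^(-2 / 3)
}

#' Pressure-dependent glass-transition temperature
#'
#' `T_g(P) = Tg0 - c * dP`, dP in kbar.
#'
#' @inheritParams forward_liquid
#' @return T_g in K.
#' @export
tg_of_p <- function(params, P) {
  params$Tg0 - params$c * .dp_kbar(params, P)
}

#' Well width at the glass transition
#'
#' `sigma_g^2(P)`, identically equal to `forward_liquid(params, P, tg_of_p(params, P))`.
#'
#' @inheritParams forward_liquid
#' @return sigma_g^2 in Angstrom^2.
#' @export
sigma_g <- function(params, P) {
  forward_liquid(params, P, tg_of_p(params, P))
}

#' Frozen-glass branch of the fluctuation model
#'
#' Below T_g(P) the system is trapped in a single well and the classical
#' harmonic limit applies: sigma^2 is linear in T through the origin and
#' continuous with the liquid branch at T_g(P),
#' `sigma^2 = sigma_g^2(P) * T / T_g(P)`.
#' Points above T_g are delegated to [forward_liquid()] with a warning.
#'
#' @inheritParams forward_liquid
#' @return sigma^2 in Angstrom^2.
#' @export
glass_branch <- function(params, P, T) {
  n <- max(length(P), length(T))
  P <- rep_len(P, n); T <- rep_len(T, n)
  tg <- tg_of_p(params, P)
  above <- T > tg
  out <- numeric(n)
  if (any(above)) {
    warning("glass_branch called above T_g; using liquid branch there")
    out[above] <- forward_liquid(params, P[above], T[above])
  }
  if (any(!above)) {
    out[!above] <- sigma_g(params, P[!above]) * T[!above] / tg[!above]
  }
  out
}

#' Full piecewise quasiharmonic forward model
#'
#' Liquid branch at and above T_g(P), frozen-glass branch below.
#'
#' @inheritParams forward_liquid
#' @return sigma^2 in Angstrom^2.
#' @export
qha_forward <- function(params, P, T) {
  n <- max(length(P), length(T))
  P <- rep_len(P, n); T <- rep_len(T, n)
  tg <- tg_of_p(params, P)
  below <- !is.na(tg) & T < tg
  out <- numeric(n)
  if (any(!below)) out[!below] <- forward_liquid(params, P[!below], T[!below])
  if (any(below)) {
    out[below] <- sigma_g(params, P[below]) * T[below] / tg[below]
  }
  out
}

# ---- fitting ----------------------------------------------------------------

.surface_df <- function(surface) {
  if (inherits(surface, "fluctuation_surface")) surface$points else surface
}

.lm_control <- minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                          gtol = 0, maxiter = 1000)

#' Stage-1 quasiharmonic fit (liquid branch)
#'
#' Unweighted nonlinear least squares of the liquid-branch model to all
#' surface points with `T >= t_min`, yielding `sigma0_sq`, `alpha_P0` and
#' `kappa_T0`. Optimisation is Levenberg-Marquardt from a 3 x 3 x 3
#' multi-start lattice (sigma0^2 seeded from the reference-state point;
#' alpha in {1, 8, 20} x 10^-3 /K; kappa in {10, 65, 150} x 10^-3 /kbar);
#' the best-cost converged solution wins, ties going to the first found.
#'
#' @param surface A [fluctuation_surface()] or a data.frame with columns
#'   `P` (pressure), `T` (K) and `sigma2` (Angstrom^2).
#' @param t_min Lower temperature bound of the liquid-branch window (K).
#' @param P0,T0 Reference state. Defaults are taken from the surface when it
#'   carries one.
#' @param pressure_unit Unit of the surface's pressure column (`"bar"` or
#'   `"kbar"`); `kappa_T0` comes out per that unit's kbar-equivalent scaling
#'   (fitting the same numbers declared as kbar yields kappa 1000x smaller).
#' @return A [qha_params()] with `Tg0`/`c` unset and `chi2_stage1` filled
#'   (reduced by N - 3). Standard errors from the linearised covariance at
#'   the optimum.
#' @export
fit_stage1 <- function(surface, t_min = 200, P0 = NULL, T0 = NULL,
                       pressure_unit = c("bar", "kbar")) {
  pressure_unit <- match.arg(pressure_unit)
  pts <- .surface_df(surface)
  if (inherits(surface, "fluctuation_surface")) {
    if (is.null(P0)) P0 <- surface$reference_state[["P0"]]
    if (is.null(T0)) T0 <- surface$reference_state[["T0"]]
  }
  if (is.null(P0)) P0 <- 1
  if (is.null(T0)) T0 <- 279
  if (any(pts$sigma2 <= 0)) {
    stop("surface contains nonpositive sigma2; invalid for QHA")
  }
  sel <- pts$T >= t_min
  pts <- pts[sel, , drop = FALSE]
  if (nrow(pts) < 4) stop("stage-1 fit needs >= 4 points with T >= ", t_min)
  if (length(unique(pts$P)) < 2 || length(unique(pts$T)) < 2) {
    stop("stage-1 fit is degenerate: need >= 2 pressures and >= 2 temperatures (alpha and kappa unidentifiable)")
  }
  scale <- if (pressure_unit == "bar") 1 / 1000 else 1
  dP <- (pts$P - P0) * scale
  dT <- pts$T - T0
  y <- pts$sigma2

  model <- function(th) {
    bracket <- (1 + th[3] * dP) * exp(-th[2] * dT)
    ifelse(bracket > 0, th[1] * (pts$T / T0) * bracket^(-2 / 3), 1e6)
  }
  resid_fn <- function(th) model(th) - y

  # sigma0^2 start: the reference-state point if present, else back-scaled mean
  i0 <- which(dP == 0 & dT == 0)
  s0 <- if (length(i0)) y[i0[1]] else mean(y * T0 / pts$T)
  starts <- expand.grid(s = s0 * c(0.5, 1, 2),
                        a = c(1, 8, 20) * 1e-3,
                        k = c(10, 65, 150) * 1e-3)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fn,
                         control = .lm_control),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(coef(fit)))) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("stage-1 fit failed to converge from any start; check surface values")
  }
  th <- coef(best)
  dof <- nrow(pts) - 3
  chi2 <- best$deviance / dof
  se <- tryCatch({
    s <- summary(best)$coefficients[, "Std. Error"]
    c(sigma0_sq = s[1], alpha_P0 = s[2], kappa_T0 = s[3])
  }, error = function(e) NULL)
  qha_params(sigma0_sq = th[1], alpha_P0 = th[2], kappa_T0 = th[3],
             P0 = P0, T0 = T0, chi2_stage1 = chi2, se = se)
}

#' Stage-2 quasiharmonic fit (glass branch)
#'
#' Least squares of the frozen-glass model over surface points with
#' `T < t_max`, with the stage-1 parameters frozen, yielding `Tg0` and `c`.
#' Branch assignment is piecewise in the current iterate: points above the
#' current T_g(P) are evaluated on the liquid branch, so points may cross
#' branches during optimisation.
#'
#' @inheritParams fit_stage1
#' @param stage1 Completed stage-1 [qha_params()].
#' @param t_max Upper temperature bound of the glass window (K).
#' @return `stage1` augmented with `Tg0`, `c` and `chi2_stage2`
#'   (reduced by N - 2). When the data show no glass break, the fitted `Tg0`
#'   collapses at or below the lowest fitted temperature and a
#'   `no_transition` attribute is set.
#' @export
fit_stage2 <- function(surface, stage1, t_max = 200,
                       pressure_unit = c("bar", "kbar")) {
  pressure_unit <- match.arg(pressure_unit)
  if (is.na(stage1$sigma0_sq)) stop("stage1 parameters incomplete")
  pts <- .surface_df(surface)
  sel <- pts$T < t_max
  pts <- pts[sel, , drop = FALSE]
  if (nrow(pts) < 2) stop("stage-2 fit needs >= 2 points with T < ", t_max)
  if (length(unique(pts$P)) < 2) {
    stop("stage-2 fit is degenerate: need >= 2 pressures to identify c")
  }
  scale <- if (pressure_unit == "bar") 1 / 1000 else 1
  dP <- (pts$P - stage1$P0) * scale
  dT <- pts$T - stage1$T0
  y <- pts$sigma2

  liquid <- function() {
    bracket <- (1 + stage1$kappa_T0 * dP) * exp(-stage1$alpha_P0 * dT)
    stage1$sigma0_sq * (pts$T / stage1$T0) * bracket^(-2 / 3)
  }
  liq <- liquid()
  model <- function(th) {
    tg <- th[1] - th[2] * dP
    tg <- pmax(tg, 1e-6)
    brk <- (1 + stage1$kappa_T0 * dP) * exp(-stage1$alpha_P0 * (tg - stage1$T0))
    sg <- stage1$sigma0_sq * (tg / stage1$T0) * ifelse(brk > 0, brk^(-2 / 3), 1e6)
    ifelse(pts$T < tg, sg * pts$T / tg, liq)
  }
  resid_fn <- function(th) model(th) - y

  starts <- expand.grid(tg = c(0.5, 0.7, 0.9) * t_max, c = c(-1, 0, 1))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fn,
                         control = .lm_control),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(coef(fit)))) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("stage-2 fit failed to converge from any start")
  th <- coef(best)
  dof <- nrow(pts) - 2
  chi2 <- best$deviance / dof
  se2 <- tryCatch({
    s <- summary(best)$coefficients[, "Std. Error"]
    c(Tg0 = s[1], c = s[2])
  }, error = function(e) NULL)
  out <- qha_params(sigma0_sq = stage1$sigma0_sq, alpha_P0 = stage1$alpha_P0,
                    kappa_T0 = stage1$kappa_T0, Tg0 = th[1], c = th[2],
                    P0 = stage1$P0, T0 = stage1$T0,
                    chi2_stage1 = stage1$chi2_stage1, chi2_stage2 = chi2,
                    se = c(stage1$se, se2))
  if (th[1] <= min(pts$T)) attr(out, "no_transition") <- TRUE
  out
}

#' Fit both quasiharmonic stages
#'
#' Convenience wrapper: [fit_stage1()] on `T >= t_split`, then [fit_stage2()]
#' on `T < t_split` with stage-1 parameters frozen.
#'
#' @inheritParams fit_stage1
#' @param t_split Temperature splitting the two fit windows (K).
#' @export
fit_qha <- function(surface, t_split = 200, P0 = NULL, T0 = NULL,
                    pressure_unit = c("bar", "kbar")) {
  pressure_unit <- match.arg(pressure_unit)
  s1 <- fit_stage1(surface, t_min = t_split, P0 = P0, T0 = T0,
                   pressure_unit = pressure_unit)
  fit_stage2(surface, s1, t_max = t_split, pressure_unit = pressure_unit)
}

#' Compare two quasiharmonic parameter sets
#'
#' Per-parameter differences `a - b` with uncertainties propagated in
#' quadrature, e.g. for contrasting the intrinsic compressibility of two
#' homologous enzymes.
#'
#' @param a,b [qha_params()] objects fitted against the same reference state.
#' @return data.frame with columns `parameter`, `a`, `b`, `difference`, `se`.
#' @export
compare_compressibility <- function(a, b) {
  if (a$P0 != b$P0 || a$T0 != b$T0) {
    stop("parameter sets have different reference states; comparison undefined")
  }
  pars <- c("sigma0_sq", "alpha_P0", "kappa_T0", "Tg0", "c")
  va <- vapply(pars, function(p) a[[p]], 0)
  vb <- vapply(pars, function(p) b[[p]], 0)
  sa <- vapply(pars, function(p) {
    if (!is.null(a$se) && p %in% names(a$se)) a$se[[p]] else NA_real_
  }, 0)
  sb <- vapply(pars, function(p) {
    if (!is.null(b$se) && p %in% names(b$se)) b$se[[p]] else NA_real_
  }, 0)
  data.frame(parameter = pars, a = va, b = vb,
             difference = va - vb,
             se = sqrt(sa^2 + sb^2),
             row.names = NULL)
}

#' Write a fit-summary table
#'
#' One row per parameter set, columns in conventional reporting units
#' (sigma0^2 in Angstrom^2, alpha and kappa in 10^-3 units, the glass-slope
#' column reported as `-c`).
#'
#' @param fits Named list of [qha_params()].
#' @param path Output TSV path.
#' @return Invisibly, the data.frame written.
#' @export
write_qha_table <- function(fits, path) {
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    p <- fits[[nm]]
    data.frame(system = nm,
               sigma0_sq_A2 = p$sigma0_sq,
               alpha_P0_1e3_per_K = p$alpha_P0 * 1e3,
               kappa_T0_1e3_per_kbar = p$kappa_T0 * 1e3,
               chi2_stage1_A4 = p$chi2_stage1,
               Tg0_K = p$Tg0,
               minus_c_K_per_kbar = -p$c,
               chi2_stage2_A4 = p$chi2_stage2)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
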