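---
title: "Methods: quasiharmonic pressure analysis, fluctuation estimators, and void volumetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quasiharmonic pressure analysis, fluctuation estimators, and void volumetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezotraj)
```

This vignette documents the statistical model, the estimator choices, and the
interpretive decisions behind each analysis stage, so that results can be
judged on their assumptions rather than on the code alone. Everything stated
here is either a mathematical property of the model or a behaviour exercised
by the package's test suite; no empirical claims beyond those are made.

## 1. The quasiharmonic pressure--temperature model

The central quantity is the average atomic mean-square fluctuation
$\sigma^2(P, T)$ of a protein over a grid of pressures and temperatures. The
package models the *liquid* (fluctuation-active) branch as

$$
\sigma^2(P, T) \;=\; \sigma_0^2 \,\frac{T}{T_0}\,
\Big[(1 + \kappa_{T_0}\,\Delta P)\, e^{-\alpha_{P_0}\,\Delta T}\Big]^{-2/3},
$$

with $\Delta P = (P - P_0)/1000$ in kbar when $P$ is given in bar, and
$\Delta T = T - T_0$. The three liquid-branch parameters are the reference
fluctuation $\sigma_0^2$ (Å²) at the reference state $(P_0, T_0)$, the
intrinsic isothermal compressibility $\kappa_{T_0}$ (kbar⁻¹), and the
intrinsic isobaric expansivity $\alpha_{P_0}$ (K⁻¹) of the effective
single-well potential. The $-2/3$ power arises because the effective force
constant of an isotropic quasiharmonic well scales with the $2/3$ power of the
well volume, which compresses with pressure and expands with temperature.

Below a pressure-dependent dynamical (glass) transition temperature

$$
T_g(P) = T_{g0} + c\,\Delta P, \qquad c < 0,
$$

the protein is trapped in a single substate and the fluctuation becomes purely
harmonic-in-temperature:

$$
\sigma^2_{\text{glass}}(P, T) \;=\; \sigma^2_g(P)\,\frac{T}{T_g(P)},
$$

where $\sigma^2_g(P)$ is fixed by continuity with the liquid branch at
$T = T_g(P)$. Reporting conventions: fit tables give $\alpha_{P_0}$ in
$10^{-3}$ K⁻¹, $\kappa_{T_0}$ in $10^{-3}$ kbar⁻¹, and the transition slope as
$-c$ (K/kbar), so that a steeper pressure-induced *drop* in $T_g$ appears as a
larger positive number.

**Interpretation of the glass branch.** $T_g(P)$ decreasing with pressure is
the signature behaviour of pressure-adapted enzymes: compression narrows the
energy landscape's wells faster than it raises barrier heights, so the
trapped (glassy) regime recedes to lower temperature. The slope $-c$ is
therefore the headline comparative quantity between homologues, and it is the
statistically weakest one: it is identified only by grid points *below* the
transition, of which a standard grid has few.

### The two-stage fit

`fit_qha()` deliberately splits estimation:

1. **Stage 1 (liquid branch).** Points with $T \ge$ `t_split` (200 K by
   default) are fit to the liquid model by Levenberg--Marquardt
   (`minpack.lm::nls.lm`) from a $3\times3\times3$ multi-start lattice over
   plausible $(\sigma_0^2, \alpha_{P_0}, \kappa_{T_0})$, keeping the lowest
   $\chi^2/(N-3)$. The multi-start guards against the shallow valley that
   couples $\alpha$ and $\sigma_0^2$ at narrow temperature ranges.
2. **Stage 2 (transition).** With stage-1 parameters *frozen*, the cold
   points ($T <$ `t_split`) determine $(T_{g0}, c)$ by fitting the piecewise
   model, re-deciding each point's branch at every iterate from the current
   $T_g(P)$; the objective is $\chi^2/(N-2)$. If the optimum drives
   $T_{g0}$ to or below the coldest grid temperature, the surface contains no
   resolvable transition and the fit is flagged (`no_transition` attribute)
   rather than reported as a spurious slope.

Freezing stage 1 is a bias--variance decision: letting all five parameters
float lets the handful of glassy points perturb the well-determined liquid
parameters, which is the wrong trade when the glassy subset is 10--20% of the
grid. Standard errors come from the local Jacobian at the optimum and should
be read as conditional on the branch assignment.

### What the fit assumes

- Fluctuations on the grid are statistically independent between state
  points (separate trajectories).
- The within-branch residuals are homoscedastic on the absolute scale; if
  relative errors are more realistic, weights should be applied upstream.
- A single global transition: the model has one $T_g(P)$ line, not
  per-residue transitions.

## 2. Fluctuation estimators

`block_msf()` computes mean-square fluctuations per contiguous block
(default 10 ns) with a **two-pass** protocol per block: superpose all frames
onto the block's first frame, compute the mean structure, re-superpose onto
that mean, then average squared deviations with the **unbiased $(m-1)$**
(Bessel) normalisation over the $m$ frames of the block. Block averaging
gives an honest between-block spread for $\pm$ reporting and suppresses slow
drift that a single whole-trajectory mean would smear into apparent
fluctuation.

Two systematic effects are worth knowing:

- **Superposition absorption.** Rigid-body fitting removes six degrees of
  freedom, deflating the summed MSF by roughly $2/N$ for $N$ fitted atoms
  (translation alone removes exactly $1/N$ of each coordinate's variance).
  For proteins ($N \gtrsim 10^3$ heavy atoms) this is well below other error
  sources; for toy systems with tens of atoms it is visible, and the test
  suite accounts for it explicitly.
- **Degenerate geometry.** Nearly collinear atom sets leave rotation about
  the chain axis unconstrained, so per-atom profiles from such fixtures are
  meaningless; `ca_msf()` is intended for three-dimensional folds.

`grid_sigma2()` uses a finer interval (10 ps by default) because the
quasiharmonic model describes intra-well motion: long windows mix substate
hopping into $\sigma^2$ and inflate it non-harmonically. A 1 ns trajectory at
1 ps sampling yields exactly 100 intervals (exposed as the `n_intervals`
attribute) whose mean is the grid value.

## 3. The synthetic generator: realism and limits

`gen_qha_trajectory()` produces coordinates whose per-atom displacement obeys
a stationary AR(1) process with the model-prescribed variance, so the
quasiharmonic pipeline can be validated end-to-end without molecular
dynamics. What it reproduces faithfully: the marginal variance at each
$(P,T)$, its pressure/temperature scaling, and short-time correlation. What
it does *not* contain: anharmonicity, substate hopping, correlated
inter-atomic motion, or solvent. Consequently, recovery tests on synthetic
trajectories validate the estimators and fits, not the physical model; they
place a floor, not a ceiling, on real-data error.

All generators take explicit seeds, restore the caller's RNG state, and are
reproducible bit-for-bit across runs.

## 4. Hydrogen-bond protocol

`hbond_occupancy()` applies strict geometric criteria — H···A distance
strictly below 2.40 Å *and* D–H···A angle strictly above 130° — to
hydrogen--acceptor pairs drawn from a versioned chemistry table
(`inst/extdata/hbond_chemistry.csv`) mapping residue/atom names to donor and
acceptor *groups*. Two decisions matter for counts:

- **Equivalent-donor/acceptor merging.** Chemically indistinguishable sites
  (e.g. carboxylate OD1/OD2, guanidinium NH1/NH2) are collapsed to one group
  *before* occupancy is computed, so a bond that migrates between equivalent
  oxygens counts as one persistent interaction, not two intermittent ones.
- **Strict inequalities at the cutoffs** make the criteria unambiguous at
  boundary geometries; the test suite pins this with exact boundary cases.

Occupancy is the fraction of frames in which a (donor-group, acceptor-group)
pair is bonded; `export_network()` thresholds it (default 0.5) into an edge
list.

## 5. Void volumetrics

`analyze_voids()` classifies empty space in a protein snapshot:

1. **Occupancy grid.** Atoms are painted onto a cubic grid (default 1.0 Å)
   with radii inflated by the probe radius (default 1.1 Å, a water-sized
   probe); free cells are those a probe centre could occupy.
2. **Connectivity.** Free cells are labelled into 26-connected components by
   flood fill.
3. **Bulk vs. internal.** The component touching the box boundary is bulk
   solvent. A morphological *closing envelope* (dilation radius 4.0 Å)
   defines the protein's outer hull: free components outside the hull are
   bulk, free components inside the hull that do not connect to bulk are
   **cavities**, and free space inside the hull that *does* connect to bulk
   is a **cleft** (solvent-accessible invagination).
4. **Lining and tie-breaks.** Each void's lining is the set of occupied
   boundary cells, attributed by majority vote of adjacent void labels; ties
   resolve toward the cleft interpretation (open to solvent), the
   conservative choice for a putative pathway.
5. **Monte-Carlo refinement.** Raw grid volumes are refined by seeded,
   stratified rejection sampling against the **bare van der Waals surface**
   (not the probe-inflated one): the probe defines *which* space is a void,
   but the reported volume is the geometric empty volume, which is the
   quantity comparable across grid spacings and probe choices. Volumes below
   `min_volume` (1.0 ų) are reported as 0 — sub-grid specks are artefacts of
   lattice placement.

**Tracking and merging.** `track_voids()` matches voids across snapshots by
maximum Jaccard overlap of their atom linings (not by volume or label order,
both of which are unstable). Two tracks are *merged* in a snapshot when both
resolve to the same connected component there; the merge constitutes a
pathway to the surface when that component is a cleft. This track-based
definition is used because, within a single snapshot, a cavity and a cleft
can never share a connected free component — "merge" is inherently a
statement about identity over time.

**Problem sizes.** The defaults are tuned for protein-sized systems (boxes of
$\sim 10^2$ Å per side at 1 Å grids). Finer grids cost $O((L/h)^3)$ in memory
and the closing envelope costs an additional $O((r_{\text{env}}/h)^3)$ per
free cell, so sub-0.5 Å grids should be paired with a smaller envelope
radius.

## 6. Limitations

- The quasiharmonic model is isotropic and global; systems with strongly
  heterogeneous domains may need per-domain fits.
- $T_g$ parameters are only as good as the sub-transition grid coverage;
  with two or three cold temperatures the slope $-c$ carries standard errors
  of the same order as inter-homologue differences.
- Hydrogen-bond detection is geometric only; no energetic criterion.
- Void classification depends on probe radius and envelope radius; both are
  reported with results and should be held fixed across compared systems.
- The synthetic generator cannot validate anharmonic or collective effects.
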