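---
title: "Methods: modelling and measuring viral carbon and nitrogen consumption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and measuring viral carbon and nitrogen consumption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virovory)
```

## The scientific problem

Marine virus particles are removed both abiotically (decay, adsorption to
surfaces) and biotically: heterotrophic bacteria degrade virions and
phagotrophic protists ingest them (virovory), returning viral carbon and
nitrogen to the microbial loop. The standard experimental design
size-fractionates seawater (<100 µm full community, <1.2 µm bacteria only,
<0.1 µm essentially cell-free), spikes each bottle with isotopically
labelled virus, and follows (i) virus and bacteria abundances by flow
cytometry and (ii) single-cell isotope incorporation by nanoSIMS. This
package implements the quantitative machinery of that design: the food-web
model used to interpret the removal dynamics, the isotope bookkeeping, the
ion-image processing, the removal-rate statistics, and synthetic-data
generators that stand in for the instrument outputs.

## The food-web model

Three compartments — viruses $V$, bacteria $B$, grazers $G$ (all ml$^{-1}$,
time in days):

$$\frac{dV}{dt} = S_v - \varphi_{g,v} G V - \varphi_{b,v} B V - \delta_v V$$
$$\frac{dB}{dt} = \mu_b B + \varepsilon_{b,v}\varphi_{b,v} B V - \varphi_{g,b} G B - \delta_b B^2$$
$$\frac{dG}{dt} = \varepsilon_{g,b}\varphi_{g,b} G B + \varepsilon_{g,v}\varphi_{g,v} G V - \delta_g G^2$$

Consumption is mass-action (encounter-rate) with clearance rates
$\varphi$ (ml consumer$^{-1}$ d$^{-1}$) and dimensionless transfer
efficiencies $\varepsilon$; mortality unrelated to the resolved predators is
closed quadratically ($\delta_b B^2$, $\delta_g G^2$). The reference
parameter set returned by `foodweb_params()` ($S_v = 5\times10^7$,
$\varphi_{g,v} = 10^{-3}$, $\varphi_{b,v} = 10^{-6}$,
$\varphi_{g,b} = 10^{-3}$, $\mu_b = 0.8$, $\delta_v = 0.1$,
$\delta_b = 10^{-6}$, $\delta_g = 0.1$, $\varepsilon_{g,b} = 0.1$,
$\varepsilon_{g,v} = 10^{-6}$, $\varepsilon_{b,v} = 10^{-3}$) is chosen for
qualitative consistency with coastal bottle incubations, not as a fitted
estimate. A note on units: the quadratic closure coefficients
$\delta_b, \delta_g$ carry units ml cell$^{-1}$ d$^{-1}$ so that
$\delta X^2$ has units of ml$^{-1}$ d$^{-1}$ — dimensional consistency
fixes the occasionally-seen d$^{-1}$ annotation.

### Simulation protocol

`simulate_treatment()` follows the experimental logic:

1. **Spin-up.** The full system is integrated to equilibrium
   (`run_to_equilibrium()`, relative derivative norm
   $\max_i |\dot X_i| / \max(X_i, 1) < 10^{-9}$, horizon 5000 d). The
   experimental observations reflect internal feedbacks, not transient
   relaxation from arbitrary initial abundances, so the simulation must
   too. The spin-up initial condition defaults to
   $(10^6, 10^5, 10^2)$ ml$^{-1}$; by construction the result does not
   depend on it, which the test suite verifies by comparing against the
   algebraic fixed point (eliminate $G^* $ and $V^*$ analytically from
   their steady-state equations, then solve the remaining scalar equation
   in $B^*$).
2. **Filtration.** Instantaneous, complete removal of the filtered
   compartments ($G$ for <1.2 µm; $B$ and $G$ for <0.1 µm). Real filters
   are leaky; a `retention` fraction (default 0) exposes that knob without
   changing the idealised default.
3. **Supply cut.** $S_v = 0$ at $t = 0$: the labelled spike is a one-time
   addition with no ongoing production (no host phytoplankton present).
4. **Integration** over 8 d, reported at the experimental sampling grid
   0, 0.5, 1, 2, 4, 8 d. Removal at time $t$ is $1 - V(t)/V(0^+)$.

Integration uses `deSolve::lsoda` (adaptive, stiff-capable) at relative
tolerance $10^{-8}$. States that dip below zero by less than $10^{-12}$
of the state scale are clipped; anything larger is an error, never a
silent NaN. A fixed-step RK4 reference at $dt = 10^{-3}$ d is used in the
tests as an independent oracle.

With no cells the virus equation collapses to pure decay,
$V(t) = V_0 e^{-\delta_v t}$, giving the closed-form 8-day abiotic removal
$1 - e^{-0.8} \approx 0.551$ that anchors the test suite. With the
reference parameters the simulated ordering
removal(<100 µm) > removal(<1.2 µm) > removal(<0.1 µm) holds at every
positive output time.

## Isotope bookkeeping

nanoSIMS records four secondary-ion masses per pixel: $^{12}$C$_2^-$,
$^{13}$C$^{12}$C$^-$, $^{12}$C$^{14}$N$^-$, $^{12}$C$^{15}$N$^-$. Under
independent binomial pairing of carbon atoms into two-carbon ions, a pool
with $^{13}$C atom fraction $f$ yields
$P(^{13}C^{12}C)/P(^{12}C_2) = 2f/(1-f)$, i.e. the dimer ion ratio is
exactly twice the atomic ratio — `dimer_ratio_factor()` evaluates this
constant from the isotopologue probabilities and the test suite verifies
it equals 2 across the composition range. The CN ion ratio equals the
atomic $^{15}$N/$^{14}$N ratio directly. Inversions:
$f_{13C} = R/(R+2)$, $f_{15N} = R/(1+R)$.

Enrichment is reported two ways:

* **APE** $= 100\,(f_{meas} - f_{nat})$, atom percent above natural
  abundance. Negative APE (noise below background) is preserved in data;
  flooring at zero is an explicit reporting option only.
* **X_net** $= 100\,(f_{meas} - f_{nat})/(f_{source} - f_{nat})$: the
  percent of the cell's element derived from the labelled substrate,
  linear two-end-member mixing between unlabelled biomass and the
  substrate. The mixing is done on atom fractions; at these enrichments
  the difference from ratio-space mixing is negligible, but the choice is
  documented rather than silent.

Under exponential growth fuelled entirely by the substrate, $d$ divisions
leave $X_{net} = 100(1 - 2^{-d})$: 50% after one division, 75% after two.
`divisions_from_xnet()` inverts this.

Defaults: natural abundances $f_{13C,nat} = 0.0111$ (VPDB convention),
$f_{15N,nat} = 0.003676$ (atmospheric N$_2$) — these baselines are
conventions, configurable in `isotope_constants()`; substrate enrichment
defaults to 40 atom% $^{13}$C / 80 atom% $^{15}$N but varies batch to
batch and should be set per experiment.

## Ion-image processing

Stacks are `[mass, cycle, row, col]` arrays; the default geometry is a
20 × 20 µm raster at 256 × 256 px (78.125 nm px$^{-1}$), 1 ms dwell,
20–30 cycles.

* **Alignment** (`align_cycles()`): each cycle's $^{12}$C$^{14}$N$^-$
  image is cross-correlated (FFT) against cycle 1 and translated by the
  best integer shift within ±10 px. Integer shifts only — sub-pixel
  interpolation would redistribute integer counts. Out-of-frame pixels
  are marked invalid; all-zero reference cycles are flagged and left
  unshifted.
* **Dead time** (`deadtime_correct()`): non-paralyzable
  $n_{true} = n/(1 - n\tau/t_{dwell})$ per pixel per cycle; $\tau$
  defaults to 44 ns but the correction is off ($\tau = 0$) for synthetic
  data, which is generated without dead-time loss. Saturated pixels
  become NA rather than fabricated counts.
* **Segmentation** (`segment_particles()`): the cycle-summed
  $^{12}$C$^{14}$N$^-$ image is thresholded at median $+ k\cdot$MAD
  (normal-scaled MAD; $k = 5$), 4-connected components are extracted, and
  components outside the equivalent-diameter band (default 0.3 µm — about
  the bacteria scale — to ∞) are discarded. These are documented defaults,
  not reconstructions of any proprietary tool. Particles that are dim in
  $^{12}$C$^{14}$N$^-$ *because* they are highly $^{15}$N-enriched are
  recovered with `channel = "CN_total"` ($^{12}$C$^{14}$N$^-$ +
  $^{12}$C$^{15}$N$^-$). Below the background level thresholding merges
  everything into one component, so ROI-count monotonicity in the
  threshold holds only above background — the tests check that regime.
* **Hotspots** (`find_hotspots()`): the same pipeline restricted to
  4–50 µm equivalent diameter with $k = 10$, for locating protist-scale
  targets in large shallow scans.
* **Per-ROI statistics** (`roi_isotope_stats()`): for each cycle, counts
  are summed over the ROI pixels and the ratio of sums taken — the
  standard low-count estimator, unbiased in the denominator-dominated
  regime, and literally "ratios by cycle". Cycles with a zero denominator
  are excluded and counted. The mean ratio across usable cycles is
  converted to atom fractions / APE / X_net; the SEM across cycles
  propagates the counting noise.

## Synthetic data: what it emulates, and what it does not

Generators are pure functions of their specification plus seed
(bit-reproducible), and every planted object comes with exact ground
truth, so the processing chain can be scored end to end.

* **Abundance series** (`generate_abundance_series()`): latent
  trajectories from `simulate_treatment()` (triplicate bottles, sampling
  grid 0, 0.5, 1, 2, 4, 8 d, virus spike $3\times10^7$ ml$^{-1}$),
  observed with independent multiplicative lognormal noise, meanlog 0 and
  sdlog $\sqrt{\ln(1 + CV^2)}$, default CV 10%. The CV of real
  flow-cytometry counts is not well constrained; 10% is a realistic
  instrument-plus-pipetting figure and is a free parameter. Note the
  noise is mean-biased by $e^{\sigma^2/2}$ (≈ 0.5% at CV 10%), which the
  moment tests account for.
* **Ion stacks** (`generate_ion_stack()`): per-pixel expected counts
  $\lambda$ = density × yield × isotopologue probability (C2 masses via
  binomial pairing of the local $f_{13C}$; CN masses split by $f_{15N}$),
  Gaussian beam blur of FWHM 150 nm applied to $\lambda$ (toggleable),
  then independent Poisson draws per pixel and cycle, with a guard
  against $\lambda > 10^6$. Planted particles are disks or ellipses with
  specified diameter, densities and atom fractions.
* **Protist table** (`generate_protist_table()`): per-cell $N_{net}$ from
  a two-component uniform mixture (80% of cells in U(0, 10)%, 20% in
  U(10, 85)% — a minority of cells feeding intensely on labelled virus,
  spanning roughly multiple divisions' worth of enrichment), with
  $C_{net}$ coupled linearly plus Gaussian noise (SD 5%), clipped to
  [0, 100)%. Defaults give a C–N enrichment correlation well above 0.8.

What the generators do **not** emulate: aggregation of virions with
detritus, filament formation in long incubations, instrument drift and
quasi-simultaneous-arrival effects, cross-feeding of remineralised
$^{15}$N, or community compositional change. Passing tests therefore
demonstrate correctness of the computations under the stated statistical
model, not robustness to every artefact of real samples.

## Removal statistics

Percent reduction is computed per replicate,
$100\,(1 - c_r(t)/c_r(0))$, then averaged with SD across the biological
replicates — per-replicate normalisation is the only convention under
which the replicate SD is well defined. Zero-baseline replicates are
excluded with a warning count. Daily removal rates assume linearity
(reduction/elapsed); reporting rounds to one decimal, half away from
zero, and rate increases are computed from *unrounded* rates and reported
to the nearest integer — with these conventions the printed worked
arithmetic of the 8-day experiments is reproduced exactly
(`reproduce_paper_numbers()`). The two 27-day rates are *not* exactly
recoverable from the printed reductions (1.56 and 3.04 % d$^{-1}$ versus
the printed 1.7 and 3.3, presumably computed from unrounded internal
means); the package reports its recomputed values with an explicit flag
rather than hard-coding the printed ones.

Welch's unequal-variance t-test wraps `stats::t.test`; the test suite
re-derives t, the Welch–Satterthwaite df and p from the textbook formula
as an independent check. One caution established by simulation: at
triplicate sizes (n = 3 vs 3) the Welch–Satterthwaite approximation is
*conservative* — its actual null rejection rate is ≈ 0.035 at nominal
0.05 — so small-sample Welch p-values near the threshold are
under-rejections, not inflations. The Wilcoxon signed-rank test is
implemented directly because the stock implementation cannot combine
exact p-values with tied ranks: zero differences are dropped, ties get
mid-ranks, and for n ≤ 25 the exact null distribution of $W^+$ is built
by generating-function convolution over the (doubled, hence integer)
ranks; above that a normal approximation with continuity and tie
corrections is used. Exactness is verified against full $2^n$ sign
enumeration.

## Numerical and design choices

* Time unit days everywhere; concentrations ml$^{-1}$.
* Integrator `lsoda`, rtol $10^{-8}$, atol $10^{-6}$; equilibrium
  tolerance $10^{-9}$ relative with a 5000 d cap — the reference rates
  converge within ~100 d, so the cap is generous.
* Negative-state clipping only below $10^{-12}$ relative; larger
  excursions error out.
* Thresholding uses the normal-scaled MAD so that $k$ reads as "robust
  sigmas"; connectivity is 4-connected; ties in ROI ordering break by
  top-left pixel.
* Pixel coordinates are 1-based (row, col) in R; masks serialise as
  run-length-encoded JSON.
* Stacks serialise as mass-major, cycle-minor multi-page 16-bit TIFF with
  a JSON sidecar (mass order, geometry, dwell, cycles, scale).
* Problem sizes in the test suite: segmentation scenes at 128² px and
  planted-recovery scenes at 256² px × 25 cycles (the instrument's native
  raster); the Welch null calibration uses 10 000 replicates; Wilcoxon
  enumeration covers n ≤ 10 exhaustively.

## Known limitations

* One virus pool, one grazer pool; no microzooplankton compartment, no
  temperature or light forcing — the model is a framework for intuition,
  and its parameters are illustrative, not fitted.
* Filtration is idealised as complete removal (a retention knob exists
  but defaults to 0).
* No instrumental mass-fractionation correction and no delta-notation
  interface; enrichments here are far above the per-mil regime.
* Manual (SEM-guided) protist ROIs are accepted as drawn; excluding
  attached virus hotspots from such ROIs is the analyst's responsibility.
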