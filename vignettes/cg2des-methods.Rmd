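---
title: "Coarse-grained 2DES of segmented exciton aggregates: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained 2DES of segmented exciton aggregates: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cg2des)
```

## The physical model

`cg2des` simulates two-dimensional electronic spectroscopy (2DES) of
Frenkel-exciton aggregates — assemblies of two-level chromophores such as
the bacteriochlorophylls of photosynthetic antenna complexes.  The
aggregate Hamiltonian has fluctuating site energies
$\epsilon_n(t)$ on the diagonal and static excitonic couplings $J_{nm}$
off the diagonal.  Site-energy fluctuations follow independent
Ornstein–Uhlenbeck (overdamped Brownian oscillator) processes with
autocorrelation $\sigma_m^2 e^{-\Lambda_m t}$, the standard minimal model
of a classical bath: two parameters per site, the fluctuation magnitude
$\sigma_m$ (cm$^{-1}$) and the memory time $\Lambda_m^{-1}$ (fs).
Coupling fluctuations are not modelled: they are typically an order of
magnitude smaller than the energy fluctuations for rigidly held
chromophores, and neglecting them keeps the intersegment interaction
time-independent, which the coarse-graining below requires.

A full third-order response calculation propagates one- and two-exciton
wavefunctions around all six double-sided diagrams (ground-state bleach
GB, stimulated emission SE, excited-state absorption EA, each rephasing
and nonrephasing).  That cost grows steeply with system size and with the
waiting time $t_2$.  The coarse-grained method instead divides the
aggregate into *segments* — groups of strongly coupled sites — chosen so
that inter-segment couplings are weak and energy transfer between
segments is incoherent.  Three approximations follow:

1. **Factorized response.**  During $t_1$ only the pumped segment
   evolves coherently (the *doorway* function $D_{i,\alpha\beta}(t_1)$);
   during $t_3$ only the detected segment does (the *window* functions
   $W^{GB/SE/EA}_{j,\gamma\delta}(t_3)$).
2. **Kinetic waiting time.**  Population motion during $t_2$ is a
   classical master equation $\dot p = K p$ over segments; the transfer
   map $T(t_2) = e^{K t_2}$ carries occupation from the pumped to the
   detected segment.  Rates are *inputs* (from multichromophoric Förster
   theory, experiment, or phenomenology); this package validates,
   corrects and analyses them but does not derive them.
3. **Instant intra-segment equilibration.**  Before and after each
   transfer step, the excitation is assumed equilibrated within its
   segment: $\rho^{eq}_{S_j}$ is the Boltzmann operator of the segment
   Hamiltonian, or exactly $\mathbb{1}/D_{S_j}$ in the high-temperature
   (HT) limit.  Consequently single-segment spectra are exactly
   independent of $t_2$, and intra-segment relaxation dynamics is not
   described — the main stated limitation of the approach.

The total response is

$$R^{\parallel/\perp}(t_1, t_2, t_3) = \sum_{d} \sum_{i,j}
  \sum_{\alpha\beta\gamma\delta} A^{\parallel/\perp}_{\alpha\beta\gamma\delta}
  \; W^{d}_{j,\gamma\delta}(t_3) \; T_{ji}(t_2) \; D_{i,\alpha\beta}(t_1),$$

with the rephasing pathway using the conjugated doorway and the EA window
carrying the overall minus sign.  $A_{\alpha\beta\gamma\delta}$ are the
isotropic four-point orientational weights (21 nonzero of 81 Cartesian
components per lab-frame scheme); `orientational_weights()` constructs
them from the two $\delta$-contraction formulas and the tests verify them
against an independent rotational-quadrature oracle rather than trusting
the constants.

## Numerical choices

**Units.**  Energies and couplings in cm$^{-1}$, propagation time in fs,
kinetics in ps$^{-1}$; $k_B = 0.695035$ cm$^{-1}$/K; phases accumulate as
$2\pi c\,\epsilon\,dt$ with $c = 2.9979\times10^{-5}$ cm/fs.

**OU update.**  The exact stationary discretization
$\epsilon(t+dt) = m + (\epsilon(t)-m)e^{-\Lambda dt} +
\sigma\sqrt{1-e^{-2\Lambda dt}}\,\xi$ keeps the trajectory statistics
independent of the time step.  All sites are driven from one
master-seeded stream (columns of a single Gaussian draw are mutually
independent), so a seed fully reproduces a run.

**Propagation.**  One- and two-exciton propagators use the symmetric
Trotter split $e^{-iDdt/2} e^{-iJdt} e^{-iDdt/2}$: the coupling
exponential is computed once per segment from the eigendecomposition of
its static $J$ block, and only the diagonal fluctuation phases change per
frame.  The split is second-order in $dt$; a dense per-frame matrix
exponential is retained as the oracle path, and unitarity is maintained
to better than $10^{-8}$ by construction.

**Two-exciton basis.**  For electronic two-level chromophores a doubly
excited *site* does not exist, so the default (`"strict"`) pair basis has
dimension $N(N-1)/2$.  A `"paper"`-convention basis of dimension
$N(N+1)/2$ including same-site pairs with a configurable anharmonic
penalty $\Delta$ (and the bosonic $\sqrt2$ dipole and coupling factors)
is provided for compatibility with vibrational-exciton conventions; the
counting of doubly excited states in the exciton literature quotes
$N(N+1)/2$ without resolving this, and the tests pin the strict mode.

**Equilibrium density normalization.**  The Boltzmann operator of the
fluctuating segment Hamiltonian can be normalized per frame or by the
trajectory-averaged partition trace.  The ensemble-trace placement
follows the trajectory-average reading of the segment-equilibrium
definition and is the default; the per-frame variant is available through
`normalization = "frame"`.  In either case the returned, averaged matrix
has unit trace, and the HT limit is exactly $\mathbb{1}/D$.

**Ensemble averaging.**  Doorway and window averages run over starting
points placed equidistantly along one long trajectory; window starting
points are offset by half a spacing (or an explicit `offset`) so the two
averages sample distinct stretches.  This is consistent with the
assumption that $t_2$ is long compared to the bath memory, which also
decorrelates the preparation and detection intervals in the exact
response.

**Detailed balance.**  The thermal correction applied to a raw rate
matrix preserves each pairwise sum $s = k_{ji} + k_{ij}$ while imposing
the Boltzmann ratio of the (optionally population-adjusted) segment
energies: $k_{j\leftarrow i} = s/(1+e^{\beta(E_j - E_i)})$.  This is the
unique pairwise form with both properties; in the HT limit it reduces to
$s/2$ in both directions.  The adjustment
$\Delta E_{S_j} = k_B T \ln(N P_{S_j}/D_{S_j})$ reconciles the corrected
stationary state with target equilibrium populations and vanishes
whenever $P \propto D$.

**Spectra.**  Site energies near 12&#8239;000 cm$^{-1}$ exceed the
Nyquist frequency of a 2 fs sampling grid, so responses are demodulated
at a carrier frequency (default: dipole-weighted mean site energy)
before the double FFT and the carrier is added back to both axes.
Apodization is a squared-cosine taper with the first point half-weighted
to suppress the baseline offset; grids are zero-padded fourfold.  The
rephasing pathway is transformed with the opposite $\omega_1$ sign so
both pathways share one positive frequency axis, and the absorptive
spectrum is the real part of their sum.  Published-style plots normalize
each spectrum to its own maximum; raw arrays are always retained.

**GB transfer kernel.**  Whether the transfer map should multiply the GB
diagram is physically debatable (the molecule is in its ground state
during $t_2$), but the literal total-response expression applies $T$ to
all three diagram types and the diagrammatic bookkeeping draws transfer
in all six diagrams, so `gb_kernel = "eq17"` is the default and
`"identity"` is available.  For a single segment, or at $t_2 = 0$, the
two choices coincide.

**Matrix exponential.**  Transfer maps use the eigendecomposition of $K$
with a scaling-and-squaring series fallback for ill-conditioned
eigenvector matrices; columns are renormalized to unit sum to remove
$10^{-16}$-scale drift.

## Fixtures: what the generators emulate

`make_dimer_fixture()` reproduces the standard two-site benchmark: mean
energies 11&#8239;500 and 12&#8239;000 cm$^{-1}$, $\sigma = 198$
cm$^{-1}$, $\Lambda^{-1} = 220$ fs, parallel unit dipoles, coupling 100
cm$^{-1}$ when the dimer is one coherent segment or 10 cm$^{-1}$ when
each site is its own segment and transfer is incoherent.

`make_two_ring_fixture()` is a *synthetic geometric surrogate* of the
LH2 antenna: an 18-site outer ring (B850-like, one segment, mean energy
11&#8239;955 cm$^{-1}$, $\sigma = 256$ cm$^{-1}$) and a 9-site inner ring
(B800-like, one segment per site, 12&#8239;465 cm$^{-1}$, $\sigma = 169$
cm$^{-1}$), $\Lambda^{-1} = 150$ fs, tangential dipoles, and point
dipole–dipole couplings rescaled per ring so the largest nearest-neighbour
couplings are 243 (outer) and 30 (inner) cm$^{-1}$.  It is *not* a
transition-charge (TrEsp) Hamiltonian: absolute LH2 spectra computed from
it are illustrative, not quantitative.  The distinct $\alpha/\beta$
site energies of the real B850 ring are deliberately collapsed to one
average frequency, following the simplification commonly made when the
ring is treated as a single equilibrated segment.

`build_lh2_rate_fixture()` encodes the published segment-to-segment
rates for the 10-segment LH2 scheme: B800→B850 at 0.775 (HT) / 1.48 (RT)
ps$^{-1}$, the back transfer at 0.0431 / 1.29×10$^{-3}$ ps$^{-1}$, and
1.83 ps$^{-1}$ between neighbouring B800 sites.  Diagonalizing these
matrices gives inter-ring relaxation eigenvalues of 1.163 and 1.492
ps$^{-1}$ — the package's rate-analysis acceptance checks.
`build_dimer_rate_fixture()` supplies phenomenological rates for the
weakly coupled dimer (0.05 ps$^{-1}$ in each direction in the HT limit,
thermally corrected at 300 K for the RT variant, giving a downhill rate
more than ten times the uphill rate across the 500 cm$^{-1}$ gap); its
magnitude is chosen so that cross-peak growth is essentially complete by
about 50 ps, matching the waiting-time range over which the
double-segment benchmark is typically displayed.

## Validation strategy and problem sizes

The brute-force path (`full_2des_small()`) evaluates all six diagrams by
explicit propagation through all three intervals on the unsegmented
system — no factorization, no equilibration assumption — and is
restricted to $N \le 4$.  Because the formalism it implements is an
HT-limit method, comparisons against the coarse-grained path are made in
the HT limit, and both paths share one trajectory and identical starting
points so that Monte-Carlo noise largely cancels in the comparison.

The package's own acceptance checks (in `tests/testthat/test-acceptance.R`
and recomputed by `scripts/acceptance.R`) run at desk scale: coherence
grids of 128 × 2 fs = 256 fs, 120–150 realizations, a 6 ps waiting time
for the full-response reference, and a 10-segment rate matrix.  At these
sizes the single-segment dimer comparison lands well below the 5%-of-peak
RMS bound (typically 0.6–0.8%), and the fitted cross-peak growth rate of
the two-segment dimer matches the rate-matrix eigenvalue to better than
one part in $10^6$ — the latter is nearly exact by construction, because
every $t_2$ dependence of a coarse-grained spectrum passes through
$e^{Kt_2}$.  Production-style settings (10$^7$-step trajectories, 10$^5$
realizations) are reachable through the same interfaces by raising
`realizations` and the trajectory length.

What passing these tests does **not** show: agreement with experiment
for any particular complex (that requires a real Hamiltonian and rate
inputs), the quality of the instant-equilibration assumption at short
waiting times (visible as line-shape differences at $t_2 \approx 0$), or
finite-temperature accuracy of the full-response reference (HT only).

## Known limitations

* No Stokes shift in emission: SE and EA windows use the same bath
  statistics as absorption, so emission peaks are not red-shifted.
* No intra-segment relaxation during $t_2$: single-segment line shapes
  are waiting-time independent by construction.
* Rates are consumed, not derived; the detailed-balance correction can
  repair their thermodynamics but not their magnitudes.
* The full-response oracle is limited to four sites and the HT limit.
* The two-ring fixture is a labelled geometric surrogate, not a real
  LH2 Hamiltonian.

## A worked micro-example

```{r example, eval = TRUE}
sys <- make_dimer_fixture("double_segment")
K <- build_dimer_rate_fixture("RT")
relaxation_eigenvalues(K)$rates
res <- cg_2des(sys, K, t2_values = c(0, 5, 20), nt1 = 48, nt3 = 48,
               realizations = 20, seed = 1)
fit <- cross_peak_kinetics(
  cg_2des(sys, K, c(0, 3, 7, 14, 25, 45), tables = res$tables)$spectra,
  c(0, 3, 7, 14, 25, 45), c(11850, 12150), c(11350, 11650))
round(fit$k, 4)    # recovers k_f + k_b = 0.1 ps^-1
```
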