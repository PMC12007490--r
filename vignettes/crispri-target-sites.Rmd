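---
title: "Modelling CRISPRi repression with heterogeneous versus identical gRNA target sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CRISPRi repression with heterogeneous versus identical gRNA target sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprisim)
```

## The question and the modelling frame

When a promoter is repressed by dCas9 through several gRNA target sites, the
sites can be *heterogeneous* (each with its own gRNA species) or *identical*
(one gRNA shared by all sites). The two strategies differ mechanistically in
two ways. First, heterogeneous designs express several gRNA species that
compete for a limited pool of dCas9, while an identical design channels the
whole complex pool at one target sequence. Second, dCas9 does not stay
rigidly bound at one site: after disengaging it can scan short distances
along the DNA and re-engage a nearby *identical* target, so one
solution-phase binding event can seed occupancy of several sites. The
package encodes both effects in a deterministic kinetic model and asks what
they imply for achievable fold repression.

The setting is transient expression after co-delivery of two vectors: V1
carrying the gRNA cassette(s) (initial dosage `D1`, default 10 copies) and
V2 carrying dCas9 and the GFP reporter (dosage `D2`, default 3 copies).
Nothing is integrated in the genome; every stable species — both vectors,
dCas9, the dCas9–gRNA complex and GFP — is diluted at rate λ by cell
division, so expression rises, peaks near `t = 1/λ`, and declines. Free gRNA
turns over faster, at δ_g ≥ λ.

## Kinetic scheme

State variables are molecule counts per cell; time is in hours. All modes
share

$$\frac{dV_1}{dt} = -\lambda V_1,\qquad \frac{dV_2}{dt} = -\lambda V_2,$$

and, per gRNA species \(g_i\) with free dCas9 \(C\) and complex \(Cg_i\),

$$\frac{dg_i}{dt} = \alpha_r V_1 - \delta_g g_i - k_{C_g} C g_i,\qquad
\frac{dC}{dt} = \alpha_C V_2 - \lambda C - \sum_i k_{C_g} C g_i,\qquad
\frac{dCg_i}{dt} = k_{C_g} C g_i - \lambda Cg_i.$$

In the heterogeneous mode each cassette sits on V1 and is transcribed at the
full per-copy rate \(\alpha_r V_1\); the dCas9 sink term is summed over all
species, which is exactly where competition for dCas9 enters. Promoter
occupancy is modelled as a *fraction*, not as bound molecules: with at most
a few promoter copies per cell against complex pools of hundreds to
thousands of molecules, DNA binding consumes a negligible amount of free
complex, so the occupancy ODEs are driven by the free-complex concentration
without a sequestration term. Heterogeneous sites are independent:

$$\frac{d\theta_i}{dt} = k_{on} Cg_i (1-\theta_i) - k_{off}\theta_i .$$

Identical sites are dependent through scanning. The promoter's occupancy
state is the number \(k\) of occupied sites, a birth–death chain on
fractions \(P_0 \dots P_n\) with

$$k \to k+1:\quad \bigl(k_{on} Cg + \mathbb{1}[k\ge 1]\,k_{scan}\bigr)(n-k),
\qquad k \to k-1:\quad k_{off}\,k .$$

Solution-phase binding is available to every empty site at all times;
scanning needs at least one anchored complex (\(k\ge1\)) and then fills
empty sites at \(k_{scan}\) per site, with \(k_{scan}\) large compared with
typical \(k_{on}Cg\) — one low-likelihood solution binding followed by
higher-likelihood lateral spreading. The chain is implemented in flux form
(each transition appears once as a gain and once as a loss), so
\(\sum_k P_k\) is conserved analytically and numerical drift stays at the
integrator's noise floor.

Each occupied site attenuates transcription by an independent factor
\(\rho\in(0,1]\):

$$R = \prod_i\bigl(1-(1-\rho)\theta_i\bigr)
\quad\text{or}\quad R=\sum_k P_k\rho^k,
\qquad \frac{dG}{dt} = \alpha_G V_2 R - \lambda G .$$

With one site the two modes are the same kinetic system (there is no second
site to scan to); the test suite verifies this identity numerically, along
with a site-level master-equation oracle for the two-site chain and the
collapse of every regulated system to base expression when `D1 = 0`. The
base system keeps dCas9 as an inert species so that regulated and
unregulated circuits share structure; its reporter has the closed form
\(G(t)=\alpha_G D_2\, t e^{-\lambda t}\), used as an analytic oracle and as
a sanity check on integrator accuracy.

## Parameters, defaults, and how they were chosen

| field | meaning | unit | default |
|---|---|---|---|
| `lambda_dilution` | dilution of stable species | /h | 0.02 |
| `delta_g` | free-gRNA degradation | /h | 0.7 |
| `alpha_r` | gRNA transcription per V1 copy | /h | 5 |
| `alpha_C` | dCas9 production per V2 copy | /h | 5 |
| `alpha_G` | GFP production per V2 copy | MEFL/h | 1000 |
| `k_Cg` | complex formation | /molecule/h | 0.01 |
| `k_on` | site association | /molecule/h | 0.03 |
| `k_off` | site dissociation | /h | 0.05 |
| `k_scan` | lateral transfer to an empty identical site | /h | 10 |
| `rho` | per-occupied-site attenuation | — | 0.1 |
| `D1`, `D2` | vector dosages | copies | 10, 3 |

Reporter molecules are identified 1:1 with calibrated MEFL units
(bead-calibrated fluorescence approximates absolute molecule-equivalent
counts), which is what makes the fitted `alpha_G` interpretable.

The defaults were fixed once, as a coherent regime rather than
field-by-field citations: λ = 0.02/h puts the unregulated expression peak at
50 h, matching the observation that transient expression has stopped rising
by ~72 h; δ_g gives free gRNA a half-life of about an hour; production and
binding rates put the complex pool in the hundreds-to-thousands range, where
dCas9 — not gRNA — is the limiting resource, which is the regime in which
gRNA competition matters. The binding/attenuation block (`k_on`, `k_off`,
`rho`, `k_scan`) was calibrated jointly so that (i) the single-gRNA circuit
lands in the fold-repression range published for single-gRNA CRISPRi in
plants (a few-fold to ~10-fold; the shipped defaults give ≈7), (ii)
repression with many sites reaches the tens-fold scale, and (iii) the
largest per-site gain comes from adding the second site. Property (iii) is
not automatic: it requires repression strong enough that strongly repressed
reporters become *onset-limited* — GFP accumulated before occupancy builds
up dominates, decaying thereafter at the dilution rate — which caps the
benefit of further sites and produces the concave increment profile.
`k_scan = 10/h` makes scanning fast against typical solution binding
(`k_on·Cg` is of order 1/h) without being instantaneous. These choices were
made before the analyses were run and are not revisited; all of them are
plain fields of `crispri_params()` for users with system-specific
information.

## The fold-repression metric

Fold repression is defined pointwise as `G_base(t)/G_repressed(t)` and then
averaged over the window grid points — not computed as a ratio of window
means. The window is 72–96 h, endpoints inclusive, on the hourly output grid
(25 points): after the unregulated peak, before dilution erodes repression.
If the repressed reporter underflows to zero the ratio is reported capped at
10^6 with a `capped` attribute rather than returning infinity. Halving the
output step changes the window mean by well under 0.1% (tested), so the
hourly grid is not a resolution compromise.

## Numerical choices

Integration uses `deSolve::ode` with `lsoda` (automatic stiff/non-stiff
switching — the occupancy chain is fast relative to dilution), relative
tolerance 1e-8 and absolute tolerance 1e-10. Negative undershoots within
-1e-9 are clipped to zero; anything larger raises a warning naming the
species and time, and integrator failures raise errors carrying the
architecture and last state. Occupancy conservation is checked to ≤1e-6
drift over the full 200-h horizon; in practice it holds to ~1e-10 because of
the flux-form chain. Structural-identity tests that assert absolute
agreement at 1e-8 integrate at tightened tolerances (rtol 1e-12, atol 1e-14)
and, where species reach 10^4–10^5 molecules, on a unit-scale parameter set
where an absolute criterion is meaningful.

## Fitting

`fit_base_expression()` fits the unregulated model to a MEFL time course by
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) with the
*parameters* log-transformed — the optimizer works on `u = log(p)`, which
guarantees positive estimates and makes steps relative — while residuals
stay on the linear MEFL scale, since it is the parameter space, not the
data, that is logarithmic here. The default free set is
`{alpha_G, lambda_dilution}` with `D2` fixed at its dosage: `alpha_G` and
`D2` enter the reporter only through their product and cannot be freed
together (the fit is then structurally unidentifiable; the residual function
guards against the optimizer wandering into integrator-breaking regions by
returning large finite residuals). A single deterministic start is used.
Scale equivariance (scaling the data scales `alpha_G` and leaves λ) and
refit idempotence are part of the test suite; recovery on noiseless
synthetic data is exact to ~1e-12 and λ recovery through full replicate
noise stays within 9% over 20 seeds (tolerance asserted: 20%).

## The synthetic-data generator

`generate_timecourse()` emulates the structure of a calibrated
agroinfiltration fluorometry experiment: 18 time points spanning 0–200 h
(the actual sampling times of such experiments are irregular; an even grid
is used since they are not published), and per time point 27 readings — 3
plants × 3 leaves × 3 readings — plus wild-type control rows. Noise is a
three-level multiplicative lognormal hierarchy: a plant effect shared by
that plant's leaves and readings, a leaf effect shared by its readings, and
a reading effect, each `exp(N(0, sdlog^2))` with `sdlog` matched to the
level's CV. Defaults (plant 30%, leaf 20%, read 10%) are frankly arbitrary —
chosen to give visually plausible spread, since the source experiment's
variance components are not published — and the variance-decomposition test
checks only that each level's CV moves its own component. A small constant
background (default 100 MEFL) models residual autofluorescence after
calibration. Effects are drawn independently per time point: successive
fluorometer readings of a living leaf are surely autocorrelated in reality,
and this generator does not model that, so passing recovery tests says
nothing about longitudinal correlation structure. Nor does it simulate raw
fluorometer counts, bead calibration, or flow-cytometry events — it starts
where calibration ends, at MEFL.

## Robustness analyses

Three procedures operationalize "the conclusion does not depend on the
specific values":

* `scan_parameter()` — one-at-a-time multiplicative perturbation of a single
  rate constant over {0.1, 0.3, 1, 3, 10}× (half-decade spacing over two
  decades; no interaction scan), re-deriving the whole repression table at
  each point and flagging whether identical sites dominate heterogeneous
  ones at every matched count. The nine rate constants are scanned; `rho` is
  excluded from the default grid because a 10× factor would leave its unit
  interval, and dosages have their own scan. The `delta_g ≥ lambda`
  cross-constraint is relaxed during scans.
* `scan_dosage()` — fold repression over a `D1 × D2` grid; `D1 = 0` must
  return fold 1 exactly (the "on" state), and fold repression is
  non-decreasing in `D1`.
* `cell_variation()` — extrinsic cell-to-cell variability as i.i.d.
  multiplicative lognormal noise on the nine rate constants, one σ for all
  (default 0.5, ≈53% CV), dosages fixed: transfection-count noise and
  intrinsic molecular noise (which would need a stochastic simulation of the
  chain) are out of scope. Each simulated cell gets its own base-expression
  reference. Draws are made for all cells before any simulation, so results
  are invariant to the architecture list — verified by the seed-isolation
  test.

Failed cells are skipped and counted rather than aborting the population;
per-cell errors in scans are recorded in the output table, not thrown.

## Problem sizes and limitations

The shipped analyses use the 200-h horizon at 1-h output resolution, the
full 9-parameter × 5-factor perturbation grid (225 repression tables), and
200 cells at σ = 0.5 — sizes chosen so the complete suite runs in a couple
of minutes on a laptop core while keeping Monte-Carlo medians stable.

Beyond the generator caveats above: the model is deterministic and
mean-field (no intrinsic noise, no delay between transcription and
translation); the scanning term is a single lumped rate with no geometry —
real lateral diffusion is limited to tens of basepairs and depends on PAM
placement, so site layout, which this model deliberately ignores, will
modulate `k_scan` in any physical implementation; and the per-site
attenuation factor ρ treats all sites and occupancy combinations
symmetrically, ignoring position-dependent repression strength. The
parameter defaults are a calibrated plausible regime, not measured
constants; conclusions shown robust under the scans are robust within this
formalism, not beyond it.
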