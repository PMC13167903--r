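---
title: "Model and methods behind ithsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind ithsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithsim)
```

`ithsim` simulates the growth of a superficially spreading melanoma on a
two-dimensional lattice, together with the immune editing it provokes,
and quantifies the intratumor heterogeneity (ITH) and morphology that
emerge. This vignette is the package's own account of the model, its
assumptions, the defaults, and the numerical choices that a careful user
should know about.

## The agent model

### Melanocytes and hallmark-scaled actions

Every melanocyte carries a binary genome of 50 genes, 7 of which are
melanoma driver genes (`driver_map()`): BRAF, NRAS, KIT, TERT, CDKN2A,
MITF and PTEN, with BRAF/NRAS/KIT mutually exclusive as founding
mutations. Each driver is tagged with the hallmarks it serves:
proliferation (`p`), survival (`q`), genetic instability (`r`), and
antigenicity decrease/increase (`c`/`ct`). With hallmark driver counts
$d_p, d_q, d_r$ a cell acts per step with

$$p = p_0\,10^{f d_p},\qquad q = q_0\,10^{-f d_q},\qquad
  r = r_0\,10^{f d_r},$$

where $f$ is the driver gene strength. $p$ and $r$ are clipped at 1:
the exponential scaling exceeds 1 already for $f \ge 1.4$, $d \ge 2$, and
clipping is the monotonicity-preserving way to keep them probabilities.
Melanoma tumor cells (at least one driver mutation) expose antigenicity
$a = a_0\,10^{f(d_{\tilde c} - d_c)}$ with $a_0$ drawn once per founding
cell uniformly from $[1, 2]$ and inherited by daughters; normal cells
expose 0. Mutation happens at division: each wild gene of the daughter
flips with probability $r$, visited in index order, with
exclusivity-group genes skipped while another group member is mutated,
and no back-mutation. Hallmark assignments per gene are an editable YAML
config; the shipped table reflects each gene's known biology but stands
in for a curated table, which is why every experiment reads it from
config.

One step sweeps the melanocytes in freshly shuffled order (random order
avoids directional artifacts; the update rule itself is order-free
except through site occupancy). Each cell tries, in order: apoptosis
($q$), division ($p$, into a uniformly chosen *empty* Moore site —
surface growth, which produces the radial lesion geometry; a fully
enclosed cell is quiescent), and, in the motile extension, movement
($m_0$, BRAF-mutant cells only). A moving cell prefers a uniformly
chosen empty Moore site; if none exists it pushes the contiguous run of
cells in a uniformly chosen direction outward by one site, aborting at
the grid boundary.

Runs start from 9 unmutated melanocytes in a 3x3 block with the
BRAF-mutated founder attached to the block's edge — contiguous, with the
founder free to divide — and stop at `c_max` melanocytes (all
melanocytes count by default; `count_mtc_only` switches this) or `t_max`
steps.

### Immune subsystem

The immune stimulatory factor (ISF) at a grid point sums the
antigenicities of melanoma cells within Chebyshev radius 5, each
weighted by a linear taper $(R + 1 - d)/(R + 1)$ in the Chebyshev
distance $d$. The taper — rather than a flat-top kernel — is deliberate:
with a flat kernel the field of an isolated antigenic cell is constant
within the radius, so strictly-uphill chemotaxis would strand CTLs on a
plateau and they could never close the last few sites; the taper makes
the field strictly increase toward every source. Recruitment, by
contrast, uses the plain (unweighted) total antigenicity $F_b$ of
*border* tumor cells (those with a non-tumor Moore neighbor): CTLs
arrive at empty sites within Chebyshev distance 2 of the border as a
Poisson process with Hill rate

$$s_T = s_0 + f_T\,\frac{F_b^{n_T}}{\gamma_T + F_b^{n_T}}.$$

Each CTL per round: dies with constant probability $q_i$; else kills the
highest-antigenicity adjacent melanoma cell with probability
$k_0\,F/(F_{sat} + F)$; else divides with probability
$p_{i0}\,F/(F_{sat} + F)$; else moves to the strictly-uphill Moore
neighbor of maximal ISF (ties uniform, staying put at a local maximum).
The saturating (Michaelis-Menten) forms are a design choice: the model
statement requires ISF-dependent proliferation and killing but no
functional form, and saturation keeps probabilities bounded while
matching the Hill-style recruitment.

### Parameter defaults and units

All probabilities are per step (the step duration is abstract;
calibration to calendar time is out of scope). Defaults:

| parameter | default | meaning |
|---|---|---|
| `p0` | 0.01 | base proliferation; the BRAF founder divides at $0.01 \cdot 10^{1.6} \approx 0.40$ |
| `q0` | 0.005 | base apoptosis; normal melanocytes are near-homeostatic so the unmutated background stays a small minority |
| `r0` | 1e-5 | base per-gene mutation probability per division; the regime dial for ITH |
| `f` | 1.6 | driver strength in the slow, SSM-like growth range |
| `m0` | 0 | BRAF-mutant motility; 0.02-0.03 produces clinically irregular borders |
| `s0`, `f_T`, `n_T` | 0.5, 5, 2 | Hill recruitment |
| `gamma_T` | 30000 | half-saturation at the squared border ISF of a ~1,000-cell *non-evading* tumor, so recruitment discriminates hot from cold tumors instead of saturating for both |
| `p_i0`, `k0`, `q_i` | 0.2, 0.5, 0.05 | CTL proliferation / kill / apoptosis bases |
| `isf_radius`, `isf_sat` | 5, 10 | ISF kernel radius and local saturation |
| grid | 600 (300 reduced) | holds `c_max` = 50,000 (10,000) at ~14% occupancy |

The immune values are conventions, not literature measurements, and are
exposed in `immune_params()` precisely so they can be replaced.

## Heterogeneity metrics

The mutation profile matrix $M$ (cells x genes) yields the similarity
matrix $S_{ij} = 1 - \tfrac{1}{n}\sum_k |g^i_k - g^j_k|$. The entropy
$\epsilon = -\sum_i p_i \log p_i$ uses **all** singular values of $S$
normalized to $p_i$; we use the natural logarithm (the source convention
is ambiguous between bases; base changes rescale $\epsilon$ by a
constant) and treat singular values below a $10^{-12}$ relative
threshold as exact zeros, which pins the monoclonal anchor
$\epsilon = 0$ exactly. Because $S = [\,\mathbf 1, r, M\,]\,
[\,\mathbf 1 - r/n,\, -\mathbf 1/n,\, 2M/n\,]^{\top}$ has rank at most
$n + 2$, the full spectrum comes from the eigenvalues of an
$(n+2)\times(n+2)$ product — exact entropy for tens of thousands of
cells without ever forming $S$. The dense SVD path is kept as an
independent cross-check in the tests. By default populations above 5,000
cells are summarized on a 10% simple random sample (the convention for
large tumors); `method = "exact"` always works and is cheap through the
low-rank route.

Subclones are k-means clusters of the 7-bit driver profiles (Euclidean,
which on binary data is monotone in Hamming distance), with $k$ the
number of distinct combinations capped at 8. The clustered fractal
dimension averages the box-counting dimension of each subclone's
occupancy mask. Box counting uses dyadic box sizes
$2, 4, \dots \le \text{extent}/2$ anchored at the bounding-box origin
and fits $\log N(\ell)$ against $\log(1/\ell)$. For *sparse* point sets
the small-box counts plateau at the number of points, dragging the slope
toward zero as a pure artifact (three scattered cells would measure
dimension 0); `clustered_fd()` therefore drops box sizes whose count
exceeds half the point count, while mask-based uses (oracle shapes,
border dimension) keep the plain ladder under which the validation
shapes — filled square (2), line (1), depth-5 Sierpinski carpet
($\log 8/\log 3$) — are recovered within 0.05.

Two known limitations. First, a finite disk measures ~1.8 rather than
2.0 because the coarsest boxes saturate; the estimator is comparative,
not absolute. Second, under this clustering convention the dominant
clone's mask is a filled disk in *every* regime, so the clustered FD of
low-mutation tumors is high (~1.85) and the metric does not decrease
monotonically from fractal to clonal regimes; we use its absolute level
in the high-mutation regime (>= 1.3) rather than cross-regime ordering.

## Morphology

`convexity()` reports $C = P_H/P$ on the largest 8-connected component
(8-connectivity because Moore-neighborhood growth produces diagonally
connected tissue): $P$ is the length of the marching-squares contour
(`contourLines` at level 0.5) of the hole-filled component, lightly
smoothed with a circular moving average over 5 vertices because the raw
staircase contour overestimates smooth perimeters by ~6% and would bias
$C$ down (a disk then measures $C \approx 0.99$; `smooth = 0` restores
the raw dialect). $P_H$ is the convex-hull perimeter of the occupied
site centers, and $C$ is clipped at 1. Interior holes are not part of
the border: hole boundaries would dominate both $P$ and the border
dimension in grown tumors whose interior retains scattered vacancies.
`border_fd()` box-counts the one-pixel outer boundary; detached
satellites (a motility phenomenon) are excluded from the main-component
morphology but counted separately.

## Spatial cross-correlation

`cross_pcf()` estimates, for each annulus $(r_1, r_2]$, the ratio of
observed reference-target pairs to the count expected from a spatially
random target pattern of the same intensity: total pairs divided by
$\lambda_{target}$ times the total annulus area, with each annulus
intersected with the observation window (the only edge correction).
Circle-window intersection areas are computed by vectorized Simpson
quadrature of the window-clipped chord length (relative error
$\sim 10^{-3}$ at 129 nodes, well below the Monte-Carlo noise of any
pattern analyzed); annuli wholly outside the window are `NA`, not 0.
On completely random patterns the estimator calibrates to 1 within
$\pm 0.05$ at 2,000 points. `aggressiveness_rank_pcf()` ranks cell
groups by driver count, uses the most aggressive as reference and labels
targets 2..k with normal cells last.

## Sampling strategies

`draw_sample()` implements simple random (SRS), time-systematic (TS,
every $\lceil 1/\text{fraction}\rceil$-th cell in birth order from a
random offset), space-systematic (SS, nearest cells to a random-origin
regular grid of nodes over the occupied bounding box), and CLARANS
k-medoids stratified sampling (CC, on scaled position plus driver
profile, $k = 8$, `numlocal = 2`, `maxneighbor = 50` — small constants
chosen for speed at 25k cells). All methods return exactly
`round(fraction * m)` distinct cells, topping up or thinning uniformly
after the systematic pass. `sampling_error()` scores estimates against
the exact full-population values (percentage error; absolute error for
entropy when the truth is 0). On spatially segregated multi-clone
populations (`synthetic_clone_population()`, which randomizes birth
order so temporal order carries no clonal signal) SS beats TS on
entropy, reproducing the known ordering.

## Experiment drivers

`run_sweep()` crosses $r_0 \times f$ with per-run seeds derived from the
parameter values (sweep order cannot change results).
`hot_cold_experiment()` contrasts the immune-evading BRAF map ("cold")
with the variant lacking the evasion tag ("hot") under paired seeds,
measuring CTL density inside the tumor's convex hull.
`classify_ith_mode()` maps (entropy, clustered FD) to
clonal/subclonal/fractal with thresholds that are package conventions
(0.1, 0.5, 1.3), calibrated on the default sweep. `morris_moat()` is a
standard Morris elementary-effects screening
($\Delta = \ell/(2(\ell-1))$ on an $\ell$-level grid): $\mu^*$ the mean
absolute effect, $\sigma$ the effect standard deviation, bootstrap CIs
over trajectories, with non-finite model outputs discarding the
trajectory. It is validated on enumerable designs (an ignored parameter
gives exactly $\mu^* = \sigma = 0$; an additive function $\sigma = 0$; a
pure interaction $\sigma > 0$).

## What the tests do and do not show

The simulation checks run at a reduced desk scale — `c_max` = 10,000 on
a 300x300 grid (5-8 replicates; the full-scale 50,000-cell setting is
one argument away) — chosen so the entire suite and the acceptance
script complete in minutes on one CPU. The synthetic clone generator
emulates spatial clonal segregation with uninformative birth order; it
does not emulate continuous clonal gradients, stromal structure,
vasculature, or 3D growth, so passing tests certify the estimators and
the model's internal logic, not fidelity to any particular patient
tumor. Known limitations worth restating: the step-to-time mapping is
abstract; immune parameters are conventions; the clustered-FD
cross-regime ordering depends on a clustering convention that is not
uniquely determined by the published description; and the 2D lattice is
inappropriate for nodular (vertically growing) melanoma.
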