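# ithsim

Agent-based simulation and analysis of intratumor heterogeneity (ITH) in
superficially spreading melanoma.

Multiregion sequencing shows that single melanomas harbor genetically
distinct subclones whose spatial arrangement, immune context and
morphology shape prognosis and therapy response. `ithsim` grows virtual
tumors on a 2D lattice under coupled genetic, spatial and immune selection
pressures, and ships the analysis toolkit needed to quantify what emerges:
heterogeneity entropy, mutational burden, fractal and convexity
morphometrics, spatial cross-correlations between cell lineages, and
population-sampling strategies for large tumors. It is aimed at
computational oncologists and mathematical biologists who want a
reproducible platform for in-silico cohorts and sensitivity experiments.

## The model

Two agent types share a lattice:

* **Melanocytes** carry a 50-gene binary genome with 7 melanoma driver
  genes (BRAF, NRAS, KIT, TERT, CDKN2A, MITF, PTEN; BRAF/NRAS/KIT are
  mutually exclusive). Each driver is tagged with cancer hallmarks, and a
  cell with hallmark driver counts d_p, d_q, d_r acts with probabilities

      p = p0 * 10^(f * d_p)      (proliferation)
      q = q0 * 10^(-f * d_q)     (apoptosis)
      r = r0 * 10^(f * d_r)      (per-gene mutation at division)

  where `f` is the driver gene strength. A cell is a melanoma tumor cell
  (MTC) once it carries any driver mutation, and exposes antigenicity
  `a = a0 * 10^(f * (d_ct - d_c))` with base antigenicity `a0 ~ U[1, 2]`.
  Daughters are placed in empty Moore-neighborhood sites (surface
  growth); BRAF-mutant cells may additionally move with probability `m0`,
  pushing occupied rows of cells outward.

* **Cytotoxic T lymphocytes (CTLs)** are recruited to the tumor periphery
  by a Poisson process with Hill-function rate
  `s_T = s0 + f_T * F_b^n_T / (gamma_T + F_b^n_T)`, where `F_b` is the
  total immune stimulatory factor (ISF) of border tumor cells. CTLs
  proliferate and kill melanoma cells in an ISF-dependent saturating
  manner, die at a constant rate, and chemotax up the ISF gradient.

Runs stop at a population ceiling `c_max` or a step ceiling `t_max`.
Analyses include the similarity-matrix SVD entropy
`eps = -sum(p_i log p_i)` with `p_i` the normalized singular values of
`S_ij = 1 - Hamming(g_i, g_j)/50`, the mean mutation count `beta`,
k-means subclone clustering with per-subclone box-counting fractal
dimension, convexity `C = P_H / P`, border fractal dimension `FD_b`, and
the cross-pair correlation function (cPCF; 1 under spatial randomness).

## Worked example

```r
library(ithsim)

cfg <- sim_config(hallmark = hallmark_params(r0 = 1e-4, f = 1.6),
                  c_max = 10000, grid = 300)
sim <- simulate_tumor(cfg, seed = 1)
sim
#> <tumor_sim> 110 steps, terminated by c_max
#>   melanocytes: 10130 (MTC 10124, NC 6), CTLs: 10
#>   snapshots: 2, seed 1

fin <- final_cells(sim)
ith_report(fin, cfg$grid, step = sim$steps)
#> # A tibble: 1 x 6
#>    step     m epsilon  beta clustered_fd     k
#>   <int> <int>   <dbl> <dbl>        <dbl> <int>
#> 1   110 10130  0.0611  1.18         1.17     4

morphology_report(fin, cfg$grid, step = sim$steps)
#> # A tibble: 1 x 8
#>    step n_mtc     C     P   P_H  FD_b n_components n_satellite_cells
#>   <int> <int> <dbl> <dbl> <dbl> <dbl>        <int>             <int>
#> 1   110 10124 0.953  383.  365.  1.06            1                 0
```

The tumor reached 10,130 melanocytes in 110 steps; the immune system kept
10 CTLs at its rim. Entropy 0.061 and burden 1.18 mutations/cell say this
replicate is dominated by the founder clone with a handful of young
subclones (4 driver combinations); convexity 0.95 and border dimension
1.06 describe a round, smooth lesion, as expected without motility. A
high-mutation-rate run colored by genome is one line:
`autoplot(sim)`. `run_sweep()`, `hot_cold_experiment()`,
`sampling_error()` and `morris_moat()` drive the larger experiments; a
thin command-line front end for shell pipelines is installed at
`system.file("cli", "ithsim", package = "ithsim")`.

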