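#' Hallmark base parameters
#'
#' Base per-step probabilities of the melanocyte hallmarks and the driver
#' gene strength. A cell with no driver mutations uses the base values
#' directly; every mutated driver scales its hallmark by one factor of
#' `10^f` (see [action_probabilities()]).
#'
#' Defaults: `p0 = 0.01` (base proliferation per step), `q0 = 0.005` (base
#' apoptosis per step: normal melanocytes are near-homeostatic, keeping the
#' unmutated background a small minority of a grown tumor), `r0 = 1e-5` (base
#' per-gene mutation probability per division), `f = 1.6` (driver strength
#' in the range reproducing superficially-spreading-melanoma growth),
#' `a0_range = c(1, 2)` (base antigenicity interval, sampled uniformly per
#' founding cell and inherited by daughters).
#'
#' @param p0,q0,r0 Base probabilities in `[0, 1]`.
#' @param f Driver gene strength (dimensionless, `>= 0`).
#' @param a0_range Length-2 interval inside `[1, 2]` for base antigenicity.
#' @return A list of class `hallmark_params`.
#' @export
hallmark_params <- function(p0 = 0.01, q0 = 0.005, r0 = 1e-5, f = 1.6,
                            a0_range = c(1, 2)) {
  stopifnot(p0 >= 0, p0 <= 1, q0 >= 0, q0 <= 1, r0 >= 0, r0 <= 1, f >= 0,
            length(a0_range) == 2, a0_range[1] <= a0_range[2],
            a0_range[1] >= 1, a0_range[2] <= 2)
  structure(list(p0 = p0, q0 = q0, r0 = r0, f = f, a0_range = a0_range),
            class = "hallmark_params")
}

#' Immune subsystem parameters
#'
#' Cytotoxic T lymphocytes (CTLs) are recruited to the tumor periphery by a
#' Poisson process whose rate follows a Hill function of the total immune
#' stimulatory factor (ISF) of border tumor cells,
#' `s_T = s0 + f_T * F_b^n_T / (gamma_T + F_b^n_T)`. CTL proliferation and
#' killing are ISF-dependent with saturating (Michaelis-Menten) local
#' responses `p_i = p_i0 * F/(isf_sat + F)` and `k = k0 * F/(isf_sat + F)`;
#' CTL apoptosis is constant. The ISF at a grid point is the unweighted sum
#' of antigenicities of melanoma cells within Chebyshev radius
#' `isf_radius`.
#'
#' The numeric defaults are package conventions, not literature values;
#' they are exposed here precisely so they can be changed. `gamma_T = 30000`
#' places half-saturation at the squared border ISF of a ~1,000-cell
#' non-evading (hot) baseline tumor, so Hill recruitment discriminates
#' antigenic from immune-evading tumors instead of saturating for both.
#'
#' @param s0 Base recruitment rate (expected CTLs per step).
#' @param f_T Maximal ISF-driven recruitment increment.
#' @param n_T Hill exponent (`>= 1`).
#' @param gamma_T Half-saturation constant in `F_b^n_T` units (`> 0`).
#' @param p_i0 Base CTL proliferation probability.
#' @param k0 Base kill probability.
#' @param q_i Constant CTL apoptosis probability.
#' @param isf_radius Chebyshev radius of ISF contributions (`>= 1`).
#' @param isf_sat Saturation constant of the local ISF responses.
#' @return A list of class `immune_params`.
#' @export
immune_params <- function(s0 = 0.5, f_T = 5, n_T = 2, gamma_T = 30000,
                          p_i0 = 0.2, k0 = 0.5, q_i = 0.05,
                          isf_radius = 5, isf_sat = 10) {
  stopifnot(s0 >= 0, f_T >= 0, n_T >= 1, gamma_T > 0,
            p_i0 >= 0, p_i0 <= 1, k0 >= 0, k0 <= 1, q_i >= 0, q_i <= 1,
            isf_radius >= 1, isf_sat > 0)
  structure(list(s0 = s0, f_T = f_T, n_T = n_T, gamma_T = gamma_T,
                 p_i0 = p_i0, k0 = k0, q_i = q_i,
                 isf_radius = as.integer(isf_radius), isf_sat = isf_sat),
            class = "immune_params")
}

#' Simulation configuration
#'
#' Bundles everything one run needs: hallmark parameters, immune
#' parameters, the driver map, motility, grid size and stopping conditions.
#' The default grid of 600 x 600 comfortably holds the full-scale
#' `c_max = 50,000` tumor (~14% occupancy); experiments at the reduced desk
#' scale (`c_max = 10,000`) use a 300 x 300 grid.
#'
#' @param hallmark A [hallmark_params()] object.
#' @param immune An [immune_params()] object, or `NULL` to disable the
#'   immune subsystem entirely.
#' @param map A [driver_map()].
#' @param m0 Per-step motility probability of cells mutated at the motility
#'   gene (BRAF); `0` recovers the non-motile base model.
#' @param c_max Stop once the melanocyte population reaches this size.
#' @param t_max Stop after this many steps.
#' @param grid Grid dimensions; a single integer means a square grid.
#' @param count_mtc_only If `TRUE` only melanoma tumor cells count toward
#'   `c_max`; the default counts all melanocytes.
#' @param snapshot_every Record a cell-table snapshot every this many steps
#'   (`0` = initial and final state only).
#' @return A list of class `sim_config`.
#' @examples
#' sim_config(c_max = 1000, grid = 150)
#' @export
sim_config <- function(hallmark = hallmark_params(), immune = immune_params(),
                       map = driver_map(), m0 = 0, c_max = 50000,
                       t_max = 5000, grid = 600, count_mtc_only = FALSE,
                       snapshot_every = 0) {
  stopifnot(inherits(hallmark, "hallmark_params"),
            is.null(immune) || inherits(immune, "immune_params"),
            m0 >= 0, m0 <= 1, c_max > 0, t_max >= 0)
  grid <- as.integer(rep(grid, length.out = 2))
  stopifnot(all(grid >= 5))
  structure(list(hallmark = hallmark, immune = immune, map = map, m0 = m0,
                 c_max = as.integer(c_max), t_max = as.integer(t_max),
                 grid = grid, count_mtc_only = count_mtc_only,
                 snapshot_every = as.integer(snapshot_every)),
            class = "sim_config")
}

# flat list handed to the C++ engine
engine_config <- function(config) {
  h <- config$hallmark
  im <- config$immune %||% immune_params(s0 = 0, f_T = 0)
  enc <- driver_map_encoding(config$map)
  list(nrow = config$grid[1], ncol = config$grid[2], n_genes = enc$n_genes,
       p0 = h$p0, q0 = h$q0, r0 = h$r0, f = h$f,
       a0_min = h$a0_range[1], a0_max = h$a0_range[2], m0 = config$m0,
       immune_enabled = !is.null(config$immune),
       s0 = im$s0, f_T = im$f_T, n_T = im$n_T, gamma_T = im$gamma_T,
       p_i0 = im$p_i0, k0 = im$k0, q_i = im$q_i, isf_sat = im$isf_sat,
       isf_radius = im$isf_radius,
       count_mtc_only = config$count_mtc_only,
       driver_idx = enc$driver_idx, driver_tags = enc$driver_tags,
       excl_idx = enc$excl_idx, motility_locus = enc$motility_locus)
}
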