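#' Parameter sweep over mutation rate and driver strength
#'
#' Runs the simulator over a grid of base mutation rates `r0` and driver
#' strengths `f`, with several replicates per grid point, and collects the
#' heterogeneity and morphology metrics of each final snapshot. Seeds are
#' derived deterministically from `seed_base`, the grid point and the
#' replicate, so the sweep is reproducible run-for-run; failures of single
#' runs are recorded and do not stop the sweep.
#'
#' @param r0_values,f_values Grid values.
#' @param replicates Runs per grid point.
#' @param config Template [sim_config()]; each run overrides its `r0` and
#'   `f`. Defaults to the reduced desk scale (`c_max = 10,000`, 300 x 300
#'   grid).
#' @param seed_base Base seed for the deterministic per-run seeds.
#' @param entropy_method Passed to [ith_entropy()] via [ith_report()].
#' @return A tibble with one row per run: `r0`, `f`, `replicate`, `seed`,
#'   `steps`, `termination`, `m`, `epsilon`, `beta`, `clustered_fd`, `k`,
#'   `C`, `FD_b`.
#' @export
run_sweep <- function(r0_values, f_values = 1.6, replicates = 5,
                      config = sim_config(c_max = 10000, grid = 300),
                      seed_base = 1L, entropy_method = "auto") {
  grid_pts <- tidyr::expand_grid(r0 = r0_values, f = f_values,
                                 replicate = seq_len(replicates))
  purrr::pmap_dfr(grid_pts, function(r0, f, replicate) {
    # seeds derive from the parameter values, so runs are independent of
    # sweep ordering
    pt <- round(-1000 * log10(r0)) * 131 + round(100 * f) * 17 + replicate
    seed <- (seed_base * 10007 + pt) %% .Machine$integer.max
    base <- tibble::tibble(r0 = r0, f = f, replicate = replicate,
                           seed = seed)
    res <- tryCatch({
      h <- config$hallmark; h$r0 <- r0; h$f <- f
      cfg <- sim_config(hallmark = do.call(hallmark_params, h),
                        immune = config$immune, map = config$map,
                        m0 = config$m0, c_max = config$c_max,
                        t_max = config$t_max, grid = config$grid,
                        count_mtc_only = config$count_mtc_only)
      sim <- simulate_tumor(cfg, seed = seed)
      fin <- final_cells(sim)
      ith <- ith_report(fin, cfg$grid, map = cfg$map, step = sim$steps,
                        method = entropy_method)
      morph <- morphology_report(fin, cfg$grid, step = sim$steps)
      dplyr::bind_cols(base,
        tibble::tibble(steps = sim$steps, termination = sim$termination,
                       m = ith$m, epsilon = ith$epsilon, beta = ith$beta,
                       clustered_fd = ith$clustered_fd, k = ith$k,
                       C = morph$C, FD_b = morph$FD_b))
    }, error = function(e)
      dplyr::bind_cols(base,
        tibble::tibble(steps = NA_integer_,
                       termination = paste("error:", conditionMessage(e)),
                       m = NA_integer_, epsilon = NA_real_, beta = NA_real_,
                       clustered_fd = NA_real_, k = NA_integer_,
                       C = NA_real_, FD_b = NA_real_)))
    res
  })
}

#' Classify the heterogeneity mode of a tumor
#'
#' Total classification of `(entropy, clustered FD)` pairs into the three
#' emergent heterogeneity regimes: `"clonal"` (a single dominant clone,
#' entropy below `eps_clonal`), `"fractal"` (high entropy with
#' space-filling subclone geometry, `clustered_fd >= fd_fractal` and
#' entropy at least `eps_fractal`), else `"subclonal"`. The thresholds are
#' package conventions calibrated on the default sweep, not measured
#' biological constants.
#'
#' @param epsilon,clustered_fd Metric values (vectorized).
#' @param eps_clonal,eps_fractal,fd_fractal Classification thresholds.
#' @return Character vector of modes.
#' @examples
#' classify_ith_mode(c(0, 0.4, 1.2), c(1.9, 1.1, 1.5))
#' @export
classify_ith_mode <- function(epsilon, clustered_fd,
                              eps_clonal = 0.1, eps_fractal = 0.5,
                              fd_fractal = 1.3) {
  stopifnot(is.finite(epsilon), is.finite(clustered_fd))
  ifelse(epsilon < eps_clonal, "clonal",
         ifelse(clustered_fd >= fd_fractal & epsilon >= eps_fractal,
                "fractal", "subclonal"))
}

#' Hot versus cold tumor immune contrast
#'
#' Paired runs of the immune-evading ("cold", BRAF keeps its
#' antigenicity-decreasing tag) and non-evading ("hot") driver-map
#' variants under equal seeds, measuring cytotoxic T-cell infiltration:
#' the number of CTLs inside the convex hull of the melanoma cells at the
#' end of each run, the hull area, and the mean melanoma-cell
#' antigenicity.
#'
#' @param r0_values Base mutation rates to test.
#' @param seeds Integer seeds; each seed is used for both variants.
#' @param config Template [sim_config()] (its map is replaced by the
#'   hot/cold variants; `t_max` sets the evaluation step).
#' @return A tibble with one row per (variant, r0, seed).
#' @export
hot_cold_experiment <- function(r0_values = 1e-6, seeds = 1:10,
                                config = sim_config(c_max = 10000,
                                                    grid = 300,
                                                    t_max = 150)) {
  grid_pts <- tidyr::expand_grid(variant = c("hot", "cold"),
                                 r0 = r0_values, seed = seeds)
  purrr::pmap_dfr(grid_pts, function(variant, r0, seed) {
    h <- config$hallmark; h$r0 <- r0
    cfg <- sim_config(hallmark = do.call(hallmark_params, h),
                      immune = config$immune, map = driver_map(variant),
                      m0 = config$m0, c_max = config$c_max,
                      t_max = config$t_max, grid = config$grid)
    sim <- simulate_tumor(cfg, seed = seed)
    fin <- annotate_cells(final_cells(sim), map = cfg$map,
                          f = cfg$hallmark$f)
    mtc <- fin[fin$type == "MTC", ]
    ctl <- fin[fin$type == "CTL", ]
    inhull <- ctls_in_hull(mtc, ctl)
    tibble::tibble(variant = variant, r0 = r0, seed = seed,
                   step = sim$steps, n_mtc = nrow(mtc), n_ctl = nrow(ctl),
                   n_ctl_in_hull = inhull$count,
                   hull_area = inhull$area,
                   ctl_density = ifelse(inhull$area > 0,
                                        inhull$count / inhull$area, 0),
                   mean_antigenicity = mean(mtc$antigenicity))
  })
}

# CTL count inside (and area of) the convex hull of melanoma cells
ctls_in_hull <- function(mtc, ctl) {
  if (nrow(mtc) < 3) return(list(count = 0L, area = 0))
  pts <- cbind(mtc$row, mtc$col)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  area <- abs(sum(hull[, 1] * c(hull[-1, 2], hull[1, 2]) -
                  hull[, 2] * c(hull[-1, 1], hull[1, 1]))) / 2
  if (nrow(ctl) == 0) return(list(count = 0L, area = area))
  bnd <- rbind(hull, hull[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, cbind(ctl$row, ctl$col))
  list(count = sum(inside), area = area)
}

#' CTL distance-to-tumor profile over time
#'
#' For each snapshot of a run, bins the distance from every CTL to its
#' nearest melanoma cell and normalizes the bin counts by the
#' melanoma-cell count - a time-by-distance picture of immune
#' infiltration.
#'
#' @param sim A `tumor_sim` (run with `snapshot_every > 0` for a useful
#'   time axis).
#' @param breaks Increasing distance-bin edges (a leading 0 is added if
#'   absent).
#' @return A tibble with one row per (snapshot, bin): `step`, `d_lo`,
#'   `d_hi`, `n_ctl`, `n_mtc`, `value` (`n_ctl / n_mtc`; `NA` with
#'   `undefined = TRUE` when a snapshot has no melanoma cells).
#' @export
ctl_distance_profile <- function(sim, breaks = seq(0, 50, by = 5)) {
  breaks <- sort(unique(c(0, breaks)))
  nb <- length(breaks) - 1L
  purrr::map2_dfr(sim$snapshots, sim$snapshot_step, function(cells, step) {
    mtc <- cells[cells$type == "MTC", ]
    ctl <- cells[cells$type == "CTL", ]
    base <- tibble::tibble(step = step,
                           d_lo = breaks[-length(breaks)], d_hi = breaks[-1])
    if (nrow(mtc) == 0)
      return(dplyr::mutate(base, n_ctl = NA_integer_, n_mtc = 0L,
                           value = NA_real_, undefined = TRUE))
    counts <- integer(nb)
    if (nrow(ctl) > 0) {
      dmin <- vapply(seq_len(nrow(ctl)), function(i)
        sqrt(min((mtc$row - ctl$row[i])^2 + (mtc$col - ctl$col[i])^2)),
        numeric(1))
      bin <- findInterval(dmin, breaks, left.open = TRUE)
      bin[dmin == 0] <- 1L   # co-located CTLs belong to the first bin
      counts <- tabulate(bin[bin >= 1L & bin <= nb], nbins = nb)
    }
    dplyr::mutate(base, n_ctl = counts, n_mtc = nrow(mtc),
                  value = counts / nrow(mtc), undefined = FALSE)
  })
}
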