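test_that("ISF field: tapered kernel, additivity, engine agrees with R", {
  params <- immune_params()
  dims <- c(40, 40)
  # single melanoma cell: peak at the cell, linear taper, zero outside
  one <- cells_tbl(row = 20, col = 20, a0 = 1.5,
                   genome = genome_string(genome_with("BRAF")),
                   map = hot_map)
  FF <- isf_field(one, dims, params, map = hot_map, f = 1.6)
  expect_equal(FF[20, 20], 1.5)
  expect_equal(FF[20, 23], 1.5 * 3 / 6)   # Chebyshev distance 3
  expect_equal(FF[15, 20], 1.5 * 1 / 6)   # distance 5, outermost ring
  expect_equal(FF[20, 26], 0)             # outside the radius
  # normal cells contribute nothing
  nc <- cells_tbl(row = 10, col = 10, type = "NC",
                  genome = genome_string(wild_genome()))
  expect_true(all(isf_field(nc, dims, params) == 0))
  # two sources superpose
  two <- rbind(one, cells_tbl(row = 22, col = 21, a0 = 1.2,
                              genome = genome_string(genome_with("BRAF")),
                              map = hot_map))
  F2 <- isf_field(two, dims, params, map = hot_map, f = 1.6)
  Fb <- isf_field(two[2, ], dims, params, map = hot_map, f = 1.6)
  expect_equal(F2, FF + Fb)

  # engine maintains the same field incrementally (independent route)
  cfg <- sim_config(hallmark = hallmark_params(p0 = 0, q0 = 0, f = 1.6),
                    immune = immune_params(s0 = 0, f_T = 0),
                    map = hot_map, grid = dims, c_max = 99, t_max = 5)
  st <- tumor_state(cfg, cells = two, seed = 1)
  expect_equal(state_field(st), F2, tolerance = 1e-12)
})

test_that("Hill recruitment rate hits its anchors and is monotone", {
  p <- immune_params(s0 = 0.4, f_T = 6, n_T = 2, gamma_T = 900)
  expect_equal(recruitment_rate(0, p), 0.4)
  expect_equal(recruitment_rate(30, p), 0.4 + 3)  # F_b^2 = gamma_T
  expect_equal(recruitment_rate(1e9, p), 0.4 + 6, tolerance = 1e-6)
  fb <- seq(0, 200, by = 5)
  expect_true(all(diff(recruitment_rate(fb, p)) > 0))
  expect_true(all(recruitment_rate(fb, p) < p$s0 + p$f_T))
  expect_error(recruitment_rate(-1, p), "nonnegative")
})

test_that("CTL recruitment is Poisson-distributed and capacity-limited", {
  # frozen melanocytes, no CTL death/kill/division: one immune round adds
  # ~Poisson(s0) CTLs while the periphery band is empty
  one <- cells_tbl(row = 15, col = 15, a0 = 1.5,
                   genome = genome_string(genome_with("BRAF")), map = hot_map)
  s0 <- 3
  cfg <- sim_config(hallmark = hallmark_params(p0 = 0, q0 = 0),
                    immune = immune_params(s0 = s0, f_T = 0, q_i = 0,
                                           p_i0 = 0, k0 = 0),
                    map = hot_map, grid = 31, c_max = 99, t_max = 1000)
  set.seed(21)
  reps <- 300
  added <- replicate(reps, {
    st <- tumor_state(cfg, cells = one)
    state_step(st)
    state_counts(st)$n_ctl
  })
  expect_lt(abs(mean(added) - s0), 4 * sqrt(s0 / reps))

  # once every band site holds a CTL, draws recruit nobody: the count
  # saturates at the 25-site Chebyshev-2 neighborhood of the lone border MTC
  st <- tumor_state(cfg, cells = one, seed = 21)
  state_step(st, 40)
  expect_equal(state_counts(st)$n_ctl, 25)
  state_step(st, 10)
  expect_equal(state_counts(st)$n_ctl, 25)

  # zero rate recruits nobody
  cfg0 <- sim_config(hallmark = hallmark_params(p0 = 0, q0 = 0),
                     immune = immune_params(s0 = 0, f_T = 0),
                     map = hot_map, grid = 31, c_max = 99, t_max = 100)
  st0 <- tumor_state(cfg0, cells = one, seed = 22)
  state_step(st0, 30)
  expect_equal(state_counts(st0)$n_ctl, 0)
})

test_that("CTL apoptosis, zero-field inertness, and kill bookkeeping", {
  # q_i = 1 removes every CTL in one immune round
  cells <- rbind(
    cells_tbl(row = 10, col = 10, a0 = 1.5,
              genome = genome_string(genome_with("BRAF")), map = hot_map),
    tibble::tibble(cell_id = 2:4, type = "CTL", row = c(3, 4, 5),
                   col = c(3, 4, 5), birth_step = 0L, a0 = NA,
                   genome = NA_character_))
  cfg <- sim_config(hallmark = hallmark_params(p0 = 0, q0 = 0),
                    immune = immune_params(s0 = 0, f_T = 0, q_i = 1),
                    map = hot_map, grid = 20, c_max = 99, t_max = 9)
  st <- tumor_state(cfg, cells = cells, seed = 31)
  state_step(st)
  expect_equal(state_counts(st)$n_ctl, 0)

  # with no melanoma cells the field is zero: CTLs neither kill nor divide
  # nor move
  ctls <- tibble::tibble(cell_id = 1:2, type = "CTL", row = c(8, 12),
                         col = c(8, 12), birth_step = 0L, a0 = NA,
                         genome = NA_character_)
  cfg0 <- sim_config(hallmark = hallmark_params(p0 = 0, q0 = 0),
                     immune = immune_params(s0 = 0, f_T = 0, q_i = 0,
                                            p_i0 = 1, k0 = 1),
                     grid = 20, c_max = 99, t_max = 9)
  st0 <- tumor_state(cfg0, cells = ctls, seed = 32)
  before <- state_cells(st0)
  state_step(st0, 3)
  expect_equal(state_cells(st0), before)

  # an adjacent CTL with saturated kill probability removes exactly one
  # melanoma cell per round, tracked by the event ledger
  pair <- rbind(
    cells_tbl(row = 10, col = c(10, 11), a0 = 2,
              genome = genome_string(genome_with("BRAF")), map = hot_map),
    tibble::tibble(cell_id = 3, type = "CTL", row = 10, col = 9,
                   birth_step = 0L, a0 = NA, genome = NA_character_))
  cfgk <- sim_config(hallmark = hallmark_params(p0 = 0, q0 = 0),
                     immune = immune_params(s0 = 0, f_T = 0, q_i = 0,
                                            p_i0 = 0, k0 = 1,
                                            isf_sat = 1e-9),
                     map = hot_map, grid = 20, c_max = 99, t_max = 9)
  stk <- tumor_state(cfgk, cells = pair, seed = 33)
  state_step(stk)
  cnt <- state_counts(stk)
  expect_equal(cnt$kills, 1)
  expect_equal(cnt$n_mtc, 1)
  # the survivor is two sites away: one chemotaxis round, then the kill
  state_step(stk, 2)
  expect_equal(state_counts(stk)$n_mtc, 0)
})

test_that("chemotaxis climbs the ISF gradient to reach an antigenic cell", {
  cells <- rbind(
    cells_tbl(row = 15, col = 15, a0 = 1.5,
              genome = genome_string(genome_with("BRAF")), map = hot_map),
    tibble::tibble(cell_id = 2, type = "CTL", row = 15, col = 18,
                   birth_step = 0L, a0 = NA, genome = NA_character_))
  cfg <- sim_config(hallmark = hallmark_params(p0 = 0, q0 = 0),
                    immune = immune_params(s0 = 0, f_T = 0, q_i = 0,
                                           p_i0 = 0, k0 = 0),
                    map = hot_map, grid = 30, c_max = 99, t_max = 9)
  st <- tumor_state(cfg, cells = cells, seed = 41)
  FF <- state_field(st)
  # the field strictly increases along the approach path
  expect_true(FF[15, 17] > FF[15, 18])
  expect_true(FF[15, 16] > FF[15, 17])
  state_step(st, 2)
  ctl <- state_cells(st) |> dplyr::filter(type == "CTL")
  expect_lte(max(abs(ctl$row - 15), abs(ctl$col - 15)), 1)
})

test_that("disabling the immune module is equivalent to zero recruitment", {
  base <- hallmark_params(r0 = 1e-4)
  cfg_off <- sim_config(hallmark = base, immune = NULL,
                        c_max = 800, t_max = 400, grid = 80)
  cfg_zero <- sim_config(hallmark = base,
                         immune = immune_params(s0 = 0, f_T = 0),
                         c_max = 800, t_max = 400, grid = 80)
  a <- simulate_tumor(cfg_off, seed = 51)
  b <- simulate_tumor(cfg_zero, seed = 51)
  expect_equal(final_cells(a), final_cells(b))
  expect_equal(a$steps, b$steps)
})

test_that("hot map yields higher melanoma antigenicity than cold early on", {
  means <- purrr::map_dfr(1:10, function(seed) {
    vals <- sapply(c("hot", "cold"), function(v) {
      cfg <- sim_config(hallmark = hallmark_params(r0 = 1e-6),
                        map = driver_map(v), c_max = 600, t_max = 60,
                        grid = 80)
      fin <- annotate_cells(final_cells(simulate_tumor(cfg, seed = seed)),
                            map = driver_map(v), f = 1.6)
      mean(fin$antigenicity[fin$type == "MTC"], na.rm = TRUE)
    })
    tibble::tibble(hot = vals[["hot"]], cold = vals[["cold"]])
  })
  expect_true(all(means$hot >= means$cold, na.rm = TRUE))
})
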