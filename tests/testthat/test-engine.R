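test_that("standard initialization seeds 9 normal cells and 1 BRAF founder", {
  cfg <- sim_config(c_max = 100, t_max = 10, grid = 40)
  st <- tumor_state(cfg, seed = 1)
  cells <- state_cells(st)
  expect_equal(nrow(cells), 10L)
  expect_equal(sum(cells$type == "MTC"), 1L)
  expect_equal(sum(cells$type == "NC"), 9L)
  founder <- parse_genome(cells$genome[cells$type == "MTC"])
  expect_equal(sum(founder), 1L)
  expect_equal(which(founder == 1L), locus_of("BRAF"))
  expect_true(all(cells$a0 >= 1 & cells$a0 <= 2))
  # contiguity: one 8-connected component
  mask <- matrix(FALSE, 40, 40)
  mask[cbind(cells$row, cells$col)] <- TRUE
  expect_equal(sum(ithsim:::mask_largest_component(mask)), 10L)
  # determinism of the initial state
  st2 <- tumor_state(cfg, seed = 1)
  expect_equal(state_cells(st2), cells)
  expect_error(tumor_state(sim_config(grid = 5, c_max = 10)), NA)
})

test_that("degenerate probabilities force the documented outcomes", {
  # q = 1 kills every unmutated cell in one sweep
  cells <- cells_tbl(row = c(5, 5, 6), col = c(5, 6, 5), type = "NC",
                     genome = genome_string(wild_genome()))
  cfg <- sim_config(hallmark = hallmark_params(p0 = 0, q0 = 1),
                    immune = NULL, grid = 12, c_max = 99, t_max = 5)
  st <- tumor_state(cfg, cells = cells, seed = 1)
  state_step(st)
  expect_equal(nrow(state_cells(st)), 0L)

  # p = 1, q = 0, r = 0: daughter genome identical to parent
  cfg2 <- sim_config(hallmark = hallmark_params(p0 = 1, q0 = 0, r0 = 0),
                     immune = NULL, grid = 12, c_max = 99, t_max = 5)
  one <- cells_tbl(row = 6, col = 6, type = "NC",
                   genome = genome_string(wild_genome()))
  st2 <- tumor_state(cfg2, cells = one, seed = 2)
  state_step(st2)
  cc <- state_cells(st2)
  expect_equal(nrow(cc), 2L)
  expect_equal(unique(cc$genome), genome_string(wild_genome()))

  # fully packed neighborhoods leave division quiescent (no growth, no loss)
  full <- expand.grid(row = 1:5, col = 1:5)
  st3 <- tumor_state(sim_config(hallmark = hallmark_params(p0 = 1, q0 = 0),
                                immune = NULL, grid = 5, c_max = 99,
                                t_max = 5),
                     cells = cells_tbl(full$row, full$col, type = "NC",
                                       genome = genome_string(wild_genome())),
                     seed = 3)
  state_step(st3)
  expect_equal(nrow(state_cells(st3)), 25L)

  # p = q = m0 = 0 with no immune: a fixed point
  st4 <- tumor_state(sim_config(hallmark = hallmark_params(p0 = 0, q0 = 0),
                                immune = NULL, grid = 12, c_max = 99,
                                t_max = 5),
                     cells = cells, seed = 4)
  before <- state_cells(st4)
  state_step(st4, 3)
  expect_equal(state_cells(st4), before)
})

test_that("push moves shift contiguous runs and abort at the boundary", {
  cfg <- sim_config(hallmark = hallmark_params(p0 = 0, q0 = 0),
                    immune = NULL, m0 = 1, grid = 9, c_max = 99, t_max = 5)
  row3 <- cells_tbl(row = c(4, 4, 4), col = 3:5,
                    genome = genome_string(genome_with("BRAF")))
  st <- tumor_state(cfg, cells = row3, seed = 1)
  # Moore direction 5 is (0, +1): push the row east by one site
  expect_true(state_push(st, 4, 3, 5))
  cc <- state_cells(st)
  expect_setequal(cc$col, 4:6)
  expect_equal(unique(cc$row), 4L)
  expect_equal(nrow(cc), 3L)

  # pushing a run that ends at the grid edge is aborted
  edge <- cells_tbl(row = rep(4, 3), col = 7:9,
                    genome = genome_string(genome_with("BRAF")))
  st2 <- tumor_state(cfg, cells = edge, seed = 1)
  expect_false(state_push(st2, 4, 7, 5))
  expect_equal(sort(state_cells(st2)$col), 7:9)

  # an empty target is a plain move
  lone <- cells_tbl(row = 4, col = 4,
                    genome = genome_string(genome_with("BRAF")))
  st3 <- tumor_state(cfg, cells = lone, seed = 1)
  expect_true(state_push(st3, 4, 4, 5))
  expect_equal(state_cells(st3)$col, 5L)
})

test_that("stopping conditions and snapshot bookkeeping behave", {
  # population already at c_max: terminate before stepping
  sim <- simulate_tumor(sim_config(c_max = 10, t_max = 50, grid = 40),
                        seed = 1)
  expect_equal(sim$steps, 0L)
  expect_equal(sim$termination, "c_max")
  expect_equal(length(sim$snapshots), 1L)

  # t_max = 0: only the initial snapshot
  sim0 <- simulate_tumor(sim_config(c_max = 1e6, t_max = 0, grid = 40),
                         seed = 1)
  expect_equal(sim0$steps, 0L)
  expect_equal(sim0$termination, "t_max")
  expect_equal(nrow(final_cells(sim0)), 10L)

  # growth-only run: population nondecreasing, bounded by the grid area
  cfg <- sim_config(hallmark = hallmark_params(p0 = 1, q0 = 0, r0 = 0),
                    immune = NULL, grid = 25, c_max = 700, t_max = 60,
                    snapshot_every = 10)
  sim2 <- simulate_tumor(cfg, seed = 5)
  tr <- tidy(sim2)
  expect_true(all(diff(tr$n_melanocytes) >= 0))
  expect_lte(max(tr$n_melanocytes), 25 * 25)
  expect_gt(length(sim2$snapshots), 2L)
})

test_that("equal seeds give identical trajectories, different seeds differ", {
  cfg <- sim_config(c_max = 400, t_max = 500, grid = 80, snapshot_every = 25)
  a <- simulate_tumor(cfg, seed = 7)
  b <- simulate_tumor(cfg, seed = 7)
  expect_equal(a$snapshots, b$snapshots)
  expect_equal(a$trace, b$trace)
  c <- simulate_tumor(cfg, seed = 8)
  expect_false(identical(a$snapshots[[length(a$snapshots)]],
                         c$snapshots[[length(c$snapshots)]]))
})

test_that("population changes reconcile with the per-step event ledger", {
  cfg <- sim_config(hallmark = hallmark_params(r0 = 1e-4),
                    c_max = 3000, t_max = 500, grid = 100)
  st <- tumor_state(cfg, seed = 11)
  prev <- state_counts(st)$n_melanocytes
  for (i in 1:60) {
    state_step(st)
    cnt <- state_counts(st)
    expect_equal(cnt$n_melanocytes,
                 prev + cnt$births - cnt$deaths - cnt$kills)
    prev <- cnt$n_melanocytes
  }
})

test_that("site exclusivity and genome invariants hold population-wide", {
  cfg <- sim_config(hallmark = hallmark_params(r0 = 1e-3),
                    c_max = 2500, t_max = 400, grid = 100)
  sim <- simulate_tumor(cfg, seed = 13)
  fin <- final_cells(sim)
  mel <- fin[fin$type != "CTL", ]
  expect_equal(anyDuplicated(mel[, c("row", "col")]), 0L)
  ctl <- fin[fin$type == "CTL", ]
  expect_equal(anyDuplicated(ctl[, c("row", "col")]), 0L)
  ex <- locus_of(c("BRAF", "NRAS", "KIT"))
  M <- mutation_matrix(mel)
  expect_true(all(rowSums(M[, ex, drop = FALSE]) <= 1L))
})

test_that("non-motile growth without death stays connected", {
  cfg <- sim_config(hallmark = hallmark_params(q0 = 0, r0 = 0),
                    immune = NULL, c_max = 1500, t_max = 2000, grid = 80)
  sim <- simulate_tumor(cfg, seed = 17)
  fin <- final_cells(sim)
  mask <- matrix(FALSE, 80, 80)
  mask[cbind(fin$row, fin$col)] <- TRUE
  expect_equal(sum(ithsim:::mask_largest_component(mask)), nrow(fin))
})

test_that("snapshots round-trip through the TSV format", {
  sim <- simulate_tumor(sim_config(c_max = 150, grid = 60), seed = 2)
  fin <- final_cells(sim)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snapshot(fin, path)
  back <- read_snapshot(path)
  expect_equal(as.data.frame(back), as.data.frame(fin))
})
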