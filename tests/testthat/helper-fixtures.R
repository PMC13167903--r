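# shared fixtures and memoized simulation runs for the test suite

the_map <- driver_map()
hot_map <- driver_map("hot")
locus_of <- function(gene, map = the_map) map$locus[match(gene, map$gene)]

# genome with the named genes mutated
genome_with <- function(..., map = the_map) {
  g <- wild_genome(map)
  genes <- c(...)
  if (length(genes)) g[map$locus[match(genes, map$gene)]] <- 1L
  g
}

# minimal snapshot-format cell table
cells_tbl <- function(row, col, type = "MTC", genome = NULL, a0 = 1.5,
                      birth_step = 0L, map = the_map) {
  n <- length(row)
  if (is.null(genome)) genome <- genome_string(founder_genome(map))
  tibble::tibble(cell_id = seq_len(n), type = rep_len(type, n),
                 row = row, col = col,
                 birth_step = rep_len(birth_step, n),
                 a0 = rep_len(a0, n), genome = rep_len(genome, n))
}

# filled disk mask
disk_mask <- function(radius, pad = 4) {
  n <- 2 * radius + 2 * pad + 1
  ctr <- radius + pad + 1
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= radius^2)
}

# a tumor_sim-shaped object around explicit snapshots (for profile tests)
fake_sim <- function(snapshots, steps = NULL) {
  if (is.null(steps)) steps <- seq_along(snapshots) - 1L
  structure(list(snapshots = snapshots, snapshot_step = steps,
                 trace = NULL, termination = "t_max",
                 steps = max(steps), config = NULL, seed = NA),
            class = "tumor_sim")
}

# memoized reduced-scale runs shared by the acceptance criteria:
# f = 1.6, m0 = 0, r0 in {1e-6, 1e-5, 1e-4}, c_max = 10,000, 8 replicates
.run_cache <- new.env(parent = emptyenv())

desk_runs <- function() {
  if (!is.null(.run_cache$desk)) return(.run_cache$desk)
  cfg <- sim_config(c_max = 10000, grid = 300)
  out <- purrr::map_dfr(c(1e-6, 1e-5, 1e-4), function(r0) {
    purrr::map_dfr(1:8, function(rep) {
      cfg_r <- sim_config(hallmark = hallmark_params(r0 = r0),
                          c_max = cfg$c_max, grid = cfg$grid)
      sim <- simulate_tumor(cfg_r, seed = 20000 + round(log10(r0) * -100) + rep)
      fin <- final_cells(sim)
      ith <- ith_report(fin, cfg_r$grid, step = sim$steps)
      morph <- morphology_report(fin, cfg_r$grid, step = sim$steps)
      tibble::tibble(r0 = r0, replicate = rep,
                     epsilon = ith$epsilon, beta = ith$beta,
                     clustered_fd = ith$clustered_fd,
                     C = morph$C, FD_b = morph$FD_b)
    })
  })
  .run_cache$desk <- out
  out
}
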