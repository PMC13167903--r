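#' Run one tumor simulation
#'
#' Grows a tumor from the standard seed (9 unmutated melanocytes plus one
#' founder melanoma cell carrying a single BRAF mutation, contiguous at the
#' grid center) until the melanocyte population reaches `c_max` or `t_max`
#' steps have elapsed. Each step sweeps the melanocytes in freshly shuffled
#' order (apoptosis, then division with daughter-genome mutation into an
#' empty Moore site, then BRAF-mutant motility with pushing), followed by
#' the immune round (Hill-function Poisson CTL recruitment at the border,
#' then CTL apoptosis / ISF-dependent killing and proliferation / uphill
#' chemotaxis).
#'
#' Runs are deterministic given `seed`: equal seed and configuration give
#' bitwise-identical trajectories.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the run (uses R's RNG stream).
#' @return An object of class `tumor_sim`: a list with `snapshots` (list of
#'   cell tibbles), `snapshot_step`, `trace` (per-step population counts),
#'   `termination` (`"c_max"`, `"t_max"` or `"extinct"`), `steps`,
#'   `config` and `seed`. The final snapshot is `final_cells(sim)`.
#' @examples
#' sim <- simulate_tumor(sim_config(c_max = 200, t_max = 200, grid = 80),
#'                       seed = 1)
#' glance(sim)
#' @export
simulate_tumor <- function(config = sim_config(), seed = 1L) {
  state <- tumor_state(config, seed = seed)
  res <- eng_run(state$ptr, config$c_max, config$t_max, config$snapshot_every)
  structure(list(
    snapshots = lapply(res$snapshots, tibble::as_tibble),
    snapshot_step = as.integer(res$snapshot_step),
    trace = tibble::as_tibble(res$trace),
    termination = res$termination,
    steps = res$steps,
    config = config, seed = seed
  ), class = "tumor_sim")
}

#' Low-level simulation state handle
#'
#' Creates a live engine state that can be stepped and inspected
#' incrementally - useful for probing individual model rules. Supply
#' `cells` to start from an explicit cell table instead of the standard
#' 10-cell seed (rows with `type == "CTL"` become immune cells; missing
#' `a0` is drawn from the configured base-antigenicity range).
#'
#' @inheritParams simulate_tumor
#' @param cells Optional starting cell table with columns `row`, `col`,
#'   `type`, `genome` (0/1 string), and optionally `a0`, `birth_step`.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return A `tumor_state` object with elements `ptr` (engine handle) and
#'   `config`.
#' @seealso [state_step()], [state_cells()], [state_field()],
#'   [state_counts()], [state_border_isf()], [state_push()]
#' @export
tumor_state <- function(config = sim_config(), cells = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  enc <- driver_map_encoding(config$map)
  ptr <- eng_new(engine_config(config))
  if (is.null(cells)) {
    eng_init_standard(ptr, enc$founder_locus)
  } else {
    cells <- tibble::as_tibble(cells)
    n <- nrow(cells)
    eng_init_cells(ptr,
                   as.integer(cells$row), as.integer(cells$col),
                   as.character(cells$type),
                   as.character(cells$genome %||% rep(genome_string(wild_genome(config$map)), n)),
                   as.numeric(cells$a0 %||% rep(NA_real_, n)),
                   as.integer(cells$birth_step %||% rep(0L, n)))
  }
  structure(list(ptr = ptr, config = config), class = "tumor_state")
}

#' Step and inspect a live simulation state
#'
#' @param state A [tumor_state()].
#' @param n Number of steps to advance.
#' @return `state_step()` the state, invisibly; `state_cells()` the current
#'   cell tibble; `state_field()` the ISF matrix; `state_counts()` a
#'   one-row tibble of population counts and last-step event tallies;
#'   `state_border_isf()` the total ISF of border tumor cells.
#' @export
state_step <- function(state, n = 1L) {
  eng_step(state$ptr, as.integer(n))
  invisible(state)
}

#' @rdname state_step
#' @export
state_cells <- function(state) tibble::as_tibble(eng_cells(state$ptr))

#' @rdname state_step
#' @export
state_field <- function(state) eng_field(state$ptr)

#' @rdname state_step
#' @export
state_counts <- function(state) tibble::as_tibble(eng_counts(state$ptr))

#' @rdname state_step
#' @export
state_border_isf <- function(state) eng_border_isf(state$ptr)

#' @rdname state_step
#' @param row,col 1-based position of the melanocyte to move.
#' @param direction Moore direction index 1..8 (row-major order of the
#'   eight neighbors).
#' @return `state_push()` returns `TRUE` if the move (or push) succeeded,
#'   `FALSE` if it was aborted at the grid boundary.
#' @export
state_push <- function(state, row, col, direction) {
  eng_push(state$ptr, as.integer(row), as.integer(col),
           as.integer(direction) - 1L)
}

#' Final snapshot of a run
#'
#' @param sim A `tumor_sim` object.
#' @return The last recorded cell tibble.
#' @export
final_cells <- function(sim) {
  sim$snapshots[[length(sim$snapshots)]]
}

#' @export
print.tumor_sim <- function(x, ...) {
  fin <- final_cells(x)
  cat("<tumor_sim> ", x$steps, " steps, terminated by ", x$termination, "\n",
      "  melanocytes: ", sum(fin$type != "CTL"),
      " (MTC ", sum(fin$type == "MTC"), ", NC ", sum(fin$type == "NC"), ")",
      ", CTLs: ", sum(fin$type == "CTL"), "\n",
      "  snapshots: ", length(x$snapshots), ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Tidiers for simulation runs
#'
#' `glance()` returns a one-row run summary; `tidy()` returns the per-step
#' population trace.
#'
#' @param x A `tumor_sim` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.tumor_sim <- function(x, ...) {
  fin <- final_cells(x)
  tibble::tibble(
    steps = x$steps, termination = x$termination,
    n_melanocytes = sum(fin$type != "CTL"),
    n_mtc = sum(fin$type == "MTC"),
    n_nc = sum(fin$type == "NC"),
    n_ctl = sum(fin$type == "CTL"),
    seed = x$seed)
}

#' @rdname glance.tumor_sim
#' @export
tidy.tumor_sim <- function(x, ...) x$trace

#' Read and write snapshot cell tables
#'
#' Snapshots are plain tab-separated tables with columns `cell_id`, `type`
#' (`NC`/`MTC`/`CTL`), `row`, `col`, `birth_step`, `a0` and `genome`
#' (0/1 string).
#'
#' @param cells A cell tibble.
#' @param path File path.
#' @return `read_snapshot()` a tibble; `write_snapshot()` `path`,
#'   invisibly.
#' @export
write_snapshot <- function(cells, path) {
  readr::write_tsv(cells, path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    cell_id = "i", type = "c", row = "i", col = "i",
    birth_step = "i", a0 = "d", genome = "c"))
}
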