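#' Synthetic spatially segregated multi-clone population
#'
#' Builds a cell table of `n_clones` genetically distinct clones arranged
#' in separate spatial blocks - the archetype of the fractal-heterogeneity
#' regime in which spatially systematic sampling shines. Each clone gets a
#' private set of mutated passenger genes (plus one driver so the cells
#' count as tumor cells); all cells of a clone share the genome. Birth
#' steps are assigned uniformly at random, so temporal order carries no
#' information about clone identity.
#'
#' @param n_clones Number of clones.
#' @param cells_per_clone Cells in each clone.
#' @param mutations_per_clone Private passenger mutations per clone.
#' @param block Side length (sites) of each clone's square block.
#' @param map A [driver_map()].
#' @return A snapshot-format cell tibble.
#' @examples
#' set.seed(1)
#' pop <- synthetic_clone_population(n_clones = 6, cells_per_clone = 50)
#' ith_entropy(pop, method = "exact")
#' @export
synthetic_clone_population <- function(n_clones = 12, cells_per_clone = 200,
                                       mutations_per_clone = 3,
                                       block = 24, map = driver_map()) {
  n_genes <- attr(map, "n_genes")
  passengers <- setdiff(seq_len(n_genes), map$locus)
  ncol_blocks <- ceiling(sqrt(n_clones))
  driver_loci <- map$locus[!map$gene %in% attr(map, "exclusivity")]
  rows <- purrr::map_dfr(seq_len(n_clones), function(cl) {
    g <- integer(n_genes)
    g[sample(passengers, mutations_per_clone)] <- 1L
    g[driver_loci[1 + (cl - 1) %% length(driver_loci)]] <- 1L
    br <- (cl - 1) %/% ncol_blocks; bc <- (cl - 1) %% ncol_blocks
    sites <- sample.int(block * block, cells_per_clone)
    tibble::tibble(
      type = "MTC",
      row = br * (block + 4) + 1 + (sites - 1) %/% block,
      col = bc * (block + 4) + 1 + (sites - 1) %% block,
      a0 = runif(cells_per_clone, 1, 2),
      genome = genome_string(g))
  })
  m <- nrow(rows)
  dplyr::mutate(rows,
                cell_id = seq_len(m),
                birth_step = sample.int(m, m),
                .before = 1)
}

#' Reference fractal shapes
#'
#' Programmatic generators for sets of known fractal dimension, used to
#' validate the box-counting estimator: the Sierpinski carpet (dimension
#' `log(8)/log(3)`) and the type-1 quadratic Koch curve (dimension
#' `log(5)/log(3)`) wrapped around a square.
#'
#' @param depth Recursion depth.
#' @return `sierpinski_carpet()` a logical `3^depth` square matrix;
#'   `koch_boundary_points()` an integer matrix of lattice points tracing
#'   the four Koch-perturbed sides of a square of side `3^depth`.
#' @examples
#' box_counting_fd(sierpinski_carpet(4))
#' @export
sierpinski_carpet <- function(depth = 5) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(depth)) {
    n <- nrow(m)
    M <- matrix(FALSE, 3 * n, 3 * n)
    for (a in 0:2) for (b in 0:2)
      if (!(a == 1 && b == 1))
        M[a * n + seq_len(n), b * n + seq_len(n)] <- m
    m <- M
  }
  m
}

#' @rdname sierpinski_carpet
#' @export
koch_boundary_points <- function(depth = 5) {
  moves <- "F"
  for (i in seq_len(depth)) {
    moves <- gsub("F", "FxLFxRFxRFxLFx", moves, fixed = TRUE)
    moves <- gsub("x", "", moves, fixed = TRUE)
  }
  side <- paste0(moves, "R")          # one square side, then turn right
  prog <- strsplit(paste(rep(side, 4), collapse = ""), "")[[1]]
  dirs <- matrix(c(1, 0, 0, 1, -1, 0, 0, -1), ncol = 2, byrow = TRUE)
  d <- 1; pos <- c(0L, 0L)
  pts <- matrix(0L, sum(prog == "F") + 1, 2)
  np <- 1L
  for (ch in prog) {
    if (ch == "F") {
      pos <- pos + dirs[d, ]
      np <- np + 1L
      pts[np, ] <- pos
    } else if (ch == "L") d <- (d %% 4) + 1
    else d <- ((d - 2) %% 4) + 1
  }
  pts
}
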