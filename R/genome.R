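#' Genome helpers
#'
#' Genomes are length-`n_genes` binary vectors (0 = wild type, 1 = mutated).
#' In cell tables they travel as compact character strings of 0s and 1s;
#' these helpers convert between the two representations.
#'
#' @param genome Integer/numeric 0-1 vector, or a single such string.
#' @param map A [driver_map()].
#' @return `genome_string()` a character scalar; `parse_genome()` an integer
#'   vector; `wild_genome()`/`founder_genome()` integer vectors of length
#'   `n_genes`.
#' @examples
#' g <- founder_genome()
#' genome_string(g)
#' is_mtc(g)
#' @export
genome_string <- function(genome) {
  paste(as.integer(genome), collapse = "")
}

#' @rdname genome_string
#' @export
parse_genome <- function(genome) {
  if (is.character(genome)) {
    stopifnot(length(genome) == 1L)
    as.integer(strsplit(genome, "")[[1]])
  } else {
    as.integer(genome)
  }
}

#' @rdname genome_string
#' @export
wild_genome <- function(map = driver_map()) {
  integer(attr(map, "n_genes"))
}

#' @rdname genome_string
#' @export
founder_genome <- function(map = driver_map()) {
  g <- wild_genome(map)
  g[map$locus[match(attr(map, "founder_gene"), map$gene)]] <- 1L
  g
}

check_genome <- function(genome, map) {
  g <- parse_genome(genome)
  n <- attr(map, "n_genes")
  if (length(g) != n)
    stop("genome must have exactly ", n, " genes, got ", length(g))
  if (!all(g %in% c(0L, 1L))) stop("genome entries must be 0 or 1")
  ex <- map$locus[match(attr(map, "exclusivity"), map$gene)]
  if (length(ex) && sum(g[ex]) > 1L)
    stop("mutual exclusivity violated: more than one of ",
         paste(attr(map, "exclusivity"), collapse = "/"), " mutated")
  g
}

#' Per-hallmark driver mutation counts
#'
#' Counts the mutated driver loci carrying each hallmark tag. A driver with
#' several tags contributes to each of its tags, so the five counts need not
#' sum to the number of mutated drivers.
#'
#' @inheritParams genome_string
#' @return Named integer vector with elements `p`, `q`, `r`, `c`, `ct`.
#' @examples
#' count_hallmark_drivers(founder_genome())
#' @export
count_hallmark_drivers <- function(genome, map = driver_map()) {
  g <- check_genome(genome, map)
  hit <- g[map$locus] == 1L
  counts <- vapply(valid_tags, function(tag)
    sum(vapply(map$tags[hit], function(tg) tag %in% tg, logical(1))),
    integer(1))
  setNames(as.integer(counts), valid_tags)
}

#' Hallmark-scaled action probabilities
#'
#' Each mutated driver scales its hallmark's base probability by a factor
#' `10^f` per driver: proliferation `p = p0 * 10^(f*d_p)`, apoptosis
#' `q = q0 * 10^(-f*d_q)`, and per-gene mutation `r = r0 * 10^(f*d_r)`.
#' `p` and `r` are clipped to 1 so they remain valid probabilities; the
#' clipping preserves monotonicity in the driver counts.
#'
#' @param counts Named counts as returned by [count_hallmark_drivers()]
#'   (only `p`, `q`, `r` are used).
#' @param params A [hallmark_params()] list.
#' @return Named numeric vector `c(p=, q=, r=)`.
#' @examples
#' action_probabilities(count_hallmark_drivers(founder_genome()),
#'                      hallmark_params(f = 1.6))
#' @export
action_probabilities <- function(counts, params = hallmark_params()) {
  stopifnot(all(counts >= 0))
  c(p = min(1, params$p0 * 10^(params$f * counts[["p"]])),
    q = params$q0 * 10^(-params$f * counts[["q"]]),
    r = min(1, params$r0 * 10^(params$f * counts[["r"]])))
}

#' Cell antigenicity
#'
#' Melanoma cells expose antigenicity `a = a0 * 10^(f * (d_ct - d_c))`,
#' where `a0` is the cell's base antigenicity drawn once at creation from
#' `[1, 2]` and inherited by daughters. Cells without any driver mutation
#' (normal melanocytes) have antigenicity 0 and contribute nothing to the
#' immune stimulatory field.
#'
#' @param a0 Base antigenicity (scalar or vector).
#' @param counts Named hallmark counts ([count_hallmark_drivers()]).
#' @param f Driver gene strength.
#' @param mtc Logical; set `FALSE` for normal cells (antigenicity 0).
#' @return Numeric antigenicity.
#' @examples
#' antigenicity(1.5, count_hallmark_drivers(founder_genome()), f = 1.6)
#' @export
antigenicity <- function(a0, counts, f, mtc = TRUE) {
  ifelse(mtc, a0 * 10^(f * (counts[["ct"]] - counts[["c"]])), 0)
}

#' Stochastic genome mutation
#'
#' Flips each wild gene to the mutated state independently with probability
#' `r`. Genes are visited in ascending index order; a gene in the mutual
#' exclusivity group (BRAF/NRAS/KIT by default) is never flipped while
#' another group member is already mutated, including mutations acquired
#' earlier in the same pass. Mutated genes never revert.
#'
#' @inheritParams genome_string
#' @param r Per-gene mutation probability in `[0, 1]`.
#' @return Integer genome vector.
#' @examples
#' set.seed(1)
#' mutate_genome(wild_genome(), r = 0.2)
#' @export
mutate_genome <- function(genome, r, map = driver_map()) {
  stopifnot(r >= 0, r <= 1)
  g <- check_genome(genome, map)
  ex <- map$locus[match(attr(map, "exclusivity"), map$gene)]
  for (k in seq_along(g)) {
    if (g[k] == 1L) next
    if (k %in% ex && sum(g[setdiff(ex, k)]) > 0L) next
    if (runif(1) < r) g[k] <- 1L
  }
  g
}

#' Is a genome a melanoma tumor cell?
#'
#' A melanocyte counts as a melanoma tumor cell (MTC) as soon as it carries
#' at least one driver mutation; passenger mutations alone leave it a
#' normal cell (NC).
#'
#' @inheritParams genome_string
#' @return Logical scalar.
#' @export
is_mtc <- function(genome, map = driver_map()) {
  g <- check_genome(genome, map)
  any(g[map$locus] == 1L)
}

# vectorized helpers over cell tables ---------------------------------------

#' Add per-cell driver summaries to a cell table
#'
#' Annotates a snapshot cell table with the driver-mutation count
#' (`n_drivers`), total mutation count (`n_mutations`) and antigenicity
#' (`antigenicity`) of each melanocyte. CTL rows get zero counts and `NA`
#' antigenicity.
#'
#' @param cells A snapshot cell table (see [simulate_tumor()]).
#' @param map A [driver_map()].
#' @param f Driver gene strength used for antigenicity.
#' @return The input tibble with columns `n_drivers`, `n_mutations` and
#'   `antigenicity` appended.
#' @export
annotate_cells <- function(cells, map = driver_map(), f = 1.6) {
  M <- mutation_matrix(cells)
  mel <- !is.na(cells$genome) & cells$type != "CTL"
  nd <- nm <- integer(nrow(cells))
  ag <- rep(NA_real_, nrow(cells))
  if (any(mel)) {
    nd[mel] <- as.integer(M[, map$locus, drop = FALSE] %*% rep(1L, nrow(map)))
    nm[mel] <- as.integer(rowSums(M))
    tagmat <- driver_map_encoding(map)$driver_tags
    dct <- M[, map$locus, drop = FALSE] %*% tagmat[, "ct"]
    dc <- M[, map$locus, drop = FALSE] %*% tagmat[, "c"]
    ag[mel] <- ifelse(nd[mel] > 0, cells$a0[mel] * 10^(f * (dct - dc)), 0)
  }
  dplyr::mutate(cells, n_drivers = nd, n_mutations = nm, antigenicity = ag)
}
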