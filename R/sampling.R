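#' Draw a population sample from a snapshot
#'
#' Implements the four strategies used for estimating heterogeneity
#' metrics from a fraction of the tumor cell population (melanocytes only;
#' CTL rows are never sampled):
#'
#' * `"SRS"` - simple random sampling without replacement.
#' * `"TS"` - time systematic: cells ordered by `birth_step` (ties broken
#'   uniformly at random), every `ceiling(1/fraction)`-th cell taken from
#'   a random start offset.
#' * `"SS"` - space systematic: a regular grid of nodes with random origin
#'   is laid over the occupied bounding box, spaced so the node count
#'   matches the target sample size, and the cell nearest each node is
#'   taken.
#' * `"CC"` - stratified via CLARANS k-medoids clustering on
#'   (position, driver profile) features, with proportional allocation and
#'   SRS within clusters.
#'
#' All methods return exactly `round(fraction * m)` distinct cells; after
#' the systematic passes the sample is topped up (or thinned) uniformly at
#' random to hit the size exactly.
#'
#' @param cells A snapshot cell table.
#' @param method One of `"SRS"`, `"CC"`, `"TS"`, `"SS"`.
#' @param fraction Sampling fraction in `(0, 1]` (default 0.10).
#' @param map Driver map (used by `"CC"` features).
#' @param k,numlocal,maxneighbor CLARANS hyper-parameters for `"CC"`.
#' @return Integer row indices into `cells`.
#' @examples
#' \donttest{
#' sim <- simulate_tumor(sim_config(c_max = 500, grid = 100), seed = 1)
#' idx <- draw_sample(final_cells(sim), "SRS", fraction = 0.1)
#' }
#' @export
draw_sample <- function(cells, method = c("SRS", "CC", "TS", "SS"),
                        fraction = 0.1, map = driver_map(),
                        k = 8, numlocal = 2, maxneighbor = 50) {
  method <- match.arg(method)
  stopifnot(fraction > 0, fraction <= 1)
  mel_idx <- which(cells$type != "CTL" & !is.na(cells$genome))
  m <- length(mel_idx)
  if (m < 10) stop("population too small to sample (need >= 10 cells)")
  size <- round(fraction * m)
  if (size < 1) stop("fraction * population < 1: nothing to sample")
  if (size >= m) return(mel_idx)
  mel <- cells[mel_idx, ]
  picked <- switch(method,
    SRS = sample.int(m, size),
    TS = sample_ts(mel, size, fraction),
    SS = sample_ss(mel, size),
    CC = sample_cc(mel, size, map, k, numlocal, maxneighbor))
  picked <- resize_sample(picked, m, size)
  mel_idx[picked]
}

# top up with uniform draws from the remainder / thin uniformly
resize_sample <- function(picked, m, size) {
  picked <- unique(picked)
  if (length(picked) > size) picked <- sample(picked, size)
  if (length(picked) < size) {
    pool <- setdiff(seq_len(m), picked)
    picked <- c(picked, sample(pool, size - length(picked)))
  }
  picked
}

sample_ts <- function(mel, size, fraction) {
  ord <- order(mel$birth_step, runif(nrow(mel)))
  stride <- ceiling(1 / fraction)
  start <- sample.int(stride, 1)
  ord[seq(start, nrow(mel), by = stride)]
}

sample_ss <- function(mel, size) {
  rmin <- min(mel$row); rmax <- max(mel$row)
  cmin <- min(mel$col); cmax <- max(mel$col)
  area <- (rmax - rmin + 1) * (cmax - cmin + 1)
  h <- sqrt(area / size)
  or <- runif(1, 0, h); oc <- runif(1, 0, h)
  nodes_r <- seq(rmin - h + or, rmax + h, by = h)
  nodes_c <- seq(cmin - h + oc, cmax + h, by = h)
  # occupancy lookup for nearest-cell search
  occ <- matrix(0L, rmax - rmin + 1, cmax - cmin + 1)
  occ[cbind(mel$row - rmin + 1, mel$col - cmin + 1)] <- seq_len(nrow(mel))
  max_ring <- ceiling(2 * h) + 2
  picked <- integer(0)
  for (nr in nodes_r) for (nc in nodes_c) {
    i <- nearest_cell(occ, nr - rmin + 1, nc - cmin + 1, max_ring)
    if (i > 0) picked <- c(picked, i)
  }
  unique(picked)
}

# nearest occupied site to real-valued (r, c) by expanding Chebyshev rings,
# refined to true Euclidean distance among the candidates found
nearest_cell <- function(occ, r, c, max_ring) {
  nr <- nrow(occ); nc <- ncol(occ)
  r0 <- round(r); c0 <- round(c)
  for (d in 0:max_ring) {
    rlo <- max(1, r0 - d); rhi <- min(nr, r0 + d)
    clo <- max(1, c0 - d); chi <- min(nc, c0 + d)
    if (rlo > rhi || clo > chi) next
    rs <- rlo:rhi; cs <- clo:chi
    ring <- occ[rs, cs, drop = FALSE]
    if (any(ring > 0)) {
      cand <- which(ring > 0, arr.ind = TRUE)
      rr <- rs[cand[, 1]]; cc <- cs[cand[, 2]]
      dist2 <- (rr - r)^2 + (cc - c)^2
      best <- which(dist2 == min(dist2))
      if (length(best) > 1) best <- sample(best, 1)
      return(ring[cand[best, , drop = FALSE]])
    }
  }
  0L
}

sample_cc <- function(mel, size, map, k, numlocal, maxneighbor) {
  X <- clarans_features(mel, map)
  k <- min(k, nrow(X))
  cl <- clarans(X, k = k, numlocal = numlocal, maxneighbor = maxneighbor)
  # proportional allocation, largest-remainder rounding to the exact size
  tab <- tabulate(cl$cluster, nbins = k)
  exact <- size * tab / sum(tab)
  alloc <- floor(exact)
  rem <- size - sum(alloc)
  if (rem > 0) {
    ord <- order(exact - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  alloc <- pmin(alloc, tab)
  unlist(lapply(seq_len(k), function(j) {
    members <- which(cl$cluster == j)
    if (alloc[j] == 0) integer(0)
    else members[sample.int(length(members), alloc[j])]
  }))
}

clarans_features <- function(mel, map) {
  D <- mutation_matrix(mel)[, map$locus, drop = FALSE]
  rr <- mel$row; cc <- mel$col
  span <- max(max(rr) - min(rr), max(cc) - min(cc), 1)
  cbind((rr - min(rr)) / span, (cc - min(cc)) / span, D)
}

#' CLARANS k-medoids clustering
#'
#' Randomized search for k medoids (Clustering Large Applications based on
#' RANdomized Search): from each of `numlocal` random starting medoid
#' sets, repeatedly propose swapping one medoid for a random non-medoid
#' and accept whenever the total distance to nearest medoids decreases;
#' a set that survives `maxneighbor` consecutive proposals is a local
#' optimum. The best local optimum is returned.
#'
#' @param X Numeric feature matrix (rows are observations).
#' @param k Number of medoids.
#' @param numlocal Number of local searches.
#' @param maxneighbor Consecutive non-improving proposals that end a
#'   local search.
#' @return A list with `medoids` (row indices), `cluster` (assignments)
#'   and `cost`.
#' @export
clarans <- function(X, k, numlocal = 2, maxneighbor = 50) {
  n <- nrow(X)
  stopifnot(k >= 1, k <= n)
  cost_of <- function(med) {
    d2 <- matrix(Inf, n, length(med))
    for (j in seq_along(med))
      d2[, j] <- rowSums((X - rep(X[med[j], ], each = n))^2)
    list(cost = sum(sqrt(pmin_row(d2))), d2 = d2)
  }
  best <- NULL
  for (l in seq_len(numlocal)) {
    med <- sample.int(n, k)
    cur <- cost_of(med)
    fails <- 0
    while (fails < maxneighbor) {
      j <- sample.int(k, 1)
      cand <- sample.int(n, 1)
      if (cand %in% med) { fails <- fails + 1; next }
      trial <- med; trial[j] <- cand
      tr <- cost_of(trial)
      if (tr$cost < cur$cost - 1e-12) {
        med <- trial; cur <- tr; fails <- 0
      } else fails <- fails + 1
    }
    if (is.null(best) || cur$cost < best$cost)
      best <- list(medoids = med, cost = cur$cost, d2 = cur$d2)
  }
  cluster <- max.col(-best$d2, ties.method = "first")
  list(medoids = best$medoids, cluster = cluster, cost = best$cost)
}

pmin_row <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmin(out, m[, j])
  out
}

#' Sampling error of heterogeneity metrics
#'
#' Evaluates how well each sampling strategy recovers the full-population
#' entropy and mean mutation count. The truth is computed exactly on the
#' entire melanocyte population; each replicate draws a fresh sample and
#' records the percentage error `100 * |estimate - truth| / truth` (the
#' absolute error is used for entropy when the true entropy is 0).
#'
#' @inheritParams draw_sample
#' @param methods Methods to evaluate.
#' @param replicates Number of independent samples per method.
#' @return A tibble with one row per method and metric: `method`, `metric`
#'   (`"epsilon"` or `"beta"`), `mean_error`, `sd_error`, `replicates`.
#'   Per-replicate errors are attached as attribute `"errors"`.
#' @export
sampling_error <- function(cells, methods = c("SRS", "CC", "TS", "SS"),
                           fraction = 0.1, replicates = 10,
                           map = driver_map(), ...) {
  M_full <- mutation_matrix(cells)
  eps_full <- ith_entropy(M_full, method = "exact")
  beta_full <- mean_mutation_count(M_full)
  pct <- function(est, true)
    if (true > 1e-12) 100 * abs(est - true) / true else abs(est - true)
  rows <- purrr::map_dfr(methods, function(mth) {
    purrr::map_dfr(seq_len(replicates), function(rep) {
      idx <- draw_sample(cells, mth, fraction = fraction, map = map, ...)
      Ms <- mutation_matrix(cells[idx, ])
      tibble::tibble(
        method = mth, replicate = rep,
        epsilon = pct(ith_entropy(Ms, method = "exact"), eps_full),
        beta = pct(mean_mutation_count(Ms), beta_full))
    })
  })
  long <- tidyr::pivot_longer(rows, c("epsilon", "beta"),
                              names_to = "metric", values_to = "error")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$method, .data$metric),
    mean_error = mean(.data$error), sd_error = sd(.data$error),
    replicates = dplyr::n(), .groups = "drop")
  attr(out, "errors") <- long
  out
}
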