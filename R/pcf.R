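#' Cross-pair correlation function
#'
#' Quantifies how target points arrange themselves around reference points
#' at increasing radial distances. For the annulus `(r1, r2]` the estimate
#' is the total number of reference-target pairs at those distances divided
#' by `lambda_target` times the total annulus area, where annulus areas are
#' intersected with the observation window (the only edge correction
#' applied) and `lambda_target` is the target intensity in the window.
#' `cPCF = 1` for spatially random arrangements, `> 1` for clustering and
#' `< 1` for anti-clustering; annuli lying entirely outside the window are
#' reported as `NA`.
#'
#' @param reference,target Point tables with numeric columns `x`, `y`
#'   (or lattice columns `row`, `col`, used as `x = row`, `y = col`).
#' @param breaks Increasing vector of annulus edges starting at the
#'   smallest radius (a leading 0 is added if absent).
#' @param window Observation window `c(xmin, xmax, ymin, ymax)`; defaults
#'   to the joint bounding box of both patterns.
#' @return A tibble of class `cross_pcf` with one row per annulus:
#'   `r_lo`, `r_hi`, `r_mid`, `pairs`, `area`, `pcf`.
#' @examples
#' set.seed(1)
#' ref <- tibble::tibble(x = runif(500, 0, 100), y = runif(500, 0, 100))
#' tar <- tibble::tibble(x = runif(500, 0, 100), y = runif(500, 0, 100))
#' cross_pcf(ref, tar, breaks = seq(0, 20, 5)) # pcf ~ 1
#' @export
cross_pcf <- function(reference, target, breaks,
                      window = NULL) {
  ref <- as_points(reference); tar <- as_points(target)
  if (nrow(ref) == 0) stop("empty reference pattern")
  if (nrow(tar) == 0) stop("empty target pattern")
  breaks <- sort(unique(c(0, breaks)))
  if (any(breaks < 0)) stop("breaks must be nonnegative")
  if (is.null(window)) {
    allp <- rbind(ref, tar)
    window <- c(min(allp[, 1]) - 0.5, max(allp[, 1]) + 0.5,
                min(allp[, 2]) - 0.5, max(allp[, 2]) + 0.5)
  }
  warea <- (window[2] - window[1]) * (window[4] - window[3])
  lambda <- nrow(tar) / warea
  # pairwise distance histogram, chunked over references
  nb <- length(breaks) - 1L
  pairs <- numeric(nb)
  chunk <- max(1L, floor(5e6 / nrow(tar)))
  for (i0 in seq(1, nrow(ref), by = chunk)) {
    idx <- i0:min(nrow(ref), i0 + chunk - 1L)
    d2 <- outer(ref[idx, 1], tar[, 1], "-")^2 +
          outer(ref[idx, 2], tar[, 2], "-")^2
    bin <- findInterval(sqrt(d2), breaks, left.open = TRUE)
    pairs <- pairs + tabulate(bin[bin >= 1L & bin <= nb], nbins = nb)
  }
  # window-intersected annulus areas summed over references
  disk_area <- vapply(breaks, function(r)
    if (r == 0) 0 else sum(circle_window_area(ref[, 1], ref[, 2], r, window)),
    numeric(1))
  area <- diff(disk_area)
  pcf <- ifelse(area > 1e-9, pairs / (lambda * area), NA_real_)
  out <- tibble::tibble(
    r_lo = breaks[-length(breaks)], r_hi = breaks[-1],
    r_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    pairs = pairs, area = area, pcf = pcf)
  class(out) <- c("cross_pcf", class(out))
  out
}

as_points <- function(p) {
  p <- as.data.frame(p)
  if (all(c("x", "y") %in% names(p))) cbind(p$x, p$y)
  else if (all(c("row", "col") %in% names(p))) cbind(p$row, p$col)
  else stop("point pattern needs x/y or row/col columns")
}

# area of the disk of radius r centered at (cx, cy) intersected with the
# rectangle win = c(x1, x2, y1, y2); vectorized over centers. Composite
# Simpson quadrature of the window-clipped chord length.
circle_window_area <- function(cx, cy, r, win, nodes = 129L) {
  lo <- pmax(win[1], cx - r); hi <- pmin(win[2], cx + r)
  span <- pmax(0, hi - lo)
  tt <- seq(0, 1, length.out = nodes)
  w <- c(1, rep(c(4, 2), length.out = nodes - 2), 1)
  w[nodes - 1] <- 4
  w <- w / sum(w)
  # u: nodes x ncenter
  u <- outer(tt, span) + rep(lo, each = nodes)
  s <- sqrt(pmax(r^2 - (u - rep(cx, each = nodes))^2, 0))
  hi_y <- pmin(s + rep(cy, each = nodes), win[4])
  lo_y <- pmax(rep(cy, each = nodes) - s, win[3])
  len <- pmax(hi_y - lo_y, 0)
  colSums(len * w) * span
}

#' Cross-PCF curves ranked by genome aggressiveness
#'
#' Groups melanocytes by their driver-mutation count (the aggressiveness of
#' the genome), takes the most aggressive group as the reference pattern,
#' and returns one cross-PCF curve per remaining group. Targets are labeled
#' by rank: 2 for the second most aggressive group downwards, with normal
#' cells (zero drivers) last.
#'
#' @param cells A snapshot cell table.
#' @param breaks Annulus edges passed to [cross_pcf()].
#' @param map A [driver_map()].
#' @param window Optional observation window.
#' @return A tibble with columns `rank`, `n_drivers`, `label` and the
#'   [cross_pcf()] columns; class `rank_pcf`.
#' @export
aggressiveness_rank_pcf <- function(cells, breaks, map = driver_map(),
                                    window = NULL) {
  mel <- annotate_cells(cells[cells$type != "CTL", ], map = map)
  counts <- sort(unique(mel$n_drivers), decreasing = TRUE)
  if (length(counts) < 2)
    stop("need at least two distinct driver counts to rank")
  if (is.null(window)) {
    window <- c(min(mel$row) - 0.5, max(mel$row) + 0.5,
                min(mel$col) - 0.5, max(mel$col) + 0.5)
  }
  ref <- mel[mel$n_drivers == counts[1], ]
  out <- purrr::map_dfr(seq_along(counts)[-1], function(i) {
    tar <- mel[mel$n_drivers == counts[i], ]
    curve <- cross_pcf(ref, tar, breaks, window = window)
    dplyr::mutate(curve,
                  rank = i, n_drivers = counts[i],
                  label = ifelse(counts[i] == 0, "NC",
                                 as.character(counts[i])),
                  .before = 1)
  })
  class(out) <- c("rank_pcf", class(out))
  out
}
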