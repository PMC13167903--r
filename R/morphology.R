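#' Binary tumor mask
#'
#' Rasterizes a snapshot to a logical grid that is `TRUE` exactly at sites
#' occupied by melanoma tumor cells; normal cells and CTLs are excluded.
#'
#' @param cells A snapshot cell table.
#' @param dims Grid dimensions `c(nrow, ncol)`.
#' @return A logical `dims[1] x dims[2]` matrix.
#' @export
tumor_mask <- function(cells, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  mtc <- cells[cells$type == "MTC", ]
  m[cbind(mtc$row, mtc$col)] <- TRUE
  m
}

# sub-pixel outer contour (marching squares via contourLines at level 0.5)
# of a mask; smoothing with a short circular moving average removes the
# staircase metrication bias that otherwise inflates the length of smooth
# boundaries by ~6%. Returns the longest closed contour as a two-column
# matrix of vertices.
outer_contour <- function(mask, smooth = 2) {
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- mask * 1
  cl <- grDevices::contourLines(x = seq_len(nr + 2), y = seq_len(nc + 2),
                                z = z, levels = 0.5)
  if (!length(cl)) stop("mask has no contour")
  lens <- vapply(cl, function(co)
    sum(sqrt(diff(co$x)^2 + diff(co$y)^2)), numeric(1))
  co <- cl[[which.max(lens)]]
  x <- co$x[-length(co$x)]; y <- co$y[-length(co$y)]  # closed: drop repeat
  if (smooth > 0 && length(x) >= 2 * smooth + 2) {
    w <- 2 * smooth + 1
    pad <- function(v) c(tail(v, smooth), v, head(v, smooth))
    x <- as.numeric(stats::filter(pad(x), rep(1 / w, w)))[smooth + seq_along(x)]
    y <- as.numeric(stats::filter(pad(y), rep(1 / w, w)))[smooth + seq_along(y)]
  }
  cbind(x, y)
}

polygon_perimeter <- function(v) {
  sum(sqrt(diff(c(v[, 1], v[1, 1]))^2 + diff(c(v[, 2], v[1, 2]))^2))
}

#' Tumor convexity
#'
#' `C = P_H / P` compares the perimeter `P` of the tumor with the perimeter
#' `P_H` of its convex hull (the smallest convex polygon containing all
#' occupied sites). `C = 1` for convex shapes; lower values indicate
#' irregular, infiltrative growth. The measurement uses the largest
#' 8-connected component; `P` is the length of its lightly smoothed
#' marching-squares outer contour (interior holes are not part of the
#' border), and the ratio is clipped to at most 1.
#'
#' @param mask Logical tumor mask ([tumor_mask()]).
#' @param smooth Half-width (in vertices) of the contour smoothing window;
#'   `0` gives the raw marching-squares (staircase) dialect.
#' @return A one-row tibble with columns `C`, `P`, `P_H`, `n_components`,
#'   `n_satellite_cells` (cells outside the largest component).
#' @examples
#' disk <- outer(1:81, 1:81, function(i, j) (i - 41)^2 + (j - 41)^2 <= 30^2)
#' convexity(disk)$C # ~1
#' @export
convexity <- function(mask, smooth = 2) {
  if (sum(mask) < 3) stop("degenerate shape: fewer than 3 occupied sites")
  comp <- mask_largest_component(mask)
  filled <- mask_fill_holes(comp)
  P <- polygon_perimeter(outer_contour(filled, smooth = smooth))
  occ <- which(comp, arr.ind = TRUE)
  hull <- occ[grDevices::chull(occ), , drop = FALSE]
  P_H <- polygon_perimeter(hull)
  ncomp <- count_components(mask)
  tibble::tibble(C = min(1, P_H / P), P = P, P_H = P_H,
                 n_components = ncomp,
                 n_satellite_cells = sum(mask) - sum(comp))
}

count_components <- function(mask) {
  n <- 0L
  rest <- mask
  while (any(rest)) {
    comp <- mask_largest_component(rest)
    rest <- rest & !comp
    n <- n + 1L
  }
  n
}

#' Boundary pixel mask
#'
#' One-pixel outer boundary of the largest 8-connected component: occupied
#' sites (after interior hole filling) with at least one empty 4-neighbor
#' or a grid edge.
#'
#' @inheritParams convexity
#' @return Logical matrix of boundary sites.
#' @export
boundary_mask <- function(mask) {
  if (!any(mask)) stop("empty mask")
  filled <- mask_fill_holes(mask_largest_component(mask))
  nr <- nrow(filled); nc <- ncol(filled)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- filled
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  filled & !interior
}

#' Border fractal dimension
#'
#' Box-counting dimension ([box_counting_fd()]) of the one-pixel boundary
#' of the largest tumor component. Smooth, near-circular borders measure
#' ~1; irregular, spray-like borders measure higher.
#'
#' @inheritParams convexity
#' @return The boundary's box-counting dimension.
#' @export
border_fd <- function(mask) {
  box_counting_fd(boundary_mask(mask))
}

#' One-row morphology report for a snapshot
#'
#' @inheritParams tumor_mask
#' @param step Step label carried into the output.
#' @return A one-row tibble with `step`, `n_mtc`, `C`, `P`, `P_H`, `FD_b`,
#'   `n_components`, `n_satellite_cells`.
#' @export
morphology_report <- function(cells, dims, step = NA_integer_) {
  mask <- tumor_mask(cells, dims)
  cx <- convexity(mask)
  tibble::tibble(step = step, n_mtc = sum(mask),
                 C = cx$C, P = cx$P, P_H = cx$P_H,
                 FD_b = border_fd(mask),
                 n_components = cx$n_components,
                 n_satellite_cells = cx$n_satellite_cells)
}
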