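#' Immune stimulatory factor field
#'
#' The ISF at grid point `h` sums the antigenicities of melanoma cells
#' within Chebyshev distance `isf_radius` of `h`, each weighted by a
#' linear taper `(R + 1 - d) / (R + 1)` in the Chebyshev distance `d`;
#' normal cells contribute nothing. The taper makes the field strictly
#' increase toward every antigenic source, so uphill chemotaxis can home
#' in even on isolated cells (a flat-top kernel would leave CTLs stranded
#' on a field plateau). This is the field CTLs sense for proliferation,
#' killing and chemotaxis; recruitment uses the plain (unweighted) total
#' antigenicity of border tumor cells. The simulation engine maintains the
#' same field incrementally ([state_field()]); this direct implementation
#' exists for analysis of external snapshots and as an independent
#' cross-check.
#'
#' @param cells A snapshot cell table.
#' @param dims Grid dimensions `c(nrow, ncol)`.
#' @param params An [immune_params()].
#' @param map,f Driver map and driver strength used to reconstruct each
#'   cell's antigenicity.
#' @return A `dims[1] x dims[2]` numeric matrix.
#' @export
isf_field <- function(cells, dims, params = immune_params(),
                      map = driver_map(), f = 1.6) {
  FF <- matrix(0, dims[1], dims[2])
  ann <- annotate_cells(cells, map = map, f = f)
  mel <- ann[ann$type %in% c("NC", "MTC") & !is.na(ann$antigenicity) &
               ann$antigenicity > 0, ]
  R <- params$isf_radius
  for (i in seq_len(nrow(mel))) {
    r1 <- max(1, mel$row[i] - R); r2 <- min(dims[1], mel$row[i] + R)
    c1 <- max(1, mel$col[i] - R); c2 <- min(dims[2], mel$col[i] + R)
    d <- outer(abs((r1:r2) - mel$row[i]), abs((c1:c2) - mel$col[i]), pmax)
    FF[r1:r2, c1:c2] <- FF[r1:r2, c1:c2] +
      mel$antigenicity[i] * (R + 1 - d) / (R + 1)
  }
  FF
}

#' Hill-function CTL recruitment rate
#'
#' Expected number of CTLs recruited per step given the total ISF of
#' border tumor cells `F_b`:
#' `s_T = s0 + f_T * F_b^n_T / (gamma_T + F_b^n_T)`.
#' The rate rises strictly with `F_b` from the base rate `s0` and
#' saturates below `s0 + f_T`.
#'
#' @param F_b Total border ISF (nonnegative scalar or vector).
#' @param params An [immune_params()].
#' @return Numeric recruitment rate(s).
#' @examples
#' recruitment_rate(c(0, 10, 1e6), immune_params())
#' @export
recruitment_rate <- function(F_b, params = immune_params()) {
  if (any(F_b < 0)) stop("F_b must be nonnegative")
  h <- F_b^params$n_T
  params$s0 + params$f_T * h / (params$gamma_T + h)
}
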