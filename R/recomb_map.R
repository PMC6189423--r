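#' Location-dependent recombination map
#'
#' Builds a symmetric recombination-rate profile for one chromosome: the
#' relative rate c(p) is minimal at the centromere and rises along each arm
#' toward the telomere following a logistic ramp in relative arm position.
#' This reproduces the canonical Marey-map shape in which genetic distance
#' increases rapidly in distal regions while staying nearly flat across the
#' pericentromere.
#'
#' The rate is parameterised in *relative arm position* t in \[0, 1\]
#' (0 = centromere, 1 = telomere), so the same map remains meaningful as the
#' chromosome shrinks or grows during simulation:
#' \deqn{c(t) = floor + (1 - floor) \frac{s(t) - s(0)}{s(1) - s(0)},\quad
#'       s(t) = \mathrm{logistic}((t - mid)/scale).}
#'
#' @param chromosome_length chromosome length in bp.
#' @param centromere_frac centromere position as a fraction of length.
#' @param mid logistic midpoint in relative arm position (default 0.65).
#' @param scale logistic steepness (default 0.08); smaller = sharper
#'   proximal/distal transition.
#' @param floor minimum relative rate at the centromere, in \[0, 1\].
#'   `floor = 1` yields a uniform map (useful for calibration runs).
#' @param total_cm total genetic map length of the chromosome in cM; used
#'   when converting the relative profile to marker genetic distances.
#' @return an object of class `recomb_map`.
#' @examples
#' m <- recomb_map(2e6)
#' recombination_rate_at(m, c(0, 1e6, 1999999))
#' @export
recomb_map <- function(chromosome_length, centromere_frac = 0.5,
                       mid = 0.65, scale = 0.08, floor = 0.02,
                       total_cm = 120) {
  stopifnot(chromosome_length > 0, centromere_frac > 0, centromere_frac < 1,
            scale > 0, floor >= 0, floor <= 1, total_cm > 0)
  structure(list(chromosome_length = chromosome_length,
                 centromere_frac = centromere_frac,
                 mid = mid, scale = scale, floor = floor,
                 total_cm = total_cm),
            class = "recomb_map")
}

#' @export
print.recomb_map <- function(x, ...) {
  cat(sprintf("recomb_map: %d bp, centromere at %.2f, logistic(mid=%.2f, scale=%.2f), floor=%.2f, %.0f cM\n",
              as.integer(x$chromosome_length), x$centromere_frac, x$mid,
              x$scale, x$floor, x$total_cm))
  invisible(x)
}

# relative arm position of physical positions, given a (possibly updated)
# chromosome length
.arm_fraction <- function(map, position, length = map$chromosome_length) {
  cen <- map$centromere_frac * length
  ifelse(position <= cen,
         (cen - position) / cen,
         (position - cen) / (length - cen))
}

#' Relative recombination rate at physical positions
#'
#' @param map a [recomb_map()].
#' @param position physical position(s) in bp, `0 <= position < length`.
#' @param length current chromosome length in bp; defaults to the length the
#'   map was built with. Passing the evolving length keeps the profile
#'   anchored to relative arm position as the chromosome changes size.
#' @return numeric vector of relative rates in `[floor, 1]`, monotone
#'   non-increasing from each telomere toward the centromere.
#' @export
recombination_rate_at <- function(map, position, length = map$chromosome_length) {
  stopifnot(inherits(map, "recomb_map"))
  if (any(position < 0 | position >= length))
    stop("position out of range [0, length)")
  t <- .arm_fraction(map, position, length)
  s <- stats::plogis((t - map$mid) / map$scale)
  s0 <- stats::plogis((0 - map$mid) / map$scale)
  s1 <- stats::plogis((1 - map$mid) / map$scale)
  u <- (s - s0) / (s1 - s0)
  map$floor + (1 - map$floor) * u
}

#' Cumulative genetic distance along a chromosome
#'
#' Integrates the relative rate profile on a fine grid (trapezoid rule) and
#' rescales so the final value equals the map's stated total map length.
#'
#' @inheritParams recombination_rate_at
#' @param position physical positions (bp) at which cumulative cM is wanted.
#' @param grid_bp integration grid spacing in bp.
#' @return cumulative genetic distance in cM at `position`.
#' @export
cumulative_cm_at <- function(map, position, length = map$chromosome_length,
                             grid_bp = 1000) {
  grid <- seq(0, length - 1, by = grid_bp)
  if (grid[length(grid)] < length - 1) grid <- c(grid, length - 1)
  cvals <- recombination_rate_at(map, grid, length)
  dl <- diff(grid)
  cum <- c(0, cumsum((cvals[-1] + cvals[-length(cvals)]) / 2 * dl))
  total <- cum[length(cum)]
  cm <- stats::approx(grid, cum, xout = pmin(position, length - 1),
                      rule = 2)$y
  cm / total * map$total_cm
}

# mean of c over the whole chromosome (quadrature)
.mean_rate <- function(map, length = map$chromosome_length, grid_bp = 1000) {
  grid <- seq(0, length - 1, by = grid_bp)
  mean(recombination_rate_at(map, grid, length))
}
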