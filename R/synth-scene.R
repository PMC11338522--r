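#' Generate a ground-truth scene of an axon with ER tubule and puncta
#'
#' Builds the simulated "truth" behind a two-channel acquisition: a single
#' centered ER tubule (modeled in projection as a band of half-width
#' `er_tubule_radius_nm`, optionally interrupted by gaps so that it consists
#' of discrete tubule stretches) and `n_puncta` ribosome-like puncta, of
#' which a programmed fraction is ER-bound.
#'
#' Geometry conventions (asserted exactly by the scene invariants):
#' * a bound punctum lies within `bind_distance_nm` of the tubule *surface*:
#'   its transverse coordinate satisfies `| |y| - r | <= bind_distance_nm`,
#'   and its x position falls on a tubule stretch;
#' * an unbound punctum is sampled uniformly over the axon strip and rejected
#'   while its transverse distance to the tubule band (`max(|y| - r, 0)`,
#'   taken over the full axon length whether or not a tubule stretch is
#'   present locally) is strictly less than `bind_distance_nm`, so the two
#'   classes are geometrically separated (a simulator convention that makes
#'   the ground-truth contact fraction identifiable, not a biological
#'   claim). With `bind_distance_nm = 0` no point is rejected and puncta
#'   are uniform over the strip;
#' * the number of bound puncta is `round(bound_fraction * n_puncta)`
#'   (half-up rounding).
#'
#' @param trace An [make_axon_trace()] result.
#' @param n_puncta Number of puncta (>= 0).
#' @param bound_fraction Programmed fraction of ER-bound puncta, in `[0, 1]`.
#' @param bind_distance_nm Maximal distance from the tubule surface at which
#'   a punctum still counts as bound (nm, >= 0).
#' @param er_tubule_radius_nm Tubule radius in projection (nm, > 0).
#' @param seed Integer seed.
#' @param er_coverage Fraction of the axon length covered by tubule
#'   stretches, in `(0, 1]`. 1 gives one uninterrupted tubule.
#' @param er_segment_um Mean length of a tubule stretch when
#'   `er_coverage < 1` (exponentially distributed run lengths).
#' @param branch_density_factor Multiplier on punctum density inside branch
#'   windows (used to program branch-point enrichment; 1 = uniform).
#' @param branch_window_um Half-width does not apply: full window width (um)
#'   centered on each branch point over which the factor acts.
#' @param amplitude Common punctum amplitude (arbitrary units).
#' @return A `gt_scene` with the trace, tubule intervals and a puncta tibble
#'   (`x_nm`, `y_nm`, `amplitude`, `bound`).
#' @examples
#' tr <- make_axon_trace(10, width_nm = 400)
#' sc <- make_scene(tr, n_puncta = 200, bound_fraction = 0.45,
#'                  bind_distance_nm = 30, er_tubule_radius_nm = 80, seed = 3)
#' sum(sc$puncta$bound)
#' @export
make_scene <- function(trace, n_puncta, bound_fraction, bind_distance_nm,
                       er_tubule_radius_nm, seed = 1L,
                       er_coverage = 1, er_segment_um = 5,
                       branch_density_factor = 1, branch_window_um = 2,
                       amplitude = 1) {
  if (!inherits(trace, "axon_trace")) {
    abort("`trace` must be an axon_trace.", class = "axc_error_parameter")
  }
  if (!is.numeric(bound_fraction) || bound_fraction < 0 || bound_fraction > 1) {
    abort("`bound_fraction` must lie in [0, 1].", class = "axc_error_parameter")
  }
  if (n_puncta < 0) abort("`n_puncta` must be >= 0.", class = "axc_error_parameter")
  if (bind_distance_nm < 0) abort("`bind_distance_nm` must be >= 0.",
                                  class = "axc_error_parameter")
  if (er_tubule_radius_nm <= 0) abort("`er_tubule_radius_nm` must be > 0.",
                                      class = "axc_error_parameter")
  if (er_coverage <= 0 || er_coverage > 1) {
    abort("`er_coverage` must lie in (0, 1].", class = "axc_error_parameter")
  }
  half_w <- trace$width_nm / 2
  r <- er_tubule_radius_nm
  if (r + bind_distance_nm >= half_w && bound_fraction < 1) {
    abort(paste0("Axon too narrow: need width/2 > er_tubule_radius_nm + ",
                 "bind_distance_nm to place unbound puncta."),
          class = "axc_error_parameter")
  }
  L <- trace$length_nm

  er_intervals <- with_seed(seed_stream(seed, "er"), {
    draw_er_intervals(L, er_coverage, er_segment_um * 1000)
  })

  n_bound <- as.integer(round_half_up(bound_fraction * n_puncta))
  n_unbound <- as.integer(n_puncta) - n_bound

  xw <- branch_weight_fun(trace, branch_density_factor, branch_window_um * 1000)

  bound <- with_seed(seed_stream(seed, "bound"), {
    sample_bound_puncta(n_bound, er_intervals, r, bind_distance_nm, half_w, xw)
  })
  unbound <- with_seed(seed_stream(seed, "unbound"), {
    sample_unbound_puncta(n_unbound, L, half_w, r, bind_distance_nm, xw)
  })

  puncta <- dplyr::bind_rows(bound, unbound)
  puncta$amplitude <- rep(as.numeric(amplitude), length.out = nrow(puncta))
  puncta <- puncta[, c("x_nm", "y_nm", "amplitude", "bound")]

  structure(
    list(trace = trace,
         er_tubule_radius_nm = r,
         er_intervals = er_intervals,
         puncta = tibble::as_tibble(puncta),
         bound_fraction = bound_fraction,
         bind_distance_nm = bind_distance_nm,
         er_coverage = er_coverage,
         seed = as.integer(seed)),
    class = "gt_scene"
  )
}

#' @export
print.gt_scene <- function(x, ...) {
  cat(sprintf(paste0("<gt_scene> %.1f um axon, tubule r = %.0f nm over ",
                     "%.0f%% of length, %d puncta (%d bound)\n"),
              x$trace$length_nm / 1000, x$er_tubule_radius_nm,
              100 * sum(x$er_intervals$end_nm - x$er_intervals$start_nm) /
                x$trace$length_nm,
              nrow(x$puncta), sum(x$puncta$bound)))
  invisible(x)
}

# Alternating on/off runs with exponential lengths; returns tibble of
# tubule stretches. Coverage 1 short-circuits to a single interval.
draw_er_intervals <- function(L, coverage, mean_on_nm) {
  if (coverage >= 1) {
    return(tibble(start_nm = 0, end_nm = L))
  }
  mean_off_nm <- mean_on_nm * (1 - coverage) / coverage
  pos <- 0
  on <- runif(1) < coverage
  starts <- c(); ends <- c()
  while (pos < L) {
    len <- stats::rexp(1, 1 / if (on) mean_on_nm else mean_off_nm)
    if (on) {
      starts <- c(starts, pos)
      ends <- c(ends, min(pos + len, L))
    }
    pos <- pos + len
    on <- !on
  }
  if (length(starts) == 0) {         # degenerate draw: force one stretch
    starts <- 0; ends <- min(mean_on_nm, L)
  }
  tibble(start_nm = starts, end_nm = ends)
}

# Piecewise-constant x-density over [0, L]; branch windows get `factor`.
branch_weight_fun <- function(trace, factor, window_nm) {
  L <- trace$length_nm
  bp <- trace$branch_points_nm
  if (factor == 1 || length(bp) == 0) {
    return(list(breaks = c(0, L), weights = 1))
  }
  lo <- pmax(bp - window_nm / 2, 0)
  hi <- pmin(bp + window_nm / 2, L)
  edges <- sort(unique(c(0, lo, hi, L)))
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  w <- vapply(mids, function(m) {
    if (any(m >= lo & m <= hi)) factor else 1
  }, numeric(1))
  list(breaks = edges, weights = w)
}

# Restrict a piecewise x-density to a union of intervals, then sample.
sample_x_in_intervals <- function(n, intervals, xw) {
  edges <- sort(unique(c(xw$breaks,
                         intervals$start_nm, intervals$end_nm)))
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  base <- xw$weights[pmax(findInterval(mids, xw$breaks,
                                       rightmost.closed = TRUE), 1)]
  inside <- vapply(mids, function(m) {
    any(m >= intervals$start_nm & m <= intervals$end_nm)
  }, logical(1))
  sample_piecewise(n, edges, base * inside)
}

sample_bound_puncta <- function(n, intervals, r, bind, half_w, xw) {
  if (n == 0) {
    return(tibble(x_nm = numeric(0), y_nm = numeric(0), bound = logical(0)))
  }
  if (nrow(intervals) == 0) {
    abort("Cannot place bound puncta: no ER tubule present.",
          class = "axc_error_parameter")
  }
  x <- sample_x_in_intervals(n, intervals, xw)
  # |y| uniform over the binding shell [max(0, r - bind), min(r + bind, axon)]
  lo <- max(0, r - bind)
  hi <- min(r + bind, half_w)
  mag <- runif(n, lo, hi)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  tibble(x_nm = x, y_nm = sgn * mag, bound = rep(TRUE, n))
}

# Transverse distance from y to the tubule band |y| <= r, taken over the
# full axon length: the unbound clearance is a property of the band, not of
# individual tubule stretches, so that gaps in ER coverage do not correlate
# the unbound class with the mask support.
band_distance <- function(y, r) {
  pmax(abs(y) - r, 0)
}

sample_unbound_puncta <- function(n, L, half_w, r, bind, xw) {
  if (n == 0) {
    return(tibble(x_nm = numeric(0), y_nm = numeric(0), bound = logical(0)))
  }
  out_x <- numeric(0); out_y <- numeric(0)
  guard <- 0L
  while (length(out_x) < n) {
    m <- max(2L * (n - length(out_x)), 32L)
    x <- sample_piecewise(m, xw$breaks, xw$weights)
    y <- runif(m, -half_w, half_w)
    keep <- band_distance(y, r) >= bind   # strict exclusion of d < bind
    out_x <- c(out_x, x[keep]); out_y <- c(out_y, y[keep])
    guard <- guard + 1L
    if (guard > 1000L) {
      abort("Unbound punctum sampling failed: exclusion zone covers the axon.",
            class = "axc_error_parameter")
    }
  }
  tibble(x_nm = out_x[seq_len(n)], y_nm = out_y[seq_len(n)],
         bound = rep(FALSE, n))
}
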