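#' Generate a straightened axon trace
#'
#' The geometric backbone of every simulated experiment: a horizontal
#' polyline standing for an axon segment that has already been straightened
#' (as segments drawn along distal axons are before quantification). Branch
#' points, when requested, are positions along the arc where a collateral
#' emerges; they carry no geometry of their own but mark windows of elevated
#' punctum density for branch-versus-shaft comparisons.
#'
#' @param length_um Arc length of the segment in micrometres (>= 1).
#' @param width_nm Axon caliber (strip width) in nanometres.
#' @param n_branches Number of branch points to place uniformly along the arc.
#' @param seed Integer seed; identical calls are bit-reproducible.
#' @return An `axon_trace`: vertices tibble (`x_nm`, `y_nm`), `width_nm`,
#'   `length_nm` and sorted `branch_points_nm`.
#' @examples
#' tr <- make_axon_trace(30, width_nm = 500, n_branches = 3, seed = 1)
#' tr$branch_points_nm
#' @export
make_axon_trace <- function(length_um, width_nm = 500, n_branches = 0L,
                            seed = 1L) {
  if (!is.numeric(length_um) || length_um < 1) {
    abort("`length_um` must be a number >= 1.", class = "axc_error_parameter")
  }
  if (width_nm <= 0) {
    abort("`width_nm` must be positive.", class = "axc_error_parameter")
  }
  if (n_branches < 0) {
    abort("`n_branches` must be a non-negative count.",
          class = "axc_error_parameter")
  }
  length_nm <- length_um * 1000
  xs <- unique(c(seq(0, length_nm, by = 1000), length_nm))
  branches <- if (n_branches > 0) {
    with_seed(seed_stream(seed, "branches"),
              sort(runif(n_branches, 0, length_nm)))
  } else {
    numeric(0)
  }
  structure(
    list(vertices = tibble(x_nm = xs, y_nm = rep(0, length(xs))),
         width_nm = as.numeric(width_nm),
         length_nm = length_nm,
         branch_points_nm = branches,
         seed = as.integer(seed)),
    class = "axon_trace"
  )
}

#' @export
print.axon_trace <- function(x, ...) {
  cat(sprintf("<axon_trace> %.1f um long, %.0f nm wide, %d branch point(s)\n",
              x$length_nm / 1000, x$width_nm, length(x$branch_points_nm)))
  invisible(x)
}

# Accept an axon_trace or a bare vertex table; returns a vertex matrix in nm.
trace_vertices <- function(trace) {
  if (inherits(trace, "axon_trace")) {
    as.matrix(trace$vertices[, c("x_nm", "y_nm")])
  } else if (is.data.frame(trace) && all(c("x_nm", "y_nm") %in% names(trace))) {
    as.matrix(trace[, c("x_nm", "y_nm")])
  } else {
    abort("`trace` must be an axon_trace or a data frame with x_nm, y_nm.",
          class = "axc_error_parameter")
  }
}
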