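#' Overlapping bin grid for time- or phase-locked pooling
#'
#' Time grids have 50 centers evenly spaced from -100 to 600 ms with a
#' 200 ms full window; phase grids have 50 centers evenly spaced over the
#' circle (7.2 degrees apart, starting at 0) with a 45-degree full window
#' and wrap-around membership.
#'
#' @param kind `"time"` or `"phase"`.
#' @param n_bins number of bins (default 50).
#' @param width full window width: seconds for time (default 0.2), degrees
#'   for phase (default 45).
#' @param time_range numeric(2), seconds (default `c(-0.1, 0.6)`).
#' @return object of class `bin_grid` with `centers` and `width`.
#' @export
bin_grid <- function(kind = c("time", "phase"), n_bins = 50, width = NULL,
                     time_range = c(-0.1, 0.6)) {
  kind <- match.arg(kind)
  if (kind == "time") {
    if (is.null(width)) width <- 0.2
    centers <- seq(time_range[1], time_range[2], length.out = n_bins)
  } else {
    if (is.null(width)) width <- 45
    centers <- seq(0, 360, length.out = n_bins + 1)[seq_len(n_bins)]
  }
  structure(list(kind = kind, centers = centers, width = width,
                 n_bins = n_bins), class = "bin_grid")
}

## circular distance in degrees, in [-180, 180)
.circ_dist <- function(a, b) ((a - b + 180) %% 360) - 180

#' Pool trial measures into overlapping bins
#'
#' A trial belongs to bin `k` iff the (circular, for phase grids) distance
#' from its click coordinate to the bin center is within half the window
#' width: inclusive on the left edge, exclusive on the right. Excluded
#' trials are never pooled.
#'
#' @param trials data.frame with columns `click_phase` (degrees) or
#'   `click_delay` (seconds), `excluded` (logical, optional), and the
#'   requested measure.
#' @param grid a [bin_grid()].
#' @param measure column name of the targeted measure.
#' @return object of class `bin_series`: list with `grid`, `measure`,
#'   `values` (list of per-bin ensembles), `trial_ids` (list),
#'   `n_events` (integer vector).
#' @export
pool <- function(trials, grid, measure) {
  stopifnot(inherits(grid, "bin_grid"))
  if (!measure %in% names(trials))
    stop("unknown measure: ", measure)
  coord_col <- if (grid$kind == "phase") "click_phase" else "click_delay"
  if (!coord_col %in% names(trials))
    stop("trials lack the ", coord_col, " column")
  keep <- if ("excluded" %in% names(trials)) !trials$excluded else
    rep(TRUE, nrow(trials))
  keep <- keep & !is.na(trials[[coord_col]])
  tr <- trials[keep, , drop = FALSE]
  ids <- which(keep)
  half <- grid$width / 2
  values <- vector("list", grid$n_bins)
  trial_ids <- vector("list", grid$n_bins)
  for (k in seq_len(grid$n_bins)) {
    d <- if (grid$kind == "phase")
      .circ_dist(tr[[coord_col]], grid$centers[k])
    else tr[[coord_col]] - grid$centers[k]
    member <- d >= -half & d < half
    member <- member & !is.na(tr[[measure]])
    values[[k]] <- tr[[measure]][member]
    trial_ids[[k]] <- ids[member]
  }
  structure(list(grid = grid, measure = measure, values = values,
                 trial_ids = trial_ids,
                 n_events = lengths(values)),
            class = "bin_series")
}

#' Across-subject histogram of bin event counts
#'
#' @param series_list list of `bin_series`, one per subject, on the same
#'   grid.
#' @return data.frame with `center`, `mean_n`, `sd_n`.
#' @export
bin_histogram <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  counts <- vapply(series_list, `[[`, numeric(
    series_list[[1]]$grid$n_bins), "n_events")
  counts <- matrix(counts, ncol = length(series_list))
  data.frame(center = series_list[[1]]$grid$centers,
             mean_n = apply(counts, 1, mean),
             sd_n = if (ncol(counts) > 1) apply(counts, 1, stats::sd)
                    else rep(0, nrow(counts)))
}

#' @export
print.bin_series <- function(x, ...) {
  cat("bin_series:", x$grid$kind, "grid,", x$grid$n_bins, "bins, measure =",
      x$measure, "\n  events per bin:",
      paste(range(x$n_events), collapse = "-"), "\n")
  invisible(x)
}
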