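#' Lane path
#'
#' A lane is a 2-D region of the image described by a polyline of control
#' nodes `(y, x, w)`: at image row `y` (0-based, may be fractional) the lane
#' center sits at column `x` with half-width `w` pixels. Center and
#' half-width are interpolated linearly between nodes, so lanes can be
#' straight or curved and their width can vary down the gel. Node rows must
#' be strictly increasing: a lane may never be horizontal at any segment,
#' because the profile is a function of the vertical (migration)
#' coordinate.
#'
#' @param nodes a data frame (or tibble) with numeric columns `y`, `x`,
#'   `w`, one row per node, ordered top to bottom; or a numeric matrix with
#'   3 columns in that order.
#' @return A `lane_path` tibble with columns `y`, `x`, `w`.
#' @examples
#' lane_path(data.frame(y = c(0, 99), x = c(10, 12), w = 3))
#' @export
lane_path <- function(nodes) {
  if (is.matrix(nodes)) {
    nodes <- as.data.frame(nodes)
    names(nodes) <- c("y", "x", "w")
  }
  if (!all(c("y", "x", "w") %in% names(nodes))) {
    stop("lane path nodes need columns y, x, w", call. = FALSE)
  }
  p <- tibble::as_tibble(nodes[, c("y", "x", "w")])
  if (nrow(p) < 2L) {
    stop("a lane path needs at least 2 nodes", call. = FALSE)
  }
  if (!all(vapply(p, is.numeric, logical(1))) || !all(is.finite(as.matrix(p)))) {
    stop("lane path nodes must be finite numerics", call. = FALSE)
  }
  if (any(diff(p$y) <= 0)) {
    stop("horizontal segment: lane node rows must be strictly increasing",
         call. = FALSE)
  }
  if (any(p$w <= 0)) {
    stop("lane half-widths must be > 0", call. = FALSE)
  }
  class(p) <- c("lane_path", class(p))
  p
}

#' Validate a lane path against an image
#'
#' Checks that node rows are strictly increasing (no horizontal segment),
#' that there are at least two nodes, and that the path's rows lie inside
#' the image. A lane whose width extends past the left or right image edge
#' is permitted — the width sum is clipped at the edges — but a message is
#' logged, since this usually follows a tight crop.
#'
#' @param p a [lane_path()] (or coercible node table).
#' @param image_shape integer vector `c(H, W)` or the raster itself.
#' @return The validated `lane_path`, invisibly unchanged.
#' @export
validate_lane_path <- function(p, image_shape) {
  p <- lane_path(p)
  if (inherits(image_shape, "gel_raster") || is.matrix(image_shape)) {
    image_shape <- dim(image_shape)
  }
  h <- image_shape[1]; w <- image_shape[2]
  if (min(p$y) < 0 || max(p$y) > h - 1) {
    stop(sprintf("lane path rows [%g, %g] outside image rows [0, %d]",
                 min(p$y), max(p$y), h - 1L), call. = FALSE)
  }
  if (any(p$x - p$w < 0) || any(p$x + p$w > w - 1)) {
    message("lane region extends past the left/right image edge; ",
            "width sums will be clipped to image columns")
  }
  p
}

#' Lane center and half-width at a row
#'
#' Linear interpolation of the lane's center column and half-width between
#' the bracketing nodes; exact at nodes. Vectorized over `y`.
#'
#' @param p a [lane_path()].
#' @param y row coordinate(s), within the path's row span.
#' @return A tibble with columns `y`, `x`, `w`.
#' @export
lane_center <- function(p, y) {
  p <- lane_path(p)
  if (any(y < p$y[1] - 1e-12) || any(y > p$y[nrow(p)] + 1e-12)) {
    stop(sprintf("row outside lane span [%g, %g]", p$y[1], p$y[nrow(p)]),
         call. = FALSE)
  }
  tibble::tibble(
    y = y,
    x = approx(p$y, p$x, xout = y, rule = 2)$y,
    w = approx(p$y, p$w, xout = y, rule = 2)$y
  )
}

#' Per-row lane intensity profile
#'
#' For every integer image row spanned by the lane path, sums the raster
#' intensities of the columns whose integer center lies within the lane's
#' half-width at that row: `p[y] = sum over x with |x - x_c(y)| <= w(y)` of
#' `r[y, x]`, columns clipped to the image. Integration is horizontal
#' (along the row), not perpendicular to the path, so the profile is
#' intensity as a function of the vertical migration coordinate and is an
#' exact pixel sum (units: intensity * px).
#'
#' @param r a [gel_raster()] or numeric matrix (background-subtracted).
#' @param p a [lane_path()], validated against `r`.
#' @return A `gel_profile` tibble with columns `row` (0-based integer image
#'   row) and `intensity`.
#' @export
lane_profile <- function(r, p) {
  m <- as_pixel_matrix(r)
  p <- validate_lane_path(p, dim(m))
  y0 <- ceiling(p$y[1])
  y1 <- floor(p$y[nrow(p)])
  rows <- seq.int(y0, y1)
  cent <- lane_center(p, rows)
  vals <- vapply(seq_along(rows), function(i) {
    lo <- max(0L, ceiling(cent$x[i] - cent$w[i]))
    hi <- min(ncol(m) - 1L, floor(cent$x[i] + cent$w[i]))
    if (lo > hi) return(0)
    sum(m[rows[i] + 1L, (lo + 1L):(hi + 1L)])
  }, numeric(1))
  out <- tibble::tibble(row = rows, intensity = vals)
  class(out) <- c("gel_profile", class(out))
  out
}

#' Per-lane baseline
#'
#' The residual background level under a lane's profile, subtracted before
#' band integration. Piecewise linear through user-set anchors `(y, b)`,
#' constant extrapolation beyond the first/last anchor. The default
#' baseline is a single anchor at 0, i.e. zero everywhere — appropriate
#' when whole-image background subtraction already levelled the profile.
#'
#' @param anchors data frame with numeric columns `y` (strictly increasing
#'   rows) and `b` (values >= 0), or `NULL` for the default zero baseline.
#' @return A `gel_baseline`.
#' @export
gel_baseline <- function(anchors = NULL) {
  if (is.null(anchors)) {
    anchors <- data.frame(y = 0, b = 0)
  }
  if (is.matrix(anchors)) {
    anchors <- as.data.frame(anchors)
    names(anchors) <- c("y", "b")
  }
  if (!all(c("y", "b") %in% names(anchors))) {
    stop("baseline anchors need columns y and b", call. = FALSE)
  }
  a <- tibble::as_tibble(anchors[, c("y", "b")])
  if (nrow(a) > 1L && any(diff(a$y) <= 0)) {
    stop("baseline anchor rows must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(a$b)) || any(a$b < 0)) {
    stop("baseline values must be finite and >= 0", call. = FALSE)
  }
  structure(list(anchors = a), class = "gel_baseline")
}

#' Evaluate a baseline at image rows
#'
#' @param b a [gel_baseline()].
#' @param y row(s) at which to evaluate.
#' @return Numeric vector of baseline values (piecewise linear between
#'   anchors, constant beyond the ends).
#' @export
baseline_at <- function(b, y) {
  stopifnot(inherits(b, "gel_baseline"))
  a <- b$anchors
  if (nrow(a) == 1L) return(rep(a$b, length(y)))
  approx(a$y, a$b, xout = y, rule = 2)$y
}

#' Measurement region
#'
#' Half-open vertical interval `[y0, y1)` of image rows over which the
#' profile-minus-baseline difference is integrated.
#'
#' @param y0,y1 integer rows, `y0 < y1`.
#' @export
measurement_region <- function(y0, y1) {
  if (y0 != round(y0) || y1 != round(y1)) {
    stop("region bounds must be integers", call. = FALSE)
  }
  if (y0 >= y1) stop("region needs y0 < y1 (half-open [y0, y1))", call. = FALSE)
  structure(list(y0 = as.integer(y0), y1 = as.integer(y1)),
            class = "measurement_region")
}

#' Estimate a per-lane baseline from off-band profile rows
#'
#' Anchors a baseline at a region's bounds with the mean profile intensity
#' over a window of rows just outside the region (a `gap` of rows is
#' skipped so band tails do not leak in). This automates the manual
#' "adjust the background reference for each lane" step for the common case
#' where residual background varies smoothly under a band.
#'
#' @param profile a `gel_profile` from [lane_profile()].
#' @param region a [measurement_region()].
#' @param gap rows skipped between the region bound and the window.
#' @param width window length in rows.
#' @return A [gel_baseline()] with anchors at `y0` and `y1`. Windows that
#'   fall entirely outside the profile contribute an anchor of 0.
#' @export
auto_baseline <- function(profile, region, gap = 1, width = 5) {
  stopifnot(inherits(region, "measurement_region"))
  win_mean <- function(lo, hi) {
    v <- profile$intensity[profile$row >= lo & profile$row <= hi]
    if (length(v) == 0) 0 else max(mean(v), 0)
  }
  below <- win_mean(region$y0 - gap - width, region$y0 - gap - 1)
  above <- win_mean(region$y1 + gap, region$y1 + gap + width - 1)
  gel_baseline(data.frame(y = c(region$y0, region$y1), b = c(below, above)))
}

#' Integrate a profile over a region
#'
#' The raw measurement value is the discrete sum of the lane profile minus
#' its baseline over the region's rows: `v = sum_{y in [y0, y1)} (p[y] -
#' baseline(y))`, in units of intensity * px^2. A negative value is allowed
#' (the baseline sits above the signal) but triggers a warning. The success
#' flag starts `TRUE`; mark failed measurements downstream.
#'
#' @param profile a `gel_profile` from [lane_profile()].
#' @param baseline a [gel_baseline()]; default zero baseline.
#' @param region a [measurement_region()] within the profile's row span.
#' @param lane_index,measurement_type attached to the result unchanged.
#' @return One-row tibble: `lane_index`, `measurement_type`, `value`,
#'   `success`.
#' @export
measure <- function(profile, baseline = gel_baseline(), region,
                    lane_index = NA_integer_, measurement_type = NA_character_) {
  stopifnot(inherits(region, "measurement_region"))
  if (region$y0 < min(profile$row) || region$y1 > max(profile$row) + 1L) {
    stop(sprintf("region [%d, %d) outside profile rows [%d, %d]",
                 region$y0, region$y1, min(profile$row), max(profile$row)),
         call. = FALSE)
  }
  rows <- seq.int(region$y0, region$y1 - 1L)
  p <- profile$intensity[match(rows, profile$row)]
  v <- sum(p - baseline_at(baseline, rows))
  if (v < 0) {
    warning("negative measurement value: baseline lies above the lane signal",
            call. = FALSE)
  }
  tibble::tibble(lane_index = as.integer(lane_index),
                 measurement_type = measurement_type,
                 value = v, success = TRUE)
}
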