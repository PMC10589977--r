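#' Background subtraction specification
#'
#' Describes how the smooth image background is estimated and removed
#' before lane profiling. `"rolling_ball"` estimates the background as the
#' grayscale morphological opening of the image with a flat disc of the
#' given radius and subtracts it; features narrower than the disc (bands)
#' survive, smooth structure (planar illumination gradients, broad stains)
#' is removed. `"flat_percentile"` subtracts a single global intensity
#' percentile, clamping at zero. `"none"` returns a copy.
#'
#' The flat-disc opening is exactly anti-extensive (output <= input, never
#' negative), idempotent, and scale-equivariant, which makes downstream
#' normalization exactly invariant to exposure scaling.
#'
#' @param method one of `"rolling_ball"`, `"flat_percentile"`, `"none"`.
#' @param radius disc radius in pixels (rolling ball); default 50.
#' @param percentile fraction in (0, 1] (flat percentile).
#' @return A `background_spec`.
#' @examples
#' background_spec("rolling_ball", radius = 30)
#' @export
background_spec <- function(method = c("rolling_ball", "flat_percentile", "none"),
                            radius = 50, percentile = 0.2) {
  method <- match.arg(method)
  if (method == "rolling_ball") {
    if (!is.finite(radius) || radius < 1) {
      stop("rolling-ball radius must be >= 1 pixel", call. = FALSE)
    }
    radius <- as.numeric(radius)
  }
  if (method == "flat_percentile") {
    if (!is.finite(percentile) || percentile <= 0 || percentile > 1) {
      stop("percentile must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(method = method,
                 radius = if (method == "rolling_ball") radius else NULL,
                 percentile = if (method == "flat_percentile") percentile else NULL),
            class = "background_spec")
}

#' @export
print.background_spec <- function(x, ...) {
  cat("<background_spec>", background_param_string(x), "\n")
  invisible(x)
}

#' Canonical parameter string of a background spec (for the analysis log)
#' @param spec a [background_spec()].
#' @return JSON string.
#' @export
background_param_string <- function(spec) {
  canonical_json(spec[!vapply(spec, is.null, logical(1))])
}

# ---- flat-disc grayscale morphology -----------------------------------
#
# Domain-restricted min/max: pixels outside the image do not participate
# (erosion treats them as +Inf, dilation as -Inf). With this border rule
# the opening is anti-extensive, idempotent and exactly scale-equivariant.
# The disc {(dy,dx): dy^2+dx^2 <= r^2} is decomposed into horizontal runs;
# row-wise running minima for all half-run lengths are built incrementally
# (2 pmin per length), then combined across row offsets.

shift_cols <- function(m, d, fill) {
  w <- ncol(m)
  if (d == 0L) return(m)
  out <- matrix(fill, nrow(m), w)
  if (abs(d) >= w) return(out)
  if (d > 0L) out[, 1:(w - d)] <- m[, (1L + d):w]
  else out[, (1L - d):w] <- m[, 1:(w + d)]
  out
}

shift_rows <- function(m, d, fill) {
  h <- nrow(m)
  if (d == 0L) return(m)
  out <- matrix(fill, h, ncol(m))
  if (abs(d) >= h) return(out)
  if (d > 0L) out[1:(h - d), ] <- m[(1L + d):h, ]
  else out[(1L - d):h, ] <- m[1:(h + d), ]
  out
}

disc_halfruns <- function(radius) {
  dy <- 0:floor(radius)
  floor(sqrt(radius^2 - dy^2))
}

morph_disc <- function(m, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  comb <- if (op == "erode") pmin else pmax
  fill <- if (op == "erode") Inf else -Inf
  runs <- disc_halfruns(radius)     # half run length for dy = 0..r
  lmax <- runs[1]
  # running row-window extrema for every half-length 0..lmax
  rm_by_l <- vector("list", lmax + 1L)
  rm_by_l[[1L]] <- m
  if (lmax >= 1L) {
    for (l in 1:lmax) {
      rm_by_l[[l + 1L]] <- comb(rm_by_l[[l]],
                                shift_cols(m, l, fill),
                                shift_cols(m, -l, fill))
    }
  }
  out <- rm_by_l[[runs[1] + 1L]]
  r_int <- length(runs) - 1L
  if (r_int >= 1L) {
    for (dy in 1:r_int) {
      band <- rm_by_l[[runs[dy + 1L] + 1L]]
      out <- comb(out, shift_rows(band, dy, fill), shift_rows(band, -dy, fill))
    }
  }
  out
}

#' Grayscale opening with a flat disc
#'
#' Erosion followed by dilation with the disc `{(dy, dx): dy^2 + dx^2 <=
#' radius^2}`, both restricted to the image domain. This is the background
#' estimate of the rolling-ball method.
#'
#' @param m numeric matrix or [gel_raster()].
#' @param radius disc radius in pixels.
#' @return Numeric matrix of the same shape.
#' @export
disc_opening <- function(m, radius) {
  m <- as_pixel_matrix(m)
  morph_disc(morph_disc(m, radius, "erode"), radius, "dilate")
}

#' Subtract the image background
#'
#' Applies the method described by a [background_spec()] to a signal-high
#' raster. The result is elementwise `<=` the input and never negative; for
#' `"rolling_ball"` the minimum of the residual is exactly 0 (the opening
#' touches the image at its global minimum).
#'
#' @param r a [gel_raster()] or numeric matrix (signal-high).
#' @param spec a [background_spec()].
#' @return Background-subtracted [gel_raster()].
#' @examples
#' r <- gel_raster(matrix(7, 20, 20))
#' max(subtract_background(r, background_spec("rolling_ball", radius = 5)))
#' @export
subtract_background <- function(r, spec) {
  stopifnot(inherits(spec, "background_spec"))
  m <- as_pixel_matrix(r)
  out <- switch(spec$method,
    none = m,
    rolling_ball = {
      if (spec$radius > min(dim(m))) {
        stop(sprintf("rolling-ball radius %g exceeds the smaller image side (%d px)",
                     spec$radius, min(dim(m))), call. = FALSE)
      }
      m - disc_opening(m, spec$radius)
    },
    flat_percentile = {
      pmax(m - as.numeric(quantile(m, spec$percentile, names = FALSE)), 0)
    })
  reraster(out, r)
}
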