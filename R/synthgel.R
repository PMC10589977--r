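#' Synthetic gel image specification
#'
#' Describes a synthetic gel/membrane image with known ground truth: a set
#' of lanes whose centers follow `x(y) = x0 + curvature * (y - H/2)^2`,
#' Gaussian bands riding each lane's curved center, a smooth background
#' (planar illumination gradient plus one broad Gaussian blob), and seeded
#' Gaussian pixel noise. Because every band's injected amount is known
#' exactly, these images are the package's universal validation fixture.
#'
#' @param height,width image size in pixels.
#' @param lanes tibble with columns `x0` (center column at mid-height),
#'   `curvature` (px^-1), `half_width` (px).
#' @param bands tibble with columns `lane` (1-based index into `lanes`),
#'   `mu` (band center row), `sigma_y`, `sigma_x` (band spread, px),
#'   `amount` (total injected intensity `A`).
#' @param background list with `offset`, `slope_x`, `slope_y` (intensity
#'   per px), `blob_amplitude`, `blob_sigma`, `blob_x`, `blob_y`.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity).
#' @param seed RNG seed; the same spec renders bit-identically.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(height, width, lanes, bands,
                       background = list(offset = 0, slope_x = 0, slope_y = 0,
                                         blob_amplitude = 0, blob_sigma = 1,
                                         blob_x = width / 2, blob_y = height / 2),
                       noise_sd = 0, seed = 1L) {
  lanes <- tibble::as_tibble(lanes)
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("x0", "curvature", "half_width") %in% names(lanes)),
            height >= 1, width >= 1, noise_sd >= 0)
  if (nrow(bands) > 0) {
    stopifnot(all(c("lane", "mu", "sigma_y", "sigma_x", "amount") %in% names(bands)))
    if (any(bands$amount <= 0)) stop("band amounts must be > 0", call. = FALSE)
    if (any(bands$lane < 1 | bands$lane > nrow(lanes))) {
      stop("band refers to a lane that does not exist", call. = FALSE)
    }
  }
  bg_defaults <- list(offset = 0, slope_x = 0, slope_y = 0, blob_amplitude = 0,
                      blob_sigma = 1, blob_x = width / 2, blob_y = height / 2)
  background <- utils::modifyList(bg_defaults, background)
  spec <- structure(list(height = as.integer(height), width = as.integer(width),
                         lanes = lanes, bands = bands, background = background,
                         noise_sd = noise_sd, seed = as.integer(seed)),
                    class = "synth_spec")
  validate_synth_spec(spec)
  spec
}

lane_center_fun <- function(spec, lane) {
  l <- spec$lanes[lane, ]
  function(y) l$x0 + l$curvature * (y - spec$height / 2)^2
}

validate_synth_spec <- function(spec) {
  h <- spec$height; w <- spec$width
  if (nrow(spec$bands) > 0) {
    for (k in seq_len(nrow(spec$bands))) {
      b <- spec$bands[k, ]
      xc <- lane_center_fun(spec, b$lane)
      ys <- seq(max(0, b$mu - 3 * b$sigma_y), min(h - 1, b$mu + 3 * b$sigma_y),
                length.out = 25)
      if (b$mu - 3 * b$sigma_y < 0 || b$mu + 3 * b$sigma_y > h - 1 ||
          any(xc(ys) - 3 * b$sigma_x < 0) || any(xc(ys) + 3 * b$sigma_x > w - 1)) {
        stop(sprintf("band outside image: lane %d band at row %g does not fit at 3 sigma",
                     b$lane, b$mu), call. = FALSE)
      }
    }
    # lanes must be separated by at least 3 sigma of their widest bands
    ys <- seq(0, h - 1, length.out = 50)
    ord <- order(spec$lanes$x0)
    for (i in seq_len(nrow(spec$lanes) - 1L)) {
      a <- ord[i]; b <- ord[i + 1L]
      sa <- max(spec$bands$sigma_x[spec$bands$lane == a], 0)
      sb <- max(spec$bands$sigma_x[spec$bands$lane == b], 0)
      gap <- min(abs(lane_center_fun(spec, b)(ys) - lane_center_fun(spec, a)(ys)))
      if (gap < 3 * (sa + sb)) {
        stop(sprintf("overlapping lanes: %d and %d closer than 3 sigma (gap %.1f px)",
                     a, b, gap), call. = FALSE)
      }
    }
  }
  invisible(spec)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render a synthetic gel image
#'
#' Evaluates every band's 2-D Gaussian (following its lane's curved center)
#' at integer pixel centers, adds the smooth background and seeded Gaussian
#' noise, and clamps at zero. The sum of a rendered band over the image
#' equals its injected amount to within discretization (< 0.5% for sigma
#' >= 1.5 px).
#'
#' @param spec a [synth_spec()].
#' @return A list: `raster` (a [gel_raster()]), `truth` (list with per-band
#'   tibble `bands` including `rendered_mass`, per-lane `lane_totals`, and
#'   the noise-free `background` matrix).
#' @examples
#' sp <- synth_spec(60, 40,
#'   lanes = tibble::tibble(x0 = 20, curvature = 0, half_width = 8),
#'   bands = tibble::tibble(lane = 1, mu = 30, sigma_y = 4, sigma_x = 3,
#'                          amount = 1000))
#' g <- synth_gel(sp)
#' sum(g$raster)  # close to 1000
#' @export
synth_gel <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  h <- spec$height; w <- spec$width
  ys <- 0:(h - 1); xs <- 0:(w - 1)
  img <- matrix(0, h, w)
  band_mass <- numeric(nrow(spec$bands))
  if (nrow(spec$bands) > 0) {
    for (k in seq_len(nrow(spec$bands))) {
      b <- spec$bands[k, ]
      xc <- lane_center_fun(spec, b$lane)(ys)
      field <- b$amount * dnorm(ys, b$mu, b$sigma_y) *
        dnorm(outer(xc, xs, function(c, x) x - c), 0, b$sigma_x)
      band_mass[k] <- sum(field)
      img <- img + field
    }
  }
  bg <- spec$background
  bgfield <- bg$offset +
    bg$slope_x * matrix(xs, h, w, byrow = TRUE) +
    bg$slope_y * matrix(ys, h, w) +
    bg$blob_amplitude * exp(-(outer(ys - bg$blob_y, xs - bg$blob_x,
                                    function(a, b) a^2 + b^2)) /
                              (2 * bg$blob_sigma^2))
  img <- img + bgfield
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed, matrix(rnorm(h * w, 0, spec$noise_sd), h, w))
  }
  img <- pmax(img, 0)
  bands <- spec$bands
  if (nrow(bands) > 0) bands$rendered_mass <- band_mass
  lane_totals <- if (nrow(bands) > 0) {
    dplyr::summarise(dplyr::group_by(bands, lane = .data$lane),
                     total = sum(.data$amount), .groups = "drop")
  } else tibble::tibble(lane = integer(), total = numeric())
  list(raster = gel_raster(img),
       truth = list(bands = bands, lane_totals = lane_totals,
                    background = bgfield))
}

#' Lane paths of a synthetic gel
#'
#' Polyline approximations of the spec's quadratic lane centers, one node
#' every `step` rows (chord error is far below a pixel for realistic
#' curvatures).
#'
#' @param spec a [synth_spec()].
#' @param step node spacing in rows.
#' @return List of [lane_path()] objects, one per lane.
#' @export
synth_lane_paths <- function(spec, step = 20) {
  purrr::map(seq_len(nrow(spec$lanes)), function(i) {
    ys <- unique(c(seq(0, spec$height - 1, by = step), spec$height - 1))
    lane_path(tibble::tibble(y = ys,
                             x = lane_center_fun(spec, i)(ys),
                             w = spec$lanes$half_width[i]))
  })
}

#' Vertical integration regions around each band
#'
#' Half-open row regions `[mu - k*sigma_y, mu + k*sigma_y)` (rounded
#' outward, clipped to the image) for every band, for driving bounded
#' integration in tests and pipelines.
#'
#' @param spec a [synth_spec()].
#' @param k half-extent in band sigmas; default 4.
#' @return Tibble `lane`, `band`, `y0`, `y1`, `amount`.
#' @export
synth_band_regions <- function(spec, k = 4) {
  b <- spec$bands
  tibble::tibble(
    lane = b$lane,
    band = seq_len(nrow(b)),
    y0 = pmax(0L, as.integer(floor(b$mu - k * b$sigma_y))),
    y1 = pmin(spec$height, as.integer(ceiling(b$mu + k * b$sigma_y)) + 1L),
    amount = b$amount
  )
}

#' Default study-condition synthetic gel
#'
#' A 360 x 300 px gel with 5 curved lanes and 3 bands per lane, a planar
#' illumination gradient plus a broad blob, and Gaussian noise at 1% of the
#' peak band intensity. Band amounts, positions and curvatures are drawn
#' reproducibly from `seed`. These are the package's standard validation
#' conditions.
#'
#' @param seed integer seed controlling both layout and rendered noise.
#' @param n_lanes,n_bands layout dimensions.
#' @param height,width image size in pixels.
#' @return A [synth_spec()].
#' @export
default_synth_spec <- function(seed = 1L, n_lanes = 5L, n_bands = 3L,
                               height = 360L, width = 300L) {
  with_seed(seed, {
    x0 <- seq(40, width - 40, length.out = n_lanes)
    lanes <- tibble::tibble(
      x0 = x0,
      curvature = runif(n_lanes, 1e-4, 4e-4),
      half_width = 12
    )
    bands <- tidyr::expand_grid(lane = seq_len(n_lanes), band = seq_len(n_bands))
    bands <- tibble::tibble(
      lane = bands$lane,
      mu = 70 + (bands$band - 1) * 100 + runif(nrow(bands), -8, 8),
      sigma_y = runif(nrow(bands), 4, 6),
      sigma_x = 4,
      amount = runif(nrow(bands), 2e4, 8e4)
    )
    peak <- max(bands$amount / (2 * pi * bands$sigma_x * bands$sigma_y))
    synth_spec(height, width, lanes, bands,
               background = list(offset = 20, slope_x = 0.04, slope_y = 0.02,
                                 blob_amplitude = 30, blob_sigma = 120,
                                 blob_x = width / 3, blob_y = height / 2),
               noise_sd = 0.01 * peak, seed = seed)
  })
}

#' Render a reference panel with designated reference lanes
#'
#' Builds a gel whose lanes carry stated protein amounts and reference
#' flags, so the true normalized value of every lane is known:
#' `w_j = (A_j / m_j) / mean over reference lanes of (A_i / m_i)`.
#'
#' @param spec a [synth_spec()].
#' @param protein numeric vector of loaded amounts, one per lane.
#' @param reference logical vector marking reference lanes; at least one.
#' @return A list: `raster`, `truth` (as [synth_gel()], plus `true_w`),
#'   `lanes` (a [lane_records()] tibble).
#' @export
render_reference_panel <- function(spec, protein, reference) {
  stopifnot(length(protein) == nrow(spec$lanes),
            length(reference) == nrow(spec$lanes))
  if (!any(reference)) stop("no reference lane designated", call. = FALSE)
  g <- synth_gel(spec)
  totals <- g$truth$lane_totals$total[order(g$truth$lane_totals$lane)]
  per_mass <- totals / protein
  r_true <- mean(per_mass[reference])
  g$truth$true_w <- tibble::tibble(lane_index = seq_along(totals),
                                   w = per_mass / r_true)
  g$lanes <- lane_records(seq_along(totals),
                          sprintf("S%02d", seq_along(totals)),
                          protein, reference)
  g
}

#' Write a synthetic gel fixture to disk
#'
#' Writes the rendered image as a 16-bit TIFF (intensities rounded to
#' integers) plus a canonical-JSON ground-truth sidecar, and returns the
#' spec re-rendered from the quantized image so that file-based pipelines
#' see exactly what replay will see.
#'
#' @param spec a [synth_spec()].
#' @param prefix output path prefix; writes `<prefix>.tif` and
#'   `<prefix>_truth.json`.
#' @return Invisibly, a list with `tif`, `truth_json` paths and the `truth`
#'   tibble list.
#' @export
write_synth_fixture <- function(spec, prefix) {
  g <- synth_gel(spec)
  tif <- paste0(prefix, ".tif")
  write_gel_tiff(g$raster, tif)
  truth_json <- paste0(prefix, "_truth.json")
  truth <- list(
    bands = purrr::transpose(as.list(g$truth$bands)),
    lane_totals = purrr::transpose(as.list(g$truth$lane_totals)),
    noise_sd = spec$noise_sd, seed = spec$seed
  )
  writeLines(canonical_json(truth), truth_json)
  invisible(list(tif = tif, truth_json = truth_json, truth = g$truth))
}
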