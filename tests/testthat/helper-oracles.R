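# Independent brute-force oracles. These deliberately use nothing from the
# implementation paths they check: plain nested loops and direct formulas.

brute_crop <- function(m, top, left, height, width) {
  out <- matrix(NA_real_, height, width)
  for (i in seq_len(height)) {
    for (j in seq_len(width)) {
      out[i, j] <- m[top + i, left + j]   # top/left are 0-based
    }
  }
  out
}

brute_disc_opening <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  offs <- expand.grid(dy = -floor(r):floor(r), dx = -floor(r):floor(r))
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  er <- matrix(NA_real_, h, w)
  for (y in 1:h) for (x in 1:w) {
    ys <- y + offs$dy; xs <- x + offs$dx
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    er[y, x] <- min(m[cbind(ys[ok], xs[ok])])
  }
  di <- matrix(NA_real_, h, w)
  for (y in 1:h) for (x in 1:w) {
    ys <- y + offs$dy; xs <- x + offs$dx
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    di[y, x] <- max(er[cbind(ys[ok], xs[ok])])
  }
  di
}

# per-row pixel-loop lane summation, 0-based coordinates as in the API
brute_lane_profile <- function(m, nodes) {
  interp <- function(ys, vs, y) {
    i <- max(which(ys <= y + 1e-12))
    if (i == length(ys)) return(vs[i])
    t <- (y - ys[i]) / (ys[i + 1] - ys[i])
    (1 - t) * vs[i] + t * vs[i + 1]
  }
  y0 <- ceiling(nodes$y[1]); y1 <- floor(nodes$y[nrow(nodes)])
  rows <- y0:y1
  vals <- numeric(length(rows))
  for (k in seq_along(rows)) {
    y <- rows[k]
    xc <- interp(nodes$y, nodes$x, y)
    wc <- interp(nodes$y, nodes$w, y)
    s <- 0
    for (x in 0:(ncol(m) - 1)) {
      if (abs(x - xc) <= wc) s <- s + m[y + 1, x + 1]
    }
    vals[k] <- s
  }
  data.frame(row = rows, intensity = vals)
}

random_monotone_path <- function(h, w, n_nodes = 4) {
  ys <- sort(runif(n_nodes, 0, h - 1))
  while (any(diff(ys) < 1)) ys <- sort(runif(n_nodes, 0, h - 1))
  lane_path(tibble::tibble(y = ys,
                           x = runif(n_nodes, 3, w - 4),
                           w = runif(n_nodes, 1.5, 6)))
}

# builds a small analyzed store in a temp dir and returns handles
make_analyzed_store <- function(dir, seed = 7) {
  sp <- synth_spec(120, 120,
                   lanes = tibble::tibble(x0 = c(25, 60, 95), curvature = 1e-4,
                                          half_width = 9),
                   bands = tibble::tibble(lane = 1:3, mu = 60, sigma_y = 4,
                                          sigma_x = 3,
                                          amount = c(10000, 20000, 10000)),
                   background = list(offset = 5, slope_x = 0.02, slope_y = 0.01),
                   noise_sd = 0.5, seed = seed)
  fx <- write_synth_fixture(sp, file.path(dir, "gel"))
  store <- open_gel_store(file.path(dir, "store.db"))
  gel_id <- add_gel(store, "membrane-1", "synthetic fixture",
                    projects = "tests/panels")
  image_id <- add_image(store, gel_id, fx$tif)
  set_lane_records(store, image_id,
                   lane_records(1:3, c("REF", "S1", "S2"), c(1, 2, 1),
                                c(TRUE, FALSE, FALSE)))
  paths <- synth_lane_paths(sp)
  params <- list(
    crop = NULL,
    background = list(method = "rolling_ball", radius = 20),
    measurement_type = "GAPDH",
    lanes = purrr::imap(paths, function(p, i) list(
      lane_index = i, path = p, baseline = NULL, regions = list(c(30, 91)))))
  mm <- analyze_image(store, image_id, params)
  list(store = store, image_id = image_id, gel_id = gel_id,
       measurements = mm, spec = sp, tif = fx$tif)
}

# the package's standard quantification pipeline on one synthetic gel:
# rolling-ball subtraction, true lane paths, auto per-lane baselines,
# bounded integration around each band
recover_bands <- function(spec, radius = 50) {
  g <- synth_gel(spec)
  r <- subtract_background(g$raster, background_spec("rolling_ball", radius = radius))
  paths <- synth_lane_paths(spec)
  regs <- synth_band_regions(spec)
  out <- lapply(seq_len(nrow(spec$lanes)), function(i) {
    prof <- suppressMessages(lane_profile(r, paths[[i]]))
    rr <- regs[regs$lane == i, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(rr)), function(k) {
      region <- measurement_region(rr$y0[k], rr$y1[k])
      bl <- auto_baseline(prof, region)
      data.frame(lane = i, amount = rr$amount[k],
                 value = measure(prof, bl, region)$value)
    }))
  })
  do.call(rbind, out)
}
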