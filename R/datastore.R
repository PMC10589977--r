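GEL_SCHEMA_VERSION <- 1L

# All objects live under the gel_* prefix so the layout ports unchanged to
# a server database schema. The three user-facing views mirror the data
# access a statistician needs: project paths, per-image reference values,
# and normalized values for every measurement.
gel_schema_sql <- function() {
  c(
    "CREATE TABLE gel_meta (key TEXT PRIMARY KEY, value TEXT NOT NULL)",
    "CREATE TABLE gel_project (
       id INTEGER PRIMARY KEY,
       name TEXT NOT NULL,
       parent_id INTEGER REFERENCES gel_project(id),
       UNIQUE(parent_id, name))",
    "CREATE TABLE gel_gel (
       id INTEGER PRIMARY KEY,
       name TEXT NOT NULL,
       comment TEXT NOT NULL DEFAULT '')",
    "CREATE TABLE gel_gel_project (
       gel_id INTEGER NOT NULL REFERENCES gel_gel(id),
       project_id INTEGER NOT NULL REFERENCES gel_project(id),
       UNIQUE(gel_id, project_id))",
    "CREATE TABLE gel_measurement_type (
       id INTEGER PRIMARY KEY,
       name TEXT NOT NULL UNIQUE)",
    "CREATE TABLE gel_image (
       id INTEGER PRIMARY KEY,
       gel_id INTEGER NOT NULL REFERENCES gel_gel(id),
       path TEXT NOT NULL,
       content_hash TEXT NOT NULL,
       invert INTEGER NOT NULL DEFAULT 0)",
    "CREATE TABLE gel_lane (
       id INTEGER PRIMARY KEY,
       image_id INTEGER NOT NULL REFERENCES gel_image(id),
       lane_index INTEGER NOT NULL,
       sample_id TEXT,
       protein REAL,
       is_reference INTEGER NOT NULL DEFAULT 0,
       UNIQUE(image_id, lane_index))",
    "CREATE TABLE gel_measurement (
       id INTEGER PRIMARY KEY,
       image_id INTEGER NOT NULL REFERENCES gel_image(id),
       lane_index INTEGER NOT NULL,
       measurement_type_id INTEGER NOT NULL REFERENCES gel_measurement_type(id),
       region_y0 INTEGER NOT NULL,
       region_y1 INTEGER NOT NULL,
       value REAL NOT NULL,
       success INTEGER NOT NULL DEFAULT 1,
       profile_json TEXT,
       UNIQUE(image_id, measurement_type_id, lane_index, region_y0, region_y1))",
    "CREATE TABLE gel_analysis_step (
       id INTEGER PRIMARY KEY,
       image_id INTEGER NOT NULL REFERENCES gel_image(id),
       step_index INTEGER NOT NULL,
       operation TEXT NOT NULL,
       params TEXT NOT NULL,
       UNIQUE(image_id, step_index))",
    "CREATE VIEW gel_view_project_paths AS
       WITH RECURSIVE pp(id, path) AS (
         SELECT id, name FROM gel_project WHERE parent_id IS NULL
         UNION ALL
         SELECT p.id, pp.path || '/' || p.name
           FROM gel_project p JOIN pp ON p.parent_id = pp.id)
       SELECT id AS project_id, path FROM pp",
    "CREATE VIEW gel_view_reference_measurements AS
       SELECT i.gel_id, g.name AS gel, m.image_id,
              m.measurement_type_id, t.name AS measurement_type,
              AVG(m.value / l.protein) AS r, COUNT(*) AS n_reference
         FROM gel_measurement m
         JOIN gel_image i ON i.id = m.image_id
         JOIN gel_gel g ON g.id = i.gel_id
         JOIN gel_lane l
           ON l.image_id = m.image_id AND l.lane_index = m.lane_index
         JOIN gel_measurement_type t ON t.id = m.measurement_type_id
        WHERE l.is_reference = 1 AND m.success = 1 AND l.protein IS NOT NULL
        GROUP BY m.image_id, m.measurement_type_id",
    "CREATE VIEW gel_view_normalized AS
       SELECT i.gel_id, g.name AS gel, m.image_id,
              rv.measurement_type, m.lane_index, l.sample_id, l.protein,
              l.is_reference, m.region_y0, m.region_y1, m.value, rv.r,
              (m.value / l.protein) / rv.r AS w
         FROM gel_measurement m
         JOIN gel_image i ON i.id = m.image_id
         JOIN gel_gel g ON g.id = i.gel_id
         JOIN gel_lane l
           ON l.image_id = m.image_id AND l.lane_index = m.lane_index
         JOIN gel_view_reference_measurements rv
           ON rv.image_id = m.image_id
          AND rv.measurement_type_id = m.measurement_type_id
        WHERE m.success = 1 AND l.protein IS NOT NULL"
  )
}

#' Open (or create) an embedded analysis store
#'
#' A single SQLite file holds the full metadata model — projects, gels,
#' images, lanes, measurement types, measurements — and the ordered,
#' parameter-complete analysis log for every image. Open with `readonly =
#' TRUE` for a viewing-mode handle: browsing and the views work, any
#' mutation is rejected by the database.
#'
#' @param path path of the store file; created if absent (unless readonly).
#' @param readonly open in viewing mode.
#' @return A `gel_store` handle. Close with [close_gel_store()].
#' @export
open_gel_store <- function(path, readonly = FALSE) {
  is_new <- !file.exists(path)
  if (is_new && readonly) {
    stop("cannot open a non-existent store read-only: ", path, call. = FALSE)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path,
                        flags = if (readonly) RSQLite::SQLITE_RO
                                else RSQLite::SQLITE_RWC)
  store <- structure(list(con = con, path = path, readonly = readonly),
                     class = "gel_store")
  if (is_new) {
    for (sql in gel_schema_sql()) DBI::dbExecute(con, sql)
    DBI::dbExecute(con, "INSERT INTO gel_meta VALUES ('schema_version', ?)",
                   params = list(as.character(GEL_SCHEMA_VERSION)))
  } else {
    ver <- tryCatch(
      as.integer(DBI::dbGetQuery(con,
        "SELECT value FROM gel_meta WHERE key = 'schema_version'")$value),
      error = function(e) NA_integer_)
    if (length(ver) != 1L || is.na(ver)) {
      DBI::dbDisconnect(con)
      stop("not a gel analysis store: ", path, call. = FALSE)
    }
    if (ver > GEL_SCHEMA_VERSION) {
      DBI::dbDisconnect(con)
      stop(sprintf(
        "store schema version %d is newer than this software supports (%d); upgrade the package",
        ver, GEL_SCHEMA_VERSION), call. = FALSE)
    }
  }
  store
}

#' @rdname open_gel_store
#' @param store a `gel_store`.
#' @export
close_gel_store <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.gel_store <- function(x, ...) {
  cat(sprintf("<gel_store> %s (%s)\n", x$path,
              if (x$readonly) "viewing" else "editing"))
  invisible(x)
}

check_writable <- function(store) {
  if (isTRUE(store$readonly)) {
    stop("store is open in viewing mode; reopen with readonly = FALSE to edit",
         call. = FALSE)
  }
}

#' Create a project (and any missing ancestors) from a path string
#'
#' Projects form a hierarchy like a file system; `"group/blotting/2026"`
#' creates up to three nested projects. Idempotent: existing components are
#' reused.
#'
#' @param store a `gel_store`.
#' @param path_string project path with `/` separators; no empty
#'   components.
#' @return One-row tibble `project_id`, `path`.
#' @export
create_project <- function(store, path_string) {
  check_writable(store)
  parts <- strsplit(path_string, "/", fixed = TRUE)[[1]]
  if (length(parts) == 0L || any(!nzchar(parts))) {
    stop("empty project name component in: '", path_string, "'", call. = FALSE)
  }
  parent <- NA_integer_
  for (name in parts) {
    row <- if (is.na(parent)) {
      DBI::dbGetQuery(store$con,
        "SELECT id FROM gel_project WHERE name = ? AND parent_id IS NULL",
        params = list(name))
    } else {
      DBI::dbGetQuery(store$con,
        "SELECT id FROM gel_project WHERE name = ? AND parent_id = ?",
        params = list(name, parent))
    }
    if (nrow(row) == 0L) {
      DBI::dbExecute(store$con,
        "INSERT INTO gel_project (name, parent_id) VALUES (?, ?)",
        params = list(name, if (is.na(parent)) NA else parent))
      parent <- as.integer(DBI::dbGetQuery(store$con,
        "SELECT last_insert_rowid() AS id")$id)
    } else {
      parent <- row$id[1]
    }
  }
  tibble::tibble(project_id = parent, path = paste(parts, collapse = "/"))
}

#' Register a gel
#'
#' @param store a `gel_store`.
#' @param name gel name.
#' @param comment free-text comment.
#' @param projects character vector of project path strings to link the gel
#'   to (created as needed); a gel may belong to zero or more projects.
#' @return The gel id (integer).
#' @export
add_gel <- function(store, name, comment = "", projects = character()) {
  check_writable(store)
  DBI::dbExecute(store$con, "INSERT INTO gel_gel (name, comment) VALUES (?, ?)",
                 params = list(name, comment))
  gel_id <- as.integer(DBI::dbGetQuery(store$con,
    "SELECT last_insert_rowid() AS id")$id)
  for (p in projects) link_gel_project(store, gel_id, p)
  gel_id
}

#' @rdname add_gel
#' @param gel_id integer gel id.
#' @param project_path project path string.
#' @export
link_gel_project <- function(store, gel_id, project_path) {
  check_writable(store)
  pr <- create_project(store, project_path)
  DBI::dbExecute(store$con,
    "INSERT OR IGNORE INTO gel_gel_project (gel_id, project_id) VALUES (?, ?)",
    params = list(gel_id, pr$project_id))
  invisible(pr$project_id)
}

#' Register a measurement type (antibody target, stain, ...)
#'
#' Idempotent on the unique name.
#' @param store a `gel_store`.
#' @param name type name, e.g. `"GAPDH"` or `"Ponceau"`.
#' @return The type id.
#' @export
add_measurement_type <- function(store, name) {
  check_writable(store)
  DBI::dbExecute(store$con,
    "INSERT OR IGNORE INTO gel_measurement_type (name) VALUES (?)",
    params = list(name))
  as.integer(DBI::dbGetQuery(store$con,
    "SELECT id FROM gel_measurement_type WHERE name = ?",
    params = list(name))$id)
}

#' Attach an image file to a gel
#'
#' The file's SHA-256 content hash is recorded at ingest; replay refuses to
#' run if the file later changes.
#'
#' @param store a `gel_store`.
#' @param gel_id gel id from [add_gel()].
#' @param path image file path (TIFF/PNG/JPEG).
#' @param invert polarity flag passed to [read_gel_image()] on every
#'   (re)load of this image.
#' @return The image id.
#' @export
add_image <- function(store, gel_id, path, invert = FALSE) {
  check_writable(store)
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  hash <- digest::digest(file = path, algo = "sha256")
  DBI::dbExecute(store$con,
    "INSERT INTO gel_image (gel_id, path, content_hash, invert) VALUES (?, ?, ?, ?)",
    params = list(gel_id, normalizePath(path), hash, as.integer(invert)))
  as.integer(DBI::dbGetQuery(store$con, "SELECT last_insert_rowid() AS id")$id)
}

#' Set the lane records of an image
#'
#' Replaces the image's sample table: one row per lane with sample id,
#' protein amount and reference flag (see [lane_records()]).
#'
#' @param store a `gel_store`.
#' @param image_id image id.
#' @param lanes a [lane_records()] tibble.
#' @return Invisibly, the number of lanes written.
#' @export
set_lane_records <- function(store, image_id, lanes) {
  check_writable(store)
  lanes <- lane_records(lanes$lane_index, lanes$sample_id, lanes$protein,
                        lanes$is_reference)
  DBI::dbExecute(store$con, "DELETE FROM gel_lane WHERE image_id = ?",
                 params = list(image_id))
  for (i in seq_len(nrow(lanes))) {
    DBI::dbExecute(store$con,
      "INSERT INTO gel_lane (image_id, lane_index, sample_id, protein, is_reference)
       VALUES (?, ?, ?, ?, ?)",
      params = list(image_id, lanes$lane_index[i], lanes$sample_id[i],
                    if (is.na(lanes$protein[i])) NA else lanes$protein[i],
                    as.integer(lanes$is_reference[i])))
  }
  invisible(nrow(lanes))
}

ANALYSIS_OPERATIONS <- c("crop", "background", "lane")

#' Append a step to an image's analysis log
#'
#' Every operation applied to an image is recorded in order with its
#' complete parameters in canonical JSON, so the whole analysis can be
#' re-executed later and must reproduce the stored results exactly.
#'
#' @param store a `gel_store`.
#' @param image_id image id.
#' @param operation one of `"crop"`, `"background"`, `"lane"`.
#' @param params named list of the operation's parameters.
#' @return The 0-based step index.
#' @export
record_step <- function(store, image_id, operation, params) {
  check_writable(store)
  if (!operation %in% ANALYSIS_OPERATIONS) {
    stop("unknown operation '", operation, "'; expected one of: ",
         paste(ANALYSIS_OPERATIONS, collapse = ", "), call. = FALSE)
  }
  n <- DBI::dbGetQuery(store$con,
    "SELECT COUNT(*) AS n FROM gel_analysis_step WHERE image_id = ?",
    params = list(image_id))$n
  DBI::dbExecute(store$con,
    "INSERT INTO gel_analysis_step (image_id, step_index, operation, params)
     VALUES (?, ?, ?, ?)",
    params = list(image_id, n, operation, canonical_json(params)))
  as.integer(n)
}

#' Read an image's analysis log
#' @param store a `gel_store`.
#' @param image_id image id.
#' @return Tibble `step_index`, `operation`, `params` (canonical JSON).
#' @export
analysis_log <- function(store, image_id) {
  tibble::as_tibble(DBI::dbGetQuery(store$con,
    "SELECT step_index, operation, params FROM gel_analysis_step
      WHERE image_id = ? ORDER BY step_index",
    params = list(image_id)))
}

#' Mark a stored measurement as successful or failed
#'
#' Failed measurements stay in the store but are excluded from reference
#' averaging and from the normalized view.
#'
#' @param store a `gel_store`.
#' @param measurement_id row id in the measurement table.
#' @param success logical.
#' @export
set_measurement_success <- function(store, measurement_id, success) {
  check_writable(store)
  n <- DBI::dbExecute(store$con,
    "UPDATE gel_measurement SET success = ? WHERE id = ?",
    params = list(as.integer(success), measurement_id))
  if (n == 0L) stop("no such measurement: ", measurement_id, call. = FALSE)
  invisible(TRUE)
}

#' Stored measurements of an image
#' @param store a `gel_store`.
#' @param image_id image id.
#' @return Tibble of stored measurement rows.
#' @export
stored_measurements <- function(store, image_id) {
  tibble::as_tibble(DBI::dbGetQuery(store$con,
    "SELECT m.id, m.image_id, m.lane_index, t.name AS measurement_type,
            m.region_y0, m.region_y1, m.value, m.success
       FROM gel_measurement m
       JOIN gel_measurement_type t ON t.id = m.measurement_type_id
      WHERE m.image_id = ?
      ORDER BY m.lane_index, m.region_y0",
    params = list(image_id))) |>
    dplyr::mutate(success = as.logical(.data$success))
}

# ---- analysis driver ---------------------------------------------------

lane_step_params <- function(lane_index, measurement_type, path, baseline,
                             region) {
  list(
    lane_index = lane_index,
    measurement_type = measurement_type,
    path = purrr::pmap(path, function(y, x, w) list(y = y, x = x, w = w)),
    baseline = if (is.null(baseline)) NULL else
      purrr::pmap(baseline$anchors, function(y, b) list(y = y, b = b)),
    region = list(y0 = region$y0, y1 = region$y1)
  )
}

apply_logged_steps <- function(raster, steps) {
  # returns list(raster = final raster, measurements = tibble, profiles = list)
  measurements <- list()
  profiles <- list()
  for (i in seq_len(nrow(steps))) {
    op <- steps$operation[i]
    par <- parse_canonical_json(steps$params[i])
    if (op == "crop") {
      raster <- crop(raster, crop_rect(par$top, par$left, par$height, par$width))
    } else if (op == "background") {
      spec <- background_spec(par$method,
                              radius = par$radius %||% 50,
                              percentile = par$percentile %||% 0.2)
      raster <- subtract_background(raster, spec)
    } else if (op == "lane") {
      nodes <- tibble::tibble(
        y = vapply(par$path, `[[`, numeric(1), "y"),
        x = vapply(par$path, `[[`, numeric(1), "x"),
        w = vapply(par$path, `[[`, numeric(1), "w"))
      p <- validate_lane_path(lane_path(nodes), dim(raster))
      prof <- lane_profile(raster, p)
      bl <- if (is.null(par$baseline)) gel_baseline() else
        gel_baseline(tibble::tibble(
          y = vapply(par$baseline, `[[`, numeric(1), "y"),
          b = vapply(par$baseline, `[[`, numeric(1), "b")))
      reg <- measurement_region(par$region$y0, par$region$y1)
      mm <- measure(prof, bl, reg, lane_index = par$lane_index,
                    measurement_type = par$measurement_type)
      mm$region_y0 <- reg$y0
      mm$region_y1 <- reg$y1
      measurements[[length(measurements) + 1L]] <- mm
      profiles[[length(profiles) + 1L]] <-
        canonical_json(list(y_start = prof$row[1], values = prof$intensity))
    } else {
      stop("unknown logged operation: ", op, call. = FALSE)
    }
  }
  list(raster = raster,
       measurements = dplyr::bind_rows(measurements),
       profiles = profiles)
}

load_image_record <- function(store, image_id, check_hash = TRUE) {
  rec <- DBI::dbGetQuery(store$con,
    "SELECT id, gel_id, path, content_hash, invert FROM gel_image WHERE id = ?",
    params = list(image_id))
  if (nrow(rec) == 0L) stop("no such image: ", image_id, call. = FALSE)
  if (!file.exists(rec$path)) {
    stop("source image file missing: ", rec$path, call. = FALSE)
  }
  if (check_hash) {
    h <- digest::digest(file = rec$path, algo = "sha256")
    if (h != rec$content_hash) {
      stop("source image changed since ingest (content hash mismatch): ",
           rec$path, call. = FALSE)
    }
  }
  rec
}

#' Run a full image analysis and record every step
#'
#' Applies crop (optional), background subtraction, and per-lane profile +
#' baseline + bounded integration according to a parameter list, records
#' each operation in the analysis log, and stores the resulting raw
#' measurement values and profiles.
#'
#' @param store a `gel_store`.
#' @param image_id image id (file and polarity come from the image record).
#' @param params list with elements:
#'   * `crop`: `NULL` or list `top, left, height, width`;
#'   * `background`: list `method` plus `radius` / `percentile`;
#'   * `measurement_type`: type name (created if new);
#'   * `lanes`: list of lane analyses, each a list with `lane_index`,
#'     `path` (node table or list), optional `baseline` (anchor table),
#'     and `regions` (list of `c(y0, y1)` pairs).
#' @return Tibble of stored measurements.
#' @export
analyze_image <- function(store, image_id, params) {
  check_writable(store)
  rec <- load_image_record(store, image_id)
  type_id <- add_measurement_type(store, params$measurement_type)
  steps <- list()
  if (!is.null(params$crop)) {
    steps[[length(steps) + 1L]] <- list(op = "crop", par = params$crop)
  }
  bg <- params$background %||% list(method = "none")
  steps[[length(steps) + 1L]] <- list(op = "background",
                                      par = bg[!vapply(bg, is.null, logical(1))])
  for (ln in params$lanes) {
    nodes <- if (is.data.frame(ln$path)) tibble::as_tibble(ln$path) else
      tibble::tibble(
        y = vapply(ln$path, function(n) as.numeric(n[[1]]), numeric(1)),
        x = vapply(ln$path, function(n) as.numeric(n[[2]]), numeric(1)),
        w = vapply(ln$path, function(n) as.numeric(n[[3]]), numeric(1)))
    bl <- if (is.null(ln$baseline)) NULL
      else if (inherits(ln$baseline, "gel_baseline")) ln$baseline
      else if (is.data.frame(ln$baseline)) gel_baseline(ln$baseline)
      else gel_baseline(tibble::tibble(
        y = vapply(ln$baseline, function(a) as.numeric(a[[1]]), numeric(1)),
        b = vapply(ln$baseline, function(a) as.numeric(a[[2]]), numeric(1))))
    for (reg in ln$regions) {
      region <- if (inherits(reg, "measurement_region")) reg else
        measurement_region(reg[[1]], reg[[2]])
      steps[[length(steps) + 1L]] <- list(
        op = "lane",
        par = lane_step_params(ln$lane_index, params$measurement_type,
                               nodes, bl, region))
    }
  }
  # record the log first, then execute it: what runs is exactly what is stored
  for (s in steps) record_step(store, image_id, s$op, s$par)
  raster <- read_gel_image(rec$path, invert = as.logical(rec$invert))
  res <- apply_logged_steps(raster, analysis_log(store, image_id))
  mm <- res$measurements
  for (i in seq_len(nrow(mm))) {
    DBI::dbExecute(store$con,
      "INSERT OR REPLACE INTO gel_measurement
         (image_id, lane_index, measurement_type_id, region_y0, region_y1,
          value, success, profile_json)
       VALUES (?, ?, ?, ?, ?, ?, 1, ?)",
      params = list(image_id, mm$lane_index[i], type_id, mm$region_y0[i],
                    mm$region_y1[i], mm$value[i], res$profiles[[i]]))
  }
  stored_measurements(store, image_id)
}

#' Replay a stored analysis and verify it
#'
#' Re-reads the source image (refusing if its content hash changed),
#' re-executes every logged step in order, and compares the recomputed raw
#' values and profiles with the stored ones. Any difference — including a
#' tampered stored value — is an error. With an empty log, returns no
#' measurements.
#'
#' @param store a `gel_store`.
#' @param image_id image id.
#' @return Tibble of verified measurements (`value` recomputed == stored).
#' @export
replay_image <- function(store, image_id) {
  rec <- load_image_record(store, image_id)
  steps <- analysis_log(store, image_id)
  if (nrow(steps) == 0L) {
    return(tibble::tibble(lane_index = integer(), measurement_type = character(),
                          region_y0 = integer(), region_y1 = integer(),
                          value = numeric(), success = logical()))
  }
  raster <- read_gel_image(rec$path, invert = as.logical(rec$invert))
  res <- apply_logged_steps(raster, steps)
  stored <- stored_measurements(store, image_id)
  mm <- res$measurements
  key <- function(d) paste(d$lane_index, d$measurement_type, d$region_y0, d$region_y1)
  idx <- match(key(mm), key(stored))
  if (anyNA(idx) || nrow(stored) != nrow(mm)) {
    stop("replay mismatch: stored measurement set differs from the analysis log",
         call. = FALSE)
  }
  same <- vapply(seq_len(nrow(mm)),
                 function(i) identical(mm$value[i], stored$value[idx[i]]),
                 logical(1))
  if (!all(same)) {
    bad <- which(!same)
    stop(sprintf(
      "replay mismatch: %d stored value(s) differ from recomputation (e.g. lane %d: stored %.17g, replayed %.17g)",
      length(bad), mm$lane_index[bad[1]], stored$value[idx[bad[1]]],
      mm$value[bad[1]]), call. = FALSE)
  }
  # profiles must match bit-identically through their canonical serialization
  stored_prof <- DBI::dbGetQuery(store$con,
    "SELECT profile_json FROM gel_measurement WHERE image_id = ?
      ORDER BY lane_index, region_y0", params = list(image_id))$profile_json
  ord <- order(mm$lane_index, mm$region_y0)
  if (!identical(unlist(res$profiles)[ord], stored_prof)) {
    stop("replay mismatch: stored lane profiles differ from recomputation",
         call. = FALSE)
  }
  dplyr::select(stored[idx, ], -dplyr::any_of("id"))
}

# ---- views -------------------------------------------------------------

#' The three user views
#'
#' Read-only tabular views over the store, matching what a statistician
#' needs to pull into an analysis: every project with its full path; the
#' per-image reference value `r` (mean of `v/m` over successful reference
#' lanes) with the reference count; and the normalized value `w` for every
#' successful measurement.
#'
#' @param store a `gel_store`.
#' @return A tibble.
#' @export
view_project_paths <- function(store) {
  tibble::as_tibble(DBI::dbGetQuery(store$con,
    "SELECT project_id, path FROM gel_view_project_paths ORDER BY path"))
}

#' @rdname view_project_paths
#' @export
view_reference_measurements <- function(store) {
  tibble::as_tibble(DBI::dbGetQuery(store$con,
    "SELECT gel_id, gel, image_id, measurement_type, r, n_reference
       FROM gel_view_reference_measurements
      ORDER BY gel_id, image_id, measurement_type"))
}

#' @rdname view_project_paths
#' @export
view_normalized <- function(store) {
  tibble::as_tibble(DBI::dbGetQuery(store$con,
    "SELECT gel_id, gel, image_id, measurement_type, lane_index, sample_id,
            protein, is_reference, region_y0, region_y1, value, r, w
       FROM gel_view_normalized
      ORDER BY gel_id, image_id, lane_index, region_y0"))
}

# ---- export ------------------------------------------------------------

project_descendant_ids <- function(store, project_path) {
  paths <- view_project_paths(store)
  hit <- paths$path == project_path |
    startsWith(paths$path, paste0(project_path, "/"))
  if (!any(paths$path == project_path)) {
    stop("unknown project: ", project_path, call. = FALSE)
  }
  paths$project_id[hit]
}

#' Export measurements to spreadsheet files
#'
#' Writes a CSV set (RFC 4180, UTF-8, header row): `raw.csv` with one row
#' per stored measurement (gel, image, measurement type, lane, sample id,
#' protein amount `m`, integrated intensity `v`, success flag) and
#' `normalized.csv` which adds the per-image reference value `r` and the
#' normalized value `w`. Rows are sorted by (gel, image, lane). Restrict to
#' one project (and its sub-projects) with `project`.
#'
#' @param store a `gel_store`.
#' @param dir output directory, created if needed.
#' @param project optional project path string.
#' @return Character vector of the two file paths, invisibly.
#' @export
export_spreadsheet <- function(store, dir, project = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gel_filter <- ""
  params <- list()
  if (!is.null(project)) {
    ids <- project_descendant_ids(store, project)
    gel_filter <- sprintf(
      " AND i.gel_id IN (SELECT gel_id FROM gel_gel_project WHERE project_id IN (%s))",
      paste(ids, collapse = ","))
  }
  raw <- tibble::as_tibble(DBI::dbGetQuery(store$con, paste0(
    "SELECT g.name AS gel, m.image_id, t.name AS measurement_type,
            m.lane_index, l.sample_id, l.protein, m.region_y0, m.region_y1,
            m.value, m.success
       FROM gel_measurement m
       JOIN gel_image i ON i.id = m.image_id
       JOIN gel_gel g ON g.id = i.gel_id
       JOIN gel_measurement_type t ON t.id = m.measurement_type_id
       LEFT JOIN gel_lane l
         ON l.image_id = m.image_id AND l.lane_index = m.lane_index
      WHERE 1=1", gel_filter,
    " ORDER BY g.name, m.image_id, m.lane_index, m.region_y0")))
  norm <- view_normalized(store)
  if (!is.null(project)) {
    keep_gels <- unique(raw$gel)
    norm <- dplyr::filter(norm, .data$gel %in% keep_gels)
  }
  norm <- dplyr::arrange(norm, .data$gel, .data$image_id, .data$lane_index,
                         .data$region_y0)
  raw_path <- file.path(dir, "raw.csv")
  norm_path <- file.path(dir, "normalized.csv")
  readr::write_csv(raw, raw_path)
  readr::write_csv(norm, norm_path)
  invisible(c(raw = raw_path, normalized = norm_path))
}

#' @export
glance.gel_store <- function(x, ...) {
  q <- function(sql) DBI::dbGetQuery(x$con, sql)[[1]]
  tibble::tibble(
    projects = q("SELECT COUNT(*) FROM gel_project"),
    gels = q("SELECT COUNT(*) FROM gel_gel"),
    images = q("SELECT COUNT(*) FROM gel_image"),
    lanes = q("SELECT COUNT(*) FROM gel_lane"),
    measurements = q("SELECT COUNT(*) FROM gel_measurement"),
    analysis_steps = q("SELECT COUNT(*) FROM gel_analysis_step")
  )
}
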