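test_that("a store survives close and reopen with identical contents", {
  dir <- withr::local_tempdir()
  h <- make_analyzed_store(dir)
  before <- glance(h$store)
  close_gel_store(h$store)
  store2 <- open_gel_store(file.path(dir, "store.db"))
  withr::defer(close_gel_store(store2))
  expect_identical(glance(store2), before)
  expect_identical(stored_measurements(store2, h$image_id)$value,
                   h$measurements$value)
})

test_that("viewing mode permits reads and rejects mutation", {
  dir <- withr::local_tempdir()
  h <- make_analyzed_store(dir)
  close_gel_store(h$store)
  ro <- open_gel_store(file.path(dir, "store.db"), readonly = TRUE)
  withr::defer(close_gel_store(ro))
  expect_gt(nrow(view_normalized(ro)), 0)
  expect_error(add_gel(ro, "x"), "viewing mode")
  expect_error(create_project(ro, "p"), "viewing mode")
})

test_that("a store with a newer schema version is refused", {
  dir <- withr::local_tempdir()
  store <- open_gel_store(file.path(dir, "s.db"))
  DBI::dbExecute(store$con,
    "UPDATE gel_meta SET value = '999' WHERE key = 'schema_version'")
  close_gel_store(store)
  expect_error(open_gel_store(file.path(dir, "s.db")), "newer")
  expect_error(open_gel_store(file.path(dir, "missing.db"), readonly = TRUE),
               "non-existent")
})

test_that("project creation is idempotent and builds missing ancestors", {
  dir <- withr::local_tempdir()
  store <- open_gel_store(file.path(dir, "s.db"))
  withr::defer(close_gel_store(store))
  create_project(store, "X")
  p1 <- create_project(store, "X/Y")
  p2 <- create_project(store, "X/Y")
  expect_identical(p1$project_id, p2$project_id)
  paths <- view_project_paths(store)
  expect_setequal(paths$path, c("X", "X/Y"))
  expect_error(create_project(store, "A//B"), "empty project name")
  expect_error(create_project(store, ""), "empty project name")
})

test_that("random project hierarchies round-trip through the path view", {
  dir <- withr::local_tempdir()
  store <- open_gel_store(file.path(dir, "s.db"))
  withr::defer(close_gel_store(store))
  set.seed(51)
  wanted <- unique(replicate(40, paste(
    sample(letters[1:6], sample(1:4, 1), replace = TRUE), collapse = "/")))
  for (p in wanted) create_project(store, p)
  got <- view_project_paths(store)$path
  expect_true(all(wanted %in% got))
  # every view path is re-creatable as a no-op
  n_before <- glance(store)$projects
  for (p in got) create_project(store, p)
  expect_identical(glance(store)$projects, n_before)
})

test_that("analysis steps are logged in order with canonical parameters", {
  dir <- withr::local_tempdir()
  h <- make_analyzed_store(dir)
  withr::defer(close_gel_store(h$store))
  log <- analysis_log(h$store, h$image_id)
  expect_identical(log$step_index, 0:(nrow(log) - 1L))
  expect_identical(log$operation[1], "background")
  expect_identical(unique(log$operation[-1]), "lane")
  expect_error(record_step(h$store, h$image_id, "sharpen", list()),
               "unknown operation")
  # crop then background then lane indexes 0,1,2 on a fresh image
  img2 <- add_image(h$store, h$gel_id, h$tif)
  i0 <- record_step(h$store, img2, "crop",
                    list(top = 0, left = 0, height = 10, width = 10))
  i1 <- record_step(h$store, img2, "background", list(method = "none"))
  expect_identical(c(i0, i1), c(0L, 1L))
})

test_that("replay reproduces stored values bit-identically", {
  dir <- withr::local_tempdir()
  h <- make_analyzed_store(dir)
  withr::defer(close_gel_store(h$store))
  verified <- replay_image(h$store, h$image_id)
  expect_identical(sort(verified$value), sort(h$measurements$value))
})

test_that("replay with an empty log returns no measurements", {
  dir <- withr::local_tempdir()
  h <- make_analyzed_store(dir)
  withr::defer(close_gel_store(h$store))
  img2 <- add_image(h$store, h$gel_id, h$tif)
  expect_identical(nrow(replay_image(h$store, img2)), 0L)
})

test_that("replay detects a tampered stored value and a changed source file", {
  dir <- withr::local_tempdir()
  h <- make_analyzed_store(dir)
  withr::defer(close_gel_store(h$store))
  DBI::dbExecute(h$store$con,
    "UPDATE gel_measurement SET value = value + 1 WHERE lane_index = 2")
  expect_error(replay_image(h$store, h$image_id), "replay mismatch")
  DBI::dbExecute(h$store$con,
    "UPDATE gel_measurement SET value = value - 1 WHERE lane_index = 2")
  expect_silent(replay_image(h$store, h$image_id))
  # now corrupt the source image
  m <- matrix(5, 10, 10)
  tiff::writeTIFF(m / 65535, h$tif, bits.per.sample = 16L)
  expect_error(replay_image(h$store, h$image_id), "hash mismatch")
})

test_that("views agree with the in-memory normalization module", {
  dir <- withr::local_tempdir()
  h <- make_analyzed_store(dir)
  withr::defer(close_gel_store(h$store))
  rv <- view_reference_measurements(h$store)
  nv <- view_normalized(h$store)
  lanes <- lane_records(1:3, c("REF", "S1", "S2"), c(1, 2, 1),
                        c(TRUE, FALSE, FALSE))
  ref <- reference_value(h$measurements, lanes)
  expect_equal(rv$r, ref$r, tolerance = 1e-12)
  expect_identical(as.integer(rv$n_reference), ref$n_reference)
  want <- normalized_values(h$measurements, lanes, ref)
  expect_equal(nv$w[order(nv$lane_index)], want$w[order(want$lane_index)],
               tolerance = 1e-12)
})

test_that("reference view arithmetic matches the hand-computed fixture", {
  dir <- withr::local_tempdir()
  store <- open_gel_store(file.path(dir, "s.db"))
  withr::defer(close_gel_store(store))
  gel_id <- add_gel(store, "g")
  f <- file.path(dir, "img.png")
  png::writePNG(matrix(0.5, 8, 8), f)
  image_id <- add_image(store, gel_id, f)
  set_lane_records(store, image_id,
                   lane_records(1:3, c("r1", "r2", "s"), c(2, 3, 1),
                                c(TRUE, TRUE, FALSE)))
  type_id <- add_measurement_type(store, "t")
  for (row in list(list(1, 4), list(2, 6), list(3, 4))) {
    DBI::dbExecute(store$con,
      "INSERT INTO gel_measurement
         (image_id, lane_index, measurement_type_id, region_y0, region_y1, value)
       VALUES (?, ?, ?, 0, 1, ?)",
      params = list(image_id, row[[1]], type_id, row[[2]]))
  }
  rv <- view_reference_measurements(store)
  expect_identical(rv$r, 2)          # mean(4/2, 6/3)
  expect_identical(as.integer(rv$n_reference), 2L)
  nv <- view_normalized(store)
  expect_identical(nv$w[nv$lane_index == 3], 2)   # (4/1)/2
})

test_that("spreadsheet export round-trips against the views", {
  dir <- withr::local_tempdir()
  h <- make_analyzed_store(dir)
  withr::defer(close_gel_store(h$store))
  out <- export_spreadsheet(h$store, file.path(dir, "xl"))
  raw <- readr::read_csv(out[["raw"]], show_col_types = FALSE)
  norm <- readr::read_csv(out[["normalized"]], show_col_types = FALSE)
  expect_identical(nrow(raw), nrow(h$measurements))
  nv <- view_normalized(h$store)
  expect_identical(nrow(norm), nrow(nv))
  expect_equal(norm$w, nv$w, tolerance = 1e-12)
  expect_equal(norm$value, nv$value, tolerance = 1e-12)
  expect_identical(norm$sample_id, nv$sample_id)
  # project-restricted export keeps the linked gel, unknown project errors
  out2 <- export_spreadsheet(h$store, file.path(dir, "xl2"), project = "tests")
  raw2 <- readr::read_csv(out2[["raw"]], show_col_types = FALSE)
  expect_identical(nrow(raw2), nrow(raw))
  expect_error(export_spreadsheet(h$store, file.path(dir, "xl3"),
                                  project = "nope"), "unknown project")
})

test_that("exporting an empty store yields headers only", {
  dir <- withr::local_tempdir()
  store <- open_gel_store(file.path(dir, "s.db"))
  withr::defer(close_gel_store(store))
  out <- export_spreadsheet(store, file.path(dir, "xl"))
  raw <- readr::read_csv(out[["raw"]], show_col_types = FALSE)
  expect_identical(nrow(raw), 0L)
  expect_true(all(c("gel", "lane_index", "value", "success") %in% names(raw)))
})
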