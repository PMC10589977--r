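#' Lane records
#'
#' Per-lane sample metadata: free-text sample ID, loaded protein amount `m`
#' (µg or any consistent mass unit, > 0), and whether the lane is a
#' designated reference sample. Reference samples shared across gels are
#' what makes normalized values comparable between images.
#'
#' @param lane_index integer lane indices, unique within a gel image.
#' @param sample_id character sample identifiers.
#' @param protein loaded amounts, > 0 (NA allowed; such lanes are excluded
#'   from normalization with a warning).
#' @param is_reference logical reference flags.
#' @return A tibble with those four columns.
#' @export
lane_records <- function(lane_index, sample_id, protein, is_reference) {
  lr <- tibble::tibble(lane_index = as.integer(lane_index),
                       sample_id = as.character(sample_id),
                       protein = as.numeric(protein),
                       is_reference = as.logical(is_reference))
  if (anyDuplicated(lr$lane_index)) {
    stop("lane_index must be unique within a gel", call. = FALSE)
  }
  if (any(!is.na(lr$protein) & lr$protein <= 0)) {
    stop("protein amounts must be > 0", call. = FALSE)
  }
  lr
}

join_measurements_lanes <- function(measurements, lanes) {
  measurements <- tibble::as_tibble(measurements)
  lanes <- tibble::as_tibble(lanes)
  stopifnot(all(c("lane_index", "value", "success") %in% names(measurements)),
            all(c("lane_index", "protein", "is_reference") %in% names(lanes)))
  measurements$success <- as.logical(measurements$success)
  lanes$is_reference <- as.logical(lanes$is_reference)
  dplyr::inner_join(measurements, lanes, by = "lane_index")
}

#' Per-image reference value
#'
#' The average of protein-normalized raw values over the image's reference
#' lanes whose measurements are marked successful:
#' \deqn{r = \frac{1}{R}\sum_{i=1}^{R} \frac{v_i}{m_i},}
#' where `R` counts only successful reference lanes. Failed reference
#' measurements are excluded; lanes without a protein amount are excluded
#' with a warning.
#'
#' @param measurements tibble with `lane_index`, `value`, `success`.
#' @param lanes tibble of [lane_records()].
#' @return One-row tibble `r`, `n_reference` (the count `R`), of class
#'   `gel_reference`.
#' @examples
#' m <- tibble::tibble(lane_index = 1:2, value = c(4, 6), success = TRUE)
#' l <- lane_records(1:2, c("a", "b"), c(2, 3), TRUE)
#' reference_value(m, l)   # r = 2, R = 2
#' @export
reference_value <- function(measurements, lanes) {
  d <- join_measurements_lanes(measurements, lanes)
  refs <- dplyr::filter(d, .data$is_reference, .data$success)
  if (any(is.na(refs$protein))) {
    warning("reference lane(s) without protein amount excluded from the average",
            call. = FALSE)
    refs <- dplyr::filter(refs, !is.na(.data$protein))
  }
  if (nrow(refs) == 0L) {
    stop("no reference: the image has no successful reference-lane measurement",
         call. = FALSE)
  }
  out <- tibble::tibble(r = mean(refs$value / refs$protein),
                        n_reference = nrow(refs))
  class(out) <- c("gel_reference", class(out))
  out
}

#' Normalized per-lane values
#'
#' Converts raw measurement values to loading-normalized values relative to
#' the image's reference value:
#' \deqn{w_j = \frac{1}{r}\,\frac{v_j}{m_j}.}
#' Only lanes with successful measurements and a protein amount appear in
#' the output; lanes missing a protein amount are dropped with a warning.
#' By construction the mean of `w` over the successful reference lanes is
#' exactly 1.
#'
#' @param measurements tibble with `lane_index`, `value`, `success`.
#' @param lanes tibble of [lane_records()].
#' @param ref a `gel_reference` from [reference_value()]; computed from the
#'   same tables when omitted.
#' @return Tibble `lane_index`, `sample_id`, `value`, `protein`,
#'   `is_reference`, `w`.
#' @export
normalized_values <- function(measurements, lanes, ref = NULL) {
  ref <- ref %||% reference_value(measurements, lanes)
  if (ref$r == 0) {
    stop("degenerate reference: r is 0, normalized values are undefined",
         call. = FALSE)
  }
  d <- join_measurements_lanes(measurements, lanes)
  d <- dplyr::filter(d, .data$success)
  if (any(is.na(d$protein))) {
    warning("lane(s) without protein amount dropped from normalized output",
            call. = FALSE)
    d <- dplyr::filter(d, !is.na(.data$protein))
  }
  d |>
    dplyr::mutate(w = (1 / ref$r) * .data$value / .data$protein) |>
    dplyr::select(dplyr::any_of(c("lane_index", "sample_id", "measurement_type",
                                  "value", "protein", "is_reference", "w"))) |>
    dplyr::arrange(.data$lane_index)
}
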