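#' Construct a spiral drawing record
#'
#' A spiral record holds one digitized drawing: per-sample pen coordinates and
#' auxiliary channels as captured by a graphics tablet. It is a tibble with one
#' row per sample and columns `x`, `y`, `t`, `pen_state`, `azimuth`,
#' `altitude`, `pressure`, carrying the subject id, drawing hand and sampling
#' rate as attributes.
#'
#' @param x,y pen coordinates in device units.
#' @param t timestamps in seconds, nondecreasing.
#' @param pen_state binary channel, 1 while the pen touches the surface.
#' @param azimuth,altitude pen orientation angles in degrees.
#' @param pressure pen pressure in device units, nonnegative.
#' @param subject_id subject identifier.
#' @param hand `"left"` or `"right"`.
#' @param sampling_rate acquisition rate in Hz (default 200, the rate used by
#'   digitizer protocols that need to resolve the 4--12 Hz action-tremor band).
#'
#' @return a `spiral_record` tibble.
#' @export
#' @examples
#' rec <- spiral_record(x = c(0, 1, 1), y = c(0, 0, 1), t = c(0, 0.005, 0.01))
#' rec
spiral_record <- function(x, y, t,
                          pen_state = rep(1, length(x)),
                          azimuth = rep(0, length(x)),
                          altitude = rep(90, length(x)),
                          pressure = rep(512, length(x)),
                          subject_id = "unknown",
                          hand = c("right", "left"),
                          sampling_rate = 200) {
  hand <- match.arg(hand)
  rec <- tibble::tibble(
    x = as.double(x), y = as.double(y), t = as.double(t),
    pen_state = as.double(pen_state),
    azimuth = as.double(azimuth), altitude = as.double(altitude),
    pressure = as.double(pressure)
  )
  rec <- new_spiral_record(rec, subject_id = subject_id, hand = hand,
                           sampling_rate = sampling_rate)
  validate_spiral_record(rec)
  rec
}

new_spiral_record <- function(data, subject_id, hand, sampling_rate) {
  structure(
    data,
    subject_id = as.character(subject_id),
    hand = hand,
    sampling_rate = as.double(sampling_rate),
    class = c("spiral_record", class(tibble::tibble()))
  )
}

# rebuild a record from an existing one with replaced channels
record_update <- function(record, ...) {
  new <- dplyr::mutate(tibble::as_tibble(record), ...)
  new_spiral_record(new,
    subject_id = subject_id(record),
    hand = record_hand(record),
    sampling_rate = sampling_rate(record)
  )
}

#' Record attribute accessors
#'
#' @param record a [spiral_record()].
#' @return the subject id, drawing hand or sampling rate stored on the record.
#' @export
subject_id <- function(record) attr(record, "subject_id")

#' @rdname subject_id
#' @export
record_hand <- function(record) attr(record, "hand")

#' @rdname subject_id
#' @export
sampling_rate <- function(record) attr(record, "sampling_rate")

#' Validate spiral record invariants
#'
#' Checks the structural contract of a drawing record: equal-length channels
#' with at least two samples, nondecreasing timestamps, a binary pen-state
#' channel, nonnegative pressure and a positive sampling rate.
#'
#' @param record object to validate.
#' @return the record, invisibly; aborts with an informative message otherwise.
#' @export
validate_spiral_record <- function(record) {
  if (!inherits(record, "spiral_record")) {
    rlang::abort("not a `spiral_record`.")
  }
  needed <- c("x", "y", "t", "pen_state", "azimuth", "altitude", "pressure")
  missing <- setdiff(needed, names(record))
  if (length(missing) > 0L) {
    rlang::abort(paste0("record is missing channels: ",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(record) < 2L) {
    rlang::abort("record too short: at least 2 samples are required.")
  }
  for (ch in c("x", "y", "t")) {
    if (!all(is.finite(record[[ch]]))) {
      rlang::abort(sprintf("channel `%s` contains non-finite values.", ch))
    }
  }
  dt <- diff(record$t)
  if (any(dt < 0)) {
    bad <- which(dt < 0)[1L] + 1L
    rlang::abort(sprintf(
      "timestamps must be nondecreasing; first decrease at row %d.", bad))
  }
  if (!all(record$pen_state %in% c(0, 1))) {
    rlang::abort("`pen_state` must contain only 0 and 1.")
  }
  if (any(record$pressure < 0, na.rm = TRUE)) {
    rlang::abort("`pressure` must be nonnegative.")
  }
  sr <- sampling_rate(record)
  if (!is.numeric(sr) || length(sr) != 1L || !is.finite(sr) || sr <= 0) {
    rlang::abort("`sampling_rate` must be a positive number.")
  }
  invisible(record)
}

#' @export
print.spiral_record <- function(x, ...) {
  cat(sprintf("<spiral_record> subject %s, %s hand, %d samples @ %g Hz\n",
              subject_id(x), record_hand(x), nrow(x), sampling_rate(x)))
  NextMethod()
}
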