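# Sensor layout: identities, segment attachments and mounting orientations of
# the eight body-worn IMUs. The layout order fixes the 48-axis column layout
# used everywhere downstream (sensor-major, acc xyz then gyr xyz per sensor).

#' Canonical sensor names
#'
#' The eight instrumented segments in canonical order. This order defines the
#' 48-column layout of every IMU matrix in the package.
#'
#' @return Character vector of length 8.
#' @export
sensor_names <- function() {
  c("trunk", "pelvis", "l_thigh", "r_thigh",
    "l_shank", "r_shank", "l_foot", "r_foot")
}

#' Canonical 48-axis column names
#'
#' Sensor-major ordering: for each sensor in [sensor_names()] order, the six
#' columns `acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z` (accelerometer in m/s^2,
#' gyroscope in deg/s), named `<acc|gyr>_<x|y|z>_<sensor>`.
#'
#' @return Character vector of length 48.
#' @export
imu_axis_names <- function() {
  unlist(lapply(sensor_names(), function(s) {
    paste0(rep(c("acc", "gyr"), each = 3), "_", rep(c("x", "y", "z"), 2), "_", s)
  }))
}

#' Column indices of a sensor's axes
#'
#' @param sensor Sensor name.
#' @return Integer vector of 6 column indices (acc xyz, gyr xyz) into the
#'   48-column layout.
#' @keywords internal
sensor_columns <- function(sensor) {
  i <- match(sensor, sensor_names())
  if (is.na(i)) stop("unknown sensor: ", sensor, call. = FALSE)
  (i - 1L) * 6L + 1:6
}

#' Accelerometer / gyroscope column indices
#' @keywords internal
acc_columns <- function() {
  as.vector(vapply(seq_len(8), function(i) (i - 1L) * 6L + 1:3, integer(3)))
}

#' @rdname acc_columns
#' @keywords internal
gyr_columns <- function() {
  as.vector(vapply(seq_len(8), function(i) (i - 1L) * 6L + 4:6, integer(3)))
}

#' Construct a sensor layout
#'
#' A sensor layout records which body segment each of the eight IMUs is
#' attached to and the mounting rotation from the segment frame to the sensor
#' frame. The default mounting is the identity (sensor axes coincide with
#' segment axes); the package's axis convention is z along the segment surface
#' normal, x pointing left during standing, y completing the right-hand rule.
#'
#' @param mountings Named list of 3x3 rotation matrices (segment frame to
#'   sensor frame), one per sensor in [sensor_names()]. Defaults to identities.
#' @param segments Named character vector mapping sensor name to segment name.
#'   Defaults to the sensor names themselves.
#' @return An object of class `sensor_layout`.
#' @export
sensor_layout <- function(mountings = NULL, segments = NULL) {
  nm <- sensor_names()
  if (is.null(mountings)) {
    mountings <- stats::setNames(replicate(8, diag(3), simplify = FALSE), nm)
  }
  if (is.null(segments)) segments <- stats::setNames(nm, nm)
  layout <- structure(
    list(sensor_names = names(mountings),
         segments = segments,
         mountings = mountings,
         axis_convention = "z_surface_normal_x_left_rh"),
    class = "sensor_layout"
  )
  validate_layout(layout)
}

#' Validate a sensor layout
#'
#' Checks the sensor count, canonical ordering, and that every mounting
#' rotation is orthonormal with determinant +1 (tolerance 1e-9).
#'
#' @param layout A `sensor_layout`.
#' @return The layout, unchanged, if valid; otherwise an error.
#' @export
validate_layout <- function(layout) {
  if (!inherits(layout, "sensor_layout")) {
    stop("not a sensor_layout object", call. = FALSE)
  }
  if (length(layout$mountings) != 8L) {
    stop("layout must have exactly 8 sensors, got ", length(layout$mountings),
         call. = FALSE)
  }
  if (!identical(layout$sensor_names, sensor_names())) {
    stop("sensors must appear in canonical order: ",
         paste(sensor_names(), collapse = ", "), call. = FALSE)
  }
  for (s in layout$sensor_names) {
    R <- layout$mountings[[s]]
    if (!is_rotation_matrix(R, tol = 1e-9)) {
      stop("mounting rotation for sensor '", s,
           "' is not a proper rotation (orthonormal, det +1)", call. = FALSE)
    }
  }
  layout
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat("<sensor_layout> 8 sensors:", paste(x$sensor_names, collapse = ", "), "\n")
  cat("axis convention:", x$axis_convention, "\n")
  invisible(x)
}
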