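#' Force-sensor calibration table
#'
#' Pairs of known masses hung from the transducer and the sensor voltages
#' they produced. Masses in grams are converted to force in mN with
#' `force = mass * g`, `g = 9.81 m/s^2` (1 g under gravity = 9.81 mN).
#'
#' @param masses_g Masses in grams (calibration weights, typically 0.2--5 g).
#' @param sensor_V Sensor readings in volts, same length.
#' @param gravity Gravitational acceleration, m/s^2.
#' @return An object of class `calibration_table`.
#' @export
calibration_table <- function(masses_g, sensor_V, gravity = 9.81) {
  if (length(masses_g) != length(sensor_V) || length(masses_g) < 2L) {
    stop("calibration needs >= 2 (mass, sensor) pairs of equal length")
  }
  if (!all(is.finite(masses_g)) || !all(is.finite(sensor_V))) {
    stop("calibration values must be finite")
  }
  if (any(masses_g <= 0)) stop("calibration masses must be > 0 g")
  structure(list(masses_g = as.numeric(masses_g),
                 sensor_V = as.numeric(sensor_V),
                 gravity = gravity),
            class = "calibration_table")
}

#' Fit the sensor-voltage to force conversion factor
#'
#' Least-squares regression of force (mN) on sensor voltage with the
#' intercept fixed at zero (after baseline subtraction, zero deflection means
#' zero force for a strain gauge).
#'
#' @param table A [calibration_table()].
#' @return An object of class `conversion_factor` with fields `value`
#'   (mN per V) and `fit_residual` (RMS residual, mN).
#' @examples
#' fit_calibration(calibration_table(1:3, c(0.981, 1.962, 2.943)))
#' @export
fit_calibration <- function(table) {
  stopifnot(inherits(table, "calibration_table"))
  if (length(unique(table$sensor_V)) < 2L) {
    stop("degenerate calibration: all sensor values identical")
  }
  force_mN <- table$masses_g * table$gravity
  fit <- stats::lm(force_mN ~ 0 + sensor_V, data = list(force_mN = force_mN,
                                                        sensor_V = table$sensor_V))
  value <- unname(stats::coef(fit)[1])
  if (!is.finite(value) || value <= 0) {
    stop("calibration produced a non-positive conversion factor (", value, ")")
  }
  structure(list(value = value,
                 fit_residual = sqrt(mean(stats::residuals(fit)^2))),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("Conversion factor: %.4g mN/V (RMS residual %.3g mN)\n",
              x$value, x$fit_residual))
  invisible(x)
}

#' Raw force-sensor trace
#'
#' @param time_s Sample times in seconds, strictly increasing.
#' @param sensor_V Sensor voltages, same length.
#' @param stim_window `(start, end)` of the stimulus in seconds, inside the
#'   trace extent.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(time_s, sensor_V, stim_window) {
  if (length(time_s) != length(sensor_V)) stop("time and sensor must align")
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  if (length(stim_window) != 2L || stim_window[1] >= stim_window[2] ||
      stim_window[1] < time_s[1] || stim_window[2] > time_s[length(time_s)]) {
    stop("stim_window must be an increasing pair inside the trace extent")
  }
  structure(list(time_s = as.numeric(time_s), sensor_V = as.numeric(sensor_V),
                 stim_window = as.numeric(stim_window)),
            class = "raw_trace")
}

#' Peak-to-peak sensor deflection during the stimulus
#'
#' The mean of the pre-stimulus samples is subtracted as baseline, then the
#' peak-to-peak value `max - min` of the baseline-referenced signal within
#' the stimulus window is returned. Adding a constant offset to the whole
#' trace therefore leaves the result unchanged.
#'
#' @param trace A [raw_trace()].
#' @return Peak-to-peak deflection in volts (>= 0).
#' @export
peak_to_peak <- function(trace) {
  stopifnot(inherits(trace, "raw_trace"))
  in_window <- trace$time_s >= trace$stim_window[1] & trace$time_s <= trace$stim_window[2]
  if (!any(in_window)) stop("no samples inside the stimulus window")
  pre <- trace$time_s < trace$stim_window[1]
  baseline <- if (any(pre)) mean(trace$sensor_V[pre]) else 0
  s <- trace$sensor_V[in_window] - baseline
  max(s) - min(s)
}

#' Convert a peak-to-peak sensor value to joint torque
#'
#' `torque = s_p2p [V] * factor [mN/V] * moment_arm [mm]`; the unit chain
#' mN x mm = uNm holds with no hidden scale factor.
#'
#' @param s_p2p Peak-to-peak sensor value in volts.
#' @param factor A [fit_calibration()] result, or a plain mN/V number.
#' @param moment_arm_mm Moment arm in mm (> 0): distance from the joint axis
#'   to the transducer attachment point on the femur.
#' @return Torque in uNm.
#' @examples
#' torque_from_sensor(0.5, 4, 6) # 12 uNm
#' @export
torque_from_sensor <- function(s_p2p, factor, moment_arm_mm) {
  value <- if (inherits(factor, "conversion_factor")) factor$value else factor
  stopifnot_scalar_number(value, "factor", positive = TRUE)
  if (any(moment_arm_mm <= 0)) stop("moment arm must be > 0 mm")
  s_p2p * value * moment_arm_mm
}

#' Read calibration / trace CSV files
#'
#' Calibration files have columns `mass_g,sensor_V`; trace files have columns
#' `time_s,sensor_V` (the stimulus window is supplied separately).
#'
#' @param path CSV file path.
#' @param gravity Passed to [calibration_table()].
#' @return A [calibration_table()].
#' @export
read_calibration_csv <- function(path, gravity = 9.81) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mass_g", "sensor_V") %in% names(df))) {
    stop("calibration CSV must have columns mass_g, sensor_V")
  }
  calibration_table(df$mass_g, df$sensor_V, gravity = gravity)
}

#' @rdname read_calibration_csv
#' @param stim_window `(start, end)` seconds for the trace.
#' @return `read_trace_csv` returns a [raw_trace()].
#' @export
read_trace_csv <- function(path, stim_window) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "sensor_V") %in% names(df))) {
    stop("trace CSV must have columns time_s, sensor_V")
  }
  raw_trace(df$time_s, df$sensor_V, stim_window)
}
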