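#' Oxygen fugacity of the iron-wustite buffer
#'
#' Log10 oxygen fugacity of the Fe-FeO (iron-wustite, IW) equilibrium as a
#' function of temperature and pressure, from the standard linear-in-1/T
#' parameterization `log10 fO2 = a + b/T + c*P/T` with `a = 6.54`,
#' `b = -27215` K and `c = 550` K/GPa (the 1-bar terms of O'Neill's
#' calibration with a first-order volume correction). Magma redox states are
#' conventionally quoted as offsets from this buffer, `delta IW` in log10
#' units; `delta_iw_to_logfo2()` applies that offset.
#'
#' @param temperature Temperature in kelvin; must lie in the calibration
#'   range 1000-2500 K.
#' @param pressure Pressure in GPa, in `[0, 5]`.
#' @return Log10 of the oxygen fugacity (fO2 in bar) on the buffer.
#' @examples
#' iw_buffer_logfo2(1673)
#' delta_iw_to_logfo2(-2, 1420, 0.25)
#' @export
iw_buffer_logfo2 <- function(temperature, pressure = 0) {
  stopifnot(is.numeric(temperature), is.numeric(pressure))
  if (any(temperature < 1000 | temperature > 2500)) {
    stop("temperature outside IW buffer calibration range [1000, 2500] K",
         call. = FALSE)
  }
  if (any(pressure < 0 | pressure > 5)) {
    stop("pressure outside IW buffer calibration range [0, 5] GPa",
         call. = FALSE)
  }
  6.54 - 27215 / temperature + 550 * pressure / temperature
}

#' @rdname iw_buffer_logfo2
#' @param delta_iw Redox offset from the IW buffer in log10 units
#'   (e.g. -2 means fO2 is 100 times below the buffer).
#' @export
delta_iw_to_logfo2 <- function(delta_iw, temperature, pressure = 0) {
  iw_buffer_logfo2(temperature, pressure) + delta_iw
}
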