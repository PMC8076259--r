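#' Light/dark schedule
#'
#' Describes the lighting regime of a recording session in Zeitgeber time
#' (ZT; hours since lights-on). The default matches a 12 h light / 11 h dark
#' session of 23 h total, the 1 h gap before the next lights-on being used
#' for animal care and therefore not recorded.
#'
#' @param light_h Hours of light (inactive) phase, starting at ZT0.
#' @param dark_h Hours of dark (active) phase, starting at ZT `light_h`.
#' @return An object of class `light_dark_schedule` with fields `light_h`,
#'   `dark_h` and `session_h = light_h + dark_h`.
#' @export
light_dark_schedule <- function(light_h = 12, dark_h = 11) {
  if (!is.numeric(light_h) || !is.numeric(dark_h) ||
      length(light_h) != 1L || length(dark_h) != 1L ||
      light_h <= 0 || dark_h <= 0) {
    stop("light_h and dark_h must be single positive numbers")
  }
  structure(
    list(light_h = light_h, dark_h = dark_h, session_h = light_h + dark_h),
    class = "light_dark_schedule"
  )
}

#' @export
print.light_dark_schedule <- function(x, ...) {
  cat(sprintf("light/dark schedule: %g h light, %g h dark (%g h session)\n",
              x$light_h, x$dark_h, x$session_h))
  invisible(x)
}

#' Phase (light or dark) at given Zeitgeber times
#'
#' @param zt_h Numeric vector of Zeitgeber hours.
#' @param schedule A [light_dark_schedule()].
#' @return Character vector, `"light"` or `"dark"`.
#' @export
zt_phase <- function(zt_h, schedule = light_dark_schedule()) {
  ifelse(zt_h < schedule$light_h, "light", "dark")
}

#' Circadian 2 h bin table
#'
#' Bin boundaries sit at ZT 0, 2, ..., 22 and the session end, so a 23 h
#' session yields eleven 2 h bins plus a final 1 h bin ending at ZT23.
#'
#' @param schedule A [light_dark_schedule()].
#' @param width_h Bin width in hours (default 2).
#' @return A data.frame with columns `bin`, `start_zt`, `end_zt`, `phase`.
#' @export
zt_bins <- function(schedule = light_dark_schedule(), width_h = 2) {
  starts <- seq(0, schedule$session_h - 1e-9, by = width_h)
  ends <- pmin(starts + width_h, schedule$session_h)
  data.frame(
    bin = seq_along(starts),
    start_zt = starts,
    end_zt = ends,
    phase = zt_phase(starts, schedule),
    stringsAsFactors = FALSE
  )
}
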