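#' @keywords internal
"_PACKAGE"

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into compass range [0, 360)
#'
#' @param x angles in degrees.
#' @return angles wrapped to [0, 360).
#' @export
wrap360 <- function(x) {
  out <- x %% 360
  # -1e-14 %% 360 == 360 in floating point; fold the boundary back
  out[out >= 360] <- 0
  out
}

#' Wrap angle differences into (-180, 180]
#'
#' @param x angle differences in degrees.
#' @return wrapped differences, positive = clockwise.
#' @export
wrap180 <- function(x) {
  out <- x %% 360
  out[out > 180] <- out[out > 180] - 360
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hods_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "hods_error"), call = call))
}

config_error <- function(msg) hods_error(msg, "hods_config_error")
format_error <- function(msg) hods_error(msg, "hods_format_error")
calibration_error <- function(msg) hods_error(msg, "hods_calibration_error")
script_error <- function(msg) hods_error(msg, "hods_script_error")
parameter_error <- function(msg) hods_error(msg, "hods_parameter_error")
alignment_error <- function(msg) hods_error(msg, "hods_alignment_error")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Full-precision numeric formatting so CSV round trips are bit-exact.
num_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out[is.nan(x)] <- "NaN"
  out
}
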