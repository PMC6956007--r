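# Phased-cosine Fourier-series stimuli.
#
# I(t) = sum_{n=1}^{NU} Amax * cos(2 pi f0 n t + phi_n), with f0 in kHz
# and t in ms so the phase argument is dimensionless without unit
# conversion.  The amplitude is common to all components; only the
# phases are random, redrawn uniformly on [-pi, pi] at every trial.

#' Stimulus specification
#'
#' @param NU Number of Fourier components (>= 1).
#' @param Amax Common component amplitude, in the stimulus current units
#'   applied directly to the model (nominally microamperes).
#' @param f0 Base frequency in kHz; component `n` has angular frequency
#'   `2 * pi * f0 * n` per ms.
#' @param phases Vector of `NU` phases in radians, each in `[-pi, pi]`.
#'   Usually drawn with [sample_phases()].
#' @return An object of class `"stimulus_spec"`.
#' @examples
#' spec <- stimulus_spec(NU = 5, Amax = 100, f0 = 1/3, phases = rep(0, 5))
#' @export
stimulus_spec <- function(NU, Amax, f0, phases) {
  NU <- as.integer(NU)
  if (is.na(NU) || NU < 1L) stop("NU must be a positive integer")
  if (!is.numeric(Amax) || Amax < 0) stop("Amax must be non-negative")
  if (!is.numeric(f0) || f0 <= 0) stop("f0 must be positive (kHz)")
  if (length(phases) != NU) stop("need exactly NU phases")
  if (any(!is.finite(phases)) || any(abs(phases) > pi + 1e-12))
    stop("phases must lie in [-pi, pi]")
  structure(list(NU = NU, Amax = Amax, f0 = f0,
                 phases = as.numeric(phases)),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("phased-cosine stimulus: NU = %d, Amax = %g, f0 = %g kHz\n",
              x$NU, x$Amax, x$f0))
  invisible(x)
}

#' Draw random component phases
#'
#' Draws `NU` phases i.i.d. uniform on `[-pi, pi]` from R's current
#' random stream; call `set.seed()` beforehand for reproducibility.
#'
#' @param NU Number of components.
#' @return Numeric vector of `NU` phases in radians.
#' @export
sample_phases <- function(NU) {
  NU <- as.integer(NU)
  if (is.na(NU) || NU < 1L) stop("NU must be a positive integer")
  stats::runif(NU, -pi, pi)
}

#' Evaluate a stimulus on a time grid
#'
#' @param spec A [stimulus_spec].
#' @param grid A [time_grid]; the waveform is evaluated at the left
#'   endpoints `0, dt, ..., Tf - dt`.
#' @return Numeric waveform of length `grid$n`.
#' @examples
#' g <- time_grid(Tf = 3, dt = 0.01)
#' I <- evaluate_stimulus(stimulus_spec(5, 100, 1/3, rep(0, 5)), g)
#' I[1]   # 500: all five cosines at argument 0
#' @export
evaluate_stimulus <- function(spec, grid) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(grid, "time_grid"))
  t <- grid_times(grid)
  I <- numeric(grid$n)
  for (n in seq_len(spec$NU))
    I <- I + spec$Amax * cos(2 * pi * spec$f0 * n * t + spec$phases[n])
  I
}

#' Serialize / deserialize stimulus specs
#'
#' JSON round-trip for stimulus specifications (fields `NU`, `Amax_uA`,
#' `f0_kHz`, `phases_rad`).
#'
#' @param spec A [stimulus_spec].
#' @param path File path.
#' @return `read_stimulus_json()` returns a [stimulus_spec].
#' @export
write_stimulus_json <- function(spec, path) {
  stopifnot(inherits(spec, "stimulus_spec"))
  jsonlite::write_json(
    list(NU = spec$NU, Amax_uA = spec$Amax, f0_kHz = spec$f0,
         phases_rad = spec$phases),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_json
#' @export
read_stimulus_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_spec(x$NU, x$Amax_uA, x$f0_kHz, x$phases_rad)
}
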