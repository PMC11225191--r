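#' Zero-mean periodic signal (harmonic form)
#'
#' Oscillatory parts of the time-dependent rates are zero-mean, 2*pi-periodic
#' functions of the fast time `tau = omega * t`. The harmonic form stores
#' coefficients of `sum_k alpha_k cos(k tau) + beta_k sin(k tau)` with
#' `k >= 1`; excluding `k = 0` enforces the zero mean by construction.
#'
#' @param k Integer vector of harmonic indices (>= 1).
#' @param cos,sin Numeric vectors of cosine and sine amplitudes, recycled to
#'   `length(k)`.
#' @return Object of class `osc_signal`.
#' @examples
#' osc_signal(k = 1, sin = 0.5)          # 0.5 sin(tau)
#' osc_signal(k = 1, cos = -1.6)         # -1.6 cos(tau)
#' @export
osc_signal <- function(k = integer(), cos = 0, sin = 0) {
  k <- as.integer(k)
  if (length(k) && any(k < 1))
    stop("harmonic indices must be >= 1 (a k = 0 term would break the zero mean)",
         call. = FALSE)
  if (anyDuplicated(k))
    stop("duplicate harmonic indices", call. = FALSE)
  n <- length(k)
  cos <- rep_len(as.numeric(cos), n)
  sin <- rep_len(as.numeric(sin), n)
  if (!all(is.finite(cos)) || !all(is.finite(sin)))
    stop("amplitudes must be finite", call. = FALSE)
  structure(list(k = k, cos = cos, sin = sin), class = "osc_signal")
}

#' Zero-mean periodic signal (tabulated form)
#'
#' For non-harmonic shapes: values on a uniform grid over one period
#' `[0, 2*pi)`. The values are mean-centered at construction so the zero-mean
#' invariant holds for any input table.
#'
#' @param values Numeric vector of samples at `tau = 2*pi*(0:(n-1))/n`.
#' @return Object of class `osc_tabulated`.
#' @export
osc_tabulated <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 8)
    stop("tabulated signal needs at least 8 samples per period", call. = FALSE)
  if (!all(is.finite(values)))
    stop("tabulated values must be finite", call. = FALSE)
  structure(list(values = values - mean(values)), class = "osc_tabulated")
}

#' Evaluate a periodic signal at fast-time points
#'
#' @param signal An `osc_signal` or `osc_tabulated` object.
#' @param tau Numeric vector of fast-time points (any real; the signal is
#'   2*pi-periodic). Tabulated signals are interpolated linearly with periodic
#'   wrap-around.
#' @return Numeric vector of signal values.
#' @export
signal_eval <- function(signal, tau) UseMethod("signal_eval")

#' @export
signal_eval.osc_signal <- function(signal, tau) {
  out <- numeric(length(tau))
  for (i in seq_along(signal$k)) {
    kt <- signal$k[i] * tau
    out <- out + signal$cos[i] * cos(kt) + signal$sin[i] * sin(kt)
  }
  out
}

#' @export
signal_eval.osc_tabulated <- function(signal, tau) {
  v <- signal$values
  n <- length(v)
  x <- (tau %% (2 * pi)) / (2 * pi) * n   # fractional grid index
  i0 <- floor(x)
  w <- x - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  (1 - w) * v[i0] + w * v[i1]
}

#' Zero-mean antiderivative of a periodic signal
#'
#' Returns the primitive fixed to have zero period-average (the arbitrary
#' integration constant is irrelevant in the payoff quadrature because the
#' gene-transfer oscillation has zero mean, but mean-centering makes
#' intermediate results reproducible). Harmonics map as
#' `cos(k tau) -> sin(k tau)/k`, `sin(k tau) -> -cos(k tau)/k`; tabulated
#' signals use cumulative trapezoid quadrature followed by mean-centering.
#'
#' @param signal An `osc_signal` or `osc_tabulated` object (zero mean; enforced
#'   at construction).
#' @return Signal object of the same class: the primitive.
#' @export
signal_primitive <- function(signal) UseMethod("signal_primitive")

#' @export
signal_primitive.osc_signal <- function(signal) {
  osc_signal(k = signal$k,
             cos = -signal$sin / signal$k,
             sin = signal$cos / signal$k)
}

#' @export
signal_primitive.osc_tabulated <- function(signal) {
  v <- signal$values
  n <- length(v)
  h <- 2 * pi / n
  # trapezoid cumulative integral on the periodic extension
  mids <- (v + c(v[-1], v[1])) / 2
  prim <- c(0, cumsum(mids[-n])) * h
  osc_tabulated(prim)   # constructor mean-centers
}

#' Test for the identically-zero signal
#' @param signal A signal object.
#' @return Logical.
#' @keywords internal
signal_is_zero <- function(signal) {
  if (inherits(signal, "osc_signal"))
    return(length(signal$k) == 0 || all(signal$cos == 0 & signal$sin == 0))
  all(signal$values == 0)
}

#' Period average of the product of two periodic signals
#'
#' `(1/2pi) integral_0^2pi s1(tau) s2(tau) dtau`. Exact coefficient algebra
#' when both signals are harmonic (orthogonality of the Fourier basis);
#' composite-trapezoid quadrature on a uniform 4096-point grid otherwise.
#'
#' @param s1,s2 Signal objects.
#' @param n_grid Grid size for the quadrature fallback.
#' @return Scalar period average.
#' @export
signal_product_mean <- function(s1, s2, n_grid = 4096) {
  if (inherits(s1, "osc_signal") && inherits(s2, "osc_signal")) {
    common <- intersect(s1$k, s2$k)
    if (!length(common)) return(0)
    i1 <- match(common, s1$k); i2 <- match(common, s2$k)
    return(sum(s1$cos[i1] * s2$cos[i2] + s1$sin[i1] * s2$sin[i2]) / 2)
  }
  tau <- 2 * pi * (0:(n_grid - 1)) / n_grid
  mean(signal_eval(s1, tau) * signal_eval(s2, tau))   # periodic trapezoid
}
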