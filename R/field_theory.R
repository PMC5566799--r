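#' Transfer functions for the neural-field model
#'
#' The field analysis needs only a nonnegative, nondecreasing mapping from
#' mean membrane potential to output rate. Two standard choices are provided:
#' a logistic sigmoid `f(v) = f_max / (1 + exp(-gain * (v - v_half)))` and a
#' threshold-linear ramp `f(v) = gain * max(v - v_th, 0)`. Both carry an
#' analytic derivative as the `"deriv"` attribute; any user function without
#' one is differentiated numerically by central differences.
#'
#' @param f_max Maximum rate of the sigmoid (sets the output scale).
#' @param gain Slope parameter.
#' @param v_half Sigmoid midpoint.
#' @param v_th Ramp threshold.
#' @return A function of class `transfer_function`.
#' @export
transfer_sigmoid <- function(f_max = 1, gain = 1, v_half = 0) {
  stopifnot(f_max > 0, gain >= 0)
  f <- function(v) f_max / (1 + exp(-gain * (v - v_half)))
  attr(f, "deriv") <- function(v) {
    s <- f(v)
    gain * s * (1 - s / f_max)
  }
  class(f) <- c("transfer_function", "function")
  f
}

#' @rdname transfer_sigmoid
#' @export
transfer_threshold_linear <- function(gain = 1, v_th = 0) {
  stopifnot(gain >= 0)
  f <- function(v) gain * pmax(v - v_th, 0)
  attr(f, "deriv") <- function(v) ifelse(v > v_th, gain, 0)
  class(f) <- c("transfer_function", "function")
  f
}

transfer_deriv <- function(f, v, h = 1e-6) {
  d <- attr(f, "deriv")
  if (!is.null(d)) d(v) else (f(v + h) - f(v - h)) / (2 * h)
}

#' Neural-field model of the inhibitory sheet
#'
#' Continuum description of the network: the mean membrane potential
#' `v(x, t)` obeys
#' `dv/dt = -v - integral f(v(y)) W(x - y) dy + I(x, t)`,
#' with `W` the (unit-integral) spatial connectivity profile and `f` the
#' transfer function; the minus sign in front of the integral encodes that
#' all recurrent coupling is inhibitory. Connection strength is absorbed
#' into `f`.
#'
#' @param transfer A [transfer_sigmoid()] / [transfer_threshold_linear()] or
#'   any nonnegative nondecreasing function.
#' @param kernel A [kernel_spec()].
#' @param I0 Constant background input level.
#' @return An object of class `field_model`.
#' @export
field_model <- function(transfer = transfer_sigmoid(), kernel = kernel_spec("gamma"),
                        I0 = 1) {
  stopifnot(is.function(transfer), inherits(kernel, "kernel_spec"))
  structure(list(transfer = transfer, kernel = kernel, I0 = I0),
            class = "field_model")
}

#' Fourier transform of the symmetric 1D connectivity kernel
#'
#' For the gamma kernel `W(x) = |x|^(n-1) exp(-|x|/theta) / (2 gamma(n) theta^n)`
#' the closed form is `cos(n * atan(theta k)) / (1 + theta^2 k^2)^(n/2)`;
#' for the Gaussian kernel it is `exp(-sigma^2 k^2 / 2)`. Both satisfy
#' `W~(0) = 1` (unit kernel integral). The gamma transform dips below zero
#' for `n > 1` — the necessary condition for bump instability in a purely
#' inhibitory network — whereas the Gaussian transform is positive
#' everywhere.
#'
#' @param kernel A [kernel_spec()].
#' @param k Wavenumbers (radians per grid unit; vectorised).
#' @return `W~(k)`, dimensionless.
#' @examples
#' kernel_fourier(kernel_spec("gamma", n = 3, theta = 1), 1) # -0.25
#' @export
kernel_fourier <- function(kernel, k) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (kernel$kind == "gamma") {
    cos(kernel$n * atan(kernel$theta * k)) /
      (1 + kernel$theta^2 * k^2)^(kernel$n / 2)
  } else {
    exp(-kernel$sigma^2 * k^2 / 2)
  }
}

#' Fourier transform by numerical quadrature (validation)
#'
#' Direct evaluation of `2 * integral_0^Inf W(x) cos(k x) dx` with the 1D
#' radial profile; used to validate the closed forms of [kernel_fourier()].
#'
#' @inheritParams kernel_fourier
#' @return Numeric vector of the same length as `k`.
#' @export
kernel_fourier_quadrature <- function(kernel, k) {
  stopifnot(inherits(kernel, "kernel_spec"))
  dens <- function(x) kernel_radial_density(x, kernel) / 2 # symmetric half
  vapply(k, function(kk) {
    2 * stats::integrate(function(x) dens(x) * cos(kk * x), 0, Inf,
                         rel.tol = 1e-10, abs.tol = 1e-12,
                         subdivisions = 2000L)$value
  }, numeric(1))
}

#' Radial (2D) kernel transform by Hankel quadrature (cross-check)
#'
#' Zeroth-order Hankel transform of the isotropic 2D profile whose radial
#' connection-distance density matches the kernel,
#' `W2(r) = rho(r) / (2 pi r)`: `W~2D(k) = integral_0^Inf rho(r) J0(k r) dr`.
#' Provided as an optional cross-check that the 1D analysis captures the 2D
#' torus case (both transforms dip negative for gamma kernels with `n > 1`).
#'
#' @inheritParams kernel_fourier
#' @return Numeric vector of the same length as `k`.
#' @export
kernel_fourier_radial2d <- function(kernel, k) {
  stopifnot(inherits(kernel, "kernel_spec"))
  vapply(k, function(kk) {
    stats::integrate(function(r) kernel_radial_density(r, kernel) * besselJ(kk * r, 0),
                     0, Inf, rel.tol = 1e-8, subdivisions = 2000L)$value
  }, numeric(1))
}

#' Spatially homogeneous fixed point of the field model
#'
#' Solves `v0 + f(v0) = I0` (residual below `tol`); the solution is unique
#' for nondecreasing `f`.
#'
#' @param model A [field_model()].
#' @param tol Residual tolerance.
#' @return The fixed point `v0`.
#' @export
homogeneous_fixed_point <- function(model, tol = 1e-10) {
  stopifnot(inherits(model, "field_model"))
  f <- model$transfer
  g <- function(v) v + f(v) - model$I0
  lo <- model$I0 - f(model$I0) - 1
  hi <- model$I0 + 1
  tries <- 0
  while (g(lo) > 0 && tries < 60) { lo <- lo - 2^tries; tries <- tries + 1 }
  while (g(hi) < 0 && tries < 120) { hi <- hi + 2^tries; tries <- tries + 1 }
  if (g(lo) > 0 || g(hi) < 0) {
    stop(sprintf("no sign change for the fixed-point residual on [%g, %g]", lo, hi))
  }
  v0 <- stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
  if (abs(g(v0)) > tol) {
    # polish by a few Newton steps with the numerical derivative
    for (i in 1:50) {
      step <- g(v0) / (1 + transfer_deriv(f, v0))
      v0 <- v0 - step
      if (abs(g(v0)) < tol) break
    }
  }
  if (abs(g(v0)) > tol) stop("fixed-point residual above tolerance")
  v0
}

#' Eigenvalue spectrum of perturbations around the homogeneous state
#'
#' Linearising the field equation around the fixed point gives, per spatial
#' wavenumber `k`, the growth rate `zeta(k) = -1 - f'(v0) * W~(k)`. The
#' homogeneous state is unstable to spatially periodic perturbations when
#' `max_k zeta(k) > 0`, which with `f' >= 0` requires `W~(k) < 0` somewhere
#' — possible for gamma kernels with `n > 1`, impossible for Gaussian
#' kernels.
#'
#' @param model A [field_model()].
#' @param k Wavenumber grid (default a dense grid on (0, 20]).
#' @return A tibble with columns `k`, `w_tilde`, `zeta`.
#' @export
eigenvalue_spectrum <- function(model, k = seq(0, 20, length.out = 2001)) {
  stopifnot(inherits(model, "field_model"))
  v0 <- homogeneous_fixed_point(model)
  fp <- transfer_deriv(model$transfer, v0)
  w <- kernel_fourier(model$kernel, k)
  tibble::tibble(k = k, w_tilde = w, zeta = -1 - fp * w)
}

#' Critical wavenumber of the gamma kernel
#'
#' The wavenumber minimising `W~(k)`, which sets the spatial period of the
#' emerging bump pattern. For the gamma kernel with `n > 1` the closed form
#' is `k_c = tan(pi / (n + 1)) / theta`; for `n <= 1` (and for Gaussian
#' kernels) `W~` has no negative minimum and no finite minimiser exists.
#'
#' @param kernel A [kernel_spec()] with `kind = "gamma"` and `n > 1`.
#' @return `k_c` in radians per grid unit.
#' @examples
#' critical_wavenumber(kernel_spec("gamma", n = 3, theta = 1)) # 1
#' @export
critical_wavenumber <- function(kernel) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (kernel$kind != "gamma" || kernel$n <= 1) {
    stop("no finite minimizer: W~(k) stays positive (needs a gamma kernel with n > 1)")
  }
  tan(pi / (kernel$n + 1)) / kernel$theta
}

#' Numerical argmin of the kernel transform
#'
#' Dense grid scan over `(0, k_max]` followed by local refinement with
#' [stats::optimize()]; used to validate [critical_wavenumber()] (`W~` is
#' oscillatory for large `n`, so the scan guards against local minima).
#'
#' @param kernel A [kernel_spec()].
#' @param k_max Upper end of the scanned range.
#' @return The minimising wavenumber.
#' @export
argmin_kernel_fourier <- function(kernel, k_max = 20) {
  kgrid <- seq(1e-6, k_max, length.out = 4000)
  w <- kernel_fourier(kernel, kgrid)
  i <- which.min(w)
  lo <- kgrid[max(1, i - 2)]
  hi <- kgrid[min(length(kgrid), i + 2)]
  stats::optimize(function(k) kernel_fourier(kernel, k), c(lo, hi),
                  tol = 1e-10)$minimum
}

#' Predicted spacing between activity bumps
#'
#' `2 * pi / k_c`, in grid units: the wavelength of the fastest-growing
#' spatially periodic mode. Increases monotonically with both the shape `n`
#' and the scale `theta` of the gamma kernel.
#'
#' @inheritParams critical_wavenumber
#' @return Predicted inter-bump spacing in grid units.
#' @export
predict_bump_spacing <- function(kernel) {
  2 * pi / critical_wavenumber(kernel)
}

#' Linear stability report for a field model
#'
#' Computes the fixed point, the transfer slope there, the eigenvalue
#' spectrum, and — when the kernel admits one — the critical wavenumber and
#' predicted bump spacing.
#'
#' @param model A [field_model()].
#' @param k Wavenumber grid for the spectrum.
#' @return An object of class `stability_report` with fields `v0`,
#'   `fprime_v0`, `spectrum` (tibble), `min_w_tilde`, `unstable`, `k_c`,
#'   `predicted_spacing` (`NA` when no finite minimiser exists).
#' @export
stability_report <- function(model, k = seq(0, 20, length.out = 2001)) {
  spec <- eigenvalue_spectrum(model, k)
  v0 <- homogeneous_fixed_point(model)
  fp <- transfer_deriv(model$transfer, v0)
  kc <- tryCatch(critical_wavenumber(model$kernel), error = function(e) NA_real_)
  structure(list(
    v0 = v0, fprime_v0 = fp, spectrum = spec,
    min_w_tilde = min(spec$w_tilde),
    unstable = max(spec$zeta) > 0,
    k_c = kc,
    predicted_spacing = if (is.na(kc)) NA_real_ else 2 * pi / kc
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> v0 = %.6g, f'(v0) = %.6g, min W~ = %.6g\n",
              x$v0, x$fprime_v0, x$min_w_tilde))
  cat(sprintf("  %s; k_c = %s, predicted spacing = %s grid units\n",
              if (x$unstable) "UNSTABLE to periodic perturbations (bump-forming)"
              else "stable (spatially homogeneous)",
              format(x$k_c, digits = 4), format(x$predicted_spacing, digits = 4)))
  invisible(x)
}

#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) x$spectrum

#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(v0 = x$v0, fprime_v0 = x$fprime_v0,
                 min_w_tilde = x$min_w_tilde, unstable = x$unstable,
                 k_c = x$k_c, predicted_spacing = x$predicted_spacing)
}
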