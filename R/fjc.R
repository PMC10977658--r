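#' Extensible freely-jointed-chain model for single-stranded DNA
#'
#' Elasticity model used to convert a constant stretching speed into a force
#' loading rate on a hybridized probe. The template is a long ssDNA held in
#' an optical trap; its end-to-end extension at tension `F` is modeled as
#'
#' \deqn{x(F) = L_c \left[\coth(u) - 1/u\right]\,(1 + F/S), \quad
#'       u = F b / k_B T, \quad L_c = n_\mathrm{bases}\, \ell}
#'
#' with per-base contour length \eqn{\ell}, Kuhn length \eqn{b} and stretch
#' modulus \eqn{S}.
#'
#' The defaults are *effective* parameters calibrated so that stretching
#' speeds of 20--300 nm/s map the 16--55 pN force window onto loading rates
#' of roughly 0.2--5.9 pN/s, the regime probed in tweezers calibration of
#' overstretching tension sensors. Only the local stiffness
#' \eqn{(dx/dF)^{-1}} matters for that conversion, and raw force-extension
#' records are typically not published; the effective Kuhn length (8 nm) and
#' stretch modulus (250 pN) absorb sequence interactions and instrument
#' series compliance that the bare ssDNA FJC (Kuhn ~1.5 nm) does not capture.
#' All parameters are tunable.
#'
#' @param contour_per_base Contour length per base, nm.
#' @param kuhn_length Effective Kuhn segment length, nm.
#' @param stretch_modulus Enthalpic stretch modulus, pN.
#' @param n_bases Number of bases in the stretched template.
#' @param kBT Thermal energy, pN nm (4.114 at 25 degrees C).
#' @return An object of class `ForceExtensionModel`.
#' @seealso [model_extension()], [loading_rate_at_force()]
#' @export
#' @examples
#' m <- force_extension_model()
#' model_extension(m, 44)
#' loading_rate_at_force(m, speed = 100, force = 44)
force_extension_model <- function(contour_per_base = 0.56,
                                  kuhn_length = 8,
                                  stretch_modulus = 250,
                                  n_bases = 25000,
                                  kBT = 4.114) {
  assert_scalar(contour_per_base, "contour_per_base", positive = TRUE)
  assert_scalar(kuhn_length, "kuhn_length", positive = TRUE)
  assert_scalar(stretch_modulus, "stretch_modulus", positive = TRUE)
  assert_scalar(n_bases, "n_bases", positive = TRUE)
  assert_scalar(kBT, "kBT", positive = TRUE)
  structure(
    list(kind = "extensible_FJC",
         contour_per_base = contour_per_base,
         kuhn_length = kuhn_length,
         stretch_modulus = stretch_modulus,
         n_bases = n_bases,
         kBT = kBT),
    class = "ForceExtensionModel")
}

#' @export
print.ForceExtensionModel <- function(x, ...) {
  cat("Extensible FJC force-extension model\n")
  cat(sprintf("  contour %g nm/base x %g bases (Lc = %g nm)\n",
              x$contour_per_base, x$n_bases, x$contour_per_base * x$n_bases))
  cat(sprintf("  Kuhn length %g nm, stretch modulus %g pN, kBT %g pN nm\n",
              x$kuhn_length, x$stretch_modulus, x$kBT))
  invisible(x)
}

# Langevin function and derivative, numerically stable near 0.
langevin <- function(u) {
  out <- u
  small <- abs(u) < 1e-4
  us <- u[small]
  out[small] <- us / 3 - us^3 / 45
  ub <- u[!small]
  out[!small] <- 1 / tanh(ub) - 1 / ub
  out
}

dlangevin <- function(u) {
  out <- u
  small <- abs(u) < 1e-4
  us <- u[small]
  out[small] <- 1 / 3 - us^2 / 15
  ub <- u[!small]
  out[!small] <- 1 / ub^2 - 1 / sinh(ub)^2
  out
}

#' Extension of the FJC template at a given force
#'
#' Vectorized over `force`. Continuous at `force = 0` with limit 0 nm.
#'
#' @param model A [force_extension_model()].
#' @param force Tension, pN; must be >= 0.
#' @return Extension in nm.
#' @export
model_extension <- function(model, force) {
  stopifnot(inherits(model, "ForceExtensionModel"))
  if (!is.numeric(force) || any(!is.finite(force))) {
    stop("'force' must be finite numeric", call. = FALSE)
  }
  if (any(force < 0)) stop("'force' must be >= 0 pN", call. = FALSE)
  Lc <- model$n_bases * model$contour_per_base
  u <- force * model$kuhn_length / model$kBT
  Lc * langevin(u) * (1 + force / model$stretch_modulus)
}

# dx/dF in nm/pN (local compliance of the template), vectorized.
model_compliance <- function(model, force) {
  Lc <- model$n_bases * model$contour_per_base
  b <- model$kuhn_length
  S <- model$stretch_modulus
  u <- force * b / model$kBT
  Lc * (dlangevin(u) * (b / model$kBT) * (1 + force / S) + langevin(u) / S)
}

#' Convert stretching speed to force loading rate
#'
#' At tension `force`, a template extended at constant speed `v` loads the
#' probe at rate \eqn{r = v \, (dx/dF)^{-1}}, the speed divided by the local
#' compliance of the force-extension model.
#'
#' @param model A [force_extension_model()].
#' @param speed Stretching speed, nm/s (>= 0; 0 is the explicit limit case
#'   returning 0 pN/s).
#' @param force Tension at which to evaluate the conversion, pN (> 0).
#' @return Loading rate in pN/s (vectorized over `force`).
#' @export
loading_rate_at_force <- function(model, speed, force) {
  stopifnot(inherits(model, "ForceExtensionModel"))
  assert_scalar(speed, "speed", nonneg = TRUE)
  if (!is.numeric(force) || any(!is.finite(force)) || any(force <= 0)) {
    stop("'force' must be > 0 pN", call. = FALSE)
  }
  if (speed == 0) return(rep(0, length(force)))
  compl <- model_compliance(model, force)
  if (any(compl <= .Machine$double.eps)) {
    stop("force-extension curve is locally flat; loading rate undefined",
         call. = FALSE)
  }
  speed / compl
}

# Inverse of model_extension on a dense force grid (internal).
# Returns a function extension(nm) -> force(pN), linear interpolation on a
# grid fine enough that interpolation error is far below the force noise of
# any simulated experiment.
model_force_fun <- function(model, f_max = 200, n_grid = 4000) {
  fg <- seq(0, f_max, length.out = n_grid)
  xg <- model_extension(model, fg)
  function(x) {
    if (any(x > xg[n_grid] | x < 0)) {
      stop("extension outside invertible range of the model", call. = FALSE)
    }
    stats::approx(xg, fg, xout = x, ties = "ordered")$y
  }
}
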