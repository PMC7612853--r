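#' Convert a Gaussian kernel FWHM to its standard deviation
#'
#' FWHM and standard deviation of a Gaussian are related by
#' \eqn{\mathrm{FWHM} = \mathrm{sd}\sqrt{8\log 2}}.
#'
#' @param fwhm full width at half maximum, voxel units.
#' @return The kernel standard deviation in voxel units.
#' @export
fwhm_to_sd <- function(fwhm) fwhm / sqrt(8 * log(2))

# Default truncation radius: 4 kernel standard deviations (~1.7 * FWHM),
# leaving < 1e-4 of the kernel mass outside the support.
kernel_radius <- function(fwhm) as.integer(ceiling(4 * fwhm_to_sd(fwhm)))

#' Discrete 1D Gaussian smoothing weights
#'
#' Samples a Gaussian with standard deviation `fwhm / sqrt(8 log 2)` at
#' integer offsets `-r, ..., r` and scales the weights to unit sum.  The
#' D-dimensional smoothing kernel is the separable (outer) product of this
#' vector along each axis; field normalisation downstream divides by the
#' square root of the sum of squares of that full D-dimensional kernel, which
#' for a separable kernel is `sum(w^2)^(D/2)`.
#'
#' @param fwhm positive kernel FWHM, voxel units.
#' @param truncation_radius positive integer half-width of the support;
#'   defaults to `ceiling(4 * fwhm_to_sd(fwhm))`.
#' @return Numeric vector of length `2 * truncation_radius + 1`, symmetric,
#'   strictly positive, peaked at the centre, summing to 1.
#' @examples
#' w <- gaussian_kernel_weights(5)
#' sum(w)
#' @export
gaussian_kernel_weights <- function(fwhm, truncation_radius = kernel_radius(fwhm)) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm <= 0)
    stop("'fwhm' must be a single positive number")
  r <- as.integer(truncation_radius)
  if (r < 1L) stop("'truncation_radius' must be >= 1")
  s <- fwhm_to_sd(fwhm)
  w <- exp(-((-r:r)^2) / (2 * s^2))
  w / sum(w)
}
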