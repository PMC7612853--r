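#' Rectangular lattice domain
#'
#' Describes the box-shaped lattice \eqn{S} on which fields are generated: a
#' grid of \eqn{c_1 \times \dots \times c_D} voxels, \eqn{D \le 3}.  Side
#' lengths are measured in voxel units, so the volume \eqn{\mu(S)} is the
#' total voxel count.
#'
#' @param dims integer vector of voxel counts per axis (length 1, 2 or 3).
#' @return An object of class `"box_domain"` with elements `dims` and `D`.
#' @examples
#' d <- box_domain(c(250, 250))
#' box_volume(d)
#' intrinsic_volumes(d)
#' @export
box_domain <- function(dims) {
  dims <- as.numeric(dims)
  if (length(dims) < 1L || length(dims) > 3L)
    stop("unsupported dimension: 'dims' must have length 1, 2 or 3")
  if (any(!is.finite(dims)) || any(dims < 1) || any(dims != round(dims)))
    stop("'dims' must be positive integers")
  structure(list(dims = as.integer(dims), D = length(dims)),
            class = "box_domain")
}

#' @rdname box_domain
#' @param domain a [box_domain()].
#' @export
box_volume <- function(domain) {
  stopifnot(inherits(domain, "box_domain"))
  prod(domain$dims)
}

#' Intrinsic volumes of a box
#'
#' For a box with side lengths \eqn{a, b, c} the intrinsic volumes are the
#' elementary symmetric polynomials of the sides:
#' \eqn{\mu_0 = 1}, \eqn{\mu_1 = a + b + c}, \eqn{\mu_2 = ab + ac + bc},
#' \eqn{\mu_3 = abc} (and the analogous truncations in 1D/2D).  They are the
#' geometric part of the Lipschitz-Killing curvatures for stationary isotropic
#' fields; see [lkcs_box()].
#'
#' @param domain a [box_domain()].
#' @return Numeric vector of length `D + 1`, the intrinsic volumes
#'   \eqn{\mu_0, \dots, \mu_D}.
#' @export
intrinsic_volumes <- function(domain) {
  stopifnot(inherits(domain, "box_domain"))
  s <- as.numeric(domain$dims)
  switch(domain$D,
         c(1, s),
         c(1, s[1] + s[2], s[1] * s[2]),
         c(1, sum(s), s[1] * s[2] + s[1] * s[3] + s[2] * s[3], prod(s)))
}

#' @export
print.box_domain <- function(x, ...) {
  cat(sprintf("box domain: %s (%dD, %g voxels)\n",
              paste(x$dims, collapse = " x "), x$D, prod(x$dims)))
  invisible(x)
}

#' Field smoothness specification
#'
#' Encodes the smoothness of an isotropically smoothed Gaussian field through
#' the full width at half maximum (FWHM, in voxels) of the Gaussian smoothing
#' kernel.  The roughness parameter is
#' \deqn{\lambda = 4 \log(2) / \mathrm{FWHM}^2,}
#' the per-axis variance of the field's spatial partial derivatives, and
#' \eqn{\Lambda = \lambda I_D} is the (diagonal, isotropic) roughness matrix.
#'
#' @param fwhm positive kernel FWHM in voxel units.
#' @param D field dimension (1, 2 or 3); sets the size of `Lambda`.
#' @return An object of class `"smoothness_spec"` with elements `fwhm`, `lam`
#'   (the scalar \eqn{\lambda}) and `Lambda` (the \eqn{D \times D} matrix).
#' @examples
#' smoothness_spec(5, D = 2)
#' @export
smoothness_spec <- function(fwhm, D = 1L) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm <= 0)
    stop("'fwhm' must be a single positive number")
  if (!(D %in% 1:3)) stop("unsupported dimension: D must be 1, 2 or 3")
  lam <- 4 * log(2) / fwhm^2
  structure(list(fwhm = fwhm, lam = lam, Lambda = diag(lam, D), D = as.integer(D)),
            class = "smoothness_spec")
}

#' @export
print.smoothness_spec <- function(x, ...) {
  cat(sprintf("smoothness: FWHM = %g voxels, lambda = %.6g (D = %d)\n",
              x$fwhm, x$lam, x$D))
  invisible(x)
}

# Internal: accept either a smoothness_spec or a bare FWHM number, coerced to
# the domain's dimension.
as_smoothness <- function(smooth, domain) {
  if (inherits(smooth, "smoothness_spec")) {
    if (smooth$D != domain$D) smooth <- smoothness_spec(smooth$fwhm, domain$D)
    smooth
  } else {
    smoothness_spec(smooth, domain$D)
  }
}
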