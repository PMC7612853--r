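#' Recipe for one Gaussian random field realisation
#'
#' Bundles everything needed to generate a stationary unit-variance Gaussian
#' random field on a lattice: the target domain, the smoothing FWHM, the
#' boundary mode and the noise buffer.
#'
#' In `"bounded"` mode, i.i.d. standard normal noise is generated on the
#' enlarged grid \eqn{(c_1 + 2C) \times \dots \times (c_D + 2C)} with buffer
#' \eqn{C = \lceil 1.7\,\mathrm{FWHM} \rceil} by default, smoothed, and the
#' central \eqn{c_1 \times \dots \times c_D} block is kept, so every retained
#' voxel has full kernel support and the field is stationary up to kernel
#' truncation.  In `"periodic"` mode the noise lives on the target grid itself
#' and the convolution wraps around (a flat torus); no buffer is needed.
#'
#' @param domain a [box_domain()].
#' @param fwhm smoothing kernel FWHM in voxels; `fwhm = 0` skips smoothing
#'   and returns the raw white noise (useful for testing).
#' @param mode `"bounded"` (default) or `"periodic"`.
#' @param buffer noise padding per side in bounded mode; defaults to
#'   `ceiling(1.7 * fwhm)` and must cover the kernel truncation radius.
#' @param seed integer seed for the noise draw (see [generate_field()]).
#' @return An object of class `"field_recipe"`.
#' @examples
#' r <- field_recipe(box_domain(c(50, 50)), fwhm = 5, seed = 1)
#' f <- generate_field(r)
#' dim(f$values)
#' @export
field_recipe <- function(domain, fwhm, mode = c("bounded", "periodic"),
                         buffer = NULL, seed = NULL) {
  stopifnot(inherits(domain, "box_domain"))
  mode <- match.arg(mode)
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm < 0)
    stop("'fwhm' must be a single non-negative number")
  radius <- if (fwhm > 0) kernel_radius(fwhm) else 0L
  if (mode == "periodic") {
    buffer <- 0L
  } else if (is.null(buffer)) {
    buffer <- if (fwhm > 0) as.integer(ceiling(1.7 * fwhm)) else 0L
  } else {
    buffer <- as.integer(buffer)
    if (buffer < 0L) stop("'buffer' must be non-negative")
    if (buffer < radius)
      stop(sprintf("buffer (%d) smaller than kernel truncation radius (%d): edge voxels would lose kernel support",
                   buffer, radius))
  }
  smooth <- if (fwhm > 0) smoothness_spec(fwhm, domain$D) else NULL
  structure(list(domain = domain, smooth = smooth, fwhm = fwhm,
                 buffer = buffer, mode = mode, seed = seed),
            class = "field_recipe")
}

#' @export
print.field_recipe <- function(x, ...) {
  cat(sprintf("field recipe: %s lattice, FWHM = %g, mode = %s, buffer = %d%s\n",
              paste(x$domain$dims, collapse = " x "), x$fwhm, x$mode, x$buffer,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

# Dimensions of the white-noise grid a recipe draws on.
noise_dims <- function(recipe) recipe$domain$dims + 2L * recipe$buffer

#' Generate a Gaussian random field
#'
#' Draws i.i.d. standard normal noise on the (buffered) grid of the recipe,
#' smooths it with the separable discrete Gaussian kernel, extracts the
#' central target block and divides by the square root of the sum of squares
#' of the full D-dimensional kernel.  Because the convolution is a fixed
#' linear combination of independent standard normals, every output voxel is
#' exactly standard normal; spatial correlation is Gaussian with FWHM
#' \eqn{\sqrt 2} times the kernel's.
#'
#' The draw is seeded from `recipe$seed`, so identical recipes give
#' bit-identical fields.
#'
#' @param recipe a [field_recipe()] with a non-`NULL` seed.
#' @return An object of class `"scalar_field"`: list with `values` (numeric
#'   array shaped like `domain$dims`; a plain vector in 1D) and `recipe`.
#' @export
generate_field <- function(recipe) {
  stopifnot(inherits(recipe, "field_recipe"))
  if (is.null(recipe$seed)) stop("recipe has no seed; set 'seed' in field_recipe()")
  set.seed(recipe$seed)
  nd <- noise_dims(recipe)
  noise <- array(rnorm(prod(nd)), dim = nd)
  field_from_noise(noise, recipe)
}

#' Generate a Gaussian random field on a flat torus
#'
#' Identical to [generate_field()] but requires (and asserts) periodic mode:
#' the smoothing convolution wraps around, so opposite edges of the lattice
#' are statistically identified and the field is stationary on the torus.
#' This mode reproduces the wrap-around simulation whose naive edge-based
#' cluster counting is the failure mode probed by [naive_labeling_bias()].
#'
#' @param recipe a [field_recipe()] with `mode = "periodic"`.
#' @return A `"scalar_field"`, as for [generate_field()].
#' @export
generate_field_periodic <- function(recipe) {
  stopifnot(inherits(recipe, "field_recipe"))
  if (recipe$mode != "periodic")
    stop("recipe mode must be 'periodic'")
  generate_field(recipe)
}

#' Smooth a given white-noise array into a field
#'
#' The deterministic part of [generate_field()]: convolves a supplied noise
#' array (shaped like the recipe's noise grid) with the separable Gaussian
#' kernel, crops the central block in bounded mode, and applies the
#' sum-of-squares normalisation.  Exposed so tests can feed controlled noise
#' (e.g. to check convolution/shift commutation on the torus).
#'
#' @param noise numeric array with dimensions `domain$dims + 2 * buffer`.
#' @param recipe a [field_recipe()].
#' @return A `"scalar_field"`.
#' @export
field_from_noise <- function(noise, recipe) {
  stopifnot(inherits(recipe, "field_recipe"))
  nd <- noise_dims(recipe)
  if (!isTRUE(all.equal(field_dims(noise), as.integer(nd))))
    stop("noise dimensions do not match the recipe's noise grid")
  if (recipe$fwhm == 0) {
    vals <- noise
  } else {
    w <- gaussian_kernel_weights(recipe$fwhm)
    periodic <- recipe$mode == "periodic"
    vals <- noise
    cur <- as.integer(nd)
    for (a in seq_len(recipe$domain$D)) {
      n_out <- recipe$domain$dims[a]
      vals <- conv_axis_cpp(as.numeric(vals), cur, a - 1L, w,
                            recipe$buffer, periodic, n_out)
      cur[a] <- n_out
    }
    # unit variance: divide by sqrt(sum of squares of the full D-dim kernel)
    vals <- vals / sqrt(sum(w^2)^recipe$domain$D)
  }
  if (recipe$domain$D > 1L) dim(vals) <- recipe$domain$dims else dim(vals) <- NULL
  structure(list(values = vals, recipe = recipe), class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("scalar field on %s lattice (FWHM = %g, %s mode)\n",
              paste(x$recipe$domain$dims, collapse = " x "),
              x$recipe$fwhm, x$recipe$mode))
  invisible(x)
}

#' Export a realized field as a NIfTI volume
#'
#' Writes the field values to a NIfTI file for visual inspection in standard
#' neuroimaging viewers.  Purely a convenience: nothing in the simulation or
#' analysis pipeline reads these files.  Requires the RNifti package.
#'
#' @param field a `"scalar_field"` or numeric array.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_field_nifti <- function(field, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("write_field_nifti() requires the RNifti package")
  vals <- field_values(field)
  dim(vals) <- field_dims(vals)
  RNifti::writeNifti(RNifti::asNifti(vals), path)
  invisible(path)
}

# Dimensions of an array, treating a bare vector as 1D.
field_dims <- function(x) {
  if (is.null(dim(x))) length(x) else as.integer(dim(x))
}

# Extract the numeric values from a scalar_field or bare array.
field_values <- function(field) {
  if (inherits(field, "scalar_field")) field$values else field
}
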