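#' Euler characteristic densities of a unit-variance Gaussian field
#'
#' The EC density \eqn{\rho_d(u)} is the order-\eqn{d} coefficient in the
#' expansion of the expected Euler characteristic of the excursion set of a
#' unit-variance Gaussian field above \eqn{u}:
#' \deqn{\rho_0(u) = 1 - \Phi(u), \quad
#'       \rho_1(u) = (2\pi)^{-1} e^{-u^2/2}, \quad
#'       \rho_2(u) = (2\pi)^{-3/2} u\, e^{-u^2/2}, \quad
#'       \rho_3(u) = (2\pi)^{-2} (u^2 - 1) e^{-u^2/2},}
#' where \eqn{\Phi} is the standard normal CDF.
#'
#' @param d integer order, 0 to 3.
#' @param u numeric threshold(s).
#' @return Numeric vector of \eqn{\rho_d(u)}, same length as `u`.
#' @examples
#' ec_density(0, 0)        # 0.5
#' ec_density(2, 2.5)
#' @export
ec_density <- function(d, u) {
  if (!is.numeric(d) || length(d) != 1L || !(d %in% 0:3))
    stop("unsupported order: 'd' must be an integer in 0..3")
  switch(d + 1L,
         pnorm(u, lower.tail = FALSE),
         exp(-u^2 / 2) / (2 * pi),
         (2 * pi)^(-3 / 2) * u * exp(-u^2 / 2),
         (2 * pi)^(-2) * (u^2 - 1) * exp(-u^2 / 2))
}

#' Lipschitz-Killing curvatures of a box domain
#'
#' For a stationary isotropic field with roughness \eqn{\lambda} on a box
#' \eqn{S}, the Lipschitz-Killing curvatures are
#' \deqn{\mathcal{L}_d = \lambda^{d/2} \, \mu_d(S), \qquad d = 0, \dots, D,}
#' where \eqn{\mu_d} are the intrinsic volumes of the box
#' (see [intrinsic_volumes()]).  \eqn{\mathcal{L}_0 = 1} always, and
#' \eqn{\mathcal{L}_D = \lambda^{D/2}\mu(S)} carries the volume term.
#'
#' @param domain a [box_domain()].
#' @param smooth a [smoothness_spec()] or a bare FWHM value.
#' @return Numeric vector of length `D + 1`:
#'   \eqn{\mathcal{L}_0, \dots, \mathcal{L}_D}.
#' @examples
#' lkcs_box(box_domain(c(250, 250)), 5)
#' @export
lkcs_box <- function(domain, smooth) {
  stopifnot(inherits(domain, "box_domain"))
  smooth <- as_smoothness(smooth, domain)
  smooth$lam^((0:domain$D) / 2) * intrinsic_volumes(domain)
}

#' Expected Euler characteristic: Adler's original formula
#'
#' The classical closed form for the expected Euler characteristic of the
#' excursion set \eqn{A_u} of a stationary \eqn{D}-dimensional Gaussian field
#' with standard deviation \eqn{\sigma} on a region of volume \eqn{\mu(S)}:
#' \deqn{E[\chi(A_u)] = \mu(S)\,(2\pi)^{-(D+1)/2}\,|\Lambda|^{1/2}\,
#'   \sigma^{-(2D-1)}\, e^{-u^2/2\sigma^2}
#'   \sum_{j=0}^{\lfloor (D-1)/2 \rfloor} (-1)^j a_j \sigma^{2j}
#'   \binom{D-1}{2j} u^{D-1-2j},}
#' with \eqn{a_j = (2j)!/(j!\,2^j)}.  This formula keeps only the
#' volume (top-order) term: it ignores local maxima on the boundary of the
#' region, and for \eqn{\sigma = 1} it equals the \eqn{d = D} term
#' \eqn{\mathcal{L}_D \rho_D(u)} of the Lipschitz-Killing expansion computed
#' by [expected_ec_lkc()].
#'
#' @param domain a [box_domain()].
#' @param smooth a [smoothness_spec()] or a bare FWHM value.
#' @param u threshold (CDT).
#' @param sigma field standard deviation; must be positive.
#' @return The expected Euler characteristic (a single number).
#' @examples
#' expected_ec_original(box_domain(10000), 5, u = 2)
#' @export
expected_ec_original <- function(domain, smooth, u, sigma = 1) {
  stopifnot(inherits(domain, "box_domain"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be positive")
  smooth <- as_smoothness(smooth, domain)
  D <- domain$D
  j <- 0:((D - 1) %/% 2)
  aj <- factorial(2 * j) / (factorial(j) * 2^j)
  poly <- sum((-1)^j * aj * sigma^(2 * j) * choose(D - 1, 2 * j) * u^(D - 1 - 2 * j))
  box_volume(domain) * (2 * pi)^(-(D + 1) / 2) * smooth$lam^(D / 2) *
    sigma^(-(2 * D - 1)) * exp(-u^2 / (2 * sigma^2)) * poly
}

#' Expected Euler characteristic: Lipschitz-Killing-curvature expansion
#'
#' The boundary-corrected expansion
#' \deqn{E[\chi(A_u)] = \sum_{d=0}^{D} \mathcal{L}_d \, \rho_d(u)}
#' for a unit-variance stationary field on a box.  This is the form
#' implemented in standard neuroimaging software; its lower-order terms
#' account for excursion components created at the faces, edges and corners
#' of the domain, which Adler's volume-only formula omits.
#'
#' @param domain a [box_domain()].
#' @param smooth a [smoothness_spec()] or a bare FWHM value.
#' @param u threshold (CDT).
#' @return An object of class `"ec_prediction"`: a list with elements `u`,
#'   `per_order` (the \eqn{D + 1} terms \eqn{\mathcal{L}_d \rho_d(u)}), `eq2`
#'   (their sum, the boundary-corrected prediction) and `eq1` (Adler's
#'   original formula at \eqn{\sigma = 1}, i.e. the top-order term alone).
#' @examples
#' expected_ec_lkc(box_domain(c(250, 250)), 5, u = 3)
#' @export
expected_ec_lkc <- function(domain, smooth, u) {
  stopifnot(inherits(domain, "box_domain"))
  smooth <- as_smoothness(smooth, domain)
  D <- domain$D
  lkc <- lkcs_box(domain, smooth)
  per_order <- vapply(0:D, function(d) lkc[d + 1L] * ec_density(d, u), numeric(1))
  structure(list(u = u,
                 per_order = per_order,
                 eq2 = sum(per_order),
                 eq1 = expected_ec_original(domain, smooth, u, sigma = 1)),
            class = "ec_prediction")
}

#' @export
print.ec_prediction <- function(x, ...) {
  D <- length(x$per_order) - 1L
  cat(sprintf("expected Euler characteristic at u = %g\n", x$u))
  cat(sprintf("  volume-only (original) : %.6g\n", x$eq1))
  cat(sprintf("  LKC expansion          : %.6g\n", x$eq2))
  cat("  per-order terms L_d * rho_d(u):\n")
  for (d in 0:D) cat(sprintf("    d = %d : %.6g\n", d, x$per_order[d + 1L]))
  invisible(x)
}

#' Expected Euler characteristic on a flat torus
#'
#' On a boundaryless flat torus (periodic boundary conditions identifying
#' opposite faces) all boundary contributions vanish and only the top-order
#' term of the Lipschitz-Killing expansion survives:
#' \deqn{E[\chi(A_u)] = \mathcal{L}_D \, \rho_D(u).}
#' This is the reference value for the correct (periodic) cluster counts of
#' torus-simulated fields; it coincides with [expected_ec_original()] at
#' \eqn{\sigma = 1}.
#'
#' @inheritParams expected_ec_lkc
#' @return The expected Euler characteristic (a single number).
#' @export
expected_ec_torus <- function(domain, smooth, u) {
  stopifnot(inherits(domain, "box_domain"))
  smooth <- as_smoothness(smooth, domain)
  D <- domain$D
  lkcs_box(domain, smooth)[D + 1L] * ec_density(D, u)
}

#' Tabulate theory predictions over a smoothness/threshold grid
#'
#' @param domain a [box_domain()].
#' @param fwhms numeric vector of kernel FWHM values (voxels).
#' @param cdts numeric vector of cluster-defining thresholds.
#' @return A data frame with one row per (fwhm, cdt): columns `D`, `dims`,
#'   `fwhm`, `cdt`, `eq1`, `eq2` and the per-order terms `L0rho0`, ...
#' @examples
#' theory_table(box_domain(c(250, 250)), fwhms = c(5, 10), cdts = c(2, 3))
#' @export
theory_table <- function(domain, fwhms, cdts) {
  stopifnot(inherits(domain, "box_domain"))
  grid <- expand.grid(cdt = cdts, fwhm = fwhms, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$fwhm, grid$cdt), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- expected_ec_lkc(domain, grid$fwhm[i], grid$cdt[i])
    terms <- as.list(p$per_order)
    names(terms) <- paste0("L", seq_along(terms) - 1L, "rho", seq_along(terms) - 1L)
    c(list(D = domain$D, dims = paste(domain$dims, collapse = "x"),
           fwhm = grid$fwhm[i], cdt = grid$cdt[i],
           eq1 = p$eq1, eq2 = p$eq2), terms)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(out) <- NULL
  out
}
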