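# Independent brute-force oracles for the topology routines.  These are
# deliberately naive (queue-based flood fill over coordinate keys, exhaustive
# cell enumeration) and share no code with the package implementation.

# Number of connected components by BFS flood fill.
oracle_count_components <- function(mask, connectivity = "max", periodic = FALSE) {
  dm <- dim(mask)
  if (is.null(dm)) {
    dm <- length(mask)
    dim(mask) <- dm
  }
  D <- length(dm)
  offs <- as.matrix(expand.grid(rep(list(-1:1), D)))
  nz <- rowSums(offs != 0)
  offs <- offs[nz > 0 & (connectivity == "max" | nz == 1), , drop = FALSE]
  idx <- which(mask, arr.ind = TRUE)
  if (!is.matrix(idx)) idx <- matrix(idx, ncol = 1L)
  n <- nrow(idx)
  if (n == 0L) return(0L)
  lookup <- stats::setNames(seq_len(n), apply(idx, 1, paste, collapse = ","))
  visited <- rep(FALSE, n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (visited[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        nb <- idx[cur, ] + offs[o, ]
        if (periodic) nb <- ((nb - 1L) %% dm) + 1L
        if (any(nb < 1L | nb > dm)) next
        j <- lookup[paste(nb, collapse = ",")]
        if (!is.na(j) && !visited[j]) {
          visited[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  ncomp
}

# Euler characteristic by exhaustive enumeration of the cells of the cubical
# complex (bounded domain).  connectivity = "max": voxels are closed unit
# cubes, a cell is present iff ANY incident voxel is foreground;
# connectivity = "min": voxels are vertices, a cell is present iff ALL its
# corner voxels are foreground.
oracle_euler_characteristic <- function(mask, connectivity = "max") {
  dm <- dim(mask)
  if (is.null(dm)) {
    dm <- length(mask)
    dim(mask) <- dm
  }
  D <- length(dm)
  at <- function(coord) {
    if (any(coord < 1L | coord > dm)) return(FALSE)
    mask[matrix(coord, ncol = D)]
  }
  total <- 0L
  for (bits in 0:(2^D - 1L)) {
    spanned <- which(bitwAnd(bits, 2^(seq_len(D) - 1L)) > 0L)
    d <- length(spanned)
    ranges <- vector("list", D)
    for (a in seq_len(D)) {
      ranges[[a]] <- if (connectivity == "max") {
        if (a %in% spanned) seq_len(dm[a]) else 0:dm[a]
      } else {
        if (a %in% spanned) seq_len(dm[a] - 1L) else seq_len(dm[a])
      }
    }
    cells <- as.matrix(expand.grid(ranges))
    coffs <- as.matrix(expand.grid(lapply(seq_len(D), function(a) {
      if (connectivity == "max") {
        if (a %in% spanned) 0L else 0:1
      } else {
        if (a %in% spanned) 0:1 else 0L
      }
    })))
    count <- 0L
    for (ci in seq_len(nrow(cells))) {
      vox <- vapply(seq_len(nrow(coffs)),
                    function(oi) at(cells[ci, ] + coffs[oi, ]), logical(1))
      present <- if (connectivity == "max") any(vox) else all(vox)
      if (present) count <- count + 1L
    }
    total <- total + (-1L)^d * count
  }
  as.integer(total)
}

dims_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# Random binary mask with foreground probability p.
random_mask <- function(dm, p = 0.4) {
  array(stats::runif(prod(dm)) < p, dim = dm)
}

# Exact expected cluster count of the discretely sampled 1D field: lattice
# upcrossings plus the left-edge term, from bivariate normal orthant
# probabilities at the kernel's lag-1 autocorrelation.  Independent of the
# package's expected-EC formulas.
oracle_discrete_1d_count <- function(n, fwhm, u) {
  testthat::skip_if_not_installed("mvtnorm")
  w <- gaussian_kernel_weights(fwhm)
  rho <- sum(w[-1] * w[-length(w)]) / sum(w^2)
  p_tail <- stats::pnorm(u, lower.tail = FALSE)
  p_both <- mvtnorm::pmvnorm(lower = c(u, u),
                             corr = matrix(c(1, rho, rho, 1), 2))[1]
  (n - 1) * (p_tail - p_both) + p_tail
}
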