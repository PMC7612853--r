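#' Deterministic topology test masks
#'
#' Small binary masks with known topology, used throughout the test suite:
#' \describe{
#'   \item{`annulus`}{2D square ring (7 x 7, one-voxel hole): one component,
#'     one hole, Euler characteristic 0.}
#'   \item{`shell`}{3D hollow cube (5 x 5 x 5 with the interior removed):
#'     one component enclosing one cavity, Euler characteristic 2.}
#'   \item{`diagonal_pair`}{two voxels touching only at a corner: one
#'     cluster under max-connectivity, two under min-connectivity.}
#'   \item{`opposite_columns`}{first and last columns of a 7 x 7 grid true:
#'     two clusters on the bounded grid, one on the torus.}
#' }
#'
#' @return Named list of logical arrays.
#' @examples
#' discrete_euler_characteristic(fixture_masks()$annulus)
#' @export
fixture_masks <- function() {
  annulus <- array(FALSE, c(7, 7))
  annulus[2:6, 2:6] <- TRUE
  annulus[4, 4] <- FALSE

  shell <- array(FALSE, c(5, 5, 5))
  shell[2:4, 2:4, 2:4] <- TRUE
  shell[3, 3, 3] <- FALSE

  diagonal_pair <- array(FALSE, c(4, 4))
  diagonal_pair[2, 2] <- TRUE
  diagonal_pair[3, 3] <- TRUE

  opposite_columns <- array(FALSE, c(7, 7))
  opposite_columns[1, ] <- TRUE
  opposite_columns[7, ] <- TRUE

  list(annulus = annulus, shell = shell,
       diagonal_pair = diagonal_pair, opposite_columns = opposite_columns)
}

#' Write deterministic fixtures to a directory
#'
#' Emits the topology masks of [fixture_masks()] as CSV (with their expected
#' Euler characteristics in a manifest), plus a seeded bank of smoothed 2D
#' fields together with their per-CDT cluster counts as computed by the
#' current implementation — a regression reference for future runs.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the field bank.
#' @param n_fields number of 50 x 50 fields in the bank.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1, n_fields = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  masks <- fixture_masks()
  for (nm in names(masks)) {
    m <- masks[[nm]]
    df <- data.frame(which(m, arr.ind = TRUE))
    utils::write.csv(df, file.path(dir, paste0("mask_", nm, ".csv")),
                     row.names = FALSE)
  }
  chi <- vapply(masks, function(m) discrete_euler_characteristic(m, "max"),
                integer(1))
  utils::write.csv(data.frame(mask = names(chi), euler_char = chi),
                   file.path(dir, "mask_manifest.csv"), row.names = FALSE)

  domain <- box_domain(c(50, 50))
  cdts <- c(1.5, 2, 2.5, 3)
  recipe <- field_recipe(domain, fwhm = 5, seed = seed)
  bank <- lapply(seq_len(n_fields), function(i) {
    recipe$seed <- seed + i
    f <- generate_field(recipe)
    counts <- vapply(cdts, function(u)
      count_clusters(excursion_mask(f, u))$n_clusters, integer(1))
    list(field = f$values, counts = counts)
  })
  counts <- do.call(rbind, lapply(bank, `[[`, "counts"))
  colnames(counts) <- paste0("cdt_", cdts)
  utils::write.csv(data.frame(field = seq_len(n_fields), counts),
                   file.path(dir, "field_bank_counts.csv"), row.names = FALSE)
  for (i in seq_len(n_fields)) {
    utils::write.csv(bank[[i]]$field,
                     file.path(dir, sprintf("field_%03d.csv", i)),
                     row.names = FALSE)
  }
  invisible(dir)
}
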