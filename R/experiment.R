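#' Monte Carlo experiment configuration
#'
#' Describes a full simulation grid: for each smoothing FWHM and each
#' cluster-defining threshold (CDT), `n_reps` independent fields are
#' generated and their excursion sets summarised.  Defaults reproduce the
#' standard validation settings per dimension — 1D: 10000 voxels; 2D:
#' 250 x 250; 3D: 90 x 90 x 90 — with FWHM in \{5, 10, 15, 20, 25\} voxels
#' and CDT in \{1.5, 2, 2.5, 3\}.  A reduced 3D lattice of 50 x 50 x 50 is
#' convenient for desk-scale runs (`dims = c(50, 50, 50)`).
#'
#' Per-replicate noise seeds are derived deterministically from `seed` and
#' depend only on the FWHM index and replicate index (not on the CDT), so a
#' single field serves every threshold and any cell can be reproduced in
#' isolation.
#'
#' @param D dimension (1, 2 or 3); sets the default `dims`.
#' @param dims voxel counts per axis; default depends on `D` (see above).
#' @param fwhms kernel FWHM values, voxels.
#' @param cdts cluster-defining thresholds.
#' @param n_reps replicates per (fwhm, cdt) cell.
#' @param seed master seed for the experiment.
#' @param mode `"bounded"` or `"periodic"` field generation.
#' @param connectivity `"max"` or `"min"` cluster adjacency.
#' @return An object of class `"experiment_config"`.
#' @examples
#' cfg <- experiment_config(D = 2, dims = c(60, 60), n_reps = 50, seed = 1)
#' @export
experiment_config <- function(D = 2, dims = NULL,
                              fwhms = c(5, 10, 15, 20, 25),
                              cdts = c(1.5, 2, 2.5, 3),
                              n_reps = 1000, seed = 1,
                              mode = c("bounded", "periodic"),
                              connectivity = c("max", "min")) {
  mode <- match.arg(mode)
  connectivity <- match.arg(connectivity)
  if (is.null(dims))
    dims <- switch(D, 10000, c(250, 250), c(90, 90, 90),
                   stop("unsupported dimension: D must be 1, 2 or 3"))
  domain <- box_domain(dims)
  if (domain$D != D) stop("'dims' length does not match 'D'")
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 0 ||
      n_reps != round(n_reps))
    stop("'n_reps' must be a non-negative integer")
  if (length(fwhms) < 1L || any(fwhms <= 0)) stop("'fwhms' must be positive")
  if (length(cdts) < 1L) stop("'cdts' must be non-empty")
  structure(list(D = as.integer(D), domain = domain,
                 fwhms = as.numeric(fwhms), cdts = as.numeric(cdts),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 mode = mode, connectivity = connectivity),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("experiment: %s lattice, FWHM {%s}, CDT {%s}, %d reps, %s mode, seed %d\n",
              paste(x$domain$dims, collapse = " x "),
              paste(x$fwhms, collapse = ", "),
              paste(x$cdts, collapse = ", "),
              x$n_reps, x$mode, x$seed))
  invisible(x)
}

# Per-replicate noise seeds: an n_reps x n_fwhms matrix drawn once from the
# master seed.  Restores the caller's RNG state.
replicate_seeds <- function(config) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(config$seed)
  matrix(sample.int(.Machine$integer.max, config$n_reps * length(config$fwhms)),
         nrow = config$n_reps)
}

# Simulate all replicates for one FWHM and return per-replicate cluster
# counts and Euler characteristics at every CDT (and, for forensic mode,
# naive bounded-labeling counts of the periodic fields).
simulate_fwhm <- function(config, k, seeds, forensic = FALSE, log_con = NULL) {
  fwhm <- config$fwhms[k]
  n_cdt <- length(config$cdts)
  counts <- matrix(NA_real_, config$n_reps, n_cdt)
  ecs <- matrix(NA_real_, config$n_reps, n_cdt)
  naive <- if (forensic) matrix(NA_real_, config$n_reps, n_cdt) else NULL
  periodic <- config$mode == "periodic"
  recipe <- field_recipe(config$domain, fwhm, mode = config$mode, seed = 1L)
  for (r in seq_len(config$n_reps)) {
    recipe$seed <- seeds[r, k]
    field <- generate_field(recipe)
    for (ci in seq_len(n_cdt)) {
      mask <- excursion_mask(field, config$cdts[ci], config$connectivity)
      s <- if (periodic) count_clusters_periodic(mask) else count_clusters(mask)
      counts[r, ci] <- s$n_clusters
      ecs[r, ci] <- s$euler_char
      if (forensic) naive[r, ci] <- count_clusters(mask)$n_clusters
      if (!is.null(log_con))
        cat(sprintf("%d\t%g\t%g\t%d\t%d\n", r, fwhm, config$cdts[ci],
                    s$n_clusters, s$euler_char), file = log_con)
    }
  }
  list(counts = counts, ecs = ecs, naive = naive)
}

mc_se <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Run one cell of the Monte Carlo grid
#'
#' Simulates `config$n_reps` fields at one FWHM (which must be one of
#' `config$fwhms`, so replicate seeds match [run_grid()]) and one CDT, and
#' pairs the Monte Carlo mean cluster count and mean Euler characteristic
#' with the two theoretical predictions.
#'
#' @param config an [experiment_config()].
#' @param fwhm one element of `config$fwhms`.
#' @param cdt a threshold (any value).
#' @return A one-row data frame with the comparison columns of [run_grid()].
#' @export
run_cell <- function(config, fwhm, cdt) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$n_reps == 0L) stop("empty experiment: n_reps is 0")
  k <- match(fwhm, config$fwhms)
  if (is.na(k)) stop("'fwhm' must be one of config$fwhms (seed derivation)")
  sub <- config
  sub$cdts <- as.numeric(cdt)
  res <- simulate_fwhm(sub, k, replicate_seeds(config))
  comparison_rows(config, fwhm, cdt, res$counts, res$ecs)
}

comparison_rows <- function(config, fwhm, cdts, counts, ecs) {
  theory <- lapply(cdts, function(u) expected_ec_lkc(config$domain, fwhm, u))
  data.frame(fwhm = fwhm, cdt = cdts,
             mc_mean_clusters = colMeans(counts),
             mc_se = apply(counts, 2, mc_se),
             mc_mean_ec = colMeans(ecs),
             theory_eq1 = vapply(theory, function(p) p$eq1, numeric(1)),
             theory_eq2 = vapply(theory, function(p) p$eq2, numeric(1)),
             n_reps = nrow(counts))
}

#' Run the full Monte Carlo comparison grid
#'
#' For every (FWHM, CDT) cell of the configuration, simulates the replicate
#' fields, counts suprathreshold clusters and discrete Euler characteristics,
#' and tabulates Monte Carlo means with standard errors next to the two
#' theoretical expected-EC predictions.  Fields are generated once per FWHM
#' and thresholded at every CDT.  Reruns with the same configuration are
#' byte-identical.
#'
#' @param config an [experiment_config()].
#' @param progress if `TRUE`, print a line per FWHM as cells complete.
#' @param replicate_log optional path; when set, per-replicate summaries
#'   (replicate, fwhm, cdt, n_clusters, euler_char) stream to this
#'   tab-separated file as the run proceeds.
#' @return A data frame of class `"rft_comparison"`, one row per
#'   (fwhm, cdt), ordered by fwhm then cdt, with columns `fwhm`, `cdt`,
#'   `mc_mean_clusters`, `mc_se`, `mc_mean_ec`, `theory_eq1`, `theory_eq2`,
#'   `n_reps`.  `mc_se` is the sample standard deviation of per-replicate
#'   counts divided by `sqrt(n_reps)` (`NA` for a single replicate).
#' @examples
#' cfg <- experiment_config(D = 2, dims = c(50, 50), fwhms = c(5, 10),
#'                          cdts = c(2, 3), n_reps = 20, seed = 1)
#' run_grid(cfg)
#' @export
run_grid <- function(config, progress = FALSE, replicate_log = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$n_reps == 0L) stop("empty experiment: n_reps is 0")
  seeds <- replicate_seeds(config)
  log_con <- NULL
  if (!is.null(replicate_log)) {
    log_con <- file(replicate_log, "w")
    on.exit(close(log_con))
    writeLines("replicate\tfwhm\tcdt\tn_clusters\teuler_char", log_con)
  }
  rows <- lapply(seq_along(config$fwhms), function(k) {
    res <- simulate_fwhm(config, k, seeds, log_con = log_con)
    out <- comparison_rows(config, config$fwhms[k], config$cdts,
                           res$counts, res$ecs)
    if (progress)
      message(sprintf("fwhm %g done (mean count at cdt %g: %.3f)",
                      config$fwhms[k], config$cdts[1], out$mc_mean_clusters[1]))
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fwhm, out$cdt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("rft_comparison", "data.frame")
  out
}

#' Torus forensic grid: naive versus periodic cluster counts
#'
#' Simulates fields with periodic boundary conditions and, per cell, reports
#' the mean cluster count under correct torus labeling next to the mean
#' count under naive bounded-box labeling of the same masks, together with
#' the torus theory value \eqn{\mathcal{L}_D \rho_D(u)}.  The naive count
#' exceeds the periodic one whenever a cluster spans the wrap-around seam;
#' the excess grows with FWHM.
#'
#' @param config an [experiment_config()] with `mode = "periodic"`.
#' @param progress if `TRUE`, print per-FWHM progress.
#' @return A data frame, one row per (fwhm, cdt), with columns `fwhm`,
#'   `cdt`, `naive_mean`, `naive_se`, `periodic_mean`, `periodic_se`,
#'   `theory_torus`, `n_reps`.
#' @export
forensic_torus_grid <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$mode != "periodic")
    stop("forensic grid requires mode = 'periodic'")
  if (config$n_reps == 0L) stop("empty experiment: n_reps is 0")
  seeds <- replicate_seeds(config)
  rows <- lapply(seq_along(config$fwhms), function(k) {
    res <- simulate_fwhm(config, k, seeds, forensic = TRUE)
    theory <- vapply(config$cdts,
                     function(u) expected_ec_torus(config$domain,
                                                   config$fwhms[k], u),
                     numeric(1))
    if (progress) message(sprintf("fwhm %g done", config$fwhms[k]))
    data.frame(fwhm = config$fwhms[k], cdt = config$cdts,
               naive_mean = colMeans(res$naive),
               naive_se = apply(res$naive, 2, mc_se),
               periodic_mean = colMeans(res$counts),
               periodic_se = apply(res$counts, 2, mc_se),
               theory_torus = theory,
               n_reps = config$n_reps)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fwhm, out$cdt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("rft_comparison", "data.frame")
  out
}

#' Write a comparison table with a reproducibility header
#'
#' Writes the table as tab-separated text preceded by `#`-comment lines
#' recording the configuration that produced it (dims, FWHMs, CDTs,
#' replicates, mode, connectivity, seed, package version), so any output
#' file can be regenerated from its own header.
#'
#' @param table a table from [run_grid()] or [forensic_torus_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(table, path) {
  cfg <- attr(table, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) {
    writeLines(sprintf(
      "# rftec %s | dims=%s fwhms=%s cdts=%s n_reps=%d mode=%s connectivity=%s seed=%d",
      as.character(utils::packageVersion("rftec")),
      paste(cfg$domain$dims, collapse = "x"),
      paste(cfg$fwhms, collapse = ","),
      paste(cfg$cdts, collapse = ","),
      cfg$n_reps, cfg$mode, cfg$connectivity, cfg$seed), con)
  }
  write.table(as.data.frame(table), con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Plot theory against Monte Carlo cluster counts
#'
#' One panel per CDT: expected Euler characteristic (LKC expansion) as a
#' line over FWHM, Monte Carlo mean cluster counts as points with ±2 SE
#' error bars.  Requires ggplot2.
#'
#' @param table a table from [run_grid()].
#' @param log_y plot the response on a log scale (counts span orders of
#'   magnitude across CDTs).
#' @return A ggplot object.
#' @export
plot_comparison <- function(table, log_y = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_comparison() requires the ggplot2 package")
  df <- as.data.frame(table)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fwhm)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$theory_eq2,
                                    colour = "theory (LKC)")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mc_mean_clusters,
                                     colour = "Monte Carlo")) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mc_mean_clusters - 2 * .data$mc_se,
                                        ymax = .data$mc_mean_clusters + 2 * .data$mc_se,
                                        colour = "Monte Carlo"), width = 0.6) +
    ggplot2::facet_wrap(~cdt, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "FWHM (voxels)", y = "mean number of clusters",
                  colour = NULL)
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
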