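test_that("excursion masks use strict thresholding", {
  expect_false(any(excursion_mask(array(0, c(4, 4)), 1)$mask))
  expect_true(all(excursion_mask(array(2, c(4, 4)), 1)$mask))
  f <- array(c(1, 2, 3, 4), c(2, 2))
  m <- excursion_mask(f, 2)
  expect_identical(as.vector(m$mask), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(excursion_mask(array(c(1, NA), c(1, 2)), 0), "finite")
})

test_that("cluster counting handles canonical configurations", {
  empty <- array(FALSE, c(6, 6))
  s <- count_clusters(empty)
  expect_identical(s$n_clusters, 0L)
  expect_length(s$cluster_sizes, 0)

  one <- empty; one[3, 3] <- TRUE
  s1 <- count_clusters(one)
  expect_identical(s1$n_clusters, 1L)
  expect_identical(s1$cluster_sizes, 1L)

  fx <- fixture_masks()
  expect_identical(count_clusters(fx$diagonal_pair, "max")$n_clusters, 1L)
  expect_identical(count_clusters(fx$diagonal_pair, "min")$n_clusters, 2L)

  # opposite edge columns: split on the box, joined on the torus
  expect_identical(count_clusters(fx$opposite_columns)$n_clusters, 2L)
  expect_identical(count_clusters_periodic(fx$opposite_columns)$n_clusters, 1L)
  expect_identical(count_clusters_periodic(array(TRUE, c(5, 7)))$n_clusters, 1L)

  # sizes sum to the foreground voxel count and come sorted
  set.seed(5)
  m <- random_mask(c(25, 25), 0.35)
  s <- count_clusters(m)
  expect_identical(sum(s$cluster_sizes), sum(m))
  expect_identical(length(s$cluster_sizes), s$n_clusters)
  expect_true(all(diff(s$cluster_sizes) <= 0))
})

test_that("component counts match a brute-force flood fill", {
  set.seed(42)
  for (i in 1:40) {
    dm <- if (i %% 3 == 0) c(6, 6, 4) else if (i %% 3 == 1) c(12, 12) else 30
    m <- random_mask(dm, runif(1, 0.2, 0.6))
    for (conn in c("max", "min")) {
      expect_identical(count_clusters(m, conn)$n_clusters,
                       oracle_count_components(m, conn, periodic = FALSE))
      expect_identical(count_clusters_periodic(m, conn)$n_clusters,
                       oracle_count_components(m, conn, periodic = TRUE))
    }
  }
})

test_that("discrete EC reproduces known topologies", {
  fx <- fixture_masks()
  solid <- array(FALSE, c(7, 7)); solid[2:6, 2:6] <- TRUE
  expect_identical(discrete_euler_characteristic(solid, "max"), 1L)
  expect_identical(discrete_euler_characteristic(solid, "min"), 1L)
  expect_identical(discrete_euler_characteristic(fx$annulus, "max"), 0L)
  expect_identical(discrete_euler_characteristic(fx$annulus, "min"), 0L)
  expect_identical(discrete_euler_characteristic(fx$shell, "max"), 2L)
  # two components, one with a hole
  two <- array(FALSE, c(12, 12))
  two[2:6, 2:6] <- TRUE; two[4, 4] <- FALSE; two[9, 9] <- TRUE
  expect_identical(discrete_euler_characteristic(two, "max"), 1L)
  # diagonal pair: connected (chi 1) under max, two contractible pieces under min
  expect_identical(discrete_euler_characteristic(fx$diagonal_pair, "max"), 1L)
  expect_identical(discrete_euler_characteristic(fx$diagonal_pair, "min"), 2L)
  # torus complexes: an all-true d-torus has chi 0
  expect_identical(discrete_euler_characteristic(array(TRUE, c(6, 6)),
                                                 "max", periodic = TRUE), 0L)
  expect_identical(discrete_euler_characteristic(array(TRUE, 8),
                                                 "max", periodic = TRUE), 0L)
})

test_that("discrete EC matches exhaustive cell enumeration", {
  set.seed(77)
  for (i in 1:40) {
    dm <- if (i %% 4 == 0) c(4, 4, 4) else c(10, 10)
    m <- random_mask(dm, runif(1, 0.25, 0.65))
    for (conn in c("max", "min")) {
      expect_identical(discrete_euler_characteristic(m, conn),
                       oracle_euler_characteristic(m, conn))
    }
  }
})

test_that("cluster counting is invariant to axis transposition", {
  set.seed(8)
  for (i in 1:10) {
    m <- random_mask(c(14, 9), 0.4)
    expect_identical(count_clusters(m)$n_clusters,
                     count_clusters(t(m))$n_clusters)
    expect_identical(discrete_euler_characteristic(m),
                     discrete_euler_characteristic(t(m)))
  }
})

test_that("naive labeling of torus fields never undercounts", {
  dom <- box_domain(c(30, 30))
  rec <- field_recipe(dom, 8, mode = "periodic", seed = 1)
  any_excess <- FALSE
  for (i in 1:40) {
    rec$seed <- 300 + i
    f <- generate_field(rec)
    b <- naive_labeling_bias(f, u = 1)
    expect_gte(b[["naive"]], b[["correct"]])
    if (b[["naive"]] > b[["correct"]]) any_excess <- TRUE
  }
  expect_true(any_excess)  # at FWHM 8 on a 30x30 torus seam clusters are common
  # explicit two-column example: naive cuts the seam-spanning cluster in two
  fx <- fixture_masks()$opposite_columns
  expect_identical(count_clusters(fx)$n_clusters -
                     count_clusters_periodic(fx)$n_clusters, 1L)
  # bounded-mode fields are rejected
  fb <- generate_field(field_recipe(dom, 5, seed = 2))
  expect_error(naive_labeling_bias(fb, 2), "periodic")
})

test_that("high-threshold excursion clusters are almost always hole-free", {
  rec <- field_recipe(box_domain(c(80, 80)), 5, seed = 1)
  mismatch <- 0L
  n <- 150
  for (i in seq_len(n)) {
    rec$seed <- 600 + i
    s <- count_clusters(excursion_mask(generate_field(rec), 2.5))
    if (s$euler_char != s$n_clusters) mismatch <- mismatch + 1L
  }
  expect_lt(mismatch / n, 0.02)
})
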