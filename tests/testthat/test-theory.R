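test_that("EC densities match their closed forms and sign structure", {
  expect_equal(ec_density(0, 0), 0.5)
  expect_equal(ec_density(2, 0), 0)
  expect_equal(ec_density(3, 1), 0)
  expect_equal(ec_density(3, -1), 0)
  expect_equal(ec_density(1, 2), exp(-2) / (2 * pi))
  expect_equal(ec_density(0, 1.96), pnorm(1.96, lower.tail = FALSE))

  u <- seq(-4, 4, by = 0.25)
  expect_true(all(ec_density(0, u) > 0 & ec_density(0, u) < 1))
  expect_true(all(ec_density(1, u) > 0))
  expect_true(all(sign(ec_density(2, u)) == sign(u)))
  expect_true(all(sign(ec_density(3, u)) == sign(u^2 - 1)))

  expect_error(ec_density(4, 1), "unsupported order")
  expect_error(ec_density(-1, 1), "unsupported order")
})

test_that("box LKCs are roughness-scaled intrinsic volumes", {
  # lambda = 1 when fwhm = 2 sqrt(log 2): LKCs reduce to intrinsic volumes
  f1 <- 2 * sqrt(log(2))
  expect_equal(lkcs_box(box_domain(10), f1), c(1, 10))

  lam <- 4 * log(2) / 25
  expect_equal(lkcs_box(box_domain(c(250, 250)), 5),
               c(1, 500 * sqrt(lam), 62500 * lam))

  lam3 <- 4 * log(2) / 100
  l3 <- lkcs_box(box_domain(c(90, 90, 90)), 10)
  expect_length(l3, 4)
  expect_equal(l3[1], 1)
  expect_equal(l3[2], 270 * sqrt(lam3))
  expect_equal(l3[3], 3 * 8100 * lam3)
  expect_equal(l3[4], 90^3 * lam3^(3 / 2))
  expect_true(all(l3 >= 0))

  # doubling all sides multiplies the top LKC by 2^D
  for (dims in list(7, c(11, 13), c(5, 6, 7))) {
    D <- length(dims)
    l1 <- lkcs_box(box_domain(dims), 8)
    l2 <- lkcs_box(box_domain(2 * unlist(dims)), 8)
    expect_identical(l2[D + 1], 2^D * l1[D + 1])
  }
})

test_that("volume-only formula equals the top-order LKC term at unit variance", {
  set.seed(101)
  for (i in 1:40) {
    D <- sample(1:3, 1)
    dom <- box_domain(sample(3:60, D, replace = TRUE))
    fwhm <- runif(1, 2, 30)
    u <- runif(1, -1, 4)
    p <- expected_ec_lkc(dom, fwhm, u)
    expect_equal(p$eq1, p$per_order[D + 1], tolerance = 1e-12)
    expect_equal(p$eq1, expected_ec_original(dom, fwhm, u, sigma = 1),
                 tolerance = 1e-12)
  }
})

test_that("volume-only formula vanishes at extreme thresholds and rejects bad sigma", {
  dom <- box_domain(c(40, 40))
  expect_lt(abs(expected_ec_original(dom, 5, u = 50)), 1e-12)
  expect_lt(abs(expected_ec_lkc(dom, 5, u = 50)$eq2), 1e-10)
  expect_error(expected_ec_original(dom, 5, u = 2, sigma = 0), "sigma")
  expect_error(expected_ec_original(dom, 5, u = 2, sigma = -1), "sigma")
})

test_that("LKC expansion assembles per-order terms coherently", {
  dom <- box_domain(c(250, 250))
  p <- expected_ec_lkc(dom, 5, 3)
  lkc <- lkcs_box(dom, 5)
  expect_equal(p$eq2,
               ec_density(0, 3) + lkc[2] * ec_density(1, 3) +
                 lkc[3] * ec_density(2, 3))
  expect_equal(p$eq2, sum(p$per_order))

  # eq2 - eq1 is exactly the boundary contribution
  for (fwhm in c(5, 12)) {
    for (u in c(1.5, 2.5)) {
      dom3 <- box_domain(c(30, 40, 50))
      p3 <- expected_ec_lkc(dom3, fwhm, u)
      lkc3 <- lkcs_box(dom3, fwhm)
      expect_equal(p3$eq2 - p3$eq1,
                   sum(lkc3[1:3] * vapply(0:2, ec_density, numeric(1), u = u)))
    }
  }
})

test_that("torus expectation keeps only the top-order term", {
  set.seed(202)
  for (i in 1:20) {
    D <- sample(1:3, 1)
    dom <- box_domain(sample(5:50, D, replace = TRUE))
    fwhm <- runif(1, 3, 25)
    u <- runif(1, 0, 4)
    expect_equal(expected_ec_torus(dom, fwhm, u),
                 expected_ec_original(dom, fwhm, u, sigma = 1),
                 tolerance = 1e-12)
  }
  dom <- box_domain(c(100, 100))
  lam <- 4 * log(2) / 64
  expect_equal(expected_ec_torus(dom, 8, 2.5),
               1e4 * lam * (2 * pi)^(-3 / 2) * 2.5 * exp(-2.5^2 / 2))
  # rho_3(0) < 0: the torus expectation can be negative at low thresholds
  expect_lt(expected_ec_torus(box_domain(c(20, 20, 20)), 6, 0), 0)
})

test_that("expected EC decreases in FWHM and in threshold", {
  fwhms <- c(5, 10, 15, 20, 25)
  for (D in 1:3) {
    dom <- switch(D, box_domain(10000), box_domain(c(250, 250)),
                  box_domain(c(90, 90, 90)))
    for (u in c(1.5, 2, 2.5, 3)) {
      eq2 <- vapply(fwhms, function(f) expected_ec_lkc(dom, f, u)$eq2,
                    numeric(1))
      expect_true(all(diff(eq2) < 0))
    }
    for (f in fwhms) {
      # rho_3 increases up to u = sqrt(3), so threshold monotonicity of the
      # 3D expansion only holds beyond it; 1D/2D are monotone from 1.5 on
      us <- seq(if (D == 3) 1.75 else 1.5, 4, by = 0.25)
      eq2u <- vapply(us, function(u) expected_ec_lkc(dom, f, u)$eq2, numeric(1))
      expect_true(all(diff(eq2u) < 0))
    }
  }
})

test_that("1D top-order term is the classical Rice upcrossing rate", {
  set.seed(303)
  for (i in 1:10) {
    L <- sample(100:20000, 1)
    fwhm <- runif(1, 2, 30)
    u <- runif(1, 0, 4)
    lam <- 4 * log(2) / fwhm^2
    rice <- L * sqrt(lam) * exp(-u^2 / 2) / (2 * pi)
    dom <- box_domain(L)
    expect_equal(lkcs_box(dom, fwhm)[2] * ec_density(1, u), rice,
                 tolerance = 1e-12)
  }
})

test_that("domain and smoothness constructors validate their inputs", {
  expect_error(box_domain(c(2, 2, 2, 2)), "unsupported dimension")
  expect_error(box_domain(integer(0)), "unsupported dimension")
  expect_error(box_domain(c(10, 0)), "positive")
  expect_error(box_domain(2.5), "positive integers")
  expect_error(smoothness_spec(-1), "positive")
  expect_error(smoothness_spec(5, D = 4), "unsupported dimension")

  s <- smoothness_spec(5, D = 3)
  expect_equal(s$lam, 4 * log(2) / 25)
  expect_equal(s$Lambda, diag(s$lam, 3))
  expect_equal(det(s$Lambda), s$lam^3)
  expect_equal(box_volume(box_domain(c(9, 8, 7))), 504)
  expect_equal(intrinsic_volumes(box_domain(c(3, 4, 5))),
               c(1, 12, 3 * 4 + 3 * 5 + 4 * 5, 60))
})
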