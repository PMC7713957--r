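test_that("noise-free single-species records are recovered exactly", {
  N <- matrix(c(10, 50, 90, 130), ncol = 1)
  lag <- lagged_from_design(N, r = 1.0, A = matrix(-0.01), species = "x")
  fit <- fit_linear(lag)
  expect_equal(unname(fit$params$r), 1.0)
  expect_equal(unname(fit$params$A[1, 1]), -0.01)
})

test_that("constant growth rates give a zero slope", {
  N <- matrix(c(10, 30, 70, 110), ncol = 1)
  lag <- lagged_from_design(N, r = 0.5, A = matrix(0), species = "x")
  fit <- fit_linear(lag)
  expect_equal(unname(fit$params$r), 0.5)
  expect_equal(unname(fit$params$A[1, 1]), 0, tolerance = 1e-12)
})

test_that("two-species coefficients are recovered to machine precision", {
  r <- c(1.0, -0.5)
  A <- matrix(c(-0.01, -0.002, 0.001, -0.005), 2, byrow = TRUE)
  grid <- expand.grid(N1 = c(5, 40, 80, 120), N2 = c(3, 20, 60, 100))
  N <- as.matrix(grid)
  lag <- lagged_from_design(N, r, A, species = c("s1", "s2"))
  fit <- fit_linear(lag)
  expect_equal(unname(fit$params$r), r, tolerance = 1e-12)
  expect_equal(unname(fit$params$A), unname(A), tolerance = 1e-12)
})

test_that("fit_linear equals the normal-equations oracle on random designs", {
  set.seed(11)
  for (rep in 1:20) {
    n_rec <- sample(4:6, 1)
    N <- matrix(runif(2 * n_rec, 1, 100), ncol = 2)
    y_extra <- rnorm(n_rec, sd = 0.3) # noise so the fit is non-trivial
    r <- runif(2, -1, 1)
    A <- matrix(runif(4, -0.02, 0.02), 2)
    lag <- lagged_from_design(N, r, A, species = c("s1", "s2"))
    lag$dNNdt[lag$species == "s1"] <- lag$dNNdt[lag$species == "s1"] + y_extra
    fit <- fit_linear(lag)
    beta <- ols_oracle(N, lag$dNNdt[lag$species == "s1"])
    expect_equal(unname(fit$params$r["s1"]), beta[1], tolerance = 1e-10)
    expect_equal(unname(fit$params$A["s1", ]), beta[2:3], tolerance = 1e-10)
  }
})

test_that("rescaling one species' abundance rescales only that column of A", {
  r <- c(0.8, 0.3)
  A <- matrix(c(-0.01, -0.004, 0.002, -0.008), 2, byrow = TRUE)
  N <- as.matrix(expand.grid(N1 = c(5, 40, 80, 120), N2 = c(3, 20, 60, 100)))
  lag <- lagged_from_design(N, r, A, species = c("s1", "s2"))
  cc <- 10
  N2 <- N; N2[, 2] <- N2[, 2] * cc
  lag2 <- lagged_from_design(N, r, A, species = c("s1", "s2"))
  lag2$N_s2 <- lag2$N_s2 * cc
  lag2$N_t1[lag2$species == "s2"] <- lag2$N_t1[lag2$species == "s2"] * cc
  f1 <- fit_linear(lag)
  f2 <- fit_linear(lag2)
  expect_equal(f2$params$r, f1$params$r, tolerance = 1e-10)
  expect_equal(f2$params$A[, 1], f1$params$A[, 1], tolerance = 1e-10)
  expect_equal(f2$params$A[, 2], f1$params$A[, 2] / cc, tolerance = 1e-10)
})

test_that("masked coefficients are excluded from the design and stay zero", {
  r <- c(1.0, -0.5)
  A <- matrix(c(-0.01, 0, 0.001, -0.005), 2, byrow = TRUE)
  N <- as.matrix(expand.grid(N1 = c(5, 40, 80), N2 = c(3, 20, 60)))
  lag <- lagged_from_design(N, r, A, species = c("s1", "s2"))
  mask <- mask_fix_zero(lv_mask(c("s1", "s2")), "a", "s1", "s2")
  fit <- fit_linear(lag, mask)
  expect_identical(unname(fit$params$A["s1", "s2"]), 0)
  expect_true(is.na(fit$se$A["s1", "s2"]))
  expect_equal(unname(fit$params$r), r, tolerance = 1e-10)
})

test_that("degenerate designs raise estimation errors naming the species", {
  # too few records
  N <- matrix(c(10, 20), ncol = 1)
  lag <- lagged_from_design(N, 1, matrix(-0.01), species = "x")
  expect_error(fit_linear(lag), "x")
  # collinear two-species design
  N <- cbind(c(5, 10, 20, 40, 70), 2 * c(5, 10, 20, 40, 70))
  lag <- lagged_from_design(N, c(1, 1), matrix(-0.01, 2, 2),
                            species = c("s1", "s2"))
  expect_error(fit_linear(lag), "rank-deficient|collinear")
})

test_that("carrying capacity follows K = -r / a_ii", {
  expect_equal(carrying_capacity(0.96, -0.005), 192)
  expect_equal(carrying_capacity(1.0, -0.01), 100)
  expect_error(carrying_capacity(0.5, 0), "a_ii")
  set.seed(3)
  r <- runif(20, 0.01, 2)
  a <- -runif(20, 1e-4, 1e-1)
  expect_true(all(carrying_capacity(r, a) > 0))
})

test_that("determine_signs takes signs from estimates with stated defaults", {
  N <- matrix(c(10, 50, 90, 130), ncol = 1)
  lag <- lagged_from_design(N, r = 0.96, A = matrix(-0.005), species = "x")
  m <- determine_signs(fit_linear(lag))
  expect_equal(unname(m$r$sign), 1)
  expect_equal(unname(m$A$sign[1, 1]), -1)
  # exactly-zero diagonal slope estimate defaults to self-limitation (-)
  lag0 <- lagged_from_design(N, r = 0.5, A = matrix(0), species = "x")
  fit0 <- fit_linear(lag0)
  fit0$params$A[1, 1] <- 0 # force the exact-zero corner case
  m0 <- determine_signs(fit0)
  expect_equal(unname(m0$A$sign[1, 1]), -1)
})

test_that("predator-prey sign pattern from the regressions is preserved", {
  r <- c(1.0, -0.5)
  A <- matrix(c(-0.005, -0.02, 0.01, -0.001), 2, byrow = TRUE)
  N <- as.matrix(expand.grid(N1 = c(10, 40, 80, 120),
                             N2 = c(5, 15, 35, 60)))
  lag <- lagged_from_design(N, r, A, species = c("prey", "pred"))
  m <- determine_signs(fit_linear(lag))
  expect_equal(unname(m$r$sign[c("prey", "pred")]), c(1, -1))
  expect_equal(unname(m$A$sign[c("prey", "pred"), c("prey", "pred")]),
               matrix(c(-1, -1, 1, -1), 2, byrow = TRUE))
})

test_that("user constraints override data-driven signs", {
  N <- as.matrix(expand.grid(N1 = c(10, 40, 80), N2 = c(5, 15, 35)))
  lag <- lagged_from_design(N, c(1, 0.5), matrix(-0.01, 2, 2) +
                              diag(c(0, 0.005)),
                            species = c("s1", "s2"))
  user <- mask_fix_zero(lv_mask(c("s1", "s2")), "a", "s2", "s1")
  user <- mask_set_sign(user, "r", "s2", sign = -1)
  m <- determine_signs(fit_linear(lag), user)
  expect_identical(unname(m$A$status["s2", "s1"]), "zero")
  expect_equal(unname(m$r$sign["s2"]), -1)
})
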