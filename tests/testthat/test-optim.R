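make_mask_2sp <- function() {
  m <- lv_mask(c("prey", "pred"))
  m$r$sign[] <- c(1, -1)
  m$A$sign[] <- matrix(c(-1, -1, 1, -1), 2, byrow = TRUE)
  m
}

test_that("pack/unpack round-trips any valid parameter set", {
  set.seed(21)
  m <- make_mask_2sp()
  for (rep in 1:20) {
    p <- lv_params(c("prey", "pred"),
                   r = c(runif(1, 0.01, 2), -runif(1, 0.01, 2)),
                   A = matrix(c(-runif(1, 1e-4, 1e-1), -runif(1, 1e-4, 1e-1),
                                runif(1, 1e-4, 1e-1), -runif(1, 1e-4, 1e-1)),
                              2, byrow = TRUE),
                   N0 = runif(2, 0.1, 50))
    back <- lv_unpack(lv_pack(p, m), m)
    expect_equal(back$r, p$r)
    expect_equal(back$A, p$A)
    expect_equal(back$N0, p$N0)
  }
})

test_that("packed entries are log magnitudes in documented order", {
  m <- lv_mask("x")
  m$r$sign[] <- 1
  m$A$sign[] <- -1
  p <- lv_params("x", r = 0.96, A = matrix(-0.005), N0 = 2)
  theta <- lv_pack(p, m)
  expect_equal(names(theta), c("r:x", "a:x:x", "n0:x"))
  expect_equal(unname(theta), c(log(0.96), log(0.005), log(2)))
})

test_that("pack rejects sign mismatches and nonzero pinned entries", {
  m <- make_mask_2sp()
  p <- lv_params(c("prey", "pred"), r = c(1, 0.5), # pred r should be < 0
                 A = matrix(c(-0.01, -0.02, 0.01, -0.001), 2, byrow = TRUE),
                 N0 = c(10, 5))
  expect_error(lv_pack(p, m), "sign")
  m2 <- mask_fix_zero(m, "a", "prey", "prey")
  p2 <- lv_params(c("prey", "pred"), r = c(1, -0.5),
                  A = matrix(c(-0.01, -0.02, 0.01, -0.001), 2, byrow = TRUE),
                  N0 = c(10, 5))
  expect_error(lv_pack(p2, m2), "zero")
})

test_that("unpack reinstates exact zeros for pinned parameters", {
  m <- mask_fix_zero(make_mask_2sp(), "a", "prey", "prey")
  theta <- rep(log(0.5), 7) # 2 r + 3 free A entries + 2 N0
  p <- lv_unpack(theta, m)
  expect_identical(unname(p$A[1, 1]), 0)
  expect_equal(unname(p$A[1, 2]), -0.5)
})

test_that("objective is ~0 at the generating parameters of noise-free data", {
  sc <- lv_preset("predator_prey_damped", noise_sd = 0)
  dat <- generate_observations(sc)
  m <- dat$mask
  fn <- make_lv_objective(dat$observations, m)
  theta <- lv_pack(dat$truth, m)
  expect_lt(fn(theta), 1e-8)
  # perturbed parameters score worse
  expect_gt(fn(theta + 0.1), fn(theta))
})

test_that("the objective is invariant to rescaling a species' unit", {
  sc <- lv_preset("paramecium_competition", noise_sd = 0)
  dat <- generate_observations(sc)
  m <- dat$mask
  fn <- make_lv_objective(dat$observations, m)
  theta <- lv_pack(dat$truth, m)
  # rescale species 1's unit by c: N0 and observations x c, column 1 of A / c
  cc <- 7
  obs2 <- dat$observations
  sel <- obs2$species == "P_caudatum"
  obs2$abundance[sel] <- obs2$abundance[sel] * cc
  tr2 <- dat$truth
  tr2$N0["P_caudatum"] <- tr2$N0["P_caudatum"] * cc
  tr2$A[, "P_caudatum"] <- tr2$A[, "P_caudatum"] / cc
  fn2 <- make_lv_objective(obs2, m)
  expect_equal(fn2(lv_pack(tr2, m)), fn(theta), tolerance = 1e-6)
})

test_that("divergent parameter regions return the finite penalty", {
  m <- lv_mask(c("a", "b"))
  m$r$sign[] <- 1
  m$A$sign[] <- matrix(c(-1, 1, 1, -1), 2) # mutualism off-diagonals
  obs <- obs_from_matrix(0:10, cbind(a = exp(0:10), b = exp(0:10)))
  p <- lv_params(c("a", "b"), r = c(1, 1),
                 A = matrix(c(-1e-9, 0.5, 0.5, -1e-9), 2, byrow = TRUE),
                 N0 = c(10, 10))
  fn <- make_lv_objective(obs, m)
  expect_identical(fn(lv_pack(p, m)), 1e10)
})

test_that("approx_se reproduces the closed-form quadratic oracle", {
  # f(x) = (x - 1)^2: H = 2 everywhere; with m residuals and k = 1,
  # sigma^2 = f/(m-k) and cov = 2 sigma^2 / H = sigma^2
  fn <- function(theta) (theta - 1)^2
  theta_hat <- 1.3 # not at the minimum: f > 0 so sigma > 0
  m_obs <- 10
  s_expected <- sqrt(fn(theta_hat) / (m_obs - 1))
  se <- approx_se(theta_hat, fn, n_obs = m_obs)
  expect_equal(unname(se$log_sd), s_expected, tolerance = 1e-5)
  p <- exp(theta_hat)
  expect_equal(unname(se$se), p * (1 - exp(-se$log_sd)), tolerance = 1e-10)
})

test_that("zero log-space spread gives zero natural-scale standard error", {
  p <- 0.96
  expect_equal(abs(p) * (1 - exp(-0)), 0)
  # and the published-order-of-magnitude consistency case
  expect_equal(0.96 * (1 - exp(-0.13)), 0.117, tolerance = 0.005)
})

test_that("optimHess agrees with an independent numerical Hessian", {
  skip_if_not_installed("pracma")
  fn <- function(x) sum((x - c(1, 2))^2 * c(2, 3)) + x[1] * x[2]
  x0 <- c(0.4, 0.9)
  H1 <- stats::optimHess(x0, fn)
  H2 <- pracma::hessian(fn, x0)
  expect_equal(H1, H2, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("an optimal start is a fixed point of the optimizer", {
  sc <- lv_preset("logistic_monoculture", noise_sd = 0)
  dat <- generate_observations(sc)
  fit <- suppressWarnings(lv_optim(dat$truth, dat$observations, dat$mask))
  fn <- make_lv_objective(dat$observations, dat$mask)
  expect_lt(fn(lv_pack(dat$truth, dat$mask)) - fit$objective_value, 1e-10)
  expect_equal(fit$params$r, dat$truth$r, tolerance = 1e-4)
})

test_that("optimization improves on the start, deterministically, sign-safely", {
  sc <- lv_preset("logistic_monoculture", noise_sd = 0.15, seed = 99)
  dat <- generate_observations(sc)
  start <- dat$truth
  start$r <- start$r * 1.5
  start$A <- start$A * 1.5
  f1 <- lv_optim(start, dat$observations, dat$mask)
  f2 <- lv_optim(start, dat$observations, dat$mask)
  expect_lte(f1$objective_value, f1$start_objective)
  expect_identical(f1$theta, f2$theta) # bit-identical repeat runs
  expect_true(f1$params$r > 0 && f1$params$A[1, 1] < 0)
  fn <- make_lv_objective(dat$observations, dat$mask)
  expect_equal(fn(f1$theta), f1$objective_value, tolerance = 1e-8)
})

test_that("zero-status parameters stay exactly zero through optimization", {
  sc <- lv_preset("predator_prey_neutral", noise_sd = 0)
  dat <- generate_observations(sc)
  fit <- lv_optim(dat$truth, dat$observations, dat$mask)
  expect_identical(unname(fit$params$A[1, 1]), 0)
  expect_identical(unname(fit$params$A[2, 2]), 0)
})

test_that("noise-free logistic start perturbed by 1.5x is recovered to <1%", {
  truth <- lv_params("x", r = 0.96, A = matrix(-0.005), N0 = 2)
  obs <- obs_from_matrix(seq(0, 24, by = 1),
                         matrix(simulate_lv(truth, seq(0, 24, 1))$x,
                                dimnames = list(NULL, "x"), ncol = 1))
  m <- lv_mask("x"); m$r$sign[] <- 1; m$A$sign[] <- -1
  start <- truth
  start$r <- start$r * 1.5
  start$A <- start$A * 1.5
  start$N0 <- start$N0 * 1.5
  fit <- lv_optim(start, obs, m)
  expect_lt(rel_err_params(fit$params, truth), 0.01)
})
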