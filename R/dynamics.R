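#' Closed-form logistic growth
#'
#' Evaluates the analytic solution of `dN/dt = r N (1 - N/K)`,
#' \deqn{N(t) = K / (1 + (K/N_0 - 1) e^{-r t}),}
#' with time measured from `t0` (by default the first requested time).
#' This is the single-species Lotka-Volterra model with `a_ii = -r/K`.
#'
#' @param n0 positive initial abundance (at `t0`).
#' @param r intrinsic growth rate.
#' @param k positive carrying capacity.
#' @param times numeric vector of times at which to evaluate.
#' @param t0 time origin; defaults to `times[1]`.
#' @return Numeric vector of abundances, one per requested time.
#' @examples
#' logistic_solution(5, 0.96, 202.31, 0:24)
#' @export
logistic_solution <- function(n0, r, k, times, t0 = times[1]) {
  if (!is.finite(n0) || n0 <= 0) stop("n0 must be positive")
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  tt <- times - t0
  k / (1 + (k / n0 - 1) * exp(-r * tt))
}

#' Lotka-Volterra right-hand sides
#'
#' `lv_rhs` returns dN/dt for the generalized Lotka-Volterra model,
#' componentwise `N_i (r_i + sum_j A[i,j] N_j)`. `lv_rhs_log` is the same
#' vector field expressed for log-transformed abundances `x = log(N)`:
#' `dx_i/dt = r_i + sum_j A[i,j] exp(x_j)`, which keeps abundances strictly
#' positive during integration and is numerically helpful when abundances
#' approach zero.
#'
#' @param N numeric vector of abundances (length n).
#' @param x numeric vector of log abundances.
#' @param params an [lv_params] object.
#' @param ceiling abundance ceiling; `lv_rhs_log` signals a divergence
#'   error when `exp(x)` would exceed it.
#' @return Numeric vector of derivatives.
#' @examples
#' p <- lv_params("x", r = 1, A = matrix(-0.005), N0 = 2)
#' lv_rhs(100, p)        # 50
#' lv_rhs_log(log(100), p) # 0.5
#' @export
lv_rhs <- function(N, params) {
  stopifnot(inherits(params, "lv_params"))
  if (length(N) != length(params$species))
    stop("length(N) must match the number of species")
  if (any(N < 0)) warning("negative abundances supplied to lv_rhs")
  as.numeric(N * (params$r + params$A %*% N))
}

#' @rdname lv_rhs
#' @export
lv_rhs_log <- function(x, params, ceiling = 1e15) {
  stopifnot(inherits(params, "lv_params"))
  if (length(x) != length(params$species))
    stop("length(x) must match the number of species")
  if (any(x > log(ceiling)))
    stop(sim_error("abundance exceeded ceiling in log-space dynamics"))
  as.numeric(params$r + params$A %*% exp(x))
}

sim_error <- function(msg, last_time = NA_real_) {
  errorCondition(msg, last_time = last_time, class = "lvfit_sim_error")
}

#' Simulate Lotka-Volterra dynamics
#'
#' Numerically integrates the n-species Lotka-Volterra system from
#' `params$N0` at `times[1]`, using adaptive step-size control
#' (`deSolve::ode`, lsoda). By default dynamics are integrated for
#' log-transformed abundances and back-transformed on return, which
#' guarantees strictly positive trajectories; `space = "linear"` integrates
#' raw abundances instead.
#'
#' @param params an [lv_params] object.
#' @param times strictly increasing numeric vector of output times.
#' @param space `"log"` (default) or `"linear"`.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param ceiling divergence guard: integration aborts (with a simulation
#'   error carrying the last good time) if any abundance exceeds this.
#' @return A data.frame trajectory in wide format: column `time` plus one
#'   abundance column per species.
#' @examples
#' p <- lv_params("x", r = 0.96, A = matrix(-0.005), N0 = 2)
#' head(simulate_lv(p, 0:24))
#' @export
simulate_lv <- function(params, times, space = c("log", "linear"),
                        rtol = 1e-8, atol = 1e-10, ceiling = 1e15) {
  stopifnot(inherits(params, "lv_params"))
  space <- match.arg(space)
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be a strictly increasing vector of length >= 2")
  n <- length(params$species)
  guard <- log(ceiling)
  if (space == "log") {
    if (any(params$N0 <= 0))
      stop("log-space simulation requires strictly positive N0")
    y0 <- log(params$N0)
    func <- function(t, x, p) {
      if (any(!is.finite(x)) || any(x > guard))
        stop(sim_error("divergence in log-space simulation", last_time = t))
      list(as.numeric(p$r + p$A %*% exp(x)))
    }
  } else {
    y0 <- params$N0
    func <- function(t, N, p) {
      if (any(!is.finite(N)) || any(abs(N) > ceiling))
        stop(sim_error("divergence in linear-space simulation", last_time = t))
      list(as.numeric(N * (p$r + p$A %*% N)))
    }
  }
  sol <- withCallingHandlers(
    tryCatch(deSolve::ode(y = y0, times = times, func = func, parms = params,
                          rtol = rtol, atol = atol),
             lvfit_sim_error = function(e) stop(e),
             error = function(e) stop(sim_error(conditionMessage(e)))),
    warning = function(w) invokeRestart("muffleWarning"))
  if (nrow(sol) < length(times) || any(!is.finite(sol)))
    stop(sim_error("integration failed before the last requested time",
                   last_time = sol[nrow(sol), 1L]))
  ab <- matrix(sol[, -1L, drop = FALSE], ncol = n)
  if (space == "log") ab <- exp(ab)
  out <- data.frame(time = times)
  for (k in seq_len(n)) out[[params$species[k]]] <- ab[, k]
  out
}

#' Predicted abundances as a single stacked vector
#'
#' Convenience front end for external optimizers: simulates the system and
#' returns predictions as one column vector, species blocks stacked in
#' order (all times for species 1, then species 2, ...).
#'
#' @inheritParams simulate_lv
#' @return Numeric vector of length `length(times) * n_species`.
#' @export
ode_prediction <- function(params, times, space = c("log", "linear"),
                           rtol = 1e-8, atol = 1e-10) {
  traj <- simulate_lv(params, times, space, rtol = rtol, atol = atol)
  as.numeric(unlist(traj[params$species], use.names = FALSE))
}

#' @rdname simulate_lv
#' @param trajectory a wide-format trajectory data.frame.
#' @param path file path for the CSV output (`time,<sp1>,<sp2>,...`).
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname simulate_lv
#' @export
read_trajectory <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                         check.names = FALSE)
  if (names(out)[1L] != "time") stop("trajectory CSV must start with 'time'")
  out
}
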