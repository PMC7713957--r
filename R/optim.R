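# theta layout: free r entries, free A entries (row-major), then all N0,
# each stored as log|value| with the sign held in the mask.
theta_template <- function(mask) {
  sp <- mask$species
  n <- length(sp)
  rows <- list()
  for (i in seq_len(n)) if (mask$r$status[i] == "free")
    rows[[length(rows) + 1L]] <- data.frame(block = "r", i = i, j = NA_integer_,
                                            sign = mask$r$sign[i],
                                            name = paste0("r:", sp[i]))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (mask$A$status[i, j] == "free")
      rows[[length(rows) + 1L]] <- data.frame(block = "a", i = i, j = j,
                                              sign = mask$A$sign[i, j],
                                              name = paste0("a:", sp[i], ":", sp[j]))
  for (i in seq_len(n))
    rows[[length(rows) + 1L]] <- data.frame(block = "n0", i = i, j = NA_integer_,
                                            sign = 1,
                                            name = paste0("n0:", sp[i]))
  tmpl <- do.call(rbind, rows)
  if (any(is.na(tmpl$sign)))
    stop("mask has free parameters without signs; run determine_signs() first")
  tmpl
}

#' Pack / unpack parameters for sign-constrained log-scale optimization
#'
#' Free parameters are optimized as the natural log of their magnitude,
#' with each parameter's sign fixed a priori in the mask. `lv_pack` maps an
#' [lv_params] to the packed vector (order: free `r` entries, free `A`
#' entries row-major, then all `N0`); `lv_unpack` inverts it exactly,
#' reinstating zeros for masked-out entries.
#'
#' @param params an [lv_params] obeying the mask (free entries non-zero
#'   with the mask's sign; zero-status entries exactly 0).
#' @param mask an [lv_mask] with signs assigned.
#' @return `lv_pack`: named numeric vector of log magnitudes.
#'   `lv_unpack`: an [lv_params].
#' @examples
#' p <- lv_params("x", r = 0.96, A = matrix(-0.005), N0 = 2)
#' m <- determine_signs(structure(list(params = p, mask = lv_mask("x")),
#'                                class = "lv_linfit"))
#' lv_unpack(lv_pack(p, m), m)
#' @export
lv_pack <- function(params, mask) {
  stopifnot(inherits(params, "lv_params"), inherits(mask, "lv_mask"))
  if (!identical(params$species, mask$species))
    stop("params and mask refer to different species sets")
  tmpl <- theta_template(mask)
  val <- numeric(nrow(tmpl))
  for (k in seq_len(nrow(tmpl))) {
    v <- switch(tmpl$block[k],
                r = params$r[tmpl$i[k]],
                a = params$A[tmpl$i[k], tmpl$j[k]],
                n0 = params$N0[tmpl$i[k]])
    if (v == 0 || sign(v) != tmpl$sign[k])
      stop("parameter ", tmpl$name[k], " (", v,
           ") is zero or contradicts its masked sign")
    val[k] <- log(abs(v))
  }
  zr <- mask$r$status == "zero"
  if (any(params$r[zr] != 0) || any(params$A[mask$A$status == "zero"] != 0))
    stop("zero-status parameters must be exactly 0 in params")
  stats::setNames(val, tmpl$name)
}

#' @rdname lv_pack
#' @param theta packed numeric vector (log magnitudes).
#' @export
lv_unpack <- function(theta, mask) {
  stopifnot(inherits(mask, "lv_mask"))
  tmpl <- theta_template(mask)
  if (length(theta) != nrow(tmpl))
    stop("theta has length ", length(theta), ", expected ", nrow(tmpl))
  n <- length(mask$species)
  r <- stats::setNames(rep(0, n), mask$species)
  A <- matrix(0, n, n, dimnames = list(mask$species, mask$species))
  N0 <- stats::setNames(rep(NA_real_, n), mask$species)
  v <- tmpl$sign * exp(as.numeric(theta))
  for (k in seq_len(nrow(tmpl))) {
    switch(tmpl$block[k],
           r = { r[tmpl$i[k]] <- v[k] },
           a = { A[tmpl$i[k], tmpl$j[k]] <- v[k] },
           n0 = { N0[tmpl$i[k]] <- v[k] })
  }
  lv_params(mask$species, r, A, N0)
}

# Align a long observation table (single treatment) to a times x species
# matrix; NA where a species was not observed at a time.
align_observations <- function(observed, species) {
  observed <- validate_observations(observed)
  if (length(unique(observed$treatment)) > 1L)
    stop("observations span several treatments; subset to one realized ",
         "trajectory before optimization")
  extra <- setdiff(unique(observed$species), species)
  if (length(extra))
    stop("observed species not in the parameter set: ",
         paste(extra, collapse = ", "))
  times <- sort(unique(observed$time))
  obs <- matrix(NA_real_, length(times), length(species),
                dimnames = list(NULL, species))
  ti <- match(observed$time, times)
  si <- match(observed$species, species)
  obs[cbind(ti, si)] <- observed$abundance
  list(times = times, obs = obs)
}

#' Sum-of-squares objective on mean-standardized abundances
#'
#' Builds the objective minimized by [lv_optim()]: the packed parameters
#' are unpacked, dynamics are simulated at the observed times, both
#' observed and predicted abundances are divided by each species' mean
#' observed abundance (so every species has mean one and abundant species
#' cannot dominate the fit), and the sum of squared differences over all
#' species and times is returned. A failed or divergent simulation returns
#' a large finite penalty so the simplex can retreat.
#'
#' @param observed a single-treatment observation table.
#' @param mask an [lv_mask] with signs assigned.
#' @param space integration space, `"log"` (default) or `"linear"`.
#' @param scales optional named per-species scales; defaults to the mean
#'   observed abundance (computed once from observations).
#' @param penalty finite value returned on simulation failure.
#' @param rtol,atol integration tolerances.
#' @return A function `f(theta) -> non-negative real`, with attributes
#'   `n_obs` (number of observed values) and `scales`.
#' @export
make_lv_objective <- function(observed, mask, space = c("log", "linear"),
                              scales = NULL, penalty = 1e10,
                              rtol = 1e-8, atol = 1e-10) {
  space <- match.arg(space)
  al <- align_observations(observed, mask$species)
  if (is.null(scales)) {
    scales <- colMeans(al$obs, na.rm = TRUE)
  } else {
    scales <- scales[mask$species]
  }
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("every species needs a positive mean observed abundance")
  obs_std <- sweep(al$obs, 2L, scales, "/")
  seen <- !is.na(obs_std)
  fn <- function(theta) {
    params <- lv_unpack(theta, mask)
    traj <- tryCatch(
      simulate_lv(params, al$times, space = space, rtol = rtol, atol = atol),
      lvfit_sim_error = function(e) NULL,
      error = function(e) NULL)
    if (is.null(traj)) return(penalty)
    pred <- as.matrix(traj[, mask$species, drop = FALSE])
    if (any(!is.finite(pred[seen]))) return(penalty)
    pred_std <- sweep(pred, 2L, scales, "/")
    sum((obs_std[seen] - pred_std[seen])^2)
  }
  attr(fn, "n_obs") <- sum(seen)
  attr(fn, "scales") <- scales
  attr(fn, "times") <- al$times
  fn
}

#' Approximate standard errors from a numerical Hessian
#'
#' Standard errors are approximated from the numerically differentiated
#' Hessian of the sum-of-squares objective with respect to the
#' log-transformed parameters, using the Gaussian least-squares
#' approximation `cov = 2 * sigma^2 * H^-1` with
#' `sigma^2 = SS / (m - k)` (m residuals, k free parameters). The
#' log-space standard deviation `s_j = sqrt(cov[j, j])` is reported on the
#' natural scale as the difference between the estimate and its lower
#' one-standard-deviation value in log space, `|p| * (1 - exp(-s_j))`.
#' Because parameter signs are constrained, these are rough measures of
#' uncertainty, not the basis for significance tests. A non-invertible or
#' non-positive-definite Hessian yields NA standard errors with a warning.
#'
#' @param theta_hat packed optimum.
#' @param fn the objective function (from [make_lv_objective()]).
#' @param n_obs number of residuals m; defaults to `attr(fn, "n_obs")`.
#' @param hessian optional precomputed Hessian; otherwise
#'   `stats::optimHess` (central differences) is used.
#' @return List with `log_sd` (per-parameter log-space sd, named as theta)
#'   and `se` (natural-scale standard errors, same names).
#' @export
approx_se <- function(theta_hat, fn, n_obs = attr(fn, "n_obs"),
                      hessian = NULL) {
  k <- length(theta_hat)
  if (is.null(n_obs) || n_obs <= k)
    stop("need more observations than free parameters for standard errors")
  if (is.null(hessian))
    hessian <- stats::optimHess(theta_hat, fn)
  s2 <- fn(theta_hat) / (n_obs - k)
  log_sd <- rep(NA_real_, k)
  covm <- tryCatch(2 * s2 * solve(hessian), error = function(e) NULL)
  if (is.null(covm) || any(!is.finite(diag(covm))) || any(diag(covm) < 0)) {
    warning("Hessian not positive definite; standard errors unavailable")
  } else {
    log_sd <- sqrt(diag(covm))
  }
  p <- exp(as.numeric(theta_hat))  # magnitudes
  se <- abs(p) * (1 - exp(-log_sd))
  names(log_sd) <- names(se) <- names(theta_hat)
  list(log_sd = log_sd, se = se)
}

# spread natural-scale SEs (named by theta) back into r/A/N0 shapes
se_to_shapes <- function(se, mask) {
  tmpl <- theta_template(mask)
  n <- length(mask$species)
  out <- list(r = stats::setNames(rep(NA_real_, n), mask$species),
              A = matrix(NA_real_, n, n,
                         dimnames = list(mask$species, mask$species)),
              N0 = stats::setNames(rep(NA_real_, n), mask$species))
  for (k in seq_len(nrow(tmpl))) {
    switch(tmpl$block[k],
           r = { out$r[tmpl$i[k]] <- se[k] },
           a = { out$A[tmpl$i[k], tmpl$j[k]] <- se[k] },
           n0 = { out$N0[tmpl$i[k]] <- se[k] })
  }
  out
}

#' Tune Lotka-Volterra parameters against simulated dynamics
#'
#' Minimizes the standardized sum-of-squares objective (observations vs.
#' fully simulated trajectories, see [make_lv_objective()]) over the
#' sign-constrained log-transformed parameters, by Nelder-Mead simplex
#' search from the supplied starting values. The run is deterministic:
#' identical inputs give identical optima. After optimization the final
#' trajectory, goodness of fit and approximate standard errors are
#' computed.
#'
#' @param start an [lv_params] of starting values (typically from
#'   [fit_linear()]), obeying `mask`.
#' @param observed a single-treatment observation table.
#' @param mask an [lv_mask] with signs (see [determine_signs()]).
#' @param space integration space for the simulations.
#' @param maxit maximum Nelder-Mead iterations per stage.
#' @param reltol relative convergence tolerance for the simplex stages.
#' @param stages number of successive Nelder-Mead runs; each restarts the
#'   simplex from the previous optimum, which helps against simplex
#'   stagnation and is still deterministic.
#' @param polish run a quasi-Newton (BFGS, central-difference gradients)
#'   refinement from the simplex optimum (default TRUE). The objective is
#'   smooth wherever simulations succeed, and the polish typically gains
#'   several orders of magnitude of accuracy at small cost; the result is
#'   kept only if it does not worsen the objective.
#' @param penalty objective value substituted for failed simulations.
#' @param compute_se set FALSE to skip the Hessian-based standard errors.
#' @param rtol,atol integration tolerances.
#' @return An object of class `lv_fit`; see [fit_lv()] for the fields.
#' @export
lv_optim <- function(start, observed, mask, space = c("log", "linear"),
                     maxit = 5000, reltol = 1e-8, stages = 1,
                     polish = TRUE, penalty = 1e10, compute_se = TRUE,
                     rtol = 1e-8, atol = 1e-10) {
  space <- match.arg(space)
  fn <- make_lv_objective(observed, mask, space = space, penalty = penalty,
                          rtol = rtol, atol = atol)
  theta <- lv_pack(start, mask)
  start_value <- fn(theta)
  value <- start_value
  counts <- 0L
  converged <- FALSE
  for (s in seq_len(max(1L, stages))) {
    opt <- stats::optim(theta, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    counts <- counts + opt$counts[["function"]]
    improved <- value - opt$value
    if (opt$value <= value) {
      theta <- opt$par
      value <- opt$value
    }
    converged <- opt$convergence == 0L
    if (s > 1L && improved < 1e-10) break
  }
  if (polish) {
    pol <- tryCatch(
      stats::optim(theta, fn, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12,
                                  ndeps = rep(1e-6, length(theta)))),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= value) {
      counts <- counts + pol$counts[["function"]]
      theta <- pol$par
      value <- pol$value
      converged <- pol$convergence == 0L
    }
  }
  if (!converged)
    warning("optimizer did not converge within the iteration budget; ",
            "returning the best point found")

  params <- lv_unpack(theta, mask)
  se <- list(log_sd = NULL,
             shapes = list(r = NULL, A = NULL, N0 = NULL))
  if (compute_se) {
    se_raw <- tryCatch(approx_se(theta, fn),
                       error = function(e) {
                         warning("standard errors unavailable: ",
                                 conditionMessage(e))
                         NULL
                       })
    if (!is.null(se_raw)) {
      se$log_sd <- se_raw$log_sd
      se$shapes <- se_to_shapes(se_raw$se, mask)
    } else {
      se$shapes <- se_to_shapes(rep(NA_real_, length(theta)), mask)
    }
  }
  times <- attr(fn, "times")
  trajectory <- simulate_lv(params, times, space = space,
                            rtol = rtol, atol = atol)
  gof <- gof_report(observed, trajectory)
  structure(list(params = params, se = se$shapes, log_sd = se$log_sd,
                 mask = mask, observed = validate_observations(observed),
                 trajectory = trajectory, gof = gof,
                 objective_value = value, start_objective = start_value,
                 theta = theta, scales = attr(fn, "scales"),
                 space = space, n_obs = attr(fn, "n_obs"),
                 evaluations = counts, converged = converged),
            class = "lv_fit")
}
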