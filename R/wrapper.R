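#' Full Lotka-Volterra fitting pipeline
#'
#' Automates the four-step workflow for fitting the generalized
#' Lotka-Volterra model to a multi-species abundance time series:
#' \enumerate{
#'   \item time-lagged observation pairs ([get_lag()]),
#'   \item per-capita growth rates over each interval ([percap_growth()]),
#'   \item ordinary least squares on the linearized model to obtain
#'     starting values and parameter signs ([fit_linear()],
#'     [determine_signs()]),
#'   \item sign-constrained Nelder-Mead refinement against fully simulated
#'     dynamics ([lv_optim()]), with initial abundances started at the
#'     first observed value of each species.
#' }
#' Linearized estimates alone often fail to reproduce long or oscillatory
#' time series because the equations are very sensitive to small parameter
#' changes; the simulation-based refinement is what makes the fitted
#' trajectories match observations.
#'
#' @param observed a single-treatment observation table (long format; see
#'   [validate_observations()]).
#' @param mask optional user [lv_mask] fixing parameters to zero or forcing
#'   signs; user constraints override the data-driven signs.
#' @param space integration space, `"log"` (default; keeps simulated
#'   abundances positive) or `"linear"`.
#' @param ... further arguments passed to [lv_optim()] (`maxit`, `reltol`,
#'   `stages`, `rtol`, `atol`, ...).
#' @return An object of class `lv_fit`: list with elements
#' \describe{
#'   \item{params}{fitted [lv_params]}
#'   \item{se}{approximate standard errors (`r`, `A`, `N0` shapes)}
#'   \item{trajectory}{fitted trajectory at the observed times}
#'   \item{gof}{[gof_report()] of the fit}
#'   \item{objective_value, start_objective}{standardized sum of squares at
#'     the optimum and at the starting values}
#'   \item{converged, evaluations}{optimizer diagnostics}
#'   \item{linear}{the `lv_linfit` stage-3 report (starting values)}
#' }
#' @examples
#' \donttest{
#' sc <- lv_preset("logistic_monoculture", noise_sd = 0)
#' dat <- generate_observations(sc)
#' fit <- fit_lv(dat$observations)
#' fit$params$r
#' }
#' @export
fit_lv <- function(observed, mask = NULL, space = c("log", "linear"), ...) {
  space <- match.arg(space)
  observed <- validate_observations(observed)
  if (length(unique(observed$treatment)) > 1L)
    stop("fit_lv() fits one realized trajectory: subset the table to a ",
         "single treatment (fit_linear() can pool treatments if you only ",
         "need the linearized estimates)")
  lagged <- withCallingHandlers(get_lag(observed),
                                message = function(m) {
                                  message("lag stage: ",
                                          conditionMessage(m), appendLF = FALSE)
                                  invokeRestart("muffleMessage")
                                })
  n_valid <- table(factor(lagged$species[lagged$valid],
                          levels = sort(unique(observed$species))))
  if (any(n_valid < 3L))
    stop("need at least 3 valid lagged records per species; short: ",
         paste(names(n_valid)[n_valid < 3L], collapse = ", "))
  linfit <- tryCatch(fit_linear(lagged, mask),
                     error = function(e)
                       stop("linear-estimation stage: ",
                            conditionMessage(e), call. = FALSE))
  smask <- determine_signs(linfit, mask)
  start <- linfit$params
  # N0 starts at the first observed abundance of each species
  first_obs <- vapply(start$species, function(sp) {
    x <- observed[observed$species == sp, , drop = FALSE]
    x <- x[!is.na(x$abundance) & x$abundance > 0, , drop = FALSE]
    if (!nrow(x)) stop("species '", sp, "' has no positive observation")
    x$abundance[which.min(x$time)]
  }, numeric(1))
  start$N0 <- first_obs
  # zero point estimates cannot be log-packed: nudge to a tiny magnitude
  # of the masked sign
  eps <- 1e-6
  fix <- start$r == 0 & smask$r$status == "free"
  start$r[fix] <- smask$r$sign[fix] * eps
  fix <- start$A == 0 & smask$A$status == "free"
  start$A[fix] <- smask$A$sign[fix] * eps
  start$r[smask$r$status == "zero"] <- 0
  start$A[smask$A$status == "zero"] <- 0
  # align start signs with any user-forced signs
  flip <- smask$r$status == "free" & sign(start$r) != smask$r$sign
  start$r[flip] <- -start$r[flip]
  flip <- smask$A$status == "free" & sign(start$A) != smask$A$sign &
    start$A != 0
  start$A[flip] <- -start$A[flip]
  fit <- lv_optim(start, observed, smask, space = space, ...)
  fit$linear <- linfit
  fit
}

#' @export
print.lv_fit <- function(x, ...) {
  cat("Lotka-Volterra fit (", length(x$params$species), " species, ",
      x$n_obs, " observations)\n", sep = "")
  fmt <- function(v, s) ifelse(is.na(s), sprintf("%.4g", v),
                               sprintf("%.4g (± %.2g)", v, s))
  cat("N0:", paste(x$params$species, fmt(x$params$N0, x$se$N0), sep = "=",
                   collapse = ", "), "\n")
  cat("r :", paste(x$params$species, fmt(x$params$r, x$se$r), sep = "=",
                   collapse = ", "), "\n")
  cat("A  (column acts on row):\n")
  am <- matrix(fmt(x$params$A, x$se$A), length(x$params$species),
               dimnames = dimnames(x$params$A))
  am[x$mask$A$status == "zero"] <- "0 (fixed)"
  print(am, quote = FALSE)
  if (length(x$params$species) == 1L && x$params$A[1, 1] != 0)
    cat("K :", sprintf("%.4g", carrying_capacity(x$params$r[1],
                                                 x$params$A[1, 1])), "\n")
  cat("objective:", format(x$objective_value, digits = 6),
      "(start", format(x$start_objective, digits = 6), ")",
      if (x$converged) "[converged]" else "[NOT converged]", "\n")
  print(x$gof)
  invisible(x)
}

#' Quick-look plot of a fitted trajectory
#'
#' Observed points and fitted curves per species (base graphics); the
#' fitted curve is re-simulated on a fine time grid for smoothness.
#'
#' @param x an `lv_fit` object.
#' @param n_grid number of points in the smooth curve.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.lv_fit <- function(x, n_grid = 200, ...) {
  times <- x$trajectory$time
  grid <- seq(min(times), max(times), length.out = n_grid)
  smooth <- simulate_lv(x$params, grid, space = x$space)
  sp <- x$params$species
  graphics::matplot(smooth$time, as.matrix(smooth[sp]), type = "l",
                    lty = 1, xlab = "time", ylab = "abundance", ...)
  for (k in seq_along(sp)) {
    o <- x$observed[x$observed$species == sp[k], , drop = FALSE]
    graphics::points(o$time, o$abundance, pch = 1, col = k)
  }
  graphics::legend("topleft", legend = sp, lty = 1,
                   col = seq_along(sp), bty = "n")
  invisible(x)
}

#' Write a fit result as JSON
#'
#' The JSON object carries the fitted parameters, approximate standard
#' errors, the constraint mask, per-species and total goodness of fit,
#' optimizer diagnostics, the effective configuration and the tool
#' version — a machine-readable, reproducible record of the fit.
#'
#' @param fit an `lv_fit` object.
#' @param path output file path.
#' @param config optional list of configuration values to embed.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, config = NULL) {
  stopifnot(inherits(fit, "lv_fit"))
  obj <- list(
    species = fit$params$species,
    params = list(r = unname(fit$params$r), A = unname(fit$params$A),
                  N0 = unname(fit$params$N0)),
    se = list(r = unname(fit$se$r), A = unname(fit$se$A),
              N0 = unname(fit$se$N0)),
    mask = list(r_status = unname(fit$mask$r$status),
                r_sign = unname(fit$mask$r$sign),
                A_status = unname(fit$mask$A$status),
                A_sign = unname(fit$mask$A$sign)),
    gof = list(per_species = as.list(fit$gof$per_species),
               total = fit$gof$total),
    objective_value = fit$objective_value,
    start_objective = fit$start_objective,
    converged = fit$converged,
    evaluations = fit$evaluations,
    space = fit$space,
    scales = as.list(fit$scales),
    config = config,
    tool_version = as.character(utils::packageVersion("lvfit")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}
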