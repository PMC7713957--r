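#' Linearized Lotka-Volterra estimation by ordinary least squares
#'
#' In per-capita form the Lotka-Volterra model is linear in abundances:
#' `dN_i/(N_i dt) = r_i + sum_j a_ij N_j`. For each species independently,
#' the per-capita growth rates from [get_lag()] are regressed on the
#' interval-start abundances of all species whose coefficient is free:
#' the intercept estimates `r_i`, the slope with respect to species `j`
#' estimates `a_ij`. Coefficients fixed to zero by the mask are excluded
#' from the design. Records flagged invalid (zero/missing abundance) or
#' with missing covariates are dropped, with a logged count.
#'
#' These OLS estimates serve as starting values (and sign determinations)
#' for the simulation-based optimizer; their standard errors are reported
#' as rough diagnostics only.
#'
#' @param lagged a lagged-growth data.frame from [get_lag()].
#' @param mask optional [lv_mask]; defaults to all parameters free. Its
#'   species set fixes the species ordering.
#' @return An object of class `lv_linfit`: list with `params`
#'   ([lv_params], `N0` set to each species' earliest observed abundance),
#'   `se` (list of `r`, `A` standard errors, NA where fixed), `sigma`
#'   (per-species residual standard deviation), `n_used`, `n_dropped`.
#' @examples
#' obs <- data.frame(time = rep(0:4, 1), species = "x",
#'                   abundance = c(10, 18, 30, 45, 60))
#' fit_linear(get_lag(obs))
#' @export
fit_linear <- function(lagged, mask = NULL) {
  if (!is.data.frame(lagged) || !all(c("species", "dNNdt", "valid") %in%
                                     names(lagged)))
    stop("'lagged' must be a data.frame from get_lag()")
  species <- if (!is.null(mask)) mask$species else sort(unique(lagged$species))
  if (is.null(mask)) mask <- lv_mask(species)
  n <- length(species)
  cov_names <- paste0("N_", species)
  if (!all(cov_names %in% names(lagged)))
    stop("lagged table lacks covariate column(s): ",
         paste(setdiff(cov_names, names(lagged)), collapse = ", "))

  r <- stats::setNames(rep(0, n), species)
  A <- matrix(0, n, n, dimnames = list(species, species))
  se_r <- stats::setNames(rep(NA_real_, n), species)
  se_A <- matrix(NA_real_, n, n, dimnames = list(species, species))
  sigma <- stats::setNames(rep(NA_real_, n), species)
  n_used <- stats::setNames(integer(n), species)
  n_dropped <- stats::setNames(integer(n), species)

  for (i in seq_len(n)) {
    sp <- species[i]
    rows <- lagged[lagged$species == sp, , drop = FALSE]
    if (nrow(rows) == 0L)
      stop("no lagged records for species '", sp, "'")
    free_j <- which(mask$A$status[i, ] == "free")
    has_intercept <- mask$r$status[i] == "free"
    X <- as.matrix(rows[, cov_names[free_j], drop = FALSE])
    keep <- rows$valid & stats::complete.cases(X)
    n_dropped[i] <- sum(!keep)
    n_used[i] <- sum(keep)
    p <- length(free_j) + as.integer(has_intercept)
    if (n_used[i] == 0L)
      stop("all lagged records invalid for species '", sp, "'")
    if (n_used[i] < p + 1L)
      stop("too few valid records (", n_used[i], ") to estimate ", p,
           " coefficient(s) for species '", sp, "'")
    y <- rows$dNNdt[keep]
    X <- X[keep, , drop = FALSE]
    df <- as.data.frame(X)
    names(df) <- paste0("x", seq_along(free_j))  # lm-safe names
    df$y <- y
    form <- stats::as.formula(paste(
      "y ~", if (has_intercept) "1" else "0",
      if (length(free_j)) paste("+", paste(names(df)[seq_along(free_j)],
                                           collapse = " + ")) else ""))
    fit <- stats::lm(form, data = df)
    cf <- stats::coef(fit)
    if (any(is.na(cf)))
      stop("rank-deficient design for species '", sp,
           "' (collinear abundances); fix more coefficients to zero")
    sm <- summary(fit)
    cse <- sm$coefficients[, "Std. Error"]
    if (has_intercept) {
      r[i] <- cf[["(Intercept)"]]
      se_r[i] <- cse[["(Intercept)"]]
    }
    for (k in seq_along(free_j)) {
      A[i, free_j[k]] <- cf[[paste0("x", k)]]
      se_A[i, free_j[k]] <- cse[[paste0("x", k)]]
    }
    sigma[i] <- sm$sigma
  }
  if (sum(n_dropped) > 0)
    message(sum(n_dropped), " invalid/incomplete lagged record(s) excluded ",
            "from the regressions")

  # N0: earliest positive observation per species, for downstream starts
  N0 <- vapply(species, function(sp) {
    rows <- lagged[lagged$species == sp, , drop = FALSE]
    rows <- rows[order(rows$t1), , drop = FALSE]
    pos <- rows$N_t1[!is.na(rows$N_t1) & rows$N_t1 > 0]
    if (length(pos)) pos[1L] else NA_real_
  }, numeric(1))
  if (any(is.na(N0)))
    stop("no positive initial abundance found for species: ",
         paste(species[is.na(N0)], collapse = ", "))

  structure(list(params = lv_params(species, r, A, N0),
                 se = list(r = se_r, A = se_A),
                 sigma = sigma, n_used = n_used, n_dropped = n_dropped,
                 mask = mask),
            class = "lv_linfit")
}

#' @export
print.lv_linfit <- function(x, ...) {
  cat("Linearized Lotka-Volterra OLS fit\n")
  print(x$params)
  cat("records used:",
      paste(sprintf("%s=%d", names(x$n_used), x$n_used), collapse = ", "),
      "\n")
  invisible(x)
}

#' Determine parameter signs from a linearized fit
#'
#' The simulation-based optimizer works on log-transformed parameter
#' magnitudes, so each free parameter needs a sign fixed a priori. Signs
#' are taken from the OLS point estimates of the linearized regression.
#' An exactly zero estimate falls back to the conventional default:
#' negative for diagonal terms `a_ii` (self-limitation, which protects the
#' optimizer from runaway dynamics) and positive for growth rates and
#' off-diagonal interactions. User-supplied constraints (zero status or
#' explicit signs) override the data-driven choices.
#'
#' @param linfit an `lv_linfit` from [fit_linear()].
#' @param mask optional user [lv_mask] merged on top (user fixing wins).
#' @return An [lv_mask] with a sign for every free parameter.
#' @export
determine_signs <- function(linfit, mask = NULL) {
  stopifnot(inherits(linfit, "lv_linfit"))
  p <- linfit$params
  m <- lv_mask(p$species)
  m$r$status <- linfit$mask$r$status
  m$A$status <- linfit$mask$A$status
  sgn <- function(est, diag_term) {
    s <- sign(est)
    if (s == 0) s <- if (diag_term) -1 else 1
    s
  }
  for (i in seq_along(p$species)) {
    if (m$r$status[i] == "free") m$r$sign[i] <- sgn(p$r[i], FALSE)
    for (j in seq_along(p$species))
      if (m$A$status[i, j] == "free")
        m$A$sign[i, j] <- sgn(p$A[i, j], i == j)
  }
  merge_masks(m, mask)
}
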