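#' Lotka-Volterra parameter set
#'
#' Container for the parameters of the generalized Lotka-Volterra model
#' \deqn{dN_i/dt = N_i (r_i + \sum_j a_{ij} N_j)}
#' where `r` holds the intrinsic growth rates (per unit time), `A` the
#' interaction matrix (units 1/(abundance x time)) with `A[i, j]` the
#' per-capita effect of species `j` on the growth of species `i` (the
#' diagonal `A[i, i]` is self-limitation), and `N0` the initial abundances.
#'
#' @param species character vector of species identifiers (length n).
#' @param r numeric vector of n intrinsic growth rates.
#' @param A numeric n x n interaction matrix; `A[i, j]` is the effect of
#'   species `j` (column) on species `i` (row).
#' @param N0 numeric vector of n positive initial abundances.
#'
#' @return An object of class `lv_params`: a list with elements `species`,
#'   `r`, `A`, `N0`, all named/dimnamed by species.
#' @examples
#' lv_params("Pc", r = 0.96, A = matrix(-0.005), N0 = 0.22)
#' @export
lv_params <- function(species, r, A, N0) {
  species <- as.character(species)
  n <- length(species)
  if (n == 0L) stop("at least one species is required")
  if (anyDuplicated(species)) stop("duplicate species identifiers")
  r <- as.numeric(r)
  A <- matrix(as.numeric(A), n, n)
  N0 <- as.numeric(N0)
  if (length(r) != n) stop("length(r) must equal the number of species")
  if (!all(dim(A) == c(n, n))) stop("A must be an n x n matrix")
  if (length(N0) != n) stop("length(N0) must equal the number of species")
  if (!all(is.finite(r)) || !all(is.finite(A)) || !all(is.finite(N0)))
    stop("all parameter values must be finite")
  names(r) <- names(N0) <- species
  dimnames(A) <- list(species, species)
  structure(list(species = species, r = r, A = A, N0 = N0),
            class = "lv_params")
}

#' @export
print.lv_params <- function(x, ...) {
  cat("Lotka-Volterra parameters (", length(x$species), " species)\n", sep = "")
  cat("r  :", paste(sprintf("%s=%.4g", x$species, x$r), collapse = ", "), "\n")
  cat("N0 :", paste(sprintf("%s=%.4g", x$species, x$N0), collapse = ", "), "\n")
  cat("A  (column acts on row):\n")
  print(signif(x$A, 4))
  invisible(x)
}

#' Equilibrium abundances of a parameter set
#'
#' Solves `r + A N* = 0` for the interior equilibrium, if `A` is invertible.
#'
#' @param params an [lv_params] object.
#' @return Named numeric vector `N*` (possibly with non-positive entries if
#'   no feasible interior equilibrium exists).
#' @export
lv_equilibrium <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  nstar <- tryCatch(solve(params$A, -params$r),
                    error = function(e) stop("A is singular; no unique equilibrium"))
  stats::setNames(as.numeric(nstar), params$species)
}

#' Carrying capacity from growth rate and self-limitation
#'
#' For a single self-limited species the equilibrium abundance (carrying
#' capacity) is `K = -r / a_ii`.
#'
#' @param r intrinsic growth rate.
#' @param a_ii self-limitation coefficient (must be non-zero).
#' @return Numeric carrying capacity. Positive whenever `r > 0` and
#'   `a_ii < 0`.
#' @examples
#' carrying_capacity(1, -0.01) # 100
#' @export
carrying_capacity <- function(r, a_ii) {
  if (any(a_ii == 0))
    stop("a_ii = 0: no equilibrium arises from self-limitation")
  -r / a_ii
}

#' Write / read a parameter set as JSON
#'
#' The JSON object has fields `species`, `r`, `A` (row-major list of rows),
#' `N0` and optionally `se` (same shapes), plus `tool_version`.
#'
#' @param params an [lv_params] object.
#' @param path file path.
#' @param se optional list with elements `r`, `A`, `N0` of standard errors.
#' @return `write_params_json` returns `path` invisibly; `read_params_json`
#'   returns an [lv_params] object (with an `se` attribute when present).
#' @export
write_params_json <- function(params, path, se = NULL) {
  stopifnot(inherits(params, "lv_params"))
  obj <- list(species = params$species, r = unname(params$r),
              A = unname(params$A), N0 = unname(params$N0))
  if (!is.null(se)) obj$se <- list(r = unname(se$r), A = unname(se$A),
                                   N0 = unname(se$N0))
  obj$tool_version <- as.character(utils::packageVersion("lvfit"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- lv_params(obj$species, obj$r, obj$A, obj$N0)
  if (!is.null(obj$se)) attr(p, "se") <- obj$se
  p
}
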