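# shared fixtures and independent oracles, built in code

# brute-force OLS via the normal equations: the independent oracle for
# fit_linear
ols_oracle <- function(X, y, intercept = TRUE) {
  if (intercept) X <- cbind(1, X)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# long observation table from a wide matrix of abundances
obs_from_matrix <- function(times, ab, species = colnames(ab),
                            treatment = "") {
  do.call(rbind, lapply(seq_along(species), function(k)
    data.frame(time = times, species = species[k], abundance = ab[, k],
               treatment = treatment, stringsAsFactors = FALSE)))
}

# lagged table crafted directly from per-capita growth rates known to lie
# exactly on dNNdt = r + A %*% N (bypasses the log-ratio discretization)
lagged_from_design <- function(N, r, A, species = paste0("sp", seq_along(r))) {
  # N: matrix of abundance states (rows = records, cols = species)
  y <- t(r + A %*% t(N))
  out <- NULL
  for (i in seq_along(species)) {
    rec <- data.frame(species = species[i], treatment = "",
                      t1 = seq_len(nrow(N)) - 1, t2 = seq_len(nrow(N)),
                      N_t1 = N[, i], N_t2 = N[, i], dNNdt = y[, i],
                      valid = TRUE, stringsAsFactors = FALSE)
    for (j in seq_along(species)) rec[[paste0("N_", species[j])]] <- N[, j]
    out <- rbind(out, rec)
  }
  out
}

max_rel_err <- function(est, tru) {
  max(ifelse(tru == 0, abs(est), abs(est - tru) / abs(tru)))
}

rel_err_params <- function(fit_params, truth) {
  i <- match(truth$species, fit_params$species) # align species ordering
  max(max_rel_err(fit_params$r[i], truth$r),
      max_rel_err(fit_params$A[i, i], truth$A),
      max_rel_err(fit_params$N0[i], truth$N0))
}

# local maxima of a sampled series (interior strict peaks)
find_peaks <- function(x) {
  i <- which(diff(sign(diff(x))) == -2) + 1L
  x[i]
}

quiet_fit <- function(...) suppressMessages(suppressWarnings(fit_lv(...)))
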