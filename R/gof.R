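#' R-squared-like goodness-of-fit index
#'
#' Compares observed and predicted values by
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`. A value of 1 means
#' the predictions reproduce the observations exactly; 0 means the model
#' predicts no better than the observed mean; values below 0 indicate a
#' poor fit (the index is unbounded below). Missing pairs are dropped
#' pairwise.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2 after
#'   dropping missing pairs).
#' @return A single numeric index, always <= 1.
#' @examples
#' test_goodness_of_fit(c(1, 2, 3), c(3, 2, 1)) # -3
#' @export
test_goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]
  p <- predicted[ok]
  if (length(o) < 2L)
    stop("need at least 2 complete observation/prediction pairs")
  ss_tot <- sum((o - mean(o))^2)
  if (ss_tot == 0)
    stop("observed values have zero variance; the index is undefined")
  1 - sum((o - p)^2) / ss_tot
}

#' Per-species and total goodness of fit for a fitted trajectory
#'
#' Aligns predictions to observations by (species, time) and computes the
#' univariate index per species on raw abundances, plus a "total" index
#' across all observations simultaneously. For the total, abundances of
#' each species (observed and predicted alike) are first divided by the
#' species' mean observed abundance, so that the pooled comparison is not
#' dominated by the most abundant species — consistent with the
#' standardization used by the optimizer. Set `standardize_total = FALSE`
#' to pool raw values instead. The univariate and total views can disagree
#' substantially; both are reported.
#'
#' @param observed an observation table (one treatment).
#' @param trajectory a wide trajectory data.frame covering all observed
#'   times (column `time` + one column per species).
#' @param standardize_total divide by per-species observed means before
#'   pooling the total index (default TRUE).
#' @return An object of class `lv_gof`: list with `per_species` (named
#'   numeric), `total` (numeric), and `n_obs` (named integer counts).
#' @export
gof_report <- function(observed, trajectory, standardize_total = TRUE) {
  observed <- validate_observations(observed)
  if (length(unique(observed$treatment)) > 1L)
    stop("gof_report expects observations from a single treatment")
  species <- intersect(names(trajectory)[-1L], unique(observed$species))
  if (!setequal(species, unique(observed$species)))
    stop("trajectory lacks predictions for species: ",
         paste(setdiff(unique(observed$species), species), collapse = ", "))
  ti <- match(observed$time, trajectory$time)
  if (any(is.na(ti))) {
    bad <- unique(observed$time[is.na(ti)])
    stop("trajectory lacks predictions at observed time(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  pred <- vapply(seq_len(nrow(observed)),
                 function(k) trajectory[[observed$species[k]]][ti[k]],
                 numeric(1))
  keep <- !is.na(observed$abundance)
  per_species <- stats::setNames(rep(NA_real_, length(species)), species)
  n_obs <- stats::setNames(integer(length(species)), species)
  means <- stats::setNames(rep(NA_real_, length(species)), species)
  for (sp in species) {
    sel <- keep & observed$species == sp
    n_obs[sp] <- sum(sel)
    per_species[sp] <- test_goodness_of_fit(observed$abundance[sel],
                                            pred[sel])
    means[sp] <- mean(observed$abundance[sel])
  }
  scl <- if (standardize_total) means[observed$species] else
    rep(1, nrow(observed))
  total <- test_goodness_of_fit(observed$abundance[keep] / scl[keep],
                                pred[keep] / scl[keep])
  structure(list(per_species = per_species, total = total, n_obs = n_obs),
            class = "lv_gof")
}

#' @export
print.lv_gof <- function(x, ...) {
  cat("Goodness of fit (1 = perfect, <= 0 = poor):\n")
  for (sp in names(x$per_species))
    cat(sprintf("  %-12s %8.4f  (n = %d)\n", sp, x$per_species[sp],
                x$n_obs[sp]))
  cat(sprintf("  %-12s %8.4f\n", "total", x$total))
  invisible(x)
}
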