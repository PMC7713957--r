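#' Validate and normalize an observation table
#'
#' Observation tables are long-format data frames with columns `time`
#' (numeric), `species` (identifier), `abundance` (non-negative or NA) and
#' an optional `treatment` grouping column (replicate, monoculture vs.
#' mixture, ...). A missing treatment column means a single treatment,
#' encoded as the empty string.
#'
#' @param data a data.frame with at least columns `time`, `species`,
#'   `abundance`.
#' @return The normalized data.frame (character species/treatment, rows
#'   ordered by treatment, species, time).
#' @export
validate_observations <- function(data) {
  req <- c("time", "species", "abundance")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("observation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(time = as.numeric(data$time),
                    species = as.character(data$species),
                    abundance = as.numeric(data$abundance),
                    treatment = if ("treatment" %in% names(data))
                      as.character(data$treatment) else rep("", nrow(data)),
                    stringsAsFactors = FALSE)
  out$treatment[is.na(out$treatment)] <- ""
  if (any(!is.finite(out$time)))
    stop("all observation times must be finite")
  if (any(out$abundance < 0, na.rm = TRUE))
    stop("abundances must be non-negative (missing values allowed)")
  key <- paste(out$time, out$species, out$treatment, sep = "\r")
  if (anyDuplicated(key)) {
    d <- out[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate observation for species '%s' at time %g%s",
                 d$species, d$time,
                 if (nzchar(d$treatment))
                   sprintf(" in treatment '%s'", d$treatment) else ""))
  }
  out[order(out$treatment, out$species, out$time), , drop = FALSE]
}

#' Read / write long-format observation CSV
#'
#' The CSV has header `time,species,abundance` plus an optional `treatment`
#' column; decimal point, comma separator, UTF-8.
#'
#' @param path file path.
#' @return `read_observations` returns a validated observation data.frame.
#' @export
read_observations <- function(path) {
  validate_observations(utils::read.csv(path, stringsAsFactors = FALSE,
                                        fileEncoding = "UTF-8"))
}

#' @rdname read_observations
#' @param data an observation data.frame.
#' @export
write_observations <- function(data, path) {
  data <- validate_observations(data)
  utils::write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-capita growth rate from a pair of abundances
#'
#' Approximates the instantaneous per-capita growth rate dN/(N dt) over an
#' interval by the log ratio of abundances divided by the elapsed time:
#' `log(n_t2 / n_t1) / dt` (natural log). This is exact for exponential
#' growth and first-order accurate for other smooth dynamics.
#'
#' Non-positive or missing abundances give `NA` (such records are excluded
#' from regression rather than pseudo-counted).
#'
#' @param n_t1,n_t2 abundances at the start and end of the interval
#'   (vectorized).
#' @param dt elapsed time, strictly positive.
#' @return Numeric vector of per-capita growth rates (per unit time).
#' @examples
#' percap_growth(10, 20, 1) # log(2)
#' @export
percap_growth <- function(n_t1, n_t2, dt) {
  if (any(!is.finite(dt)) || any(dt <= 0))
    stop("dt must be strictly positive")
  n <- max(length(n_t1), length(n_t2), length(dt))
  n_t1 <- rep_len(as.numeric(n_t1), n)
  n_t2 <- rep_len(as.numeric(n_t2), n)
  dt <- rep_len(as.numeric(dt), n)
  out <- rep(NA_real_, n)
  ok <- !is.na(n_t1) & !is.na(n_t2) & n_t1 > 0 & n_t2 > 0
  out[ok] <- log(n_t2[ok] / n_t1[ok]) / dt[ok]
  out
}

#' Time-lagged observation pairs with per-capita growth rates
#'
#' For each (species, treatment) group, pairs each observation with the next
#' one in time (lag of one sampling step, whatever the actual interval) and
#' computes the per-capita growth rate over the interval via
#' [percap_growth()]. Pairs never span treatments. Each record also carries,
#' as covariates, the abundance of every species at the interval start `t1`
#' in the same treatment: these are the predictors of the linearized
#' Lotka-Volterra regression. A species observed in the treatment but not at
#' `t1` gives an NA covariate; a species entirely absent from the treatment
#' (e.g. the competitor in a monoculture) gives 0.
#'
#' @param data an observation table (see [validate_observations()]).
#' @return A data.frame with columns `species`, `treatment`, `t1`, `t2`,
#'   `N_t1`, `N_t2`, `dNNdt`, `valid`, plus one covariate column `N_<sp>`
#'   per species. `valid` is TRUE when both abundances are positive so the
#'   growth rate is finite.
#' @examples
#' obs <- data.frame(time = 0:2, species = "x", abundance = c(10, 20, 40))
#' get_lag(obs)
#' @export
get_lag <- function(data) {
  data <- validate_observations(data)
  all_species <- sort(unique(data$species))
  cov_names <- paste0("N_", all_species)
  empty <- data.frame(species = character(), treatment = character(),
                      t1 = numeric(), t2 = numeric(),
                      N_t1 = numeric(), N_t2 = numeric(),
                      dNNdt = numeric(), valid = logical())
  for (cn in cov_names) empty[[cn]] <- numeric()
  if (nrow(data) == 0L) return(empty)

  pieces <- list()
  for (tr in unique(data$treatment)) {
    sub <- data[data$treatment == tr, , drop = FALSE]
    present <- unique(sub$species)
    # abundance lookup at (time, species) within this treatment
    lookup <- function(sp, times) {
      if (!sp %in% present) return(rep(0, length(times)))
      idx <- match(times, sub$time[sub$species == sp])
      sub$abundance[sub$species == sp][idx]
    }
    for (sp in present) {
      g <- sub[sub$species == sp, , drop = FALSE]
      g <- g[order(g$time), , drop = FALSE]
      if (nrow(g) < 2L) next
      i1 <- seq_len(nrow(g) - 1L)
      rec <- data.frame(species = sp, treatment = tr,
                        t1 = g$time[i1], t2 = g$time[i1 + 1L],
                        N_t1 = g$abundance[i1], N_t2 = g$abundance[i1 + 1L],
                        stringsAsFactors = FALSE)
      rec$dNNdt <- percap_growth(rec$N_t1, rec$N_t2, rec$t2 - rec$t1)
      rec$valid <- !is.na(rec$N_t1) & !is.na(rec$N_t2) &
        rec$N_t1 > 0 & rec$N_t2 > 0
      for (k in seq_along(all_species))
        rec[[cov_names[k]]] <- lookup(all_species[k], rec$t1)
      pieces[[length(pieces) + 1L]] <- rec
    }
  }
  if (!length(pieces)) return(empty)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  n_invalid <- sum(!out$valid)
  if (n_invalid > 0)
    message(n_invalid, " lagged record(s) flagged invalid ",
            "(zero or missing abundance)")
  out
}

#' @rdname get_lag
#' @param lagged a lagged-growth data.frame from `get_lag`.
#' @param path file path for the CSV output.
#' @export
write_lagged <- function(lagged, path) {
  utils::write.csv(lagged, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
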