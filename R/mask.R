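#' Constraint mask for Lotka-Volterra parameters
#'
#' A mask records, for every parameter of an [lv_params] set, whether it is
#' `free` (optimized) or `zero` (pinned at exactly 0 and excluded from the
#' optimization vector), and — for free parameters — the sign enforced
#' during optimization. Signs are needed because the optimizer works on
#' log-transformed parameter magnitudes, with each parameter's sign fixed
#' a priori (normally from the linearized regression estimates, see
#' [determine_signs()]). Initial abundances `N0` are always free with
#' positive sign.
#'
#' @param species character vector of species identifiers.
#' @param r_status,r_sign per-species status (`"free"`/`"zero"`) and sign
#'   (+1/-1) for the growth rates; recycled.
#' @param A_status,A_sign n x n status and sign for the interaction matrix
#'   (scalars are recycled).
#' @return An object of class `lv_mask`.
#' @examples
#' m <- lv_mask(c("prey", "pred"))
#' m <- mask_fix_zero(m, "a", "prey", "prey") # no prey self-limitation
#' @export
lv_mask <- function(species, r_status = "free", r_sign = NA_real_,
                    A_status = "free", A_sign = NA_real_) {
  species <- as.character(species)
  n <- length(species)
  m <- structure(list(
    species = species,
    r = list(status = stats::setNames(rep_len(r_status, n), species),
             sign = stats::setNames(rep_len(as.numeric(r_sign), n), species)),
    A = list(status = matrix(rep_len(A_status, n * n), n,
                             dimnames = list(species, species)),
             sign = matrix(rep_len(as.numeric(A_sign), n * n), n,
                           dimnames = list(species, species))),
    N0 = list(status = stats::setNames(rep("free", n), species),
              sign = stats::setNames(rep(1, n), species))
  ), class = "lv_mask")
  validate_mask(m)
}

validate_mask <- function(m) {
  ok_status <- function(s) all(s %in% c("free", "zero"))
  if (!ok_status(m$r$status) || !ok_status(m$A$status))
    stop("mask status values must be 'free' or 'zero'")
  if (any(m$N0$status != "free"))
    stop("N0 may not have zero status: initial abundances are always fitted")
  bad_sign <- function(st, sg) any(st == "free" & !is.na(sg) & !(sg %in% c(-1, 1)))
  if (bad_sign(m$r$status, m$r$sign) || bad_sign(m$A$status, m$A$sign))
    stop("signs must be +1 or -1 (or NA before sign determination)")
  m
}

#' @rdname lv_mask
#' @param mask an `lv_mask`.
#' @param block one of `"r"`, `"a"`.
#' @param i,j species identifiers (row/column for `"a"`; `j` ignored for
#'   `"r"`).
#' @export
mask_fix_zero <- function(mask, block, i, j = NULL) {
  stopifnot(inherits(mask, "lv_mask"))
  block <- match.arg(block, c("r", "a"))
  if (block == "r") {
    mask$r$status[i] <- "zero"
  } else {
    mask$A$status[i, j] <- "zero"
  }
  validate_mask(mask)
}

#' @rdname lv_mask
#' @param sign +1 or -1, the sign to force for a free parameter.
#' @export
mask_set_sign <- function(mask, block, i, j = NULL, sign) {
  stopifnot(inherits(mask, "lv_mask"), sign %in% c(-1, 1))
  block <- match.arg(block, c("r", "a"))
  if (block == "r") mask$r$sign[i] <- sign else mask$A$sign[i, j] <- sign
  validate_mask(mask)
}

#' @export
print.lv_mask <- function(x, ...) {
  lab <- function(st, sg) ifelse(st == "zero", "0",
                                 ifelse(is.na(sg), "free",
                                        ifelse(sg > 0, "+", "-")))
  cat("Constraint mask (", length(x$species), " species)\n", sep = "")
  cat("r :", paste(x$species, lab(x$r$status, x$r$sign), sep = "=",
                   collapse = ", "), "\n")
  cat("A :\n")
  print(matrix(lab(x$A$status, x$A$sign), length(x$species),
               dimnames = dimnames(x$A$status)), quote = FALSE)
  invisible(x)
}

# user-supplied constraints win over data-driven ones: zero status always,
# and any explicit sign, carry through from `user` into `base`.
merge_masks <- function(base, user) {
  if (is.null(user)) return(base)
  stopifnot(inherits(base, "lv_mask"), inherits(user, "lv_mask"))
  if (!identical(base$species, user$species))
    stop("masks refer to different species sets")
  base$r$status[user$r$status == "zero"] <- "zero"
  base$A$status[user$A$status == "zero"] <- "zero"
  keep <- !is.na(user$r$sign)
  base$r$sign[keep] <- user$r$sign[keep]
  keep <- !is.na(user$A$sign)
  base$A$sign[keep] <- user$A$sign[keep]
  base$r$sign[base$r$status == "zero"] <- NA_real_
  base$A$sign[base$A$status == "zero"] <- NA_real_
  validate_mask(base)
}

#' Read a constraint configuration file
#'
#' The configuration is a JSON or YAML map from parameter names to
#' constraints. Keys are `r:<species>`, `a:<species_i>:<species_j>` or
#' `n0:<species>`; values are `"free"`, `"zero"`, or a map `{sign: 1}` /
#' `{sign: -1}`. Unlisted parameters stay free with data-driven sign.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @param species character vector of species the mask applies to.
#' @return An [lv_mask].
#' @export
read_mask <- function(path, species) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  mask_from_config(cfg, species)
}

#' @rdname read_mask
#' @param cfg a named list as described above.
#' @export
mask_from_config <- function(cfg, species) {
  m <- lv_mask(species)
  for (key in names(cfg)) {
    val <- cfg[[key]]
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    block <- tolower(parts[1])
    if (!block %in% c("r", "a", "n0"))
      stop("unknown parameter key: ", key)
    if (block == "a" && length(parts) != 3L)
      stop("interaction keys must look like a:<sp_i>:<sp_j>: ", key)
    if (block != "a" && length(parts) != 2L)
      stop("keys must look like ", block, ":<species>: ", key)
    sp <- parts[-1]
    if (!all(sp %in% species))
      stop("unknown species in constraint key: ", key)
    if (identical(val, "free")) next
    if (identical(val, "zero")) {
      if (block == "n0") stop("N0 may not be fixed to zero: ", key)
      m <- mask_fix_zero(m, block, sp[1], if (block == "a") sp[2])
    } else if (is.list(val) && !is.null(val$sign)) {
      if (block == "n0" && val$sign != 1)
        stop("N0 must have positive sign: ", key)
      if (block != "n0")
        m <- mask_set_sign(m, block, sp[1], if (block == "a") sp[2],
                           sign = as.numeric(val$sign))
    } else {
      stop("constraint for ", key,
           " must be 'free', 'zero', or a map with a 'sign' entry")
    }
  }
  m
}

# mask built from a true parameter set: exact zeros get zero status, other
# entries get their true sign. Used by the synthetic-data generator so the
# fitting pipeline can be told the true zero structure.
mask_from_params <- function(params) {
  stopifnot(inherits(params, "lv_params"))
  m <- lv_mask(params$species)
  m$r$status[params$r == 0] <- "zero"
  m$r$sign[params$r != 0] <- sign(params$r[params$r != 0])
  m$A$status[params$A == 0] <- "zero"
  m$A$sign[params$A != 0] <- sign(params$A[params$A != 0])
  validate_mask(m)
}
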