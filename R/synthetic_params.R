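#' @title Synthetic parameter cohorts
#' @description The survey data behind the original calibration (interviews
#'   and documents from 16 inpatient pharmacies) are not published. This
#'   module stands in for them: per-pharmacy parameter sets are drawn with
#'   seeded randomness from documented plausible ranges around the reference
#'   calibration, so every downstream stage (simulation, validation,
#'   scenarios) is testable without any external data. Ranges are entirely
#'   synthetic and labelled as such; fields are sampled independently (no
#'   correlation structure is claimed).
#' @name synthetic_params
NULL

#' Default sampling ranges for the parameter fields
#'
#' Reads the versioned ranges file
#' (`inst/extdata/parameter_ranges_synthetic.json`): per field a distribution
#' family (`"uniform"` for fractions, indices and counts; `"loguniform"` for
#' strictly positive scale parameters such as prices, costs and rates) and
#' `low < high` bounds inside the field's valid range, spanning roughly
#' +/- 25% around the reference calibration.
#'
#' @return named list: field -> list(dist, low, high).
#' @export
default_parameter_ranges <- function() {
  path <- system.file("extdata", "parameter_ranges_synthetic.json",
                      package = "pharmsd")
  ranges <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_parameter_ranges(ranges)
}

validate_parameter_ranges <- function(ranges) {
  ranges <- lapply(ranges, as.list)
  missing <- setdiff(parameter_names(), names(ranges))
  if (length(missing))
    stop("ranges missing field(s): ", paste(missing, collapse = ", "))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!r$dist %in% c("uniform", "loguniform"))
      stop(nm, ": dist must be 'uniform' or 'loguniform'")
    if (!is.numeric(r$low) || !is.numeric(r$high) || r$low >= r$high)
      stop(nm, ": need numeric low < high")
    if (r$dist == "loguniform" && r$low <= 0)
      stop(nm, ": loguniform requires low > 0")
  }
  ranges
}

# 32-bit multiply mod 2^32 kept exact in doubles by 16-bit splitting.
mulmod32 <- function(a, b) {
  a <- a %% 4294967296; b <- b %% 4294967296
  hi <- floor(a / 65536); lo <- a %% 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

#' Derive a reproducible sub-seed
#'
#' Splitmix-style 32-bit hash of `(master seed, index)`: the index is folded
#' in with the golden-ratio increment and the result is finalized with two
#' xor-shift multiplications. Stable across platforms and versions; the
#' returned value is a valid R seed (below 2^31).
#'
#' @param seed master seed (non-negative integer).
#' @param index stream index (non-negative integer).
#' @return integer sub-seed in `[0, 2^31)`.
#' @export
derive_subseed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index), seed >= 0, index >= 0)
  x <- (seed + mulmod32(index, 2654435769)) %% 4294967296
  x <- bitwXor32(x, floor(x / 65536))
  x <- mulmod32(x, 2246822519)
  x <- bitwXor32(x, floor(x / 8192))
  x <- mulmod32(x, 3266489917)
  x <- bitwXor32(x, floor(x / 65536))
  as.integer(x %% 2147483648)
}

bitwXor32 <- function(a, b) {
  # xor on doubles representing 32-bit unsigned ints
  r <- 0; bit <- 1
  a <- a %% 4294967296; b <- b %% 4294967296
  for (i in 1:32) {
    ab <- a %% 2; bb <- b %% 2
    if (ab != bb) r <- r + bit
    a <- (a - ab) / 2; b <- (b - bb) / 2
    bit <- bit * 2
    if (a == 0 && b == 0) break
  }
  r
}

#' Draw one synthetic parameter set
#'
#' Deterministic given the seed: fields are drawn in the canonical field order
#' from their declared distributions. The result always passes
#' [validate_parameter_set()].
#'
#' @param seed integer seed.
#' @param ranges sampling ranges, see [default_parameter_ranges()].
#' @return named list of parameters.
#' @export
sample_parameter_set <- function(seed, ranges = default_parameter_ranges()) {
  ranges <- validate_parameter_ranges(ranges)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% 2147483648))
  params <- stats::setNames(vector("list", length(parameter_names())),
                            parameter_names())
  for (nm in parameter_names()) {
    r <- ranges[[nm]]
    params[[nm]] <- if (r$dist == "uniform") {
      stats::runif(1, r$low, r$high)
    } else {
      exp(stats::runif(1, log(r$low), log(r$high)))
    }
  }
  assert_valid_parameters(params)
}

#' Draw a cohort of synthetic pharmacies
#'
#' Each member is drawn from its own sub-seed
#' (`derive_subseed(seed, index)`), so cohorts regenerate exactly from the
#' master seed and member `i` is independent of cohort size.
#'
#' @param n cohort size (default 16, the surveyed number of inpatient
#'   pharmacies).
#' @param seed master seed.
#' @param ranges sampling ranges.
#' @return list of `n` parameter sets.
#' @export
sample_cohort <- function(n = 16, seed = 1, ranges = default_parameter_ranges()) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i)
    sample_parameter_set(derive_subseed(seed, i), ranges))
}

#' Cohort as a data frame
#'
#' @param cohort list of parameter sets.
#' @return data.frame, one row per set, one column per field.
#' @export
cohort_data_frame <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p)
    as.data.frame(p[parameter_names()])))
}

#' Pattern prevalence over a cohort
#'
#' Runs every parameter set through the pharmacy model and the pattern
#' classifier and reports, per reported pattern, the fraction of successful
#' runs exhibiting it. Runs that fail to integrate are recorded and excluded
#' from the denominators.
#'
#' @param cohort non-empty list of parameter sets.
#' @param config a [sim_config()].
#' @return list of class `pattern_prevalence`: `fractions` (named numeric),
#'   `n_samples`, `n_failed`, `failures` (character messages).
#' @export
ensemble_patterns <- function(cohort, config = sim_config()) {
  if (!is.list(cohort) || length(cohort) == 0L)
    stop("cohort must be a non-empty list of parameter sets")
  results <- list()
  failures <- character()
  for (i in seq_along(cohort)) {
    res <- tryCatch({
      p <- assert_valid_parameters(cohort[[i]])
      traj <- simulate(build_pharmacy_model(p), p, config)
      pattern_checks(traj, p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("set %d: %s", i, conditionMessage(res)))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  fractions <- if (length(results)) colMeans(do.call(rbind, results))
               else stats::setNames(numeric(), character())
  structure(list(fractions = fractions,
                 n_samples = length(cohort),
                 n_failed = length(failures),
                 failures = failures),
            class = "pattern_prevalence")
}

#' @export
print.pattern_prevalence <- function(x, ...) {
  cat("<pattern_prevalence> ", x$n_samples, " sets (", x$n_failed, " failed)\n",
      sep = "")
  for (nm in names(x$fractions))
    cat(sprintf("  %-42s %.2f\n", nm, x$fractions[[nm]]))
  invisible(x)
}
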