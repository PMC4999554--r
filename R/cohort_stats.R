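#' Percent phage-resistant isolates in a cohort
#'
#' The percent resistance at a time point is 100 times the number of
#' resistant isolates divided by the total isolates screened.  An exact
#' (Clopper-Pearson) binomial 95% confidence interval is reported
#' alongside, since cohorts are small (typically n = 20 per time point).
#'
#' @param resistant resistant isolate count
#' @param total total isolates screened (> 0)
#' @param conf_level confidence level for the interval
#' @return data.frame with columns `resistant`, `total`, `percent`,
#'   `lower`, `upper` (interval bounds, percent scale)
#' @export
#' @examples
#' percent_resistant(20, 20)  # 100 percent
percent_resistant <- function(resistant, total, conf_level = 0.95) {
  stopifnot(length(resistant) == length(total))
  if (any(total <= 0)) stop("total must be > 0", call. = FALSE)
  if (any(resistant < 0 | resistant > total))
    stop("resistant count must lie in [0, total]", call. = FALSE)
  ci <- t(mapply(function(k, n)
    binom.test(k, n, conf.level = conf_level)$conf.int, resistant, total))
  data.frame(resistant = resistant, total = total,
             percent = 100 * resistant / total,
             lower = 100 * ci[, 1], upper = 100 * ci[, 2])
}

#' Spontaneous phage-resistance frequency
#'
#' Resistant colonies per cell challenged.  Observed frequencies for the
#' PIP clade representatives fall around 1e-5 to 1e-6.  When no colony is
#' observed the point estimate is 0 and the rule-of-three upper 95% bound
#' (3 / CFU) is reported.
#'
#' @param colonies resistant colony count (>= 0)
#' @param cfu cells challenged (> 0)
#' @return data.frame with columns `colonies`, `cfu`, `frequency`,
#'   `upper95`
#' @export
#' @examples
#' resistance_frequency(10, 1e7)  # 1e-6
resistance_frequency <- function(colonies, cfu) {
  stopifnot(length(colonies) == length(cfu))
  if (any(cfu <= 0)) stop("cfu must be > 0", call. = FALSE)
  if (any(colonies < 0)) stop("colony count must be >= 0", call. = FALSE)
  upper <- ifelse(colonies == 0, 3 / cfu, NA_real_)
  data.frame(colonies = colonies, cfu = cfu,
             frequency = colonies / cfu, upper95 = upper)
}

#' Fold reduction of bacterial load under treatment
#'
#' @param control_load load (e.g. CFU per gram) without treatment
#' @param treated_load load under treatment
#' @return numeric fold change `control_load / treated_load`; a zero
#'   treated load yields `Inf` with a warning
#' @export
#' @examples
#' fold_reduction(3e8, 1e8)  # 3
fold_reduction <- function(control_load, treated_load) {
  stopifnot(length(control_load) == length(treated_load))
  if (any(control_load < 0 | treated_load < 0))
    stop("loads must be >= 0", call. = FALSE)
  if (any(treated_load == 0))
    warning("treated load of zero: fold reduction is infinite",
            call. = FALSE)
  control_load / treated_load
}
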