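#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per group: `S(0) = 1`, right-continuous
#' non-increasing steps at event times; a censored subject leaves the risk
#' set without a step. At tied times events are processed before censorings
#' (the standard convention).
#'
#' @param data Tibble with columns `time` (nonnegative), `event` (1 = event,
#'   0 = censored) and optionally `group`.
#' @param group Optional single group label to restrict to (requires a
#'   `group` column).
#' @return A tibble with columns `group` (if present), `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(data, group = NULL) {
  data <- validate_survival(data)
  if (!is.null(group)) {
    if (!"group" %in% names(data)) stop("`data` has no `group` column")
    data <- data[data$group == group, ]
    if (nrow(data) == 0L) stop("no subjects in group '", group, "'")
  }
  grouped <- "group" %in% names(data) && is.null(group) &&
    length(unique(data$group)) > 1L
  fit <- if (grouped) {
    survival::survfit(survival::Surv(time, event) ~ group, data = data)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  }
  s <- summary(fit, censored = TRUE)
  out <- tibble::tibble(
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    n_censor = s$n.censor,
    surv = s$surv
  )
  if (grouped) {
    out <- dplyr::bind_cols(
      tibble::tibble(group = sub("^group=", "", as.character(s$strata))),
      out
    )
  } else if (!is.null(group)) {
    out <- dplyr::bind_cols(tibble::tibble(group = group), out)
  }
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom (hypergeometric
#' observed-minus-expected increments at each event time), two-sided p-value.
#'
#' @param data Tibble with columns `time`, `event`, `group` (exactly two
#'   levels; at least one event overall).
#' @return A one-row tibble with `chisq`, `df`, `p`.
#' @export
logrank <- function(data) {
  data <- validate_survival(data)
  if (!"group" %in% names(data)) stop("`data` needs a `group` column")
  if (length(unique(data$group)) != 2L) {
    stop("log-rank comparison needs exactly 2 groups")
  }
  if (sum(data$event) == 0L) stop("no events in either group")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = data)
  chisq <- unname(fit$chisq)
  tibble::tibble(chisq = chisq, df = 1L,
                 p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Stratify subjects into high/low score groups at the step threshold
#'
#' Fits a one-step function to the sorted composite scores ([fit_step()]) and
#' splits at its threshold: `score > sthr` is `"high"`, otherwise `"low"`
#' (ties at the threshold go low, the same rule as [binarize()]).
#'
#' @param scores Tibble with columns `sample_id`, `score` (e.g. from
#'   [composite_score()]).
#' @param data Survival tibble with columns `sample_id`, `time`, `event`.
#' @return The survival tibble with `score` and `group` columns added; the
#'   threshold is attached as attribute `sthr`.
#' @export
stratify_by_score <- function(scores, data) {
  stopifnot(all(c("sample_id", "score") %in% names(scores)))
  data <- validate_survival(data)
  if (!"sample_id" %in% names(data)) {
    stop("`data` needs a `sample_id` column")
  }
  merged <- dplyr::inner_join(
    data, scores[, c("sample_id", "score")], by = "sample_id"
  )
  if (nrow(merged) == 0L) stop("no shared sample ids")
  if (all(merged$score == merged$score[1L])) {
    stop("no threshold: all scores identical")
  }
  sthr <- fit_step(sort(merged$score))$sthr
  merged$group <- ifelse(merged$score > sthr, "high", "low")
  attr(merged, "sthr") <- sthr
  merged
}

validate_survival <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("time", "event") %in% names(data))) {
    stop("survival data needs `time` and `event` columns")
  }
  if (any(data$time < 0, na.rm = TRUE)) stop("negative survival time")
  if (!all(data$event %in% c(0, 1))) {
    stop("`event` must be 0 (censored) or 1 (event)")
  }
  data
}
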