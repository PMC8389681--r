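# Prognostic screening: median split, product-limit survival curves,
# two-group log-rank test, binary-covariate Cox proportional hazards with
# Breslow/Efron tie handling, signature scores and the strict prognostic
# filter (p < 0.001, HR <= 0.5 or >= 2, n >= 200).

#' Median split of a score vector
#'
#' High group = score strictly above the median; ties go to the low group,
#' so the split is deterministic.
#'
#' @param scores Numeric vector, length >= 4.
#' @return Character vector of `"high"`/`"low"` labels, names preserved.
#' @export
median_split <- function(scores) {
  if (length(scores) < 4L) stop("need >= 4 samples to split", call. = FALSE)
  if (length(unique(scores)) == 1L)
    stop("degenerate split: all scores identical", call. = FALSE)
  m <- stats::median(scores)
  out <- ifelse(scores > m, "high", "low")
  names(out) <- names(scores)
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' Standard product-limit curve: `S(0) = 1`, multiplied by
#' `(1 - d_i / n_i)` at each distinct event time; censored observations
#' leave the risk set without a step.
#'
#' @param time Positive event/censoring times (months).
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Data frame `time`, `n_risk`, `n_event`, `survival` — one row per
#'   distinct event time; class `km_curve`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0))
  o <- order(time)
  time <- time[o]; event <- event[o]
  etimes <- sort(unique(time[event == 1]))
  if (!length(etimes))
    return(structure(data.frame(time = numeric(), n_risk = integer(),
                                n_event = integer(), survival = numeric()),
                     class = c("km_curve", "data.frame")))
  s <- 1
  rows <- lapply(etimes, function(t) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <<- s * (1 - d / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = d, survival = s)
  })
  structure(do.call(rbind, rows), class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed events in group 1 are compared
#' with the hypergeometric expectation given the risk sets; the summed
#' (O - E) over the summed hypergeometric variance is referred to a
#' chi-square with 1 degree of freedom.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level grouping vector (e.g. `"high"`/`"low"`).
#' @return List `statistic` (chi-square), `p_value`, `observed`,
#'   `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("log-rank needs exactly two groups", call. = FALSE)
  if (sum(event) == 0) stop("no events in either group", call. = FALSE)
  etimes <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  g1 <- g == levels(g)[1L]
  for (t in etimes) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p,
       observed = c(O1, sum(event) - O1),
       expected = c(E1, sum(event) - E1))
}

#' Binary-covariate Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood for a single binary covariate
#' (`group == "high"`) by Newton iteration, with Breslow (default) or Efron
#' handling of tied event times. Convergence when the absolute score drops
#' below `1e-8` or after 50 iterations. Complete separation of event times
#' (monotone likelihood) is returned as a flagged infinite-HR result, not
#' an error.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level vector; the hazard ratio is high vs low.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List `hr`, `log_hr`, `se`, `ci_low`, `ci_high` (95% Wald),
#'   `wald_p`, `n`, `n_events`, `degenerate` flag.
#' @export
cox_hr_binary <- function(time, event, group, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  x <- as.numeric(group == "high")
  if (length(unique(x)) != 2L) stop("covariate is constant", call. = FALSE)
  if (sum(event[x == 1]) == 0 || sum(event[x == 0]) == 0 || sum(event) < 2)
    return(list(hr = NA_real_, log_hr = NA_real_, se = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, wald_p = NA_real_,
                n = length(time), n_events = sum(event), degenerate = TRUE))
  etimes <- sort(unique(time[event == 1]))
  beta <- 0
  for (iter in 1:50) {
    U <- 0; I <- 0
    eb <- exp(beta * x)
    for (t in etimes) {
      risk <- time >= t
      dead <- time == t & event == 1
      d <- sum(dead); s1d <- sum(x[dead])
      S0 <- sum(eb[risk]); S1 <- sum((x * eb)[risk])
      if (ties == "breslow") {
        U <- U + s1d - d * S1 / S0
        I <- I + d * (S1 / S0) * (1 - S1 / S0)   # x binary: S2 == S1
      } else {
        S0d <- sum(eb[dead]); S1d <- sum((x * eb)[dead])
        for (l in seq_len(d) - 1) {
          S0l <- S0 - (l / d) * S0d; S1l <- S1 - (l / d) * S1d
          U <- U + s1d / d - S1l / S0l
          I <- I + (S1l / S0l) * (1 - S1l / S0l)
        }
      }
    }
    if (I <= 0) break
    step <- U / I
    if (abs(step) > 5) step <- sign(step) * 5   # guard monotone likelihood
    beta <- beta + step
    if (abs(U) < 1e-8) break
  }
  if (abs(beta) > 20 || I <= 0)
    return(list(hr = if (beta > 0) Inf else 0, log_hr = beta, se = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, wald_p = NA_real_,
                n = length(time), n_events = sum(event), degenerate = TRUE))
  se <- 1 / sqrt(I)
  z <- beta / se
  list(hr = exp(beta), log_hr = beta, se = se,
       ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
       wald_p = 2 * stats::pnorm(-abs(z)),
       n = length(time), n_events = sum(event), degenerate = FALSE)
}

#' Multi-gene signature score
#'
#' Per-sample mean of the log2(TPM+1)-scale values over the signature genes
#' present in the matrix. Missing genes are reported via the
#' `"missing_genes"` attribute.
#'
#' @param cohort An [expression_cohort()] (or any genes x samples matrix).
#' @param gene_set Character vector of signature genes.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(cohort, gene_set) {
  mat <- if (inherits(cohort, "expression_cohort")) cohort$mat else cohort
  present <- intersect(gene_set, rownames(mat))
  if (!length(present)) stop("no signature gene present in matrix", call. = FALSE)
  out <- colMeans(mat[present, , drop = FALSE])
  attr(out, "missing_genes") <- setdiff(gene_set, present)
  out
}

#' Screening criteria
#'
#' Default map threshold is BH-FDR q <= 0.05; the strict filter demands raw
#' log-rank p < 0.001, HR <= `hr_low` or >= `hr_high`, and at least
#' `min_cases` samples.
#'
#' @param alpha_default FDR threshold for the default screen (0.05).
#' @param strict_p Raw p threshold of the strict filter (0.001).
#' @param hr_low,hr_high Hazard-ratio gates (0.5 and 2).
#' @param min_cases Minimum cohort size for the strict filter (200).
#' @return List of class `screen_criteria`.
#' @export
screen_criteria <- function(alpha_default = 0.05, strict_p = 0.001,
                            hr_low = 0.5, hr_high = 2.0, min_cases = 200) {
  stopifnot(strict_p > 0, strict_p < alpha_default, hr_low < 1, hr_high > 1)
  structure(list(alpha_default = alpha_default, strict_p = strict_p,
                 hr_low = hr_low, hr_high = hr_high, min_cases = min_cases),
            class = "screen_criteria")
}

#' Prognostic screen of genes or signatures across cohorts
#'
#' Each unit (gene or signature) is median-split in each cohort; the
#' log-rank p and binary Cox HR are computed; q-values are BH-adjusted over
#' units within a cohort. `passes_default` uses q <= `alpha_default`;
#' `passes_strict` uses the raw p, the HR gates and the case-count gate.
#'
#' @param units Named list: each element is a data frame with columns
#'   `cohort_id`, `time`, `event`, `score` (one row per sample). Build with
#'   [survival_unit_table()].
#' @param criteria A [screen_criteria()].
#' @param ties Passed to [cox_hr_binary()].
#' @return Data frame `unit`, `cohort_id`, `n_cases`, `hr`, `ci_low`,
#'   `ci_high`, `logrank_p`, `q_value`, `passes_default`, `passes_strict`.
#' @export
screen_prognostic <- function(units, criteria = screen_criteria(),
                              ties = "breslow") {
  rows <- list()
  for (u in names(units)) {
    d <- units[[u]]
    for (cid in unique(d$cohort_id)) {
      dc <- d[d$cohort_id == cid, , drop = FALSE]
      grp <- median_split(dc$score)
      lr <- logrank_test(dc$time, dc$event, grp)
      cx <- cox_hr_binary(dc$time, dc$event, grp, ties = ties)
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, cohort_id = cid, n_cases = nrow(dc),
        hr = cx$hr, ci_low = cx$ci_low, ci_high = cx$ci_high,
        logrank_p = lr$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  for (cid in unique(out$cohort_id)) {
    i <- out$cohort_id == cid
    out$q_value[i] <- bh_adjust(out$logrank_p[i])
  }
  out$passes_default <- out$q_value <= criteria$alpha_default
  out$passes_strict <- !is.na(out$hr) &
    out$logrank_p < criteria$strict_p &
    (out$hr <= criteria$hr_low | out$hr >= criteria$hr_high) &
    out$n_cases >= criteria$min_cases
  rownames(out) <- NULL
  out
}

#' Assemble a per-unit survival table from expression and follow-up data
#'
#' Joins a survival table (`sample`, `time_months`, `event`) with per-sample
#' scores for one unit (a gene's expression or a signature score).
#'
#' @param surv Data frame `sample`, `time_months`, `event`.
#' @param scores Named numeric vector of per-sample scores.
#' @param cohort_id Cohort label.
#' @return Data frame `cohort_id`, `time`, `event`, `score`.
#' @export
survival_unit_table <- function(surv, scores, cohort_id) {
  common <- intersect(surv$sample, names(scores))
  s <- surv[match(common, surv$sample), , drop = FALSE]
  data.frame(cohort_id = cohort_id, time = s$time_months, event = s$event,
             score = unname(scores[common]), stringsAsFactors = FALSE)
}
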