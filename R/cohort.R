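#' Kaplan-Meier (product-limit) survival estimate
#'
#' At each distinct event time t with d events among n animals at risk the
#' survival estimate multiplies by (1 - d/n); animals censored at t leave
#' the risk set after the events at t (the usual convention for ties
#' between deaths and censoring).
#'
#' @param cohort Cohort data.frame (columns `time_weeks`, `event`; see
#'   [read_cohort()]). Typically pre-filtered to one genotype.
#' @return A data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (estimated survival just after
#'   `time`). Survival starts at 1 and is non-increasing.
#' @examples
#' km <- km_estimate(data.frame(time_weeks = c(6, 12, 12, 20, 35),
#'                              event = c(TRUE, TRUE, TRUE, TRUE, FALSE)))
#' km_median(km)
#' @export
km_estimate <- function(cohort) {
  assert_columns(cohort, c("time_weeks", "event"), "cohort")
  if (nrow(cohort) == 0) stopf("cohort is empty")
  time <- cohort$time_weeks
  event <- as.logical(cohort$event)
  if (anyNA(time) || any(time <= 0)) stopf("times must be positive")
  if (anyNA(event)) stopf("`event` must not contain missing values")

  times <- sort(unique(time))
  n_event <- vapply(times, function(t) sum(time == t & event), integer(1))
  n_censor <- vapply(times, function(t) sum(time == t & !event), integer(1))
  n_risk <- vapply(times, function(t) sum(time >= t), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = times, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

#' @rdname km_estimate
#' @param km A curve returned by `km_estimate()`.
#' @return `km_median()`: the smallest observed time at which estimated
#'   survival drops to 0.5 or below, or `NA` if it never does within the
#'   observation window.
#' @export
km_median <- function(km) {
  assert_columns(km, c("time", "surv"), "km")
  hit <- which(km$surv <= 0.5 + 1e-12)
  if (length(hit) == 0) return(NA_real_)
  km$time[hit[1]]
}

#' Log-rank (Mantel-Cox) two-group survival comparison
#'
#' Accumulates observed minus expected event counts over the distinct event
#' times of the pooled sample, with the hypergeometric variance for tied
#' events, and refers (O - E)^2 / V to a chi-square distribution with one
#' degree of freedom. Identical groups give statistic 0 and p = 1.
#'
#' @param group_a,group_b Cohort data.frames (columns `time_weeks`,
#'   `event`), both non-empty.
#' @return A list of class `logrank_result`: `chisq`, `df`, `p_value`,
#'   `observed` and `expected` (length-2 vectors, groups a and b).
#' @export
logrank_test <- function(group_a, group_b) {
  assert_columns(group_a, c("time_weeks", "event"), "group_a")
  assert_columns(group_b, c("time_weeks", "event"), "group_b")
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    stopf("both groups must be non-empty")
  }
  time <- c(group_a$time_weeks, group_b$time_weeks)
  event <- as.logical(c(group_a$event, group_b$event))
  in_a <- rep(c(TRUE, FALSE), c(nrow(group_a), nrow(group_b)))
  if (!any(event)) {
    stopf("log-rank test undefined: no events in either group")
  }
  ts <- sort(unique(time[event]))
  o_a <- 0
  e_a <- 0
  v <- 0
  obs <- c(a = 0, b = 0)
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & in_a)
    d <- sum(time == t & event)
    d_a <- sum(time == t & event & in_a)
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    if (n > 1) {
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
    obs["a"] <- obs["a"] + d_a
    obs["b"] <- obs["b"] + (d - d_a)
  }
  chisq <- if (v > 0) (o_a - e_a)^2 / v else 0
  total <- obs["a"] + obs["b"]
  structure(
    list(chisq = unname(chisq), df = 1L,
         p_value = stats::pchisq(unname(chisq), df = 1, lower.tail = FALSE),
         observed = unname(obs),
         expected = unname(c(e_a, total - e_a))),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank (Mantel-Cox): chisq = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  cat(sprintf("  observed events: %g vs %g; expected: %.3g vs %.3g\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  invisible(x)
}

#' Tumor spectrum of a genotype cohort
#'
#' Tabulates diagnoses over all animals of the requested genotype,
#' expressing each as a percentage of the cohort size. Animals found dead
#' without a visible tumor are events with diagnosis `"none"`; tumor-free
#' animals censored at study end (no recorded diagnosis) are reported under
#' `"none"` as well.
#'
#' @param cohort Cohort data.frame (see [read_cohort()]).
#' @param genotype One of `"wt"`, `"het"`, `"null"`.
#' @return A data.frame with columns `diagnosis`, `count`, `percent`
#'   (summing to the cohort size and 100), with attributes `genotype` and
#'   `n`.
#' @examples
#' nulls <- data.frame(
#'   id = paste0("m", 1:5), genotype = "null",
#'   time_weeks = c(11, 12, 13, 14, 12), event = TRUE,
#'   diagnosis = c("thymic_lymphoma", "thymic_lymphoma",
#'                 "testicular_teratoma", "testicular_teratoma", "none")
#' )
#' tumor_spectrum(nulls, "null")  # 40% / 40% / 20%
#' @export
tumor_spectrum <- function(cohort, genotype) {
  validate_cohort(cohort)
  if (!genotype %in% GENOTYPES) {
    stopf("genotype must be one of: %s", paste(GENOTYPES, collapse = ", "))
  }
  sel <- cohort[cohort$genotype == genotype, , drop = FALSE]
  if (nrow(sel) == 0) stopf("no animals with genotype '%s'", genotype)
  diag <- sel$diagnosis
  diag[is.na(diag) | !nzchar(diag)] <- "none"
  tab <- table(diag)
  out <- data.frame(diagnosis = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$diagnosis), , drop = FALSE]
  out$percent <- 100 * out$count / nrow(sel)
  rownames(out) <- NULL
  attr(out, "genotype") <- genotype
  attr(out, "n") <- nrow(sel)
  out
}

#' Chi-square test of observed genotype counts against a Mendelian ratio
#'
#' Goodness-of-fit chi-square of litter genotype counts against the
#' expected segregation ratio — by default 1:2:1
#' (wild type : heterozygous : homozygous null) for a heterozygote
#' intercross. The ratio is caller-supplied so any expected segregation can
#' be tested.
#'
#' @param observed Numeric vector of genotype counts (conventionally wt,
#'   het, null), total > 0.
#' @param ratio Expected ratio, same length as `observed`, entries > 0.
#' @return A list: `chisq`, `df` (length(observed) - 1), `p_value`,
#'   `expected` counts.
#' @examples
#' mendelian_test(c(15, 30, 5))          # against 1:2:1
#' @export
mendelian_test <- function(observed, ratio = c(1, 2, 1)) {
  if (!is.numeric(observed) || length(observed) < 2 || any(observed < 0)) {
    stopf("`observed` must be non-negative counts of at least two classes")
  }
  if (sum(observed) <= 0) stopf("total observed count must be positive")
  if (length(ratio) != length(observed) || any(ratio <= 0)) {
    stopf("`ratio` must be positive and match `observed` in length")
  }
  ht <- suppressWarnings(
    stats::chisq.test(observed, p = ratio / sum(ratio))
  )
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = unname(ht$expected))
}
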