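#' Limiting-dilution frequency estimation (single-hit Poisson model)
#'
#' Estimates the frequency `f` of assay-active (sphere-initiating) cells
#' from well outcomes of a limiting-dilution assay. Under the single-hit
#' model a well seeded with `d` cells is negative with probability
#' `exp(-f * d)`, i.e. positives follow a binomial generalized linear
#' model with complementary log-log link and `log(dose)` offset. The
#' maximum-likelihood estimate is found as the unique root of the
#' analytic score equation (the binomial log-likelihood is unimodal in
#' `log f` for interior data), and the confidence interval comes from
#' the profile likelihood, cutting the deviance at the chi-square
#' quantile with one degree of freedom (3.841 at 95%). Profile intervals
#' are preferred to Wald intervals here because well counts are small
#' (24 per dose in the standard design) and the likelihood is skewed.
#'
#' Boundary data yield one-sided results rather than a point estimate:
#' with no positive wells the estimate is 0 with an upper confidence
#' bound only; with no negative wells it is `Inf` (frequency
#' indistinguishable from 1 per cell at these doses) with a lower bound
#' only.
#'
#' @param data A `data.frame` with columns `dose` (cells per well,
#'   integer >= 1), `wells` and `positive` (counts,
#'   `0 <= positive <= wells`).
#' @param conf_level Confidence level for the profile interval.
#' @return An object of class `lda_fit`: list with `frequency` (active
#'   cells per plated cell), `ci_low`, `ci_high`, `loglik` (maximized),
#'   `boundary` (`NA`, `"all_negative"` or `"all_positive"`),
#'   `conf_level` and `data`.
#' @examples
#' wells <- data.frame(dose = 100, wells = 24, positive = 12)
#' lda_fit(wells)  # f = -log(12/24)/100, about 1 in 144
#' @seealso [lda_compare()], [simulate_lda_wells()]
#' @export
lda_fit <- function(data, conf_level = 0.95) {
  data <- check_lda_input(data)
  stopifnot(conf_level > 0, conf_level < 1)
  cutoff <- qchisq(conf_level, df = 1)
  ll <- function(f) lda_loglik(f, data)
  tot_pos <- sum(data$positive)
  tot_neg <- sum(data$wells - data$positive)
  if (tot_pos == 0L) {
    # no positives: MLE at the f = 0 boundary, ll(0) = 0
    wd <- sum(data$wells * data$dose)
    return(new_lda_fit(0, 0, cutoff / (2 * wd), 0, "all_negative",
                       conf_level, data))
  }
  if (tot_neg == 0L) {
    # no negatives: likelihood increases toward f = Inf, sup ll = 0
    g <- function(u) -2 * ll(exp(u)) - cutoff
    u0 <- log(50 / min(data$dose))  # f at which every well is near-surely hit
    lo <- uniroot_expand(g, u0, -1)
    return(new_lda_fit(Inf, exp(lo), Inf, 0, "all_positive",
                       conf_level, data))
  }
  # interior MLE: score is strictly decreasing in f with a sign change
  score <- function(f) {
    sum(data$positive * data$dose / expm1(f * data$dose)) -
      sum((data$wells - data$positive) * data$dose)
  }
  lower <- 1 / max(data$dose)
  while (score(lower) < 0) lower <- lower / 10
  upper <- lower * 10
  while (score(upper) > 0) upper <- upper * 10
  fhat <- uniroot(score, c(lower, upper), tol = 1e-14)$root
  llmax <- ll(fhat)
  dev <- function(u) 2 * (llmax - ll(exp(u))) - cutoff
  ci_low <- exp(uniroot_expand(dev, log(fhat), -1))
  ci_high <- exp(uniroot_expand(dev, log(fhat), +1))
  new_lda_fit(fhat, ci_low, ci_high, llmax, NA_character_, conf_level, data)
}

# binomial log-likelihood of frequency f given (dose, wells, positive)
lda_loglik <- function(f, data) {
  if (f < 0) return(-Inf)
  if (f == 0) return(if (sum(data$positive) > 0) -Inf else 0)
  p_pos <- -expm1(-f * data$dose)
  sum(data$positive * log(p_pos)) -
    f * sum((data$wells - data$positive) * data$dose)
}

# find the root of g along direction `dir` starting at u0 (g(u0) < 0,
# g increasing away from u0); expands the bracket geometrically
uniroot_expand <- function(g, u0, dir, step = 1, max_steps = 200L) {
  a <- u0
  b <- u0 + dir * step
  k <- 0L
  while (g(b) < 0) {
    a <- b
    b <- b + dir * step
    step <- step * 2
    k <- k + 1L
    if (k > max_steps) stop("profile bound bracketing failed", call. = FALSE)
  }
  uniroot(g, sort(c(a, b)), tol = 1e-12)$root
}

new_lda_fit <- function(frequency, ci_low, ci_high, loglik, boundary,
                        conf_level, data) {
  structure(
    list(frequency = frequency, ci_low = ci_low, ci_high = ci_high,
         loglik = loglik, boundary = boundary, conf_level = conf_level,
         data = data),
    class = "lda_fit"
  )
}

#' @export
print.lda_fit <- function(x, ...) {
  as_1in <- function(f) {
    if (f <= 0) "0 (1 in Inf)"
    else if (!is.finite(f)) "Inf"
    else sprintf("%.4g (1 in %.4g)", f, 1 / f)
  }
  cat("Limiting-dilution frequency (single-hit Poisson model)\n")
  cat("  frequency:", as_1in(x$frequency), "\n")
  cat(sprintf("  %g%% profile CI: [%s, %s]\n", 100 * x$conf_level,
              as_1in(x$ci_low), as_1in(x$ci_high)))
  if (!is.na(x$boundary)) cat("  boundary data:", x$boundary, "\n")
  invisible(x)
}

#' Likelihood-ratio comparison of two limiting-dilution groups
#'
#' Tests whether two groups share the same active-cell frequency: the
#' null fits one common `f` to the pooled well data, the alternative
#' fits each group separately, and twice the log-likelihood gain is
#' referred to a chi-square distribution with one degree of freedom.
#' The test is symmetric in the two groups.
#'
#' @param a,b Well tables as in [lda_fit()], or fitted `lda_fit`
#'   objects.
#' @return An object of class `htest` with the chi-square statistic,
#'   `df = 1` and the p-value.
#' @examples
#' g1 <- simulate_lda_wells(1 / 150, seed = 1)
#' g2 <- simulate_lda_wells(1 / 15, seed = 2)
#' lda_compare(g1, g2)
#' @export
lda_compare <- function(a, b) {
  fit_a <- if (inherits(a, "lda_fit")) a else lda_fit(a)
  fit_b <- if (inherits(b, "lda_fit")) b else lda_fit(b)
  pooled <- lda_fit(rbind(fit_a$data, fit_b$data))
  stat <- max(0, 2 * (fit_a$loglik + fit_b$loglik - pooled$loglik))
  structure(
    list(statistic = c("X-squared" = stat),
         parameter = c(df = 1),
         p.value = pchisq(stat, df = 1, lower.tail = FALSE),
         estimate = c("frequency a" = fit_a$frequency,
                      "frequency b" = fit_b$frequency),
         method = paste("Likelihood-ratio test of equal",
                        "limiting-dilution frequency"),
         data.name = "a vs b"),
    class = "htest"
  )
}

check_lda_input <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("dose", "wells", "positive")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!nrow(data)) stop("empty limiting-dilution table", call. = FALSE)
  with(data, {
    if (any(dose < 1) || any(dose != floor(dose))) {
      stop("`dose` must be integer >= 1", call. = FALSE)
    }
    if (any(wells < 1) || any(positive < 0) || any(positive > wells)) {
      stop("need 0 <= positive <= wells with wells >= 1", call. = FALSE)
    }
  })
  data[, need]
}
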