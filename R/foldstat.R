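# Native-state populations and survival-analysis folding kinetics.
#
# Folding events are first passages of a CaB RMSD series below the native
# cutoff (1.96 A by default); simulations that never reach it are
# right-censored at their last saved time.  Mean times-to-folding come
# either from the Kaplan-Meier restricted mean or from a parametric
# (exponential/Weibull) fit, both through the survival package.

#' Native-state criterion
#'
#' @param cutoff RMSD cutoff in A below (or at) which a conformation counts
#'   as native; default 1.96.
#' @param selection atom selection the RMSD refers to.
#' @return list with `cutoff` and `selection`.
#' @export
nativeStateCriterion <- function(cutoff = 1.96, selection = "CA+CB") {
  if (cutoff <= 0) stopUsage("cutoff must be positive")
  list(cutoff = cutoff, selection = selection)
}

#' First-passage folding time of one RMSD series
#'
#' The first saved time at which the series reaches the cutoff (boundary
#' inclusive) is the individual folding time; a series that never reaches
#' it yields a right-censored observation at its last saved time.
#'
#' @param series data.frame with columns `time` (ns) and `rmsd` (A), as
#'   returned by [rmsdSeries()].
#' @param criterion see [nativeStateCriterion()].
#' @param simId identifier carried into the observation.
#' @return data.frame row with columns `simId`, `time`, `event`.
#' @export
individualFoldingTime <- function(series, criterion = nativeStateCriterion(),
                                  simId = NA) {
  if (!nrow(series)) stopUsage("empty RMSD series")
  hit <- which(series$rmsd <= criterion$cutoff)
  if (length(hit))
    data.frame(simId = simId, time = series$time[hit[1]], event = TRUE)
  else
    data.frame(simId = simId, time = series$time[nrow(series)], event = FALSE)
}

#' Native-state population of one RMSD series
#'
#' Fraction of saved conformations at or below the cutoff.
#'
#' @inheritParams individualFoldingTime
#' @return fraction in \[0, 1\].
#' @export
nativePopulation <- function(series, criterion = nativeStateCriterion()) {
  if (!nrow(series)) stopUsage("empty RMSD series")
  mean(series$rmsd <= criterion$cutoff)
}

#' Aggregate per-simulation populations
#'
#' Mean of the individual populations over simulations, with the sample
#' standard deviation across simulations and the standard error SD/sqrt(n).
#'
#' @param p numeric vector of per-simulation populations in \[0, 1\].
#' @return list with `perSim`, `mean`, `sd`, `se`, `n` (`sd`/`se` are `NA`
#'   for n < 2).
#' @export
aggregatePopulation <- function(p) {
  n <- length(p)
  s <- if (n >= 2) stats::sd(p) else NA_real_
  list(perSim = p, mean = mean(p), sd = s,
       se = if (n >= 2) s / sqrt(n) else NA_real_, n = n)
}

checkObservations <- function(observations) {
  need <- c("time", "event")
  if (!all(need %in% names(observations)))
    stopUsage("observations need columns time and event")
  if (any(observations$time < 0)) stopUsage("negative observation time")
  observations
}

#' Kaplan-Meier mean time-to-folding
#'
#' Restricted mean of the Kaplan-Meier survival curve, integrated up to the
#' largest observed time, with a 95\% confidence interval from the
#' Greenwood standard error applied on the log scale.
#'
#' @param observations data.frame with columns `time` (ns) and `event`
#'   (logical), one row per simulation.
#' @return a [FoldingTimeEstimate-class].
#' @export
kmFoldingTime <- function(observations) {
  observations <- checkObservations(observations)
  if (!any(observations$event)) stopUsage("no folding events observed")
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = observations, conf.type = "log")
  tmax <- max(observations$time)
  tab <- summary(fit, rmean = tmax)$table
  m <- unname(tab["rmean"])
  se <- unname(tab["se(rmean)"])
  if (!is.finite(se) || m <= 0) {
    lcl <- ucl <- m
  } else {
    lcl <- m * exp(-1.96 * se / m)
    ucl <- m * exp(1.96 * se / m)
  }
  new("FoldingTimeEstimate", mean = m, lcl = lcl, ucl = ucl,
      nEvents = as.integer(sum(observations$event)),
      nTotal = nrow(observations), method = "km", distribution = "none")
}

#' Parametric mean time-to-folding
#'
#' Maximum-likelihood fit of an exponential or Weibull survival model with
#' right censoring (via [survival::survreg()]).  The mean is `1/lambda`
#' for the exponential and `scale * gamma(1 + 1/shape)` for the Weibull;
#' the 95\% CI comes from normal asymptotics on the log-scale parameters
#' (delta method for the Weibull mean).  Estimation is refused unless more
#' than half of the simulations captured a folding event, because the CI
#' would otherwise be too wide to be informative.
#'
#' @inheritParams kmFoldingTime
#' @param distribution `"exponential"` or `"weibull"`.
#' @return a [FoldingTimeEstimate-class].
#' @export
parametricFoldingTime <- function(observations,
                                  distribution = c("exponential", "weibull")) {
  distribution <- match.arg(distribution)
  observations <- checkObservations(observations)
  nev <- sum(observations$event)
  if (nev <= nrow(observations) / 2)
    stopUsage("insufficient events: ", nev, " of ", nrow(observations),
              " simulations captured a folding event; more than half are ",
              "required for a parametric fit")
  fit <- survival::survreg(survival::Surv(time, event) ~ 1,
                           data = observations, dist = distribution)
  mu <- unname(stats::coef(fit)[1])
  if (distribution == "exponential") {
    seMu <- sqrt(stats::vcov(fit)[1, 1])
    m <- exp(mu)
    lcl <- exp(mu - 1.96 * seMu); ucl <- exp(mu + 1.96 * seMu)
  } else {
    # log(mean) = mu + log(gamma(1 + sigma-ish)); delta method on (mu, log sigma)
    sigma <- fit$scale
    shape <- 1 / sigma
    m <- exp(mu) * gamma(1 + sigma)
    V <- stats::vcov(fit)  # parameters (mu, log sigma)
    grad <- c(1, sigma * digamma(1 + sigma))
    seLog <- sqrt(drop(t(grad) %*% V %*% grad))
    lcl <- m * exp(-1.96 * seLog); ucl <- m * exp(1.96 * seLog)
  }
  new("FoldingTimeEstimate", mean = m, lcl = lcl, ucl = ucl,
      nEvents = as.integer(nev), nTotal = nrow(observations),
      method = "parametric", distribution = distribution)
}

#' Agreement of a parametric survival curve with the Kaplan-Meier band
#'
#' Fraction of event-time grid points at which the fitted parametric
#' survival function lies inside the pointwise 95\% confidence band of the
#' Kaplan-Meier estimate.  Values above `threshold` (default 0.5) count as
#' "mostly within" the band.
#'
#' @inheritParams parametricFoldingTime
#' @param threshold agreement fraction regarded as acceptable.
#' @return list with `fraction`, `agreed` (logical) and `grid` (the
#'   per-event-time comparison).
#' @export
kmParametricAgreement <- function(observations,
                                  distribution = c("exponential", "weibull"),
                                  threshold = 0.5) {
  distribution <- match.arg(distribution)
  observations <- checkObservations(observations)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = observations, conf.type = "log")
  par <- survival::survreg(survival::Surv(time, event) ~ 1,
                           data = observations, dist = distribution)
  sm <- summary(fit)
  times <- sm$time
  if (!length(times)) stopUsage("no folding events observed")
  mu <- unname(stats::coef(par)[1])
  Spar <- if (distribution == "exponential")
    exp(-times / exp(mu))
  else
    exp(-(times / exp(mu))^(1 / par$scale))
  lower <- ifelse(is.na(sm$lower), 0, sm$lower)
  upper <- ifelse(is.na(sm$upper), 1, sm$upper)
  inside <- Spar >= lower & Spar <= upper
  frac <- mean(inside)
  list(fraction = frac, agreed = frac >= threshold,
       grid = data.frame(time = times, parametric = Spar,
                         lower = lower, upper = upper, inside = inside))
}

#' Two-state kinetics diagnostic
#'
#' For an all-events dataset, ordinary least squares of the natural
#' logarithm of the nonnative-state fraction remaining just after each
#' folding event against the event time.  Two-state (single-exponential)
#' kinetics shows up as a straight line with slope equal to minus the
#' folding rate.
#'
#' @param observations data.frame with columns `time` and `event`; every
#'   row must be an event.
#' @return list with `slope` (1/ns), `intercept`, `rSquared` and the
#'   regression data.
#' @export
twoStateCheck <- function(observations) {
  observations <- checkObservations(observations)
  if (!all(observations$event))
    stopUsage("two-state check requires a dataset in which every ",
              "simulation captured a folding event")
  t <- sort(observations$time)
  n <- length(t)
  if (length(unique(t)) < 3)
    stopUsage("need at least 3 distinct event times")
  frac <- (n - seq_len(n)) / n
  keep <- frac > 0
  x <- t[keep]; y <- log(frac[keep])
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rSquared = summary(fit)$r.squared,
       data = data.frame(time = x, logNonnative = y))
}
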