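#' Arrival profile for one working day
#'
#' Describes the arrival process of one simulated working day: a
#' piecewise-constant general-patient (GP) arrival-rate profile, the mean
#' interarrival time of the emergency stream, and the fraction of that
#' stream classified as urgent (UP) rather than emergency (EP).
#'
#' @param gp_rates A data.frame with columns `start`, `end`, `rate`:
#'   contiguous intervals (minutes since opening) partitioning
#'   `[0, open_minutes)` and the GP arrival rate (patients/minute) on each.
#' @param ep_mean_interarrival Mean interarrival time of the emergency
#'   stream, in minutes (exponential gaps).
#' @param urgent_fraction Probability that an emergency-stream arrival is
#'   urgent (UP); the complement is emergency (EP).
#'
#' @return An object of class `arrival_profile` with elements `gp_rates`,
#'   `ep_mean_interarrival`, `urgent_fraction` and `open_minutes`
#'   (the end of the last interval).
#' @seealso [default_profile()], [sample_gp_arrivals()], [sample_ep_arrivals()]
#' @export
arrival_profile <- function(gp_rates, ep_mean_interarrival = 7,
                            urgent_fraction = 0.7) {
  if (!is.data.frame(gp_rates) ||
      !all(c("start", "end", "rate") %in% names(gp_rates)))
    stop("profile.gp_rates must be a data.frame with start, end, rate")
  gp_rates <- gp_rates[c("start", "end", "rate")]
  if (nrow(gp_rates) == 0L) stop("profile.gp_rates must be nonempty")
  if (gp_rates$start[1L] != 0)
    stop("profile.gp_rates must start at 0")
  if (any(gp_rates$end <= gp_rates$start))
    stop("profile.gp_rates intervals must have positive length")
  if (nrow(gp_rates) > 1L &&
      any(gp_rates$start[-1L] != gp_rates$end[-nrow(gp_rates)]))
    stop("profile.gp_rates intervals must be contiguous")
  if (any(gp_rates$rate < 0))
    stop("profile.gp_rates rates must be nonnegative")
  if (!is.numeric(ep_mean_interarrival) || ep_mean_interarrival <= 0)
    stop("profile.ep_mean_interarrival must be positive")
  if (urgent_fraction < 0 || urgent_fraction > 1)
    stop("profile.urgent_fraction must lie in [0, 1]")
  structure(list(gp_rates = gp_rates,
                 ep_mean_interarrival = as.numeric(ep_mean_interarrival),
                 urgent_fraction = as.numeric(urgent_fraction),
                 open_minutes = max(gp_rates$end)),
            class = "arrival_profile")
}

#' @export
print.arrival_profile <- function(x, ...) {
  cat("arrival_profile:", nrow(x$gp_rates), "GP rate intervals over [0,",
      x$open_minutes, ") min;",
      format(gp_expected_count(x), digits = 4), "GP/day expected;\n",
      " emergency stream mean interarrival",
      format(x$ep_mean_interarrival, digits = 4), "min, urgent fraction",
      x$urgent_fraction, "\n")
  invisible(x)
}

#' Default synthetic arrival profile
#'
#' A stand-in for the (unpublished) empirical GP arrival pattern of a busy
#' radiology department: 13 hourly intervals over a 13-hour working day
#' (780 minutes, 8:00--21:00) with a pronounced morning peak in which
#' appointment arrivals temporarily exceed scanner capacity, a quieter
#' early afternoon, a smaller mid-afternoon shoulder and a sparse evening.
#' The hourly counts sum to 162 expected GP arrivals per day.  Combined
#' with the emergency stream this reproduces, after [calibrate()], the
#' historical congestion level of the base discipline (GP mean wait about
#' an hour at roughly 245 examinations/day).
#'
#' @return An [arrival_profile()].
#' @export
default_profile <- function() {
  hourly <- c(24, 28, 28, 24, 12, 8, 10, 10, 8, 6, 2, 1, 1)
  arrival_profile(
    data.frame(start = (seq_along(hourly) - 1) * 60,
               end = seq_along(hourly) * 60,
               rate = hourly / 60),
    ep_mean_interarrival = 7,
    urgent_fraction = 0.7
  )
}

#' Expected daily GP count of a profile
#'
#' @param profile An [arrival_profile()].
#' @return Expected number of GP arrivals per day
#'   (sum of rate x interval length).
#' @export
gp_expected_count <- function(profile) {
  with(profile$gp_rates, sum(rate * (end - start)))
}

#' Scale the GP rates of a profile
#'
#' Multiplies every GP arrival rate by a constant; used by [calibrate()].
#'
#' @param profile An [arrival_profile()].
#' @param mult Nonnegative multiplier.
#' @return The scaled [arrival_profile()].
#' @export
scale_gp_rates <- function(profile, mult) {
  stopifnot(inherits(profile, "arrival_profile"), mult >= 0)
  r <- profile$gp_rates
  r$rate <- r$rate * mult
  arrival_profile(r, profile$ep_mean_interarrival, profile$urgent_fraction)
}

#' Sample general-patient arrival times
#'
#' Realizes one day of the nonhomogeneous Poisson GP arrival process by
#' inversion of the cumulative intensity: unit-rate exponential gaps are
#' mapped through the inverse of the piecewise-linear integrated rate, so
#' per-interval counts are Poisson with mean rate x length and increments
#' over disjoint intervals are independent.  Uses the current R random
#' stream.
#'
#' @param profile An [arrival_profile()].
#' @param horizon Arrival horizon in minutes (arrivals stop here); defaults
#'   to the profile's `open_minutes`.
#' @return Sorted numeric vector of arrival times in `[0, horizon)`.
#' @export
sample_gp_arrivals <- function(profile, horizon = profile$open_minutes) {
  stopifnot(inherits(profile, "arrival_profile"))
  if (horizon <= 0) stop("horizon must be positive")
  r <- profile$gp_rates
  r$end <- pmin(r$end, horizon)
  r <- r[r$start < horizon, , drop = FALSE]
  lens <- r$end - r$start
  cum <- c(0, cumsum(r$rate * lens))   # integrated rate at interval bounds
  total <- cum[length(cum)]
  if (total <= 0) return(numeric(0))
  # unit-rate Poisson epochs on [0, total)
  s <- cumsum(stats::rexp(ceiling(total + 6 * sqrt(total) + 20)))
  while (s[length(s)] < total)
    s <- c(s, s[length(s)] + cumsum(stats::rexp(50L)))
  s <- s[s < total]
  if (length(s) == 0L) return(numeric(0))
  k <- findInterval(s, cum)            # rightmost bound <= s; zero-rate
                                       # intervals collapse to duplicates
  r$start[k] + (s - cum[k]) / r$rate[k]
}

#' Sample the emergency-stream arrivals
#'
#' One day of the urgent/emergency arrival stream: interarrival gaps are
#' i.i.d. exponential with the profile's mean, and each arrival is labelled
#' `"UP"` with probability `urgent_fraction`, else `"EP"`, independently.
#' Uses the current R random stream.
#'
#' @inheritParams sample_gp_arrivals
#' @return A data.frame with columns `time` (sorted, in `[0, horizon)`) and
#'   `cls` (`"UP"` or `"EP"`).
#' @export
sample_ep_arrivals <- function(profile, horizon = profile$open_minutes) {
  stopifnot(inherits(profile, "arrival_profile"))
  if (horizon <= 0) stop("horizon must be positive")
  m <- profile$ep_mean_interarrival
  n0 <- ceiling(horizon / m + 6 * sqrt(horizon / m) + 20)
  s <- cumsum(stats::rexp(n0, rate = 1 / m))
  while (s[length(s)] < horizon)
    s <- c(s, s[length(s)] + cumsum(stats::rexp(50L, rate = 1 / m)))
  s <- s[s < horizon]
  cls <- ifelse(stats::runif(length(s)) < profile$urgent_fraction, "UP", "EP")
  data.frame(time = s, cls = cls, stringsAsFactors = FALSE)
}
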