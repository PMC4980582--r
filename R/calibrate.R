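#' Calibrate the arrival profile to a historical congestion level
#'
#' Scales the GP arrival rates of a profile (and, if needed, the emergency
#' stream's mean interarrival time) so that pilot replications of the
#' **base** discipline reproduce a target mean GP waiting time and a target
#' daily examination quantity.  The search bisects a scalar multiplier on
#' the GP rates against the pilot mean GP wait, which is monotone in GP
#' load; the emergency interarrival mean is then adjusted within
#' `ep_mean_bounds` so the expected daily total matches, and the bisection
#' is repeated until both targets are met.  Given `seed`, the whole
#' procedure is deterministic.
#'
#' @param profile Starting [arrival_profile()].
#' @param target_gp_wait Target mean GP waiting time (minutes), positive.
#' @param target_daily_total Target mean daily examination quantity,
#'   positive.
#' @param n_pilot Number of pilot replications per candidate profile.
#' @param seed Master seed of the pilot runs.
#' @param gp_durations,ep_durations Duration distributions of the pilot
#'   model.
#' @param open_minutes Day length in minutes.
#' @param wait_tol,total_tol Relative tolerances of the achieved pilot GP
#'   wait and daily total; the search aims at half of each, leaving margin
#'   for verification runs under other seeds.
#' @param ep_mean_bounds Admissible range of the emergency mean
#'   interarrival time (minutes).
#' @param max_outer Maximum alternations between the wait bisection and the
#'   emergency-mean adjustment.
#' @param max_bisect Maximum bisection evaluations per outer round.
#' @param verbose Print the search trajectory.
#'
#' @return The calibrated [arrival_profile()], with an attribute
#'   `"calibration"`: a list with `multiplier` (cumulative GP-rate scale),
#'   `ep_mean_interarrival`, `achieved_gp_wait`, `achieved_daily_total`,
#'   `pilot_reps`, `evaluations` and `converged = TRUE`.
#' @export
#' @examples
#' \donttest{
#' prof <- calibrate(default_profile(), 66.8, 245, n_pilot = 20, seed = 1)
#' attr(prof, "calibration")$achieved_gp_wait
#' }
calibrate <- function(profile, target_gp_wait = 66.8,
                      target_daily_total = 245, n_pilot = 800L, seed = 1L,
                      gp_durations = gp_duration_dist(),
                      ep_durations = ep_duration_dist(),
                      open_minutes = 780, wait_tol = 0.10, total_tol = 0.05,
                      ep_mean_bounds = c(7, 9.3), max_outer = 5L,
                      max_bisect = 20L, verbose = FALSE) {
  stopifnot(inherits(profile, "arrival_profile"))
  if (target_gp_wait <= 0 || target_daily_total <= 0)
    stop("calibration targets must be positive")
  if (n_pilot < 2L) stop("n_pilot must be at least 2")

  base_gp_total <- gp_expected_count(profile)
  if (base_gp_total <= 0) stop("profile has no GP arrivals to scale")
  ep_mean <- profile$ep_mean_interarrival
  evaluations <- 0L

  pilot <- function(mult, ep_m) {
    prof <- scale_gp_rates(profile, mult)
    prof$ep_mean_interarrival <- ep_m
    cfg <- sim_config(profile = prof, policy = policy_config("base"),
                      open_minutes = open_minutes, n_reps = n_pilot,
                      master_seed = seed, gp_durations = gp_durations,
                      ep_durations = ep_durations)
    ind <- run_replications(cfg)$indicators
    evaluations <<- evaluations + 1L
    c(wait = mean(ind[, "wait_gp"], na.rm = TRUE),
      total = mean(ind[, "quantity"]))
  }

  aim_wait <- wait_tol / 8 * target_gp_wait
  aim_total <- total_tol / 2 * target_daily_total
  mult <- 1
  achieved <- NULL

  for (outer in seq_len(max_outer)) {
    lo <- 0.1
    hi <- 4
    m <- mult                       # start at the incumbent: an already
    ok <- FALSE                     # calibrated profile converges at once
    for (it in seq_len(max_bisect)) {
      got <- pilot(m, ep_mean)
      if (verbose)
        message(sprintf("outer %d it %d: mult %.4f ep_mean %.3f -> wait %.2f total %.1f",
                        outer, it, m, ep_mean, got["wait"], got["total"]))
      if (abs(got["wait"] - target_gp_wait) <= aim_wait) {
        ok <- TRUE
        achieved <- got
        break
      }
      if (got["wait"] < target_gp_wait) lo <- m else hi <- m
      m <- (lo + hi) / 2
    }
    if (!ok)
      stop("calibration failure: GP-wait bisection did not converge to ",
           target_gp_wait, " min (load target infeasible for this profile)",
           call. = FALSE)
    mult <- m
    # match the daily total by moving the emergency interarrival mean
    gp_count <- mult * base_gp_total
    ep_needed <- target_daily_total - gp_count
    ep_new <- if (ep_needed <= 0) ep_mean_bounds[2L]
              else min(max(open_minutes / ep_needed, ep_mean_bounds[1L]),
                       ep_mean_bounds[2L])
    if (abs(achieved["total"] - target_daily_total) <= aim_total &&
        abs(ep_new - ep_mean) / ep_mean < 0.01) {
      attr_prof <- scale_gp_rates(profile, mult)
      attr_prof$ep_mean_interarrival <- ep_mean
      attr(attr_prof, "calibration") <-
        list(multiplier = mult, ep_mean_interarrival = ep_mean,
             achieved_gp_wait = unname(achieved["wait"]),
             achieved_daily_total = unname(achieved["total"]),
             pilot_reps = n_pilot, evaluations = evaluations,
             converged = TRUE)
      return(attr_prof)
    }
    ep_mean <- ep_new
  }
  stop("calibration failure: could not meet both the GP-wait and the ",
       "daily-quantity targets within ", max_outer, " rounds",
       call. = FALSE)
}
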