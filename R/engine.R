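#' Simulation configuration
#'
#' Bundles everything needed to replicate simulated working days: the
#' arrival profile, the queue discipline, the day length, the replication
#' count and the master seed from which every per-day random substream is
#' derived.
#'
#' @param profile An [arrival_profile()].
#' @param policy A [policy_config()].
#' @param open_minutes Length of the arrival horizon in minutes (default
#'   780, a 13-hour working day 8:00--21:00).  Arrivals stop at closing;
#'   the scanner works overtime until the queue empties.
#' @param n_reps Number of replicated days (terminating replications,
#'   each starting empty).
#' @param master_seed Integer master seed; all randomness flows from named
#'   substreams derived from `(master_seed, rep_index, stream)`, so two
#'   policies run under the same configuration share identical arrival and
#'   duration streams (common random numbers).
#' @param gp_durations,ep_durations [service_distribution()]s for general
#'   patients and for the emergency stream (urgent patients use the
#'   emergency distribution: they come from the same stream).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(profile = default_profile(),
                       policy = policy_config("base"),
                       open_minutes = 780, n_reps = 100L, master_seed = 1L,
                       gp_durations = gp_duration_dist(),
                       ep_durations = ep_duration_dist()) {
  stopifnot(inherits(profile, "arrival_profile"),
            inherits(policy, "policy_config"),
            inherits(gp_durations, "service_distribution"),
            inherits(ep_durations, "service_distribution"))
  if (open_minutes <= 0) stop("sim.open_minutes must be positive")
  if (n_reps < 1) stop("sim.n_reps must be at least 1")
  if (length(master_seed) != 1L || is.na(master_seed) ||
      master_seed != round(master_seed))
    stop("sim.master_seed must be an integer")
  structure(list(profile = profile, policy = policy,
                 open_minutes = as.numeric(open_minutes),
                 n_reps = as.integer(n_reps),
                 master_seed = as.integer(master_seed %% 2147483647),
                 gp_durations = gp_durations, ep_durations = ep_durations),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_reps, "replicated days of", x$open_minutes,
      "min, seed", x$master_seed, "\n")
  print(x$policy)
  print(x$profile)
  invisible(x)
}

#' Named random substream seed
#'
#' Deterministically derives the seed of one named random substream from
#' `(master_seed, rep_index, stream)` by iterating a Lehmer step, so that
#' arrival and duration streams are independent of the policy being run and
#' of each other.  Stream 1 is the GP arrival stream, 2 the emergency
#' stream, 3 the duration stream.
#'
#' @param master_seed,rep_index,stream Nonnegative integers.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master_seed, rep_index, stream) {
  m <- 2147483647  # 2^31 - 1
  a <- 48271
  mix <- function(x, k) {
    x <- (x + k) %% m
    for (i in 1:3) x <- (a * x) %% m
    x
  }
  x <- master_seed %% m
  x <- mix(x, 1)
  x <- mix(x, rep_index)
  x <- mix(x, stream)
  as.integer(x)
}

#' Sample the patient stream of one day
#'
#' Draws the full arrival table of one replicated day — GP arrivals from the
#' nonhomogeneous Poisson profile, the emergency stream with its UP/EP
#' split, and an examination duration for every patient — from substreams
#' derived only from `(master_seed, rep_index)`.  The table is therefore
#' identical across policies (common random numbers).  Simultaneous
#' arrivals keep draw order (GP stream before emergency stream).
#'
#' @param config A [sim_config()].
#' @param rep_index Replication (day) index, a positive integer.
#' @return A data.frame with one row per arrival, sorted by `arrival`:
#'   columns `id` (1..n in arrival order), `cls`, `arrival`, `duration`.
#' @export
sample_day_patients <- function(config, rep_index) {
  stopifnot(inherits(config, "sim_config"))
  ms <- config$master_seed
  set.seed(substream_seed(ms, rep_index, 1L))
  gp_t <- sample_gp_arrivals(config$profile, config$open_minutes)
  set.seed(substream_seed(ms, rep_index, 2L))
  ep <- sample_ep_arrivals(config$profile, config$open_minutes)
  t <- c(gp_t, ep$time)
  cls <- c(rep("GP", length(gp_t)), ep$cls)
  ord <- order(t)                      # stable: ties keep draw order
  t <- t[ord]; cls <- cls[ord]
  n <- length(t)
  dur <- integer(n)
  set.seed(substream_seed(ms, rep_index, 3L))
  dur[cls == "GP"] <- sample_duration(config$gp_durations, sum(cls == "GP"))
  dur[cls != "GP"] <- sample_duration(config$ep_durations, sum(cls != "GP"))
  data.frame(id = seq_len(n), cls = cls, arrival = t, duration = dur,
             stringsAsFactors = FALSE)
}

#' Simulate one day over a fixed patient table
#'
#' The deterministic event kernel: given a fully sampled (or hand-written)
#' arrival table, plays out the day for a single non-preemptive scanner
#' under the given discipline.  Every patient is served exactly once; the
#' scanner never idles while patients wait, works past closing until the
#' queue empties, and at equal timestamps processes service completions
#' before arrivals.  An exam in progress is never interrupted.
#'
#' @param patients A data.frame with columns `cls` (`"GP"`, `"UP"`, `"EP"`),
#'   `arrival` (nondecreasing minutes) and `duration` (positive minutes);
#'   an `id` column is added if absent.
#' @param policy A [policy_config()].
#' @return The `patients` data.frame with added columns `service_start`,
#'   `service_end` and `wait` (`service_start - arrival`).
#' @export
#' @examples
#' simulate_day(
#'   data.frame(cls = c("GP", "EP"), arrival = c(0, 1), duration = c(4, 2)),
#'   policy_config("base")
#' )
simulate_day <- function(patients, policy) {
  stopifnot(inherits(policy, "policy_config"))
  n <- nrow(patients)
  if (is.null(patients$id)) patients$id <- seq_len(max(n, 0L))
  cls <- as.character(patients$cls)
  arr <- as.numeric(patients$arrival)
  dur <- as.numeric(patients$duration)
  if (n && is.unsorted(arr)) stop("patients must be sorted by arrival")
  if (any(dur <= 0)) stop("durations must be positive")
  if (any(arr < 0)) stop("arrival times must be nonnegative")
  if (!all(cls %in% c("GP", "UP", "EP")))
    stop("patient cls must be GP, UP or EP")

  kind <- policy$kind
  ocls <- cls                          # ordering class (base may remap UPs)
  if (kind == "base" && policy$up_as != "UP")
    ocls[cls == "UP"] <- policy$up_as

  start <- rep(NA_real_, n)
  queue <- integer(0)                  # waiting list of patient ids
  in_service <- 0L
  busy_until <- Inf
  i <- 1L                              # next arrival
  while (i <= n || length(queue) || in_service) {
    next_arr <- if (i <= n) arr[i] else Inf
    if (in_service && busy_until <= next_arr) {
      now <- busy_until                # completion (first on tie)
      in_service <- 0L
      busy_until <- Inf
      if (length(queue)) {
        k <- if (kind == "dynamic")
          select_dynamic_idx(cls[queue], arr[queue], queue, now, policy)
        else 1L
        p <- queue[k]
        queue <- queue[-k]
        start[p] <- now
        in_service <- p
        busy_until <- now + dur[p]
      }
    } else {                           # arrival
      now <- next_arr
      if (!in_service && !length(queue)) {
        start[i] <- now
        in_service <- i
        busy_until <- now + dur[i]
      } else {
        pos <- switch(kind,
                      base = insert_base(ocls[queue], ocls[i]),
                      fixed = insert_fixed(cls[queue], cls[i], policy$P),
                      dynamic = length(queue) + 1L)
        queue <- append(queue, i, after = pos - 1L)
      }
      i <- i + 1L
    }
  }
  patients$service_start <- start
  patients$service_end <- start + dur
  patients$wait <- start - arr
  patients
}

#' Run one replicated day
#'
#' Samples the day's patient stream with [sample_day_patients()] and plays
#' it out with [simulate_day()].  Identical `(config, rep_index)` give a
#' bit-identical result.
#'
#' @inheritParams sample_day_patients
#' @return An object of class `ctq_day`: a list with `records` (the served
#'   patient table), `indicators` (named vector, see [day_indicators()]),
#'   `rep_index` and `policy`.
#' @export
run_day <- function(config, rep_index) {
  patients <- sample_day_patients(config, rep_index)
  records <- simulate_day(patients, config$policy)
  structure(list(records = records,
                 indicators = day_indicators(records, config$policy),
                 rep_index = as.integer(rep_index),
                 policy = config$policy),
            class = "ctq_day")
}

#' @export
print.ctq_day <- function(x, ...) {
  cat("ctq_day (rep", x$rep_index, ",", x$policy$kind, "policy):",
      nrow(x$records), "patients served\n")
  print(round(x$indicators, 3))
  invisible(x)
}
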