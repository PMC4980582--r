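#' Satisfaction rate of a class
#'
#' The fraction of waiting times within (less than or equal to) the class
#' threshold.  The boundary counts as satisfied; waits are continuous, so
#' the boundary mass is negligible.  An empty input has no defined rate and
#' returns `NA`, which replication summaries exclude.
#'
#' @param waits Numeric vector of waiting times in minutes (nonnegative).
#' @param threshold Class waiting-time threshold in minutes, positive.
#' @return A fraction in `[0, 1]`, or `NA` for empty input.
#' @export
#' @examples
#' satisfaction_rate(c(10, 50), 40)  # 0.5
satisfaction_rate <- function(waits, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  if (any(waits < 0)) stop("negative waiting time in input")
  if (length(waits) == 0L) return(NA_real_)
  mean(waits <= threshold)
}

#' Per-day output indicators
#'
#' Computes the daily indicator vector from one day's served records:
#' mean waits per class and overall, satisfaction rates of GPs and UPs at
#' their thresholds (EPs are excluded from threshold-based satisfaction,
#' equivalently their threshold is infinite), the daily examination
#' quantity, and the fraction of UPs waiting beyond their threshold.
#' Indicators for an absent class are `NA`.  Patients served after closing
#' still count toward their day.
#'
#' @param records A served patient table from [simulate_day()].
#' @param policy A [policy_config()] supplying the thresholds.
#' @return Named numeric vector: `wait_gp`, `wait_up`, `wait_ep`,
#'   `wait_all`, `sat_gp`, `sat_up`, `quantity`, `frac_up_over`.
#' @export
day_indicators <- function(records, policy) {
  w <- records$wait
  cls <- records$cls
  if (any(is.na(w))) stop("records contain unserved patients")
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  w_up <- w[cls == "UP"]
  c(wait_gp = mean_or_na(w[cls == "GP"]),
    wait_up = mean_or_na(w_up),
    wait_ep = mean_or_na(w[cls == "EP"]),
    wait_all = mean_or_na(w),
    sat_gp = satisfaction_rate(w[cls == "GP"], policy$t_gp_threshold),
    sat_up = satisfaction_rate(w_up, policy$t_up_threshold),
    quantity = length(w),
    frac_up_over = if (length(w_up)) mean(w_up > policy$t_up_threshold)
                   else NA_real_)
}

#' Run all replications of a configuration
#'
#' Runs `config$n_reps` independent terminating days (each starting empty)
#' and collects the per-day indicator matrix.
#'
#' @param config A [sim_config()].
#' @return An object of class `ctq_reps`: list with `days` (list of
#'   [run_day()] results), `indicators` (matrix, one row per day),
#'   and `config`.
#' @export
run_replications <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  days <- lapply(seq_len(config$n_reps), function(r) run_day(config, r))
  ind <- do.call(rbind, lapply(days, `[[`, "indicators"))
  rownames(ind) <- NULL
  structure(list(days = days, indicators = ind, config = config),
            class = "ctq_reps")
}

#' @export
print.ctq_reps <- function(x, ...) {
  cat("ctq_reps:", nrow(x$indicators), "replicated days,",
      x$config$policy$kind, "policy\n")
  print(summarize_replications(x))
  invisible(x)
}

#' Across-replication summary with Student-t confidence intervals
#'
#' Summarizes per-day indicators across replicated days: mean, standard
#' deviation and the 95% Student-t confidence interval of the mean
#' (`mean ± t[0.975, n-1] * sd / sqrt(n)`), per indicator.  Days on which an
#' indicator is undefined (e.g. no UP arrived) are excluded from that
#' indicator's summary.
#'
#' @param days A `ctq_reps` object, a list of `ctq_day` objects, or a
#'   numeric matrix/data.frame of per-day indicator values (one row per
#'   day).
#' @param conf Confidence level (default 0.95).
#' @return A data.frame with one row per indicator: `indicator`, `n`,
#'   `mean`, `sd`, `ci_lo`, `ci_hi`.
#' @export
summarize_replications <- function(days, conf = 0.95) {
  ind <- if (inherits(days, "ctq_reps")) days$indicators
         else if (is.list(days) && length(days) &&
                  inherits(days[[1L]], "ctq_day"))
           do.call(rbind, lapply(days, `[[`, "indicators"))
         else as.matrix(days)
  if (is.null(dim(ind)) || nrow(ind) < 2L)
    stop("summarize_replications needs at least 2 replicated days")
  one <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2L) return(c(n = n, mean = if (n) mean(x) else NA_real_,
                         sd = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_))
    m <- mean(x)
    s <- stats::sd(x)
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1L) * s / sqrt(n)
    c(n = n, mean = m, sd = s, ci_lo = m - half, ci_hi = m + half)
  }
  res <- t(apply(ind, 2L, one))
  out <- data.frame(indicator = colnames(ind), res,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ctq_summary", "data.frame")
  out
}

#' @export
print.ctq_summary <- function(x, digits = 3, ...) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print.data.frame(y, ...)
  invisible(x)
}

# Internal: check the common-random-number contract of a set of runs.
check_common_streams <- function(runs) {
  seeds <- vapply(runs, function(r) r$config$master_seed, numeric(1))
  reps <- vapply(runs, function(r) r$config$n_reps, numeric(1))
  if (length(unique(seeds)) != 1L || length(unique(reps)) != 1L)
    stop("common-random-number contract broken: ",
         "policies were run with different master seeds or rep counts")
  invisible(TRUE)
}

#' Compare queue disciplines on common random numbers
#'
#' Runs each policy of `policies` under the same `config` (same master
#' seed, same replication count), so all policies replay identical arrival
#' and duration streams and differences reflect only the discipline.
#'
#' @param config A [sim_config()]; its `policy` element is ignored.
#' @param policies A named list of [policy_config()]s.
#' @return An object of class `ctq_comparison`: list with `runs` (named
#'   list of `ctq_reps`), `summaries` (named list of summary data.frames),
#'   `master_seed` and `n_reps`.
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(n_reps = 5, master_seed = 42)
#' cmp <- compare_policies(cfg, list(base = policy_config("base"),
#'                                   dynamic = policy_config("dynamic")))
#' comparison_table(cmp)
#' }
compare_policies <- function(config, policies) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(policies)) || any(names(policies) == ""))
    stop("policies must be a named list of policy_config objects")
  runs <- lapply(policies, function(p) {
    cfg <- config
    cfg$policy <- p
    run_replications(cfg)
  })
  check_common_streams(runs)
  structure(list(runs = runs,
                 summaries = lapply(runs, summarize_replications),
                 master_seed = config$master_seed,
                 n_reps = config$n_reps),
            class = "ctq_comparison")
}

#' Tabulate a policy comparison
#'
#' @param cmp A `ctq_comparison` from [compare_policies()].
#' @param stat Which statistic to tabulate (`"mean"`, `"sd"`, `"ci_lo"`,
#'   `"ci_hi"`).
#' @return A data.frame, one row per indicator and one column per policy.
#' @export
comparison_table <- function(cmp, stat = "mean") {
  stopifnot(inherits(cmp, "ctq_comparison"))
  stat <- match.arg(stat, c("mean", "sd", "ci_lo", "ci_hi"))
  cols <- lapply(cmp$summaries, function(s) s[[stat]])
  out <- data.frame(indicator = cmp$summaries[[1L]]$indicator, cols,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("indicator", names(cmp$summaries))
  out
}

#' Long-format comparison report
#'
#' One row per indicator and policy, with mean, sd and the 95% confidence
#' interval — the shape written by [cmd_sweep()] as CSV and JSON.
#'
#' @param cmp A `ctq_comparison`.
#' @return A data.frame with columns `indicator`, `policy`, `n`, `mean`,
#'   `sd`, `ci_lo`, `ci_hi`.
#' @export
comparison_report <- function(cmp) {
  stopifnot(inherits(cmp, "ctq_comparison"))
  do.call(rbind, lapply(names(cmp$summaries), function(nm) {
    s <- cmp$summaries[[nm]]
    data.frame(indicator = s$indicator, policy = nm, s[-1L],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' @export
print.ctq_comparison <- function(x, ...) {
  cat("ctq_comparison of", length(x$runs), "policies over", x$n_reps,
      "common-random-number days (seed", x$master_seed, ")\n")
  print(comparison_table(x), digits = 4)
  invisible(x)
}
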