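#' Queue-discipline configuration
#'
#' Configures one of the three queueing disciplines of the simulator.
#'
#' * `"base"` — severity-ordered class priority: an arriving patient joins
#'   the waiting list immediately after the last patient of the same or
#'   higher severity (EP > UP > GP), i.e. the emergency stream wedges ahead
#'   of all GPs, FIFO within class.  `up_as` controls how urgent patients
#'   are ranked when the base discipline is run on the three-class stream:
#'   `"EP"` (default) merges them with emergency patients into one
#'   emergency class (the historical discipline), `"UP"` keeps the split
#'   severity ranks, and `"GP"` demotes them to general rank.
#' * `"fixed"` — as base for GPs and EPs, but an arriving UP wedges after at
#'   most `P` general patients: it is placed `P` GPs past the last waiting
#'   UP (else the last EP, else the queue head) when more than `P` GPs wait
#'   there, and at the tail otherwise.
#' * `"dynamic"` — arrivals join the tail; at each service completion the
#'   patient with the smallest priority value `f` is served, where `f = 1`
#'   for EPs and `f = threshold / wait` clamped below at 1 for UPs (20-min
#'   threshold) and GPs (40-min threshold).  Ties at equal `f` — in practice
#'   the patients at or beyond their thresholds, who all sit at `f = 1` —
#'   are broken by `tie_break`:
#'   * `"class"` (default): severer class first (EP < UP < GP), then
#'     earlier arrival.  An urgent patient reaching its threshold
#'     therefore jumps all over-threshold general patients, which keeps
#'     urgent waits pinned near their 20-minute threshold and emergency
#'     waits at the head-of-queue minimum even under heavy congestion.
#'   * `"deadline"`: emergency patients first, then by the time at which
#'     the patient reached (or will reach) priority 1, i.e.
#'     `arrival + threshold` — the order produced by a rank queue that
#'     re-inserts a patient at the tail of rank 1 upon promotion.
#'   * `"ep_fifo"`: emergency patients first, then earlier arrival.
#'   * `"fifo"`: earlier arrival regardless of class.
#'
#' @param kind Discipline: `"base"`, `"fixed"` or `"dynamic"`.
#' @param P Wedging interval for the fixed discipline: the number of general
#'   patients an urgent patient may stand behind, an integer in 0..10.
#' @param t_up_threshold,t_gp_threshold Waiting-time thresholds (minutes)
#'   for urgent and general patients; they drive both the dynamic priority
#'   values and the reported satisfaction rates.
#' @param up_as Severity rank given to urgent patients under the base
#'   discipline (see above).
#' @param tie_break Tie-break among equal dynamic priority values.
#'
#' @return An object of class `policy_config`.
#' @export
#' @examples
#' policy_config("fixed", P = 1)
#' policy_config("dynamic")
policy_config <- function(kind = c("base", "fixed", "dynamic"), P = 1L,
                          t_up_threshold = 20, t_gp_threshold = 40,
                          up_as = c("EP", "UP", "GP"),
                          tie_break = c("class", "deadline", "ep_fifo",
                                        "fifo")) {
  kind <- match.arg(kind)
  up_as <- match.arg(up_as)
  tie_break <- match.arg(tie_break)
  if (length(P) != 1L || is.na(P) || P != round(P) || P < 0 || P > 10)
    stop("policy.P must be an integer between 0 and 10")
  if (t_up_threshold <= 0 || t_gp_threshold <= 0)
    stop("policy.t_up_threshold and policy.t_gp_threshold must be positive")
  structure(list(kind = kind, P = as.integer(P),
                 t_up_threshold = as.numeric(t_up_threshold),
                 t_gp_threshold = as.numeric(t_gp_threshold),
                 up_as = up_as, tie_break = tie_break),
            class = "policy_config")
}

#' @export
print.policy_config <- function(x, ...) {
  cat("policy_config:", x$kind,
      if (x$kind == "fixed") paste0("(P = ", x$P, ")") else "",
      "thresholds UP", x$t_up_threshold, "/ GP", x$t_gp_threshold, "min\n")
  invisible(x)
}

.cls_rank <- c(EP = 1L, UP = 2L, GP = 3L)

#' Insertion position under the base (severity-ordered) discipline
#'
#' Returns the 1-based position at which a new patient joins the ordered
#' waiting list: immediately after the last waiting patient of the same or
#' higher severity (EP > UP > GP).  A GP therefore always joins the tail;
#' an emergency-class patient wedges before all GPs, FIFO within class.
#' Relative order of patients already waiting is never changed.
#'
#' @param queue_cls Character vector of the classes (`"EP"`, `"UP"`, `"GP"`)
#'   of the patients currently waiting, in queue order (position 1 is next
#'   to serve).
#' @param cls Class of the arriving patient.
#' @return Integer insertion position in `1:(length(queue_cls) + 1)`.
#' @export
#' @examples
#' insert_base(c("GP", "GP"), "EP")   # 1: wedges before all GPs
#' insert_base(c("EP", "GP"), "EP")   # 2: FIFO within the emergency class
insert_base <- function(queue_cls, cls) {
  r <- .cls_rank[[cls]]
  max(c(0L, which(.cls_rank[queue_cls] <= r))) + 1L
}

#' Insertion position under the fixed-interval wedging discipline
#'
#' GPs join the tail and EPs join immediately after the last waiting EP
#' (ahead of all UPs and GPs).  An arriving UP looks for the last waiting
#' UP, else the last waiting EP, else the queue head; if more than `P` GPs
#' wait beyond that marker the UP wedges exactly `P` GPs past it, otherwise
#' it joins the tail.  The patient in service is not part of the waiting
#' list and never counts.
#'
#' @inheritParams insert_base
#' @param P Wedging interval, an integer in 0..10.
#' @return Integer insertion position.
#' @export
#' @examples
#' insert_fixed(c("GP", "GP", "GP"), "UP", P = 1)            # 2
#' insert_fixed(c("UP", "GP", "GP", "GP"), "UP", P = 2)      # 4
insert_fixed <- function(queue_cls, cls, P) {
  if (P != round(P) || P < 0 || P > 10)
    stop("policy.P must be an integer between 0 and 10")
  n <- length(queue_cls)
  if (cls == "GP") return(n + 1L)
  if (cls == "EP") return(max(c(0L, which(queue_cls == "EP"))) + 1L)
  ups <- which(queue_cls == "UP")
  marker <- if (length(ups)) max(ups)
            else max(c(0L, which(queue_cls == "EP")))
  g <- n - marker                      # trailing GPs beyond the marker
  if (g > P) marker + as.integer(P) + 1L else n + 1L
}

#' Dynamic (aging) priority value
#'
#' The priority value of a waiting patient under the dynamic discipline:
#' `f = 1` for emergency patients regardless of wait; for urgent and general
#' patients `f = threshold / wait`, which decreases towards 1 as the wait
#' approaches the class threshold and equals 1 at and beyond it.  Smaller
#' `f` is served earlier, so a patient's priority improves as it waits.  A
#' zero wait for a non-emergency patient maps to `Inf` (a just-arrived
#' UP/GP outranks no one), the limit of `threshold / wait`.
#'
#' @param cls Character vector of classes (`"EP"`, `"UP"`, `"GP"`).
#' @param wait Nonnegative waiting times in minutes (recycled with `cls`).
#' @param config A [policy_config()] supplying the thresholds.
#' @return Numeric vector of priority values, `>= 1` (possibly `Inf`).
#' @export
#' @examples
#' p <- policy_config("dynamic")
#' dynamic_priority_value(c("UP", "UP", "GP", "EP"), c(20, 10, 10, 0), p)
dynamic_priority_value <- function(cls, wait, config) {
  if (any(wait < 0)) stop("waiting times must be nonnegative")
  thr <- ifelse(cls == "UP", config$t_up_threshold, config$t_gp_threshold)
  ifelse(cls == "EP", 1, ifelse(wait >= thr, 1, thr / wait))
}

# Engine-internal selection: index into parallel vectors (cls, arrival, id)
# of the waiting list, minimizing f at time `now`.
select_dynamic_idx <- function(cls, arrival, id, now, config) {
  f <- dynamic_priority_value(cls, now - arrival, config)
  r <- .cls_rank[cls]
  ord <- switch(config$tie_break,
                class = order(f, r, arrival, id),
                deadline = {
                  dl <- arrival + ifelse(cls == "EP", 0,
                                         ifelse(cls == "UP",
                                                config$t_up_threshold,
                                                config$t_gp_threshold))
                  order(f, r != 1L, dl, r, id)
                },
                ep_fifo = order(f, r != 1L, arrival, r, id),
                fifo = order(f, arrival, r, id))
  ord[1L]
}

#' Select the next patient under the dynamic discipline
#'
#' Returns the index (position in the waiting list) of the patient with the
#' smallest [dynamic_priority_value()] evaluated at time `now`.  Ties are
#' broken according to `config$tie_break`: severer class first
#' (EP < UP < GP) then earlier arrival (`"class"`, the default), or earlier
#' arrival first (`"fifo"`); remaining ties fall back to the patient id.
#'
#' @param waiting A data.frame of the waiting patients, in queue order, with
#'   columns `id`, `cls` and `arrival`.
#' @param now Current clock time (minutes since opening).
#' @param config A [policy_config()].
#' @return Integer index into `waiting`.
#' @export
select_dynamic <- function(waiting, now, config) {
  if (nrow(waiting) == 0L) stop("select_dynamic: the waiting list is empty")
  select_dynamic_idx(waiting$cls, waiting$arrival, waiting$id, now, config)
}

#' Pick the patient to serve next
#'
#' The dispatch point of the event kernel: under the base and fixed
#' disciplines the head of the (insertion-ordered) waiting list is served;
#' under the dynamic discipline the patient minimizing the aging priority
#' value at time `now` is served.
#'
#' @inheritParams select_dynamic
#' @param policy A [policy_config()].
#' @return Integer index into `waiting` of the patient to serve.
#' @export
dispatch <- function(waiting, policy, now) {
  if (nrow(waiting) == 0L) stop("dispatch: the waiting list is empty")
  if (policy$kind == "dynamic") select_dynamic(waiting, now, policy) else 1L
}
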