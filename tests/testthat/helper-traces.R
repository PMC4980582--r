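# Pencil-traced oracle fixtures: tiny hand-listed arrival sets whose event
# sequences were worked out by hand and frozen as expected service starts.
# Each trace is (patients, policy, expected service_start).

trace_patients <- function(cls, arrival, duration) {
  data.frame(cls = cls, arrival = arrival, duration = duration,
             stringsAsFactors = FALSE)
}

oracle_traces <- list(
  idle_server_gp = list(
    patients = trace_patients("GP", 0, 2),
    policy = policy_config("base"),
    starts = 0
  ),
  base_fifo_two_gps = list(
    patients = trace_patients(c("GP", "GP"), c(0, 1), c(2, 2)),
    policy = policy_config("base"),
    starts = c(0, 2)
  ),
  base_nonpreemptive_ep = list(
    # EP arrives during a GP exam: no preemption, EP waits 3
    patients = trace_patients(c("GP", "EP"), c(0, 1), c(4, 2)),
    policy = policy_config("base"),
    starts = c(0, 4)
  ),
  base_ep_wedges_before_gp = list(
    patients = trace_patients(c("GP", "GP", "EP"), c(0, 1, 2), c(5, 3, 2)),
    policy = policy_config("base"),
    starts = c(0, 7, 5)
  ),
  base_merged_emergency_fifo = list(
    # up_as = "EP": UPs and EPs form one FIFO emergency class
    patients = trace_patients(c("GP", "UP", "EP", "UP"), c(0, 1, 2, 3),
                              c(5, 2, 3, 2)),
    policy = policy_config("base", up_as = "EP"),
    starts = c(0, 5, 7, 10)
  ),
  base_severity_ordered = list(
    # up_as = "UP": an arriving EP wedges ahead of the waiting UP
    patients = trace_patients(c("GP", "UP", "EP", "UP"), c(0, 1, 2, 3),
                              c(5, 2, 3, 2)),
    policy = policy_config("base", up_as = "UP"),
    starts = c(0, 8, 5, 10)
  ),
  fixed_up_wedges_past_P_gps = list(
    # queue [G1,G2,G3], P = 1: UP takes position 2, one GP ahead
    patients = trace_patients(c("GP", "GP", "GP", "GP", "UP"), 0:4,
                              c(20, 2, 2, 2, 3)),
    policy = policy_config("fixed", P = 1),
    starts = c(0, 20, 25, 27, 22)
  ),
  fixed_up_appends_when_few_gps = list(
    # queue [G1], P = 2: one GP is not more than P, UP joins the tail
    patients = trace_patients(c("GP", "GP", "UP"), c(0, 1, 2), c(10, 2, 3)),
    policy = policy_config("fixed", P = 2),
    starts = c(0, 10, 12)
  ),
  fixed_up_after_last_ep = list(
    # queue of EPs only: UP waits directly after the last EP; a later EP
    # still wedges ahead of the waiting UP
    patients = trace_patients(c("EP", "EP", "UP", "GP", "EP"), 0:4,
                              c(5, 3, 2, 2, 1)),
    policy = policy_config("fixed", P = 1),
    starts = c(0, 5, 9, 11, 8)
  ),
  fixed_up_after_previous_up = list(
    # last waiting patient is a UP: the new UP queues right behind it
    patients = trace_patients(c("GP", "UP", "UP"), c(0, 1, 2), c(10, 2, 3)),
    policy = policy_config("fixed", P = 5),
    starts = c(0, 10, 12)
  ),
  fixed_up_counts_gps_past_last_up = list(
    # queue [U1,G1,G2,G3], P = 2: new UP goes two GPs past U1 (position 4)
    patients = trace_patients(c("GP", "UP", "GP", "GP", "GP", "UP"), 0:5,
                              c(15, 2, 2, 2, 2, 3)),
    policy = policy_config("fixed", P = 2),
    starts = c(0, 15, 17, 19, 24, 21)
  ),
  fixed_up_counts_gps_behind_ep = list(
    # queue [E1,G1,G2], P = 1: GPs behind the last EP exceed P, UP wedges
    # one GP past the EP (position 3)
    patients = trace_patients(c("GP", "EP", "GP", "GP", "UP"), 0:4,
                              c(12, 3, 2, 2, 2)),
    policy = policy_config("fixed", P = 1),
    starts = c(0, 12, 15, 19, 17)
  ),
  dynamic_up_outranks_young_gp = list(
    # at t=10: f_UP = 20/9 < f_GP = 40/8, UP first
    patients = trace_patients(c("GP", "UP", "GP"), c(0, 1, 2), c(10, 2, 2)),
    policy = policy_config("dynamic"),
    starts = c(0, 10, 12)
  ),
  dynamic_gp_outranks_young_up = list(
    # at t=30: f_GP = 40/25 = 1.6 < f_UP = 20/8 = 2.5, GP first
    patients = trace_patients(c("GP", "GP", "UP"), c(0, 5, 22), c(30, 2, 2)),
    policy = policy_config("dynamic"),
    starts = c(0, 30, 32)
  ),
  dynamic_class_tiebreak_up_first = list(
    # both over threshold (f = 1): class tie-break serves the UP first
    patients = trace_patients(c("GP", "GP", "UP"), c(0, 1, 5), c(50, 3, 2)),
    policy = policy_config("dynamic", tie_break = "class"),
    starts = c(0, 52, 50)
  ),
  dynamic_fifo_tiebreak_earlier_first = list(
    # same arrivals, FIFO tie-break: the earlier-arrived GP wins at f = 1
    patients = trace_patients(c("GP", "GP", "UP"), c(0, 1, 5), c(50, 3, 2)),
    policy = policy_config("dynamic", tie_break = "fifo"),
    starts = c(0, 50, 53)
  ),
  dynamic_fifo_gp_beats_late_ep = list(
    # f = 1 tie between an over-threshold GP and a fresh EP: FIFO serves
    # the GP; the class rule would serve the EP
    patients = trace_patients(c("GP", "GP", "EP"), c(0, 1, 44), c(46, 2, 2)),
    policy = policy_config("dynamic", tie_break = "fifo"),
    starts = c(0, 46, 48)
  ),
  dynamic_deadline_orders_by_crossing = list(
    # f = 1 tie: GP crossed its threshold at 41, UP at 42; the deadline
    # rule serves the GP, the class rule would serve the UP
    patients = trace_patients(c("GP", "GP", "UP"), c(0, 1, 22), c(60, 3, 2)),
    policy = policy_config("dynamic", tie_break = "deadline"),
    starts = c(0, 60, 63)
  )
)

expect_trace <- function(trace) {
  out <- simulate_day(trace$patients, trace$policy)
  expect_equal(out$service_start, trace$starts)
  expect_equal(out$service_end, trace$starts + trace$patients$duration)
  expect_true(all(out$wait >= 0))
}

# Deterministic small config for fast property tests.
small_config <- function(policy = policy_config("base"), n_reps = 3L,
                         master_seed = 99L) {
  sim_config(profile = default_profile(), policy = policy, n_reps = n_reps,
             master_seed = master_seed)
}
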