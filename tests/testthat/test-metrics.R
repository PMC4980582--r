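test_that("satisfaction rate counts the inclusive boundary", {
  expect_equal(satisfaction_rate(c(10, 50), 40), 0.5)
  expect_equal(satisfaction_rate(40, 40), 1)
  expect_true(is.na(satisfaction_rate(numeric(0), 40)))
  expect_error(satisfaction_rate(c(3, -1), 40), "negative")
  expect_error(satisfaction_rate(10, 0), "positive")
})

test_that("per-day indicators are internally consistent", {
  cfg <- small_config(policy = policy_config("dynamic"))
  day <- run_day(cfg, 1)
  ind <- day$indicators
  rec <- day$records
  expect_equal(unname(ind["quantity"]), nrow(rec))
  # overall wait is the count-weighted mean of the per-class means
  counts <- c(GP = sum(rec$cls == "GP"), UP = sum(rec$cls == "UP"),
              EP = sum(rec$cls == "EP"))
  weighted <- sum(ind[c("wait_gp", "wait_up", "wait_ep")] * counts) /
    sum(counts)
  expect_equal(unname(ind["wait_all"]), weighted)
  expect_true(ind["sat_gp"] >= 0 && ind["sat_gp"] <= 1)
  expect_equal(unname(ind["sat_up"] + ind["frac_up_over"]), 1)
  # absent classes yield NA indicators
  gp_only <- simulate_day(trace_patients("GP", 0, 2), cfg$policy)
  expect_true(is.na(day_indicators(gp_only, cfg$policy)["wait_up"]))
})

test_that("replication summary matches the closed-form t interval", {
  two <- matrix(c(1, 3), ncol = 1, dimnames = list(NULL, "x"))
  s <- summarize_replications(two)
  expect_equal(s$mean, 2)
  expect_equal(s$ci_lo, 2 - 12.7062, tolerance = 1e-4)
  expect_equal(s$ci_hi, 2 + 12.7062, tolerance = 1e-4)
  # identical days: zero-width interval at the common value
  same <- matrix(5, nrow = 4, ncol = 1, dimnames = list(NULL, "x"))
  s2 <- summarize_replications(same)
  expect_equal(s2$sd, 0)
  expect_equal(s2$ci_lo, 5)
  expect_equal(s2$ci_hi, 5)
  expect_error(summarize_replications(two[1, , drop = FALSE]), "at least 2")
  # the interval always brackets the mean
  set.seed(8)
  m <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  s3 <- summarize_replications(m)
  expect_true(all(s3$ci_lo <= s3$mean & s3$mean <= s3$ci_hi))
})

test_that("the 95% t interval covers the truth about 95% of the time", {
  set.seed(9)
  covered <- replicate(600, {
    s <- summarize_replications(matrix(rnorm(100), ncol = 1,
                                       dimnames = list(NULL, "x")))
    s$ci_lo <= 0 && 0 <= s$ci_hi
  })
  expect_gt(mean(covered), 0.91)
  expect_lt(mean(covered), 0.99)
})

test_that("comparisons share streams and degenerate to a plain summary", {
  cfg <- small_config(n_reps = 4L)
  cmp <- compare_policies(cfg, list(base = policy_config("base")))
  expect_equal(cmp$summaries$base,
               summarize_replications(run_replications(cfg)))
  expect_error(compare_policies(cfg, list(policy_config("base"))), "named")
  # the CRN contract is enforced when combining runs
  r1 <- run_replications(cfg)
  cfg2 <- small_config(n_reps = 4L, master_seed = 123L)
  r2 <- run_replications(cfg2)
  expect_error(ctqsim:::check_common_streams(list(r1, r2)),
               "common-random-number")
  tab <- comparison_table(cmp)
  expect_equal(names(tab), c("indicator", "base"))
  rep_long <- comparison_report(cmp)
  expect_true(all(c("indicator", "policy", "mean", "ci_lo") %in%
                    names(rep_long)))
})

test_that("dynamic urgent waits never exceed base-with-UP-as-GP waits", {
  cfg <- small_config(n_reps = 15L, master_seed = 17L)
  cmp <- compare_policies(cfg, list(
    demoted = policy_config("base", up_as = "GP"),
    dynamic = policy_config("dynamic")))
  up_demoted <- cmp$runs$demoted$indicators[, "wait_up"]
  up_dynamic <- cmp$runs$dynamic$indicators[, "wait_up"]
  expect_true(all(up_dynamic <= up_demoted + 1e-9))
})
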