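test_that("policy_config validates P and thresholds", {
  expect_error(policy_config("fixed", P = 11), "policy.P")
  expect_error(policy_config("fixed", P = -1), "policy.P")
  expect_error(policy_config("base", t_up_threshold = 0), "positive")
  expect_silent(policy_config("fixed", P = 0))
  expect_silent(policy_config("fixed", P = 10))
})

test_that("base insertion is severity-ordered FIFO", {
  expect_equal(insert_base(c("GP", "GP"), "EP"), 1L)
  expect_equal(insert_base(character(0), "GP"), 1L)
  expect_equal(insert_base(c("EP", "GP"), "EP"), 2L)
  expect_equal(insert_base(c("EP", "UP", "GP"), "UP"), 3L)
  expect_equal(insert_base(c("EP", "UP", "GP"), "GP"), 4L)
  expect_equal(insert_base(c("EP", "UP", "GP"), "EP"), 2L)
})

test_that("fixed insertion follows the wedging case analysis", {
  # more than P trailing GPs: wedge P GPs past the marker
  expect_equal(insert_fixed(c("GP", "GP", "GP"), "UP", P = 1), 2L)
  # P or fewer: join the tail
  expect_equal(insert_fixed(c("GP"), "UP", P = 2), 2L)
  # queue of EPs only: directly after the last EP
  expect_equal(insert_fixed(c("EP"), "UP", P = 1), 2L)
  # marker is the last UP when one waits
  expect_equal(insert_fixed(c("UP", "GP", "GP", "GP"), "UP", P = 2), 4L)
  # GPs behind the last EP
  expect_equal(insert_fixed(c("EP", "GP", "GP"), "UP", P = 1), 3L)
  # boundary: exactly P GPs is not "more than P"
  expect_equal(insert_fixed(c("GP", "GP"), "UP", P = 2), 3L)
  # EPs keep absolute precedence over waiting UPs and GPs
  expect_equal(insert_fixed(c("EP", "UP", "GP"), "EP", P = 3), 2L)
  expect_equal(insert_fixed(c("UP", "GP"), "EP", P = 3), 1L)
  expect_error(insert_fixed("GP", "UP", P = 11), "policy.P")
})

test_that("fixed insertion with P = 0 equals severity-ordered base insertion", {
  # exhaustive over all reachable queues (every EP ahead of every UP) of
  # length <= 6; also checks the UP never jumps an EP or an earlier UP
  classes <- c("EP", "UP", "GP")
  for (len in 0:6) {
    grid <- if (len == 0) list(character(0))
            else asplit(as.matrix(expand.grid(rep(list(classes), len),
                                              stringsAsFactors = FALSE)), 1)
    for (q in grid) {
      q <- unname(as.character(q))
      if (any(q == "UP") && any(q == "EP") &&
          min(which(q == "UP")) < max(which(q == "EP")))
        next  # unreachable: a UP ahead of an EP
      pos_fixed <- insert_fixed(q, "UP", P = 0)
      expect_identical(pos_fixed, insert_base(q, "UP"))
      expect_true(pos_fixed > max(c(0L, which(q %in% c("EP", "UP")))))
    }
  }
})

test_that("dynamic priority values follow the aging formula", {
  p <- policy_config("dynamic")
  expect_equal(dynamic_priority_value("UP", 20, p), 1)
  expect_equal(dynamic_priority_value("UP", 10, p), 2)
  expect_equal(dynamic_priority_value("GP", 40, p), 1)
  expect_equal(dynamic_priority_value("GP", 10, p), 4)
  expect_equal(dynamic_priority_value("EP", 0, p), 1)
  expect_equal(dynamic_priority_value("EP", 500, p), 1)
  # a just-arrived non-emergency patient outranks no one
  expect_identical(dynamic_priority_value("UP", 0, p), Inf)
  expect_error(dynamic_priority_value("GP", -1, p), "nonnegative")
})

test_that("dynamic priority is non-increasing, continuous and clamped", {
  p <- policy_config("dynamic")
  for (cl in c("UP", "GP")) {
    thr <- if (cl == "UP") 20 else 40
    w <- seq(0.25, thr + 20, by = 0.25)
    f <- dynamic_priority_value(rep(cl, length(w)), w, p)
    expect_true(all(diff(f) <= 0))
    expect_true(all(f[w >= thr] == 1))
    expect_true(all(f >= 1))
    # continuity at the threshold: f -> 1 from above
    eps <- dynamic_priority_value(cl, thr - 1e-9, p)
    expect_equal(eps, 1, tolerance = 1e-8)
  }
})

test_that("dynamic selection minimizes f with documented tie-breaks", {
  p <- policy_config("dynamic")
  waiting <- data.frame(id = 1:2, cls = c("GP", "UP"),
                        arrival = c(0, 20), stringsAsFactors = FALSE)
  # at t = 30: f_GP = 40/30 < f_UP = 20/10 -> the GP outranks the UP
  expect_equal(select_dynamic(waiting, now = 30, p), 1L)
  # single waiting patient is always chosen
  expect_equal(select_dynamic(waiting[2, ], now = 21, p), 1L)
  expect_error(select_dynamic(waiting[0, ], now = 0, p), "empty")

  # f = 1 ties: class rule prefers the severer class, FIFO the earlier
  over <- data.frame(id = 1:2, cls = c("GP", "EP"), arrival = c(0, 44),
                     stringsAsFactors = FALSE)
  expect_equal(select_dynamic(over, now = 46, policy_config("dynamic")), 2L)
  expect_equal(select_dynamic(over, now = 46,
                              policy_config("dynamic", tie_break = "fifo")),
               1L)
})

test_that("vanishing thresholds degenerate to global FIFO under fifo ties", {
  p <- policy_config("dynamic", t_up_threshold = 1e-9, t_gp_threshold = 1e-9,
                     tie_break = "fifo")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    waiting <- data.frame(id = 1:n,
                          cls = sample(c("GP", "UP", "EP"), n, replace = TRUE),
                          arrival = round(sort(runif(n, 0, 100)), 3))
    expect_equal(select_dynamic(waiting, now = 101, p), 1L)
  }
})

test_that("dispatch serves the head for base/fixed and the f-minimizer for dynamic", {
  waiting <- data.frame(id = 1:3, cls = c("GP", "GP", "UP"),
                        arrival = c(0, 1, 30), stringsAsFactors = FALSE)
  expect_equal(dispatch(waiting, policy_config("base"), now = 35), 1L)
  expect_equal(dispatch(waiting, policy_config("fixed", P = 1), now = 35), 1L)
  # t = 35: f_GP(35) = 40/35 > 1? no: 1.14; f_UP(5) = 4 -> GP1 wins
  expect_equal(dispatch(waiting, policy_config("dynamic"), now = 35), 1L)
  expect_error(dispatch(waiting[0, ], policy_config("base"), now = 0), "empty")
})
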