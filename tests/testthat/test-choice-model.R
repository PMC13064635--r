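test_that("utility components match the hand-arithmetic oracle", {
  tr <- data.frame(c_one = 100, c_group = 40, n_group = 3)
  uc <- utility_components(tr, list(alpha = 0.95, phi = -10, tau = 0.1))
  expect_equal(uc$delta_total, 20)
  expect_equal(uc$delta_single, 60)
  expect_equal(uc$delta_u, 0.05 * 20 - 0.95 * 50)   # -46.5
  # softmax at tau = 0.1: 1 / (1 + exp(4.65))
  expect_equal(choice_prob(tr, list(alpha = 0.95, phi = -10, tau = 0.1)),
               1 / (1 + exp(4.65)), tolerance = 1e-12)
})

test_that("utility and softmax agree with an independent oracle on random trials", {
  # second, independent code path written from the displayed algebra
  oracle <- function(co, cg, n, a, p, t) {
    u1 <- -(1 - a) * co - a * (co + p)
    ug <- -(1 - a) * cg * n - a * cg
    list(du = u1 - ug, prob = 1 / (1 + exp(-t * (u1 - ug))))
  }
  for (s in 1:25) {
    tr <- random_trials(1, seed = 100 + s)
    pr <- random_params(seed = 200 + s)
    o <- oracle(tr$c_one, tr$c_group, tr$n_group, pr$alpha, pr$phi, pr$tau)
    uc <- utility_components(tr, pr)
    expect_equal(uc$delta_u, o$du, tolerance = 1e-12)
    expect_equal(uc$u_one - uc$u_group, uc$delta_u, tolerance = 1e-12)
    expect_equal(choice_prob(tr, pr), o$prob, tolerance = 1e-12)
  }
})

test_that("boundary cases of the mixing weight", {
  # alpha = 0: pure utilitarian, phi drops; at c_one = c_group * n, delta_u = 0
  tr <- data.frame(c_one = 120, c_group = 40, n_group = 3)
  uc <- utility_components(tr, list(alpha = 0, phi = 123, tau = 1))
  expect_equal(uc$delta_u, 0)
  # alpha = 1, phi = 0: delta_u = -delta_single <= 0 on any valid trial
  trs <- random_trials(20, seed = 9)
  uc1 <- utility_components(trs, list(alpha = 1, phi = 0, tau = 1))
  expect_equal(uc1$delta_u, -uc1$delta_single)
  expect_true(all(uc1$delta_u <= 0))
  # valid trials always have nonnegative component differences
  expect_true(all(uc1$delta_total >= 0 & uc1$delta_single >= 0))
})

test_that("choice probability is monotone and saturates safely", {
  base <- data.frame(c_one = seq(40, 120, by = 10), c_group = 40, n_group = 3)
  pr <- list(alpha = 0.6, phi = -5, tau = 0.2)
  p <- choice_prob(base, pr)
  expect_true(all(diff(p) < 0))              # decreasing in c_one
  # dDeltaU/dC_one = -1 exactly, for any alpha (finite differences)
  for (a in c(0, 0.3, 0.95, 1)) {
    u1 <- utility_components(data.frame(c_one = 100, c_group = 40, n_group = 3),
                             list(alpha = a, phi = -5, tau = 1))$delta_u
    u2 <- utility_components(data.frame(c_one = 101, c_group = 40, n_group = 3),
                             list(alpha = a, phi = -5, tau = 1))$delta_u
    expect_equal(u2 - u1, -1, tolerance = 1e-9)
  }
  # increasing c_group raises delta_u via (1-a) n + a > 0
  cg <- utility_components(data.frame(c_one = 120, c_group = c(40, 50), n_group = 3),
                           list(alpha = 0.5, phi = 0, tau = 1))$delta_u
  expect_true(diff(cg) > 0)
  # saturation: huge tau with negative delta_u -> probability 0 within machine limits
  expect_equal(choice_prob(data.frame(c_one = 180, c_group = 30, n_group = 4),
                           list(alpha = 1, phi = 0, tau = 1e6)), 0)
  expect_equal(choice_prob(data.frame(c_one = 60, c_group = 60, n_group = 3),
                           list(alpha = 1, phi = -10, tau = 1e6)), 1)
})

test_that("alpha = 1 threshold property: one preferred iff delta_single < -phi", {
  phi <- -40
  trs <- enumerate_valid_pairs()
  p <- choice_prob(trs, list(alpha = 1, phi = phi, tau = 0.5))
  expect_equal(p > 0.5, trs$c_one - trs$c_group < -phi)
  expect_equal(choice_prob(data.frame(c_one = 70, c_group = 30, n_group = 3),
                           list(alpha = 1, phi = phi, tau = 2)), 0.5)
})

test_that("ratio and constant agreeability variants coincide where expected", {
  trs <- random_trials(15, seed = 77)
  pr_ratio <- list(alpha = 0.7, phi = 1, tau = 0.1)
  pr_const <- list(alpha = 0.7, phi = 0, tau = 0.1)
  expect_equal(
    utility_components(trs, pr_ratio, harm_model("ratio_phi"))$delta_u,
    utility_components(trs, pr_const, harm_model("full"))$delta_u,
    tolerance = 1e-12)
  # the ratio variant keeps the U(one) - U(group) identity too
  uc <- utility_components(trs, list(alpha = 0.4, phi = 1.7, tau = 1),
                           harm_model("ratio_phi"))
  expect_equal(uc$u_one - uc$u_group, uc$delta_u, tolerance = 1e-12)
})

test_that("default-bias variant shifts utility toward the default", {
  tr <- data.frame(c_one = 100, c_group = 40, n_group = 3,
                   default_cond = c("none", "one_default", "group_default"))
  pr <- list(alpha = 0.95, phi = -10, tau = 0.1, bias = 12)
  du <- utility_components(tr, pr, harm_model("default_bias"))$delta_u
  expect_equal(du[2] - du[1], 12)
  expect_equal(du[3] - du[1], -12)
  expect_error(utility_components(tr[, 1:3], pr, harm_model("default_bias")),
               "default_cond")
})

test_that("log-likelihood matches independent per-trial recomputation", {
  d <- simulate_choices(tiny_design(), list(alpha = 0.9, phi = -8, tau = 0.15),
                        seed = 5)
  pr <- list(alpha = 0.85, phi = -6, tau = 0.12)
  ll <- log_likelihood(d, pr)
  # brute-force recomputation, one trial at a time
  brute <- vapply(seq_len(nrow(d)), function(i) {
    p1 <- choice_prob(d[i, ], pr)
    if (d$choice[i] == "one") log(p1) else log(1 - p1)
  }, numeric(1))
  expect_equal(ll$pointwise, brute, tolerance = 1e-12)
  expect_equal(ll$total, sum(brute), tolerance = 1e-12)
  # delta_u = 0 trial contributes log 0.5
  tr0 <- data.frame(c_one = 60, c_group = 60, n_group = 3, choice = "one")
  expect_equal(log_likelihood(tr0, list(alpha = 1, phi = 0, tau = 1))$total,
               log(0.5))
  d$choice[3] <- NA
  expect_error(log_likelihood(d, pr), "observed choice")
})

test_that("simulated choices are reproducible and converge to the analytic mean", {
  des <- tiny_design()
  pr <- list(alpha = 0.95, phi = -10, tau = 0.1)
  s1 <- simulate_choices(des, pr, seed = 31)
  s2 <- simulate_choices(des, pr, seed = 31)
  expect_identical(s1, s2)
  # extreme determinism: all delta_u < 0 -> all group choices
  det <- simulate_choices(data.frame(c_one = 180, c_group = 30, n_group = 4),
                          list(alpha = 1, phi = 0, tau = 100), seed = 1)
  expect_equal(det$choice, "group")
  # long-run group-choice proportion approaches analytic mean of 1 - P(one)
  big <- des[rep(seq_len(nrow(des)), 20), ]
  sim <- simulate_choices(big, pr, seed = 8)
  expect_equal(mean(sim$choice == "group"),
               mean(1 - choice_prob(des, pr)), tolerance = 0.03)
  expect_gt(mean(sim$choice == "group"), 0.5)
})
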