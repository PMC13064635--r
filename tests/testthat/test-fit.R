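# Hierarchical MCMC tests use deliberately small cohorts and short chains;
# they exercise contracts and identifiability direction, not full convergence.

test_that("fit returns the contracted structure and is seed-deterministic", {
  coh <- tiny_cohort(n_subjects = 4, seed = 1)
  fit <- suppressWarnings(fit_harmalloc(coh, settings = test_profile(), seed = 3))
  st <- fit$settings
  expect_s3_class(fit, "harmalloc_fit")
  ndraw <- st$chains * st$iter
  expect_equal(nrow(fit$subject_draws$alpha), ndraw)
  expect_equal(dim(fit$log_lik), c(ndraw, nrow(coh$data)))
  expect_true(all(fit$subject_draws$alpha >= 0 & fit$subject_draws$alpha <= 1))
  expect_true(all(fit$subject_draws$tau > 0 &
                    fit$subject_draws$tau <= st$tau_max))
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))
  fit2 <- suppressWarnings(fit_harmalloc(coh, settings = test_profile(), seed = 3))
  expect_identical(fit$subject_draws, fit2$subject_draws)
  # pointwise log-likelihood recomputes from the draws
  i <- 17
  pars <- lapply(fit$subject_draws, function(m) m[i, ])
  manual <- sapply(seq_len(nrow(coh$data)), function(j) {
    s <- as.character(coh$data$subject[j])
    log_likelihood(coh$data[j, ],
                   list(alpha = pars$alpha[s], phi = pars$phi[s],
                        tau = pars$tau[s]))$total
  })
  expect_equal(unname(fit$log_lik[i, ]), manual, tolerance = 1e-10)
})

test_that("constrained variants drop the fixed parameter", {
  coh <- tiny_cohort(n_subjects = 4, seed = 2)
  f0 <- suppressWarnings(fit_harmalloc(coh, model = harm_model("alpha0"),
                                       settings = test_profile(), seed = 1))
  expect_null(f0$subject_draws$alpha)
  expect_null(f0$subject_draws$phi)     # phi is meaningless at alpha = 0
  expect_named(f0$subject_draws, "tau")
  f1 <- suppressWarnings(fit_harmalloc(coh, model = harm_model("alpha1"),
                                       settings = test_profile(), seed = 1))
  expect_setequal(names(f1$subject_draws), c("phi", "tau"))
})

test_that("coin-flip data concentrate tau near zero and widen alpha", {
  des <- tiny_design(n_pairs = 15, seed = 8)
  flip <- do.call(rbind, lapply(1:5, function(s) {
    d <- as.data.frame(des)
    d$choice <- with_seed_test(700 + s,
                               sample(c("one", "group"), nrow(d), replace = TRUE))
    cbind(subject = s, d)
  }))
  ffl <- suppressWarnings(fit_harmalloc(flip, settings = test_profile(), seed = 4))
  inf <- tiny_cohort(n_subjects = 5, seed = 9)
  fin <- suppressWarnings(fit_harmalloc(inf$data, settings = test_profile(), seed = 4))
  expect_lt(mean(ffl$subject_draws$tau), mean(fin$subject_draws$tau))
  # alpha posterior wider under uninformative choices
  expect_gt(mean(apply(ffl$subject_draws$alpha, 2, sd)),
            mean(apply(fin$subject_draws$alpha, 2, sd)))
})

test_that("summary reports both group-spread readings and bounded estimates", {
  coh <- tiny_cohort(n_subjects = 5, seed = 3)
  fit <- suppressWarnings(fit_harmalloc(coh, settings = test_profile(), seed = 6))
  sm <- summary(fit)
  g <- sm$group
  expect_setequal(g$parameter, c("alpha", "phi", "tau"))
  a <- g[g$parameter == "alpha", ]
  expect_true(a$group_mean >= 0 && a$group_mean <= 1)
  expect_true(all(c("group_sd", "between_sd") %in% names(g)))
  cf <- coef(fit)
  expect_equal(dim(cf), c(5, 3))
  expect_true(all(cf[, "alpha"] >= 0 & cf[, "alpha"] <= 1))
  # predict/residuals are probabilities and centred residuals
  p <- predict(fit)
  expect_true(all(p > 0 & p < 1))
  expect_equal(residuals(fit), as.integer(coh$data$choice == "one") - p)
  # simulate returns reproducible datasets with choices refreshed
  s1 <- simulate(fit, nsim = 2, seed = 10)
  s2 <- simulate(fit, nsim = 2, seed = 10)
  expect_identical(s1, s2)
  expect_equal(nrow(s1[[1]]), nrow(coh$data))
})

test_that("fixing the group scale to zero collapses to complete pooling", {
  coh <- tiny_cohort(n_subjects = 5, seed = 13)
  fit <- suppressWarnings(fit_harmalloc(
    coh, settings = test_profile(fix_scale = c(phi = 0)), seed = 2))
  ph <- coef(fit)[, "phi"]
  expect_lt(max(ph) - min(ph), 1e-8)    # all subjects share one phi
  free <- suppressWarnings(fit_harmalloc(coh, settings = test_profile(), seed = 2))
  expect_gt(max(coef(free)[, "phi"]) - min(coef(free)[, "phi"]), 0.1)
})

test_that("centered and noncentered parameterizations agree on a small cohort", {
  coh <- tiny_cohort(n_subjects = 5, seed = 21)
  nc <- suppressWarnings(fit_harmalloc(coh, settings = test_profile(), seed = 5))
  ce <- suppressWarnings(fit_harmalloc(
    coh, settings = test_profile(centered = TRUE), seed = 5))
  # posterior means agree within Monte-Carlo error (generous for short chains)
  expect_equal(coef(nc)[, "alpha"], coef(ce)[, "alpha"], tolerance = 0.1)
  expect_equal(coef(nc)[, "phi"], coef(ce)[, "phi"], tolerance = 0.35)
})

test_that("posterior predictive check is near-perfect on self-simulated data", {
  coh <- tiny_cohort(n_subjects = 6, seed = 23)
  fit <- suppressWarnings(fit_harmalloc(coh, settings = test_profile(), seed = 7))
  pp <- posterior_predictive(fit, nsim = 50, seed = 1)
  expect_gt(pp$correlation, 0.9)
  # thinning stability: 50 vs 200 draws changes r only marginally
  pp2 <- posterior_predictive(fit, nsim = 200, seed = 1)
  expect_lt(abs(pp$correlation - pp2$correlation), 0.05)
  # degenerate single-subject cohort: correlation undefined
  one <- coh$data[coh$data$subject %in% 1:2, ]
  f1 <- suppressWarnings(fit_harmalloc(one, settings = test_profile(), seed = 1))
  pp1 <- posterior_predictive(f1, nsim = 10, seed = 1)
  expect_true(is.na(pp1$correlation))
  expect_match(pp1$note, "undefined")
})

test_that("fit input validation", {
  coh <- tiny_cohort(n_subjects = 3, seed = 2)
  expect_error(fit_harmalloc(coh$data[coh$data$subject == 1, ]), "at least 2")
  d <- coh$data; d$choice[4] <- NA
  expect_error(fit_harmalloc(d), "missing choices")
  d2 <- coh$data; d2$choice[1] <- "both"
  expect_error(fit_harmalloc(d2), "coded")
  expect_error(fit_harmalloc(coh$data[, -1]), "lacks columns")
})
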