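#' Sampler and prior settings for the hierarchical fit
#'
#' Default profile matches the reference analysis: 4 chains, 1,000 warm-up
#' iterations discarded and 1,000 kept per chain.  The fast profile (2 chains,
#' 500 + 500) is intended for simulation studies and tests.
#'
#' Priors follow common hierarchical conventions for bounded decision-model
#' parameters: group locations on an unconstrained scale with standard-normal
#' (alpha, tau) or wide-normal (phi, in seconds) priors, half-normal group
#' scales, and noncentered subject-level parameters
#' \eqn{\theta_s = \mu + \sigma z_s}, \eqn{z_s \sim N(0,1)}.  Subject
#' \eqn{\alpha} is the inverse probit of its latent score; \eqn{\tau} is the
#' inverse probit scaled to \code{(0, tau_max]}.  With utilities measured in
#' tens to hundreds of seconds, \code{tau_max = 2} already spans effectively
#' deterministic choice.
#'
#' @param chains number of MCMC chains.
#' @param warmup warm-up (discarded) iterations per chain.
#' @param iter kept iterations per chain.
#' @param adapt JAGS adaptation iterations.
#' @param tau_max upper bound of the inverse-temperature transform.
#' @param priors named list of prior hyperparameters; any subset of
#'   \code{alpha_loc_sd}, \code{alpha_scale_sd}, \code{phi_loc_sd},
#'   \code{phi_scale_sd}, \code{tau_loc_sd}, \code{tau_scale_sd},
#'   \code{bias_loc_sd}, \code{bias_scale_sd}.
#' @param fix_scale optional named numeric fixing group-level scales (e.g.
#'   \code{c(phi = 0)} for complete pooling of phi); names among
#'   \code{alpha}, \code{phi}, \code{tau}, \code{bias}.
#' @param centered if TRUE use the centered parameterization (subject
#'   parameters drawn directly from the group distribution) instead of the
#'   noncentered default; provided for cross-checks.
#' @return named list of settings.
#' @export
fit_settings <- function(chains = 4, warmup = 1000, iter = 1000, adapt = 500,
                         tau_max = 2, priors = list(), fix_scale = NULL,
                         centered = FALSE) {
  pr <- utils::modifyList(
    list(alpha_loc_sd = 1, alpha_scale_sd = 1,
         phi_loc_sd = 20, phi_scale_sd = 10,
         tau_loc_sd = 1, tau_scale_sd = 1,
         bias_loc_sd = 5, bias_scale_sd = 5),
    priors)
  list(chains = chains, warmup = warmup, iter = iter, adapt = adapt,
       tau_max = tau_max, priors = pr, fix_scale = fix_scale,
       centered = centered)
}

#' @rdname fit_settings
#' @export
fast_profile <- function(...) fit_settings(chains = 2, warmup = 500,
                                           iter = 500, adapt = 400, ...)

# Build the JAGS model string for a variant.  Subject-level parameters use
# the noncentered parameterization unless settings$centered; fixed group
# scales are spliced in as constants.
jags_model_code <- function(model, settings) {
  pr <- settings$priors
  fx <- settings$fix_scale
  scale_line <- function(par, sd_) {
    if (!is.null(fx) && par %in% names(fx))
      sprintf("  sg_%s <- %.10g", par, fx[[par]])
    else
      sprintf("  sg_%s ~ dnorm(0, %.10g) T(0,)", par, 1 / sd_^2)
  }
  subj_line <- function(par) {
    if (settings$centered)
      sprintf("    l%s[s] ~ dnorm(mu_%s, 1 / max(sg_%s^2, 1.0E-12))", par, par, par)
    else
      sprintf("    z%s[s] ~ dnorm(0, 1)\n    l%s[s] <- mu_%s + sg_%s * z%s[s]",
              par, par, par, par, par)
  }
  free <- model$params
  blocks <- character(0)
  subj <- character(0)
  if ("alpha" %in% free) {
    blocks <- c(blocks,
      sprintf("  mu_alpha ~ dnorm(0, %.10g)", 1 / pr$alpha_loc_sd^2),
      scale_line("alpha", pr$alpha_scale_sd))
    subj <- c(subj, subj_line("alpha"), "    alpha[s] <- phi(lalpha[s])")
  } else {
    subj <- c(subj, sprintf("    alpha[s] <- %d",
                            as.integer(model$fixed[["alpha"]])))
  }
  if ("phi" %in% free) {
    blocks <- c(blocks,
      sprintf("  mu_phi ~ dnorm(0, %.10g)", 1 / pr$phi_loc_sd^2),
      scale_line("phi", pr$phi_scale_sd))
    subj <- c(subj, subj_line("phi"), "    ph[s] <- lphi[s]")
  } else {
    subj <- c(subj, "    ph[s] <- 0")
  }
  blocks <- c(blocks,
    sprintf("  mu_tau ~ dnorm(0, %.10g)", 1 / pr$tau_loc_sd^2),
    scale_line("tau", pr$tau_scale_sd))
  subj <- c(subj, subj_line("tau"),
            sprintf("    tau[s] <- phi(ltau[s]) * %.10g", settings$tau_max))
  if ("bias" %in% free) {
    blocks <- c(blocks,
      sprintf("  mu_bias ~ dnorm(0, %.10g)", 1 / pr$bias_loc_sd^2),
      scale_line("bias", pr$bias_scale_sd))
    subj <- c(subj, subj_line("bias"), "    b[s] <- lbias[s]")
  } else {
    subj <- c(subj, "    b[s] <- 0")
  }
  du <- if (model$variant == "ratio_phi")
    "(1 - alpha[subj[i]]) * dtot[i] - alpha[subj[i]] * (cone[i] - ph[subj[i]] * cgrp[i])"
  else
    "(1 - alpha[subj[i]]) * dtot[i] - alpha[subj[i]] * (dsing[i] + ph[subj[i]])"
  paste0(
    "model {\n",
    paste(blocks, collapse = "\n"), "\n",
    "  for (s in 1:S) {\n",
    paste(subj, collapse = "\n"), "\n",
    "  }\n",
    "  for (i in 1:N) {\n",
    "    du[i] <- ", du, " + b[subj[i]] * dflt[i]\n",
    "    p[i] <- max(1.0E-9, min(1 - 1.0E-9, ilogit(tau[subj[i]] * du[i])))\n",
    "    y[i] ~ dbern(p[i])\n",
    "  }\n",
    "}\n")
}

#' Fit the hierarchical harm-allocation model to a cohort
#'
#' Subject parameters are modelled as draws from group-level distributions
#' and estimated jointly with the group parameters by MCMC (JAGS), using a
#' noncentered parameterization of the subject level.  The pointwise
#' log-likelihood of every kept draw is stored for LOO-based model
#' comparison.  Convergence is summarised by split-chain R-hat and effective
#' sample size; any monitored parameter with R-hat >= 1.1 triggers a warning
#' (never silent).
#'
#' @param data cohort trial table: data.frame with columns \code{subject},
#'   \code{c_one}, \code{c_group}, \code{n_group}, \code{default_cond},
#'   \code{choice} (\code{"one"}/\code{"group"}); or a
#'   \code{\link{generate_cohort}} result.
#' @param model a \code{\link{harm_model}}.
#' @param settings a \code{\link{fit_settings}} list.
#' @param seed integer seed for the MCMC chains.
#' @param quiet suppress JAGS progress output.
#' @return object of class \code{"harmalloc_fit"} with elements
#'   \describe{
#'     \item{\code{subject_draws}}{named list of draws x subjects matrices
#'       for each free parameter on the natural scale.}
#'     \item{\code{group_draws}}{draws matrix of group-level locations and
#'       scales, both latent (\code{mu_*}, \code{sg_*}) and natural-scale
#'       locations (\code{alpha_group}, \code{tau_group}).}
#'     \item{\code{log_lik}}{draws x observations pointwise log-likelihood.}
#'     \item{\code{diagnostics}}{R-hat and effective sample size per
#'       monitored parameter.}
#'     \item{\code{data}, \code{model}, \code{settings}, \code{seed}}{inputs.}
#'   }
#' @seealso \code{\link{psis_loo}}, \code{\link{posterior_predictive}},
#'   \code{\link{parameter_recovery}}
#' @export
fit_harmalloc <- function(data, model = harm_model("full"),
                          settings = fit_settings(), seed = 1L,
                          quiet = TRUE) {
  if (inherits(data, "harm_cohort")) data <- data$data
  need <- c("subject", "c_one", "c_group", "n_group", "choice")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  if (anyNA(data$choice)) stop("missing choices; filter or impute before fitting")
  if (!all(data$choice %in% c("one", "group")))
    stop("choice must be coded 'one' or 'group'")
  subj_ids <- sort(unique(data$subject))
  S <- length(subj_ids)
  if (S < 2) stop("need at least 2 subjects for a hierarchical fit")
  subj <- match(data$subject, subj_ids)
  dflt <- if (!is.null(data$default_cond))
    (data$default_cond == "one_default") - (data$default_cond == "group_default")
  else rep(0, nrow(data))
  if (model$variant == "default_bias" && is.null(data$default_cond))
    stop("default-bias variant needs a 'default_cond' column")
  jd <- list(S = S, N = nrow(data), subj = subj,
             dtot = data$c_group * data$n_group - data$c_one,
             dsing = data$c_one - data$c_group,
             cone = data$c_one, cgrp = data$c_group,
             dflt = as.numeric(dflt),
             y = as.integer(data$choice == "one"))
  if (model$variant != "ratio_phi") { jd$cone <- NULL; jd$cgrp <- NULL }
  if (!("bias" %in% model$params)) jd$dflt <- NULL
  code <- jags_model_code(model, settings)
  if (is.null(jd$dflt)) code <- sub(" + b[subj[i]] * dflt[i]", "", code, fixed = TRUE)

  inits <- lapply(seq_len(settings$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) * 1000L + ch)
  })
  monitors <- c(
    if ("alpha" %in% model$params) c("mu_alpha", "sg_alpha", "alpha"),
    if ("phi" %in% model$params) c("mu_phi", "sg_phi", "ph"),
    c("mu_tau", "sg_tau", "tau"),
    if ("bias" %in% model$params) c("mu_bias", "sg_bias", "b"))
  if (!is.null(settings$fix_scale))
    monitors <- setdiff(monitors, paste0("sg_", names(settings$fix_scale)))

  run <- function() {
    jm <- rjags::jags.model(textConnection(code), data = jd, inits = inits,
                            n.chains = settings$chains,
                            n.adapt = settings$adapt, quiet = quiet)
    stats::update(jm, settings$warmup, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = settings$iter,
                        progress.bar = "none")
  }
  sm <- if (quiet) suppressWarnings(run()) else run()

  draws <- do.call(rbind, lapply(sm, as.matrix))
  grab <- function(stub) {
    cols <- paste0(stub, "[", seq_len(S), "]")
    if (!all(cols %in% colnames(draws))) return(NULL)
    m <- draws[, cols, drop = FALSE]
    colnames(m) <- subj_ids
    m
  }
  subject_draws <- Filter(Negate(is.null), list(
    alpha = grab("alpha"), phi = grab("ph"), tau = grab("tau"),
    bias = grab("b")))
  # constant-alpha variants: drop the deterministic columns JAGS refuses to
  # monitor anyway; subject_draws holds free parameters only
  subject_draws <- subject_draws[intersect(names(subject_draws), model$params)]

  gcols <- grep("^(mu|sg)_", colnames(draws), value = TRUE)
  group_draws <- draws[, gcols, drop = FALSE]
  if ("mu_alpha" %in% gcols)
    group_draws <- cbind(group_draws, alpha_group = stats::pnorm(draws[, "mu_alpha"]))
  group_draws <- cbind(group_draws,
                       tau_group = stats::pnorm(draws[, "mu_tau"]) * settings$tau_max)

  log_lik <- pointwise_loglik(subject_draws, model, data, subj, dflt)

  diag <- fit_diagnostics(sm)
  bad <- diag$rhat[is.finite(diag$rhat)] >= 1.1
  if (any(bad))
    warning("possible non-convergence: R-hat >= 1.1 for ",
            sum(bad), " monitored parameter(s); max R-hat = ",
            round(max(diag$rhat, na.rm = TRUE), 3))

  structure(list(subject_draws = subject_draws, group_draws = group_draws,
                 log_lik = log_lik, diagnostics = diag, data = data,
                 subject_ids = subj_ids, model = model, settings = settings,
                 seed = seed),
            class = "harmalloc_fit")
}

# draws x N pointwise Bernoulli log-likelihood from subject-level draws
pointwise_loglik <- function(subject_draws, model, data, subj, dflt) {
  ndraw <- nrow(subject_draws[[1]])
  fixed <- resolve_params(list(), model)
  getp <- function(nm, default) {
    if (!is.null(subject_draws[[nm]])) subject_draws[[nm]][, subj, drop = FALSE]
    else matrix(default, ndraw, length(subj))
  }
  A <- getp("alpha", fixed$alpha %||% NA_real_)
  P <- getp("phi", 0)
  Tau <- getp("tau", NA_real_)
  dtot <- data$c_group * data$n_group - data$c_one
  dsing <- data$c_one - data$c_group
  if (model$variant == "ratio_phi") {
    du <- sweep((1 - A), 2, dtot, "*") -
      A * (matrix(data$c_one, ndraw, length(subj), byrow = TRUE) -
             P * matrix(data$c_group, ndraw, length(subj), byrow = TRUE))
  } else {
    du <- sweep(1 - A, 2, dtot, "*") - A * sweep(P, 2, dsing, "+")
  }
  if (!is.null(subject_draws$bias))
    du <- du + sweep(getp("bias", 0), 2, dflt, "*")
  eta <- Tau * du
  y <- matrix(as.integer(data$choice == "one"), ndraw, length(subj), byrow = TRUE)
  # log plogis is numerically safe for large |eta|
  ll <- ifelse(y == 1L, stats::plogis(eta, log.p = TRUE),
               stats::plogis(-eta, log.p = TRUE))
  ll
}

# split-chain R-hat and effective sample size via coda
fit_diagnostics <- function(sm) {
  split2 <- lapply(sm, function(ch) {
    n <- nrow(ch); h <- floor(n / 2)
    list(coda::as.mcmc(ch[seq_len(h), , drop = FALSE]),
         coda::as.mcmc(ch[(n - h + 1):n, , drop = FALSE]))
  })
  split_list <- coda::as.mcmc.list(unlist(split2, recursive = FALSE))
  keep <- apply(as.matrix(split_list), 2, stats::var) > 0
  rhat <- rep(NA_real_, ncol(sm[[1]]))
  names(rhat) <- colnames(sm[[1]])
  if (any(keep)) {
    gd <- try(coda::gelman.diag(split_list[, keep, drop = FALSE],
                                autoburnin = FALSE, multivariate = FALSE),
              silent = TRUE)
    if (!inherits(gd, "try-error")) rhat[keep] <- gd$psrf[, 1]
  }
  ess <- coda::effectiveSize(coda::as.mcmc.list(sm))
  list(rhat = rhat, ess = ess)
}
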