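#' @export
print.harmalloc_fit <- function(x, ...) {
  st <- x$settings
  cat("Hierarchical harm-allocation model fit (variant '",
      x$model$variant, "')\n", sep = "")
  cat("  ", length(x$subject_ids), " subjects, ", nrow(x$data), " trials; ",
      st$chains, " chains x (", st$warmup, " warmup + ", st$iter,
      " kept)\n", sep = "")
  rh <- x$diagnostics$rhat
  cat("  max R-hat: ", round(max(rh, na.rm = TRUE), 3),
      "; min ESS: ", round(min(x$diagnostics$ess, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Summarise a hierarchical fit
#'
#' Group-level rows report the posterior mean and SD of each natural-scale
#' group location (e.g. \code{alpha_group} = inverse probit of the latent
#' location), plus the posterior mean of the between-subject SD of the
#' subject-level posterior means (\code{between_sd}) -- both spreads are
#' reported because a printed "SD" for a group parameter may refer to either.
#'
#' @param object a \code{\link{fit_harmalloc}} result.
#' @param ... unused.
#' @return object of class \code{"summary.harmalloc_fit"}: list with
#'   \code{group} (data.frame) and \code{subjects} (posterior means/SDs per
#'   subject and parameter).
#' @export
summary.harmalloc_fit <- function(object, ...) {
  gd <- object$group_draws
  nat <- list(alpha = "alpha_group", phi = "mu_phi", tau = "tau_group",
              bias = "mu_bias")
  subj_mean <- coef(object)
  rows <- lapply(names(object$subject_draws), function(par) {
    col <- nat[[par]]
    d <- gd[, col]
    data.frame(parameter = par,
               group_mean = mean(d), group_sd = stats::sd(d),
               between_sd = stats::sd(subj_mean[, par]),
               q2.5 = unname(stats::quantile(d, 0.025)),
               q97.5 = unname(stats::quantile(d, 0.975)))
  })
  subjects <- data.frame(subject = object$subject_ids, subj_mean,
                         check.names = FALSE)
  sds <- vapply(object$subject_draws, function(m) apply(m, 2, stats::sd),
                numeric(length(object$subject_ids)))
  colnames(sds) <- paste0(colnames(sds), "_sd")
  out <- list(group = do.call(rbind, rows),
              subjects = cbind(subjects, sds),
              model = object$model, diagnostics = object$diagnostics)
  class(out) <- "summary.harmalloc_fit"
  out
}

#' @export
print.summary.harmalloc_fit <- function(x, digits = 3, ...) {
  cat("Group-level posterior (variant '", x$model$variant, "'):\n", sep = "")
  print(format(x$group, digits = digits), row.names = FALSE)
  cat("\nSubject-level posterior means (first 6):\n")
  print(utils::head(format(x$subjects, digits = digits)), row.names = FALSE)
  invisible(x)
}

#' Subject-level posterior mean parameters
#'
#' @param object a fit.
#' @param ... unused.
#' @return matrix subjects x free parameters of posterior means.
#' @export
coef.harmalloc_fit <- function(object, ...) {
  sapply(object$subject_draws, colMeans)
}

#' Posterior-mean choice probabilities for the fitted trials
#'
#' @param object a fit.
#' @param newdata optional trial table with a \code{subject} column (defaults
#'   to the fitted data).
#' @param ... unused.
#' @return numeric vector: posterior-mean probability of choosing the one
#'   option per trial (averaged over draws, not evaluated at mean
#'   parameters).
#' @export
predict.harmalloc_fit <- function(object, newdata = NULL, ...) {
  data <- newdata %||% object$data
  subj <- match(data$subject, object$subject_ids)
  if (anyNA(subj)) stop("newdata contains subjects absent from the fit")
  dflt <- if (!is.null(data$default_cond))
    (data$default_cond == "one_default") - (data$default_cond == "group_default")
  else rep(0, nrow(data))
  dat <- data
  dat$choice <- factor("one", levels = c("one", "group"))  # placeholder
  ll1 <- pointwise_loglik(object$subject_draws, object$model,
                          transform(dat, choice = "one"), subj, dflt)
  colMeans(exp(ll1))
}

#' Response residuals
#'
#' Observed choice indicator (1 = one) minus the posterior-mean probability
#' of choosing one, per trial.
#' @param object a fit.
#' @param ... unused.
#' @export
residuals.harmalloc_fit <- function(object, ...) {
  as.integer(object$data$choice == "one") - predict(object)
}

#' Simulate choice datasets from the posterior
#'
#' Draws \code{nsim} posterior draws (without replacement if possible) and
#' simulates a full cohort dataset from each, as used by posterior
#' predictive checks.
#'
#' @param object a fit.
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of \code{nsim} data.frames, each the fitted trial table with
#'   the \code{choice} column resimulated.
#' @export
simulate.harmalloc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  ndraw <- nrow(object$subject_draws[[1]])
  with_seed(seed, {
    idx <- if (nsim <= ndraw) sample.int(ndraw, nsim)
           else sample.int(ndraw, nsim, replace = TRUE)
    lapply(idx, function(i) {
      data <- object$data
      subj <- match(data$subject, object$subject_ids)
      pars <- lapply(object$subject_draws, function(m) m[i, ])
      fixed <- resolve_params(list(), object$model)
      alpha <- if (!is.null(pars$alpha)) pars$alpha[subj] else fixed$alpha
      phv <- if (!is.null(pars$phi)) pars$phi[subj] else 0
      tau <- pars$tau[subj]
      uc <- if (object$model$variant == "ratio_phi")
        (1 - alpha) * (data$c_group * data$n_group - data$c_one) -
          alpha * (data$c_one - phv * data$c_group)
      else
        (1 - alpha) * (data$c_group * data$n_group - data$c_one) -
          alpha * (data$c_one - data$c_group + phv)
      if (!is.null(pars$bias)) {
        dflt <- (data$default_cond == "one_default") -
          (data$default_cond == "group_default")
        uc <- uc + pars$bias[subj] * dflt
      }
      p1 <- stats::plogis(tau * uc)
      data$choice <- ifelse(stats::rbinom(length(p1), 1L, p1) == 1L,
                            "one", "group")
      data
    })
  })
}

#' Plot a fit: posterior predictive check of Rawlsian choice proportions
#'
#' Scatter of observed per-subject proportion of Rawlsian (group) choices
#' against the model-predicted proportion, with the identity line.
#'
#' @param x a fit.
#' @param nsim posterior draws used for the prediction (passed to
#'   \code{\link{posterior_predictive}}).
#' @param ... further arguments to \code{plot}.
#' @export
plot.harmalloc_fit <- function(x, nsim = 100, ...) {
  pp <- posterior_predictive(x, nsim = nsim, seed = 1L)
  plot(pp$table$predicted, pp$table$observed,
       xlab = "predicted P(Rawlsian choice)",
       ylab = "observed P(Rawlsian choice)",
       xlim = c(0, 1), ylim = c(0, 1), pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("r = %.3f", pp$correlation))
  invisible(x)
}
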