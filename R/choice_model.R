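#' Specify a harm-allocation utility model
#'
#' The model family expresses the utility difference between choosing the one
#' (utilitarian option) and choosing the group (Rawlsian option) as a mixture
#' of two strategies, weighted by the maximin weight \eqn{\alpha \in [0,1]}:
#' \deqn{U(one)   = -(1-\alpha) C_{one} - \alpha (C_{one} + \varphi)}
#' \deqn{U(group) = -(1-\alpha) C_{group} N_{group} - \alpha C_{group}}
#' \deqn{\Delta U = U(one) - U(group)
#'       = (1-\alpha)\Delta_{total} - \alpha(\Delta_{single} + \varphi)}
#' with \eqn{\Delta_{total} = C_{group} N_{group} - C_{one}} (extra total harm
#' of the group option) and \eqn{\Delta_{single} = C_{one} - C_{group}} (extra
#' harm the worst-off individual receives under the one option).  The
#' agreeability threshold \eqn{\varphi} (seconds) shifts what extra harm to a
#' single person is still deemed acceptable; the softmax
#' \eqn{P(one) = 1/(1+e^{-\tau \Delta U})} converts utility to choice
#' probability with inverse temperature \eqn{\tau}.
#'
#' Variants: \describe{
#'   \item{\code{"full"}}{the winning model; free \eqn{\alpha,\varphi,\tau},
#'     constant (additive) agreeability term.}
#'   \item{\code{"alpha1"}}{\eqn{\alpha} fixed at 1 (pure maximin).}
#'   \item{\code{"alpha0"}}{\eqn{\alpha} fixed at 0 (pure utilitarian;
#'     \eqn{\varphi} drops out).}
#'   \item{\code{"nophi"}}{free \eqn{\alpha}, no agreeability term.}
#'   \item{\code{"ratio_phi"}}{agreeability as a multiplicative threshold:
#'     \eqn{\Delta U = (1-\alpha)\Delta_{total} -
#'     \alpha(C_{one} - \varphi C_{group})}, i.e. the acceptable harm to the
#'     one is \eqn{\varphi} times each group member's harm.}
#'   \item{\code{"default_bias"}}{the full model plus a stickiness parameter
#'     \eqn{b} added to the utility of whichever option is the default; an
#'     extension beyond the winning model for probing Kantian inaction
#'     preferences.}
#' }
#'
#' @param variant one of \code{"full"}, \code{"alpha1"}, \code{"alpha0"},
#'   \code{"nophi"}, \code{"ratio_phi"}, \code{"default_bias"}.
#' @return object of class \code{"harm_model"} with elements \code{variant},
#'   \code{params} (free parameter names) and \code{fixed} (fixed values).
#' @examples
#' harm_model("full")$params        # "alpha" "phi" "tau"
#' harm_model("alpha0")$params      # "tau"
#' @export
harm_model <- function(variant = c("full", "alpha1", "alpha0", "nophi",
                                   "ratio_phi", "default_bias")) {
  variant <- match.arg(variant)
  params <- switch(variant,
    full         = c("alpha", "phi", "tau"),
    alpha1       = c("phi", "tau"),
    alpha0       = c("tau"),
    nophi        = c("alpha", "tau"),
    ratio_phi    = c("alpha", "phi", "tau"),
    default_bias = c("alpha", "phi", "tau", "bias"))
  fixed <- switch(variant,
    alpha1 = c(alpha = 1), alpha0 = c(alpha = 0), numeric(0))
  structure(list(variant = variant, params = params, fixed = fixed),
            class = "harm_model")
}

#' @export
print.harm_model <- function(x, ...) {
  cat("Harm-allocation choice model, variant '", x$variant, "'\n", sep = "")
  cat("  free parameters:", paste(x$params, collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n")
  invisible(x)
}

check_params <- function(params) {
  alpha <- params$alpha %||% NA_real_
  tau <- params$tau
  if (!is.na(alpha) && (alpha < 0 || alpha > 1)) stop("alpha must lie in [0, 1]")
  if (is.null(tau) || tau <= 0) stop("tau must be positive")
  if (!is.null(params$phi) && !is.finite(params$phi)) stop("phi must be finite")
  invisible(TRUE)
}

# Fill in fixed parameter values and defaults implied by the variant.
resolve_params <- function(params, model) {
  params <- as.list(params)
  for (nm in names(model$fixed)) params[[nm]] <- unname(model$fixed[nm])
  if (model$variant %in% c("nophi", "alpha0")) params$phi <- 0
  if (model$variant != "default_bias") params$bias <- 0
  params
}

#' Utility components of a trial
#'
#' Computes \eqn{\Delta_{total}}, \eqn{\Delta_{single}}, the option utilities
#' and their difference for one or more trials under a parameter set.
#'
#' @param trials data.frame with columns \code{c_one}, \code{c_group},
#'   \code{n_group} (and \code{default_cond} for the default-bias variant).
#' @param params named list or vector with elements among \code{alpha},
#'   \code{phi}, \code{tau}, \code{bias} as required by \code{model}.
#' @param model a \code{\link{harm_model}}; default the winning full model.
#' @return data.frame with columns \code{delta_total}, \code{delta_single},
#'   \code{u_one}, \code{u_group}, \code{delta_u} (one row per trial).
#'   For the default-bias variant \code{delta_u} includes the stickiness
#'   term; \code{u_one}/\code{u_group} are reported without it.
#' @examples
#' tr <- data.frame(c_one = 100, c_group = 40, n_group = 3)
#' utility_components(tr, list(alpha = 0.95, phi = -10, tau = 0.1))
#' @export
utility_components <- function(trials, params, model = harm_model("full")) {
  params <- resolve_params(params, model)
  check_params(params)
  a <- params$alpha; ph <- params$phi
  dtot <- trials$c_group * trials$n_group - trials$c_one
  dsing <- trials$c_one - trials$c_group
  if (model$variant == "ratio_phi") {
    # multiplicative threshold: acceptable harm to the one is phi times each
    # group member's harm, so the threshold sits on the group side of U
    du <- (1 - a) * dtot - a * (trials$c_one - ph * trials$c_group)
    u_one <- -(1 - a) * trials$c_one - a * trials$c_one
    u_group <- -(1 - a) * trials$c_group * trials$n_group - a * ph * trials$c_group
  } else {
    u_one <- -(1 - a) * trials$c_one - a * (trials$c_one + ph)
    u_group <- -(1 - a) * trials$c_group * trials$n_group - a * trials$c_group
    du <- (1 - a) * dtot - a * (dsing + ph)
  }
  if (model$variant == "default_bias") {
    if (is.null(trials$default_cond))
      stop("default-bias variant needs a 'default_cond' column")
    b <- params$bias
    du <- du + b * (trials$default_cond == "one_default") -
      b * (trials$default_cond == "group_default")
  }
  data.frame(delta_total = dtot, delta_single = dsing,
             u_one = u_one, u_group = u_group, delta_u = du)
}

#' Probability of choosing the one option
#'
#' Softmax choice rule \eqn{P(one) = 1/(1 + e^{-\tau \Delta U})}.  The
#' probability is strictly decreasing in \code{c_one}
#' (\eqn{\partial \Delta U / \partial C_{one} = -1} for every \eqn{\alpha})
#' and saturates to 0/1 within machine limits for extreme utilities.
#'
#' @inheritParams utility_components
#' @return numeric vector of probabilities in (0, 1), one per trial.
#' @examples
#' tr <- data.frame(c_one = 100, c_group = 40, n_group = 3)
#' choice_prob(tr, list(alpha = 0.95, phi = -10, tau = 0.1))  # ~0.0095
#' @export
choice_prob <- function(trials, params, model = harm_model("full")) {
  uc <- utility_components(trials, params, model)
  tau <- resolve_params(params, model)$tau
  stats::plogis(tau * uc$delta_u)
}

#' Log-likelihood of observed choices
#'
#' @param data data.frame with the trial columns plus a \code{choice} column
#'   coded \code{"one"}/\code{"group"} (a single subject's data; see
#'   \code{\link{fit_harmalloc}} for cohorts).
#' @inheritParams utility_components
#' @return list with \code{total} (sum) and \code{pointwise} (per-trial
#'   log-likelihood vector, retained for LOO).
#' @export
log_likelihood <- function(data, params, model = harm_model("full")) {
  if (is.null(data$choice) || anyNA(data$choice))
    stop("every trial needs an observed choice ('one' or 'group')")
  if (!all(data$choice %in% c("one", "group")))
    stop("choice must be coded 'one' or 'group'")
  p_one <- choice_prob(data, params, model)
  y <- as.integer(data$choice == "one")
  pw <- stats::dbinom(y, 1L, p_one, log = TRUE)
  list(total = sum(pw), pointwise = pw)
}

#' Simulate choices from the model
#'
#' Draws a Bernoulli choice per trial with \code{\link{choice_prob}};
#' byte-reproducible under \code{seed}.
#'
#' @param design a \code{\link{harm_design}} (or any trial data.frame).
#' @inheritParams utility_components
#' @param seed integer seed.
#' @return the design with an added \code{choice} column
#'   (\code{"one"}/\code{"group"}).
#' @export
simulate_choices <- function(design, params, model = harm_model("full"),
                             seed = NULL) {
  p_one <- choice_prob(design, params, model)
  out <- as.data.frame(design)
  out$choice <- with_seed(seed, ifelse(stats::rbinom(length(p_one), 1L, p_one) == 1L,
                                       "one", "group"))
  out
}
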