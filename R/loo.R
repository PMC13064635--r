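#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Approximates leave-one-out expected log predictive density from the
#' pointwise log-likelihood matrix of a fitted model.  For each observation
#' the importance ratios are the inverse pointwise likelihoods; the largest
#' 20\% of ratios (at most \eqn{3\sqrt{S}}) are replaced by expected order
#' statistics of a generalized Pareto distribution fitted to the tail
#' (Zhang--Stephens estimator), and smoothed weights are truncated at the raw
#' maximum.  Observations whose tail shape exceeds \eqn{k > 0.7} are flagged
#' as unreliable.
#'
#' @param fit a \code{\link{fit_harmalloc}} object, or a draws x observations
#'   pointwise log-likelihood matrix.
#' @return object of class \code{"harm_loo"}: list with \code{elpd_loo},
#'   \code{se}, \code{looic} (\eqn{-2\,\mathrm{elpd}}), \code{pointwise}
#'   (per-observation elpd), \code{pareto_k}, \code{n_obs}, \code{n_draws},
#'   \code{flagged} (indices with \eqn{k > 0.7}).
#' @examples
#' ll <- matrix(log(0.5), nrow = 200, ncol = 10)  # p = 0.5 Bernoulli model
#' psis_loo(ll)$elpd_loo                           # 10 * log(0.5)
#' @export
psis_loo <- function(fit) {
  ll <- if (inherits(fit, "harmalloc_fit")) fit$log_lik else as.matrix(fit)
  if (is.null(ll) || !is.numeric(ll))
    stop("no pointwise log-likelihood matrix available")
  S <- nrow(ll); n <- ncol(ll)
  pw <- numeric(n); k <- numeric(n)
  for (i in seq_len(n)) {
    ps <- psis_smooth(-ll[, i])
    lw <- ps$log_weights
    pw[i] <- log_sum_exp(lw + ll[, i]) - log_sum_exp(lw)
    k[i] <- ps$k
  }
  structure(list(elpd_loo = sum(pw), se = stats::sd(pw) * sqrt(n),
                 looic = -2 * sum(pw), pointwise = pw, pareto_k = k,
                 n_obs = n, n_draws = S, flagged = which(k > 0.7)),
            class = "harm_loo")
}

#' @export
print.harm_loo <- function(x, ...) {
  cat("PSIS-LOO (", x$n_obs, " observations, ", x$n_draws, " draws)\n",
      sep = "")
  cat(sprintf("  elpd_loo = %.1f (SE %.1f), LOOIC = %.1f\n",
              x$elpd_loo, x$se, x$looic))
  if (length(x$flagged))
    cat("  ", length(x$flagged), " observation(s) with Pareto k > 0.7\n")
  invisible(x)
}

# Pareto-smooth one vector of log importance ratios.
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || stats::sd(lw) == 0)
    return(list(log_weights = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  # heavily tied ratios leave too little tail variation for a Pareto fit
  if (max(exceed) <= 0 || sort(exceed)[max(1, floor(length(exceed) / 4 + 0.5))] <= 0)
    return(list(log_weights = lw, k = NA_real_))
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k) || !is.finite(fit$sigma) || fit$sigma <= 0)
    return(list(log_weights = lw, k = NA_real_))
  qq <- (seq_len(M) - 0.5) / M
  smoothed <- log(exp(cutoff) + qgpd(qq, fit$k, fit$sigma))
  smoothed <- pmin(smoothed, max(lw))      # truncate at raw maximum
  lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  list(log_weights = lw, k = fit$k)
}

# Zhang & Stephens (2009) generalized Pareto fit (shape k, scale sigma) with
# the weak prior regularisation used for PSIS tail diagnostics.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30 + floor(sqrt(n))
  j <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (prior * x[max(1, floor(n / 4 + 0.5))])
  k_of <- function(th) -mean(log1p(-th * x))   # Zhang-Stephens profile k
  lik <- vapply(theta, function(th) {
    k <- k_of(th)
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(jj) sum(exp(lik - lik[jj])), numeric(1))
  th_hat <- sum(theta * w)
  zk <- k_of(th_hat)
  sigma <- zk / th_hat
  k_hat <- -zk                              # Pareto shape xi
  k_hat <- (n * k_hat + 5) / (n + 10)       # weak prior, regularise toward 0.5
  list(k = k_hat, sigma = sigma)
}

# generalized Pareto quantile function
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Compare models by expected predictive accuracy
#'
#' Pairwise differences in elpd_loo with the standard error of the
#' difference computed from the paired pointwise elpd values
#' (\code{sd(diff) * sqrt(n)}).  All fits must be computed on the identical
#' observation set.
#'
#' @param ... two or more \code{\link{psis_loo}} results (optionally named),
#'   or \code{\link{fit_harmalloc}} objects (LOO is computed on the fly).
#' @return data.frame of class \code{"harm_loo_compare"}: one row per ordered
#'   model pair with \code{elpd_diff} (row model minus column model) and
#'   \code{se_diff}, plus per-model \code{elpd_loo} and \code{looic} as an
#'   attribute table.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], c("harm_loo", "harmalloc_fit")))
    fits <- fits[[1]]
  fits <- lapply(fits, function(f)
    if (inherits(f, "harmalloc_fit")) psis_loo(f) else f)
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  nm[nm == ""] <- paste0("model", which(nm == ""))
  ns <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("fits were computed on different observation sets (n = ",
         paste(ns, collapse = ", "), ")")
  rows <- list()
  for (a in seq_along(fits)) for (b in seq_along(fits)) {
    if (a == b) next
    d <- fits[[a]]$pointwise - fits[[b]]$pointwise
    rows[[length(rows) + 1L]] <- data.frame(
      model = nm[a], reference = nm[b],
      elpd_diff = sum(d), se_diff = stats::sd(d) * sqrt(length(d)))
  }
  out <- do.call(rbind, rows)
  attr(out, "models") <- data.frame(
    model = nm,
    elpd_loo = vapply(fits, function(f) f$elpd_loo, numeric(1)),
    looic = vapply(fits, function(f) f$looic, numeric(1)))
  class(out) <- c("harm_loo_compare", "data.frame")
  out
}

#' @export
print.harm_loo_compare <- function(x, ...) {
  cat("Model comparison (elpd_diff = model - reference):\n")
  print(format(as.data.frame(x), digits = 4), row.names = FALSE)
  cat("\nPer-model fit:\n")
  print(format(attr(x, "models"), digits = 6), row.names = FALSE)
  invisible(x)
}

#' Posterior predictive check of Rawlsian choice proportions
#'
#' Simulates choice data from posterior draws, averages to a predicted
#' per-subject proportion of Rawlsian (group) choices, and correlates it with
#' the observed proportions.
#'
#' @param fit a \code{\link{fit_harmalloc}} object.
#' @param nsim number of posterior draws to simulate (default 100).
#' @param seed integer seed.
#' @return list of class \code{"harm_ppc"}: \code{table} (per-subject
#'   observed and predicted proportions), \code{correlation} (Pearson r, or
#'   NA with a note when the observed proportions have zero variance).
#' @export
posterior_predictive <- function(fit, nsim = 100, seed = 1L) {
  sims <- simulate(fit, nsim = nsim, seed = seed)
  obs <- tapply(fit$data$choice == "group", fit$data$subject, mean)
  pred <- Reduce(`+`, lapply(sims, function(d)
    tapply(d$choice == "group", d$subject, mean))) / length(sims)
  tab <- data.frame(subject = fit$subject_ids,
                    observed = as.numeric(obs[as.character(fit$subject_ids)]),
                    predicted = as.numeric(pred[as.character(fit$subject_ids)]))
  r <- if (length(unique(tab$observed)) < 2 || nrow(tab) < 3) NA_real_
       else stats::cor(tab$observed, tab$predicted)
  structure(list(table = tab, correlation = r,
                 note = if (is.na(r)) "correlation undefined (needs >= 3 subjects with varying proportions)"),
            class = "harm_ppc")
}

#' @export
print.harm_ppc <- function(x, ...) {
  cat("Posterior predictive check:", nrow(x$table), "subjects\n")
  if (is.na(x$correlation)) cat(" ", x$note, "\n")
  else cat(sprintf("  observed vs predicted Rawlsian proportion: r = %.3f\n",
                   x$correlation))
  invisible(x)
}
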