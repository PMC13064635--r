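#' Parameter-recovery simulation
#'
#' Simulates a cohort with known ("true") subject parameters drawn from the
#' group-level generating distributions, refits the model hierarchically, and
#' correlates the posterior-mean subject estimates with the truths.  Good
#' recovery (high Pearson r, small bias) indicates the parameters are
#' identifiable from choices on the design.
#'
#' @param n_subjects cohort size (default 68; >= 16 recommended).
#' @param design a \code{\link{harm_design}}; defaults to the 150-trial
#'   design drawn under \code{seed}.
#' @param truth_sampler function \code{(n, seed)} returning a data.frame of
#'   subject truths with columns \code{alpha}, \code{phi}, \code{tau};
#'   defaults to \code{\link{sample_subject_params}} with
#'   \code{group_params}.
#' @param group_params generating distributions for the default sampler.
#' @param model a \code{\link{harm_model}} used both to simulate and refit.
#' @param settings sampler settings (default \code{\link{fast_profile}()}).
#' @param seed integer seed for truths, choices and MCMC.
#' @return object of class \code{"harm_recovery"}: \code{summary}
#'   (per-parameter Pearson r, bias, RMSE; r is NA with a note when the
#'   truths are degenerate), \code{truths}, \code{estimates}, \code{fit}.
#' @examples
#' \donttest{
#' rec <- parameter_recovery(n_subjects = 16, seed = 1,
#'                           settings = fast_profile())
#' rec$summary
#' }
#' @export
parameter_recovery <- function(n_subjects = 68, design = NULL,
                               truth_sampler = NULL,
                               group_params = default_group_params(),
                               model = harm_model("full"),
                               settings = fast_profile(), seed = 1L) {
  if (is.null(design)) design <- harm_design(seed = seed)
  if (nrow(design) == 0) stop("design has no trials")
  sampler <- truth_sampler %||%
    function(n, seed) sample_subject_params(n, group_params, seed = seed)
  truths <- sampler(n_subjects, seed)
  check <- function(p) all(is.finite(p))
  if (!all(truths$alpha >= 0 & truths$alpha <= 1) || any(truths$tau <= 0) ||
      !check(truths$phi))
    stop("truth sampler returned invalid parameters")
  cohort <- with_seed(seed + 1L, {
    do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      d <- simulate_choices(design, as.list(truths[s, c("alpha", "phi", "tau")]),
                            model = model, seed = NULL)
      cbind(subject = s, d)
    }))
  })
  fit <- fit_harmalloc(cohort, model = model, settings = settings,
                       seed = seed + 2L)
  est <- coef(fit)
  pars <- intersect(model$params, colnames(est))
  rows <- lapply(pars, function(p) {
    tr <- truths[[p]]; e <- est[, p]
    degenerate <- stats::sd(tr) == 0
    data.frame(parameter = p,
               r = if (degenerate) NA_real_ else stats::cor(tr, e),
               bias = mean(e - tr),
               rmse = sqrt(mean((e - tr)^2)),
               truth_sd = stats::sd(tr))
  })
  structure(list(summary = do.call(rbind, rows), truths = truths,
                 estimates = est, fit = fit, seed = seed,
                 note = if (any(vapply(rows, function(r) is.na(r$r), logical(1))))
                   "r undefined for parameters with degenerate (constant) truths"),
            class = "harm_recovery")
}

#' @export
print.harm_recovery <- function(x, ...) {
  cat("Parameter recovery:", nrow(x$truths), "subjects\n")
  print(format(x$summary, digits = 3), row.names = FALSE)
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Scatter plot of recovery truths vs estimates
#' @param x a \code{\link{parameter_recovery}} result.
#' @param parameter which parameter to plot (default \code{"phi"}).
#' @param ... passed to \code{plot}.
#' @export
plot.harm_recovery <- function(x, parameter = "phi", ...) {
  tr <- x$truths[[parameter]]; e <- x$estimates[, parameter]
  plot(tr, e, xlab = paste("true", parameter),
       ylab = paste("recovered", parameter), pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  r <- x$summary$r[x$summary$parameter == parameter]
  graphics::legend("topleft", bty = "n", legend = sprintf("r = %.3f", r))
  invisible(x)
}
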