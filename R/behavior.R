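#' Model-free Rawlsian choice statistics
#'
#' Per-subject proportion of Rawlsian (group) choices, a one-sample t test of
#' those proportions against chance (0.5), and the extra total harm accepted:
#' choosing the group on a trial adds \eqn{\Delta_{total} =
#' C_{group} N_{group} - C_{one}} seconds relative to choosing the one, so a
#' subject's extra harm is the mean of \eqn{\Delta_{total}} over their group
#' choices (0 on one-choices).
#'
#' @param cohort cohort trial table (or \code{\link{generate_cohort}}
#'   result) with columns \code{subject}, \code{c_one}, \code{c_group},
#'   \code{n_group}, \code{choice}.
#' @return list of class \code{"harm_behavior"}: \code{subjects}
#'   (per-subject proportion and extra harm), \code{prop_mean},
#'   \code{prop_sd}, \code{t}, \code{df}, \code{p} (t test vs 0.5; t is
#'   \code{NaN} with a note when the between-subject SD is 0),
#'   \code{extra_harm_mean}, \code{extra_harm_sd}.
#' @examples
#' coh <- generate_cohort(n_subjects = 6, seed = 1)
#' rawlsian_choice_stats(coh)$prop_mean
#' @export
rawlsian_choice_stats <- function(cohort) {
  data <- if (inherits(cohort, "harm_cohort")) cohort$data else cohort
  if (is.null(data) || nrow(data) == 0) stop("empty cohort")
  if (anyNA(data$choice)) stop("every trial needs an implemented option")
  dtot <- data$c_group * data$n_group - data$c_one
  grp <- data$choice == "group"
  prop <- tapply(grp, data$subject, mean)
  extra <- tapply(dtot * grp, data$subject, mean)
  n <- length(prop)
  m <- mean(prop); s <- stats::sd(prop)
  if (n < 2 || s == 0) {
    t <- NaN; p <- NA_real_
    note <- "t undefined: fewer than 2 subjects or zero between-subject SD"
  } else {
    t <- (m - 0.5) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
    note <- NULL
  }
  structure(list(
    subjects = data.frame(subject = names(prop),
                          prop_rawlsian = as.numeric(prop),
                          extra_harm = as.numeric(extra)),
    prop_mean = m, prop_sd = s, t = t, df = n - 1, p = p,
    extra_harm_mean = mean(extra), extra_harm_sd = stats::sd(extra),
    note = note), class = "harm_behavior")
}

#' @export
print.harm_behavior <- function(x, ...) {
  cat(sprintf("Rawlsian choice proportion: M = %.2f, SD = %.2f, t(%d) = %.2f, p = %.3g\n",
              x$prop_mean, x$prop_sd, x$df, x$t, x$p))
  cat(sprintf("Extra total harm accepted: %.2f s (SD = %.2f)\n",
              x$extra_harm_mean, x$extra_harm_sd))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

# One-way repeated-measures ANOVA with Greenhouse-Geisser correction.
# Y: subjects x conditions matrix.  The GG epsilon is computed from the
# double-centered sample covariance of the condition scores.
rm_anova_gg <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions")
  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  F <- (ss_cond / df1) / (ss_err / df2)
  Sig <- stats::cov(Y)
  dc <- Sig - outer(rowMeans(Sig), rep(1, k)) -
    outer(rep(1, k), colMeans(Sig)) + mean(Sig)
  eps <- sum(diag(dc))^2 / (df1 * sum(dc^2))
  eps <- min(1, max(eps, 1 / df1))
  p_gg <- stats::pf(F, eps * df1, eps * df2, lower.tail = FALSE)
  list(F = F, df1 = df1, df2 = df2, gg_epsilon = eps,
       df1_gg = eps * df1, df2_gg = eps * df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE), p_gg = p_gg)
}

#' Default-condition effects on Rawlsian choice
#'
#' Computes per-condition Rawlsian choice rates, a one-way repeated-measures
#' ANOVA across the three default conditions with Greenhouse-Geisser
#' sphericity correction, the paired t tests between group-default and the
#' other conditions, and the paired t test of switch probability (choosing
#' against the default) between the one-default and group-default
#' conditions.
#'
#' @inheritParams rawlsian_choice_stats
#' @return list of class \code{"harm_default_effects"}: \code{rates}
#'   (subjects x conditions matrix of Rawlsian choice rates), \code{anova}
#'   (F, GG epsilon, corrected dfs, p), \code{paired} (data.frame of paired t
#'   contrasts), \code{switch} (t test of switch rates between default
#'   conditions plus the per-condition switch rates).
#' @export
default_effect_tests <- function(cohort) {
  data <- if (inherits(cohort, "harm_cohort")) cohort$data else cohort
  if (is.null(data$default_cond)) stop("cohort lacks a 'default_cond' column")
  conds <- default_conditions()
  have <- tapply(data$default_cond, data$subject,
                 function(x) all(conds %in% x))
  if (!all(have))
    stop("subjects missing a default condition: ",
         paste(names(have)[!have], collapse = ", "))
  grp <- data$choice == "group"
  rates <- tapply(grp, list(data$subject, data$default_cond), mean)
  rates <- rates[, conds, drop = FALSE]
  an <- rm_anova_gg(rates)
  pt_pair <- function(a, b) {
    tt <- stats::t.test(rates[, a], rates[, b], paired = TRUE)
    data.frame(contrast = paste(a, "vs", b),
               mean_diff = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }
  paired <- rbind(pt_pair("group_default", "none"),
                  pt_pair("group_default", "one_default"))
  # switch probability: acting against the default, defined only where a
  # default exists
  sw <- data$default_cond != "none" &
    ((data$default_cond == "one_default" & data$choice == "group") |
       (data$default_cond == "group_default" & data$choice == "one"))
  swrate <- tapply(sw[data$default_cond != "none"],
                   list(data$subject[data$default_cond != "none"],
                        data$default_cond[data$default_cond != "none"]),
                   mean)
  swrate <- swrate[, c("one_default", "group_default"), drop = FALSE]
  stt <- stats::t.test(swrate[, "one_default"], swrate[, "group_default"],
                       paired = TRUE)
  structure(list(rates = rates, anova = an, paired = paired,
                 switch = list(rates = swrate, t = unname(stt$statistic),
                               df = unname(stt$parameter), p = stt$p.value)),
            class = "harm_default_effects")
}

#' @export
print.harm_default_effects <- function(x, ...) {
  cat("Rawlsian choice rate by default condition (means):\n")
  print(round(colMeans(x$rates), 3))
  a <- x$anova
  cat(sprintf("RM-ANOVA (GG corrected): F(%.2f, %.2f) = %.2f, p = %.3g (epsilon = %.2f)\n",
              a$df1_gg, a$df2_gg, a$F, a$p_gg, a$gg_epsilon))
  print(format(x$paired, digits = 3), row.names = FALSE)
  cat(sprintf("Switch-rate t (one-default vs group-default): t(%d) = %.2f, p = %.3g\n",
              x$switch$df, x$switch$t, x$switch$p))
  invisible(x)
}
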