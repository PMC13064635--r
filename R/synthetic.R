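#' Default group-level generating distributions
#'
#' The generator draws subject parameters from
#' \itemize{
#'   \item \eqn{\alpha = \Phi(z)}, \eqn{z \sim N(\Phi^{-1}(0.95), 0.8)} -- a
#'     probit-normal centred so the group-level location maps to
#'     \eqn{\alpha = 0.95}, heavily Rawlsian;
#'   \item \eqn{\varphi \sim N(-10.03, 10)} seconds -- centred on the reported
#'     group mean with a between-subject spread wide enough that individual
#'     thresholds span negative to positive values;
#'   \item \eqn{\tau \sim LogNormal(\log 0.2, 0.5)} -- moderately
#'     deterministic choice on the seconds utility scale.
#' }
#' These spreads were calibrated once against the cohort-level behavioural
#' anchors (mean Rawlsian choice proportion near 0.59 with between-subject SD
#' near 0.20); see the methods vignette.
#'
#' @return named list with elements \code{alpha_probit_mean},
#'   \code{alpha_probit_sd}, \code{phi_mean}, \code{phi_sd},
#'   \code{log_tau_mean}, \code{log_tau_sd}.
#' @export
default_group_params <- function() {
  list(alpha_probit_mean = stats::qnorm(0.95), alpha_probit_sd = 0.8,
       phi_mean = -10.03, phi_sd = 10,
       log_tau_mean = log(0.2), log_tau_sd = 0.5)
}

#' Draw subject parameters from group-level distributions
#'
#' @param n_subjects number of subjects.
#' @param group_params list as returned by \code{\link{default_group_params}}.
#' @param seed integer seed.
#' @return data.frame with columns \code{subject}, \code{alpha}, \code{phi},
#'   \code{tau}.
#' @export
sample_subject_params <- function(n_subjects, group_params = default_group_params(),
                                  seed = NULL) {
  gp <- utils::modifyList(default_group_params(), as.list(group_params))
  if (gp$alpha_probit_sd < 0 || gp$phi_sd < 0 || gp$log_tau_sd < 0)
    stop("group-level scale parameters must be nonnegative")
  if (n_subjects < 1) stop("n_subjects must be positive")
  with_seed(seed, data.frame(
    subject = seq_len(n_subjects),
    alpha = stats::pnorm(stats::rnorm(n_subjects, gp$alpha_probit_mean,
                                      gp$alpha_probit_sd)),
    phi = stats::rnorm(n_subjects, gp$phi_mean, gp$phi_sd),
    tau = exp(stats::rnorm(n_subjects, gp$log_tau_mean, gp$log_tau_sd))))
}

#' Generate a synthetic cohort
#'
#' Draws subject parameters from the group distributions and simulates every
#' subject's choices on the design with the chosen model variant.  The
#' generator always records a response (inaction under a default is logged as
#' a choice of the default option upstream of this representation).
#'
#' @param n_subjects cohort size (default 68).
#' @param design a \code{\link{harm_design}}; defaults to the 150-trial design
#'   drawn under \code{seed}.
#' @param group_params see \code{\link{default_group_params}}.
#' @param model a \code{\link{harm_model}} used to simulate (default the
#'   winning full model).
#' @param seed integer seed controlling parameters, design and choices.
#' @return list of class \code{"harm_cohort"}: \code{params} (subject truth
#'   table), \code{data} (stacked per-subject trial table with \code{subject}
#'   and \code{choice} columns), \code{design}, \code{model}, \code{seed}.
#' @examples
#' coh <- generate_cohort(n_subjects = 4, seed = 1)
#' table(coh$data$choice)
#' @export
generate_cohort <- function(n_subjects = 68, design = NULL,
                            group_params = default_group_params(),
                            model = harm_model("full"), seed = 1L) {
  if (is.null(design)) design <- harm_design(seed = seed)
  validate_design(design, grid = sort(unique(c(design$c_one, design$c_group))),
                  group_sizes = sort(unique(design$n_group)))
  params <- sample_subject_params(n_subjects, group_params, seed = seed)
  data <- with_seed(seed + 1L, {
    do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      d <- simulate_choices(design, as.list(params[s, c("alpha", "phi", "tau")]),
                            model = model, seed = NULL)
      cbind(subject = s, d)
    }))
  })
  rownames(data) <- NULL
  structure(list(params = params, data = data, design = design,
                 model = model, seed = seed),
            class = "harm_cohort")
}

#' @export
print.harm_cohort <- function(x, ...) {
  cat("Synthetic harm-allocation cohort: ", nrow(x$params), " subjects x ",
      nrow(x$design), " trials (model '", x$model$variant, "', seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Generate synthetic voxelwise beta maps
#'
#' Emulates per-subject parametric-response maps (one beta per voxel per
#' subject) with a planted region whose response varies smoothly and
#' monotonically with the subject's agreeability threshold \eqn{\varphi}:
#' inside the plant, \code{beta = slope * phi + noise}, so subjects with
#' similar \eqn{\varphi} have similar planted-region responses by
#' construction.  All other voxels are independent Gaussian noise.
#'
#' @param phi numeric vector of subject agreeability values.
#' @param grid_dim integer length-3 voxel grid (default \code{c(20, 20, 20)}).
#' @param plant either \code{NULL} (no planted region) or a list with
#'   \code{corner} (1-based voxel coordinate of the region's lower corner),
#'   \code{size} (edge length, default 5) and \code{slope} (default 1).
#' @param noise_sd Gaussian noise SD added to every voxel (default 1).
#' @param seed integer seed.
#' @return matrix of class \code{"harm_betamaps"} (subjects x voxels) with
#'   attributes \code{grid_dim} and \code{plant_voxels} (linear indices of the
#'   planted region, or \code{integer(0)}).
#' @examples
#' bm <- generate_beta_maps(rnorm(6), grid_dim = c(8, 8, 8),
#'                          plant = list(corner = c(2, 2, 2), size = 3), seed = 1)
#' dim(bm)   # 6 x 512
#' @export
generate_beta_maps <- function(phi, grid_dim = c(20, 20, 20),
                               plant = list(corner = c(3, 3, 3), size = 5,
                                            slope = 1),
                               noise_sd = 1, seed = NULL) {
  stopifnot(length(grid_dim) == 3, all(grid_dim >= 1))
  n_vox <- prod(grid_dim)
  n_sub <- length(phi)
  plant_idx <- integer(0)
  if (!is.null(plant)) {
    size <- plant$size %||% 5
    slope <- plant$slope %||% 1
    hi <- plant$corner + size - 1L
    if (any(plant$corner < 1) || any(hi > grid_dim))
      stop("planted region extends outside the voxel grid")
    coords <- as.matrix(expand.grid(
      x = plant$corner[1]:hi[1], y = plant$corner[2]:hi[2],
      z = plant$corner[3]:hi[3]))
    plant_idx <- coords[, 1] + (coords[, 2] - 1L) * grid_dim[1] +
      (coords[, 3] - 1L) * grid_dim[1] * grid_dim[2]
  }
  B <- with_seed(seed, {
    B <- matrix(stats::rnorm(n_sub * n_vox, 0, noise_sd), n_sub, n_vox)
    if (length(plant_idx))
      B[, plant_idx] <- B[, plant_idx] + outer(slope * phi, rep(1, length(plant_idx)))
    B
  })
  structure(B, grid_dim = as.integer(grid_dim),
            plant_voxels = as.integer(plant_idx), class = "harm_betamaps")
}
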