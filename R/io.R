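#' Read and write trial and choice tables
#'
#' Designs and cohort choice datasets are stored as tab-separated text with a
#' header row.  Required columns: \code{c_one}, \code{c_group},
#'   \code{n_group}, \code{default_cond}; designs carry \code{trial},
#'   \code{pair_id}, \code{side_one}; choice data add \code{subject} and
#'   \code{choice}.  Reading validates the header and the design invariants
#'   and fails loudly on truncated or malformed files.
#'
#' @param x design or cohort data.frame.
#' @param path file path.
#' @return \code{read_design}/\code{read_choices} return the validated
#'   data.frame; writers return the path invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_design <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_design <- function(path) {
  x <- read_tsv_checked(path, c("trial", "c_one", "c_group", "n_group",
                                "default_cond"))
  validate_design(x, grid = sort(unique(c(x$c_one, x$c_group))),
                  group_sizes = sort(unique(x$n_group)))
  class(x) <- c("harm_design", "data.frame")
  x
}

#' @rdname table_io
#' @export
write_choices <- function(x, path) {
  if (inherits(x, "harm_cohort")) x <- x$data
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_choices <- function(path) {
  x <- read_tsv_checked(path, c("subject", "c_one", "c_group", "n_group",
                                "default_cond", "choice"))
  if (!all(x$choice %in% c("one", "group")))
    stop("parse error in ", path, ": choice must be 'one' or 'group'")
  x
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE),
                error = function(e) stop("parse error in ", path, ": ",
                                         conditionMessage(e)))
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("parse error in ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  if (nrow(x) == 0) stop("parse error in ", path, ": no data rows")
  x
}

#' Read and write beta maps as NIfTI volumes
#'
#' Beta maps (subjects x voxels with 3-D grid geometry) are stored as a 4-D
#' NIfTI volume (x, y, z, subject).  Round trips are voxel-exact.
#'
#' @param betas a \code{subjects x voxels} matrix with a \code{grid_dim}
#'   attribute (see \code{\link{generate_beta_maps}}).
#' @param path NIfTI file path (.nii or .nii.gz).
#' @return \code{read_beta_maps} returns the \code{"harm_betamaps"} matrix;
#'   the writer returns the path invisibly.
#' @export
write_beta_maps <- function(betas, path) {
  gd <- attr(betas, "grid_dim")
  if (is.null(gd)) stop("betas lack a 'grid_dim' attribute")
  arr <- array(t(as.matrix(betas)), dim = c(gd, nrow(betas)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname write_beta_maps
#' @export
read_beta_maps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- RNifti::readNifti(path)
  d <- dim(arr)
  if (length(d) != 4) stop("parse error in ", path, ": expected a 4-D volume")
  B <- t(matrix(arr, nrow = prod(d[1:3]), ncol = d[4]))
  structure(B, grid_dim = as.integer(d[1:3]), class = "harm_betamaps")
}

#' Write a voxelwise statistic map as NIfTI
#'
#' @param values per-voxel vector (e.g. coefficients or q-values).
#' @param grid_dim 3-D grid dimensions.
#' @param path output path.
#' @export
write_stat_map <- function(values, grid_dim, path) {
  stopifnot(prod(grid_dim) == length(values))
  RNifti::writeNifti(RNifti::asNifti(array(values, dim = grid_dim)), path)
  invisible(path)
}

#' Serialize and restore a hierarchical fit
#'
#' The posterior draws are written as plain-text tables (one CSV per
#' parameter block) with a JSON sidecar recording the model variant, sampler
#' settings, seed, subject ids and convergence diagnostics.  The pointwise
#' log-likelihood matrix is recomputed on load from the subject-level draws,
#' so the on-disk artifact stays compact.
#'
#' @param fit a \code{\link{fit_harmalloc}} object.
#' @param dir output directory (created if needed).
#' @return \code{read_fit} returns the restored \code{"harmalloc_fit"};
#'   the writer returns \code{dir} invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (par in names(fit$subject_draws))
    utils::write.csv(fit$subject_draws[[par]],
                     file.path(dir, paste0("draws_", par, ".csv")),
                     row.names = FALSE)
  utils::write.csv(fit$group_draws, file.path(dir, "draws_group.csv"),
                   row.names = FALSE)
  write_choices(fit$data, file.path(dir, "data.tsv"))
  meta <- list(variant = fit$model$variant, settings = fit$settings,
               seed = fit$seed, subject_ids = fit$subject_ids,
               diagnostics = list(rhat = as.list(fit$diagnostics$rhat),
                                  ess = as.list(fit$diagnostics$ess)))
  jsonlite::write_json(meta, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_fit
#' @export
read_fit <- function(dir) {
  meta_path <- file.path(dir, "fit.json")
  if (!file.exists(meta_path)) stop("not a fit directory: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  model <- harm_model(meta$variant)
  data <- read_choices(file.path(dir, "data.tsv"))
  subject_draws <- list()
  for (par in model$params) {
    f <- file.path(dir, paste0("draws_", par, ".csv"))
    if (file.exists(f)) {
      m <- as.matrix(utils::read.csv(f, check.names = FALSE))
      colnames(m) <- meta$subject_ids
      subject_draws[[par]] <- m
    }
  }
  group_draws <- as.matrix(utils::read.csv(file.path(dir, "draws_group.csv"),
                                           check.names = FALSE))
  subj <- match(data$subject, meta$subject_ids)
  dflt <- if (!is.null(data$default_cond))
    (data$default_cond == "one_default") - (data$default_cond == "group_default")
  else rep(0, nrow(data))
  settings <- meta$settings
  settings$priors <- as.list(settings$priors)
  structure(list(subject_draws = subject_draws, group_draws = group_draws,
                 log_lik = pointwise_loglik(subject_draws, model, data, subj, dflt),
                 diagnostics = list(rhat = unlist(meta$diagnostics$rhat),
                                    ess = unlist(meta$diagnostics$ess)),
                 data = data, subject_ids = meta$subject_ids, model = model,
                 settings = settings, seed = meta$seed),
            class = "harmalloc_fit")
}
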