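#' Default pipeline configuration
#'
#' Every seed, prior, sampler setting and threshold used by
#' \code{\link{run_pipeline}} is explicit here; values can be overridden by a
#' nested list or a YAML file with the same structure.
#'
#' @param fast if TRUE use the reduced sampler profile and a smaller cohort,
#'   intended for smoke tests.
#' @return nested named list.
#' @export
pipeline_config <- function(fast = FALSE) {
  list(
    seed = 1L,
    design = list(n_pairs = 50, grid_min = 30, grid_max = 180, grid_step = 10,
                  group_sizes = c(3, 4)),
    cohort = list(n_subjects = if (fast) 12 else 68,
                  group_params = default_group_params()),
    fit = list(variants = if (fast) c("full", "alpha0")
                          else c("full", "alpha0", "alpha1", "nophi"),
               settings = if (fast) fast_profile() else fit_settings()),
    recovery = list(n_subjects = if (fast) 12 else 68),
    isrsa = list(grid_dim = if (fast) c(10, 10, 10) else c(20, 20, 20),
                 plant = list(corner = c(3, 3, 3), size = 5, slope = 1),
                 noise_sd = 1, q = 0.05, min_cluster = 5, connectivity = 6))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(pipeline_config(), config %||% list())
}

need_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' needs missing input: ", path,
         " (run the upstream stage first)")
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages, writing every artifact (design, cohort,
#' fits, comparison table, recovery report, IS-RSA maps) under
#' \code{outdir} together with a JSON manifest of seeds, settings and
#' artifact hashes.  Stages are individually invokable and read their inputs
#' from \code{outdir}; a missing upstream artifact raises an error naming the
#' file.
#'
#' @param stages character vector among \code{"design"}, \code{"simulate"},
#'   \code{"fit"}, \code{"compare"}, \code{"behavior"}, \code{"recover"},
#'   \code{"isrsa"}, or \code{"all"}.
#' @param outdir output directory.
#' @param config configuration list or YAML path (see
#'   \code{\link{pipeline_config}}).
#' @param seed overrides \code{config$seed} if given.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(stages = "all", outdir = "harmalloc_out",
                         config = NULL, seed = NULL) {
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  all_stages <- c("design", "simulate", "fit", "compare", "behavior",
                  "recover", "isrsa")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else list()
  manifest$config <- cfg
  manifest$seeds <- list(base = cfg$seed)

  paths <- list(design = file.path(outdir, "design.tsv"),
                cohort = file.path(outdir, "cohort.tsv"),
                truths = file.path(outdir, "cohort_params.tsv"),
                fits = file.path(outdir, "fits"),
                comparison = file.path(outdir, "model_comparison.tsv"),
                behavior = file.path(outdir, "behavior.tsv"),
                recovery = file.path(outdir, "recovery.tsv"),
                betas = file.path(outdir, "beta_maps.nii.gz"),
                isrsa_coef = file.path(outdir, "isrsa_coef.nii.gz"),
                isrsa_q = file.path(outdir, "isrsa_q.nii.gz"),
                isrsa_clusters = file.path(outdir, "isrsa_clusters.tsv"))

  if ("design" %in% stages) {
    dc <- cfg$design
    des <- harm_design(n_pairs = dc$n_pairs,
                       grid = seq(dc$grid_min, dc$grid_max, by = dc$grid_step),
                       group_sizes = dc$group_sizes, seed = cfg$seed)
    write_design(des, paths$design)
  }
  if ("simulate" %in% stages) {
    des <- read_design(need_artifact(paths$design, "simulate"))
    coh <- generate_cohort(cfg$cohort$n_subjects, design = des,
                           group_params = cfg$cohort$group_params,
                           seed = cfg$seed)
    write_choices(coh, paths$cohort)
    utils::write.table(coh$params, paths$truths, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if ("fit" %in% stages) {
    data <- read_choices(need_artifact(paths$cohort, "fit"))
    dir.create(paths$fits, showWarnings = FALSE)
    for (v in cfg$fit$variants) {
      fit <- fit_harmalloc(data, model = harm_model(v),
                           settings = cfg$fit$settings, seed = cfg$seed)
      write_fit(fit, file.path(paths$fits, v))
    }
  }
  if ("compare" %in% stages) {
    fits <- lapply(cfg$fit$variants, function(v) {
      need_artifact(file.path(paths$fits, v, "fit.json"), "compare")
      read_fit(file.path(paths$fits, v))
    })
    names(fits) <- cfg$fit$variants
    cmp <- compare_models(lapply(fits, psis_loo))
    utils::write.table(as.data.frame(cmp), paths$comparison, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if ("behavior" %in% stages) {
    data <- read_choices(need_artifact(paths$cohort, "behavior"))
    bs <- rawlsian_choice_stats(data)
    de <- default_effect_tests(data)
    tab <- data.frame(
      statistic = c("prop_rawlsian_mean", "prop_rawlsian_sd", "t_vs_chance",
                    "extra_harm_mean", "extra_harm_sd", "anova_F",
                    "anova_df1_gg", "anova_df2_gg", "anova_p_gg",
                    "switch_t", "switch_p"),
      value = c(bs$prop_mean, bs$prop_sd, bs$t, bs$extra_harm_mean,
                bs$extra_harm_sd, de$anova$F, de$anova$df1_gg,
                de$anova$df2_gg, de$anova$p_gg, de$switch$t, de$switch$p))
    utils::write.table(tab, paths$behavior, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if ("recover" %in% stages) {
    des <- read_design(need_artifact(paths$design, "recover"))
    rec <- parameter_recovery(cfg$recovery$n_subjects, design = des,
                              group_params = cfg$cohort$group_params,
                              settings = cfg$fit$settings, seed = cfg$seed)
    utils::write.table(rec$summary, paths$recovery, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if ("isrsa" %in% stages) {
    truths <- read_tsv_checked(need_artifact(paths$truths, "isrsa"),
                               c("subject", "alpha", "phi", "tau"))
    ic <- cfg$isrsa
    betas <- generate_beta_maps(truths$phi, grid_dim = ic$grid_dim,
                                plant = ic$plant, noise_sd = ic$noise_sd,
                                seed = cfg$seed)
    write_beta_maps(betas, paths$betas)
    res <- isrsa(betas, truths$phi, truths$alpha, q = ic$q,
                 min_cluster = ic$min_cluster,
                 connectivity = ic$connectivity)
    write_stat_map(res$voxels$estimate, ic$grid_dim, paths$isrsa_coef)
    write_stat_map(res$voxels$q, ic$grid_dim, paths$isrsa_q)
    utils::write.table(res$voxels[res$voxels$cluster > 0, ],
                       paths$isrsa_clusters, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  done <- intersect(names(paths), c(
    if ("design" %in% stages) "design",
    if ("simulate" %in% stages) c("cohort", "truths"),
    if ("compare" %in% stages) "comparison",
    if ("behavior" %in% stages) "behavior",
    if ("recover" %in% stages) "recovery",
    if ("isrsa" %in% stages) c("betas", "isrsa_coef", "isrsa_q",
                               "isrsa_clusters")))
  manifest$artifacts <- lapply(paths[done], function(p)
    list(path = p, md5 = as.character(tools::md5sum(p))))
  manifest$stages_run <- stages
  manifest$timestamp <- NULL  # manifests are content-addressed, not timestamped
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
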