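#' Run the full inference protocol on a perturbation dataset
#'
#' The single entry point that chains the whole pipeline on a real or
#' synthetic dataset: read the TSV trio (or take an in-memory dataset),
#' optionally select \eqn{(\beta, \lambda)} by target connectivity, run
#' Belief Propagation, instantiate and refine a ranked model ensemble by
#' BP-guided decimation, export the average network and marginals, and
#' optionally run leave-k-out cross-validation and the in silico
#' perturbation screen. All outputs land in \code{out_dir} together with a
#' manifest carrying the seed and configuration hash.
#'
#' @param config a named list, or path to a YAML/JSON file with the same
#'   structure. Recognized fields: \code{data} (list of \code{x}, \code{u},
#'   \code{roles} paths, or a [perturbation_data()]), \code{grid} (list
#'   \code{low}, \code{high}, \code{step}), \code{bp} (arguments to
#'   [bp_control()]), \code{select} (NULL or arguments to
#'   [select_hyperparameters()]), \code{ensemble} (\code{n_generate},
#'   \code{n_keep}, \code{refine}), \code{cv} (NULL or TRUE/list; needs
#'   \code{design}), \code{screen} (NULL or list with \code{mode},
#'   \code{strength}, \code{targets}), \code{design} (a
#'   [design_perturbations()] object for cross-validation), \code{seed},
#'   \code{out_dir}.
#' @return invisible list with components \code{data}, \code{control},
#'   \code{fit}, \code{ensemble}, \code{avg}, \code{cv}, \code{screen}.
#' @export
run_protocol <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs needs the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  seed <- config$seed %||% 1
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  data <- config$data
  if (!inherits(data, "perturbation_data"))
    data <- read_perturbation_data(data$x, data$u, data$roles)
  g <- config$grid %||% list(low = -1, high = 1, step = 0.2)
  grid <- value_grid(g$low, g$high, g$step)
  control <- do.call(bp_control, c(config$bp %||% list(), list(seed = seed)))
  if (!is.null(config$select))
    control <- do.call(select_hyperparameters,
                       c(list(data = data, grid = grid, control = control),
                         config$select))
  fit <- bp_infer(data, grid, control)
  ens_cfg <- config$ensemble %||% list()
  refine_ctl <- do.call(refine_control, config$refine %||% list())
  ensemble <- generate_ensemble(
    data, grid, control,
    n_generate = ens_cfg$n_generate %||% 100,
    n_keep = ens_cfg$n_keep %||% 10,
    refine = ens_cfg$refine %||% TRUE,
    refine_ctl = refine_ctl,
    seed = seed, fit = fit)
  avg <- average_network(ensemble)
  cv <- NULL
  if (!is.null(config$cv) && !identical(config$cv, FALSE)) {
    if (is.null(config$design))
      stop("cross-validation needs the perturbation design")
    cv_cfg <- if (is.list(config$cv)) config$cv else list()
    cv <- leave_k_out_cv(data, config$design, grid, control,
                         n_generate = cv_cfg$n_generate %||%
                           (ens_cfg$n_generate %||% 100),
                         n_keep = cv_cfg$n_keep %||% (ens_cfg$n_keep %||% 10),
                         refine = cv_cfg$refine %||%
                           (ens_cfg$refine %||% TRUE),
                         refine_ctl = refine_ctl,
                         drugs = cv_cfg$drugs,
                         seed = seed)
  }
  screen <- NULL
  if (!is.null(config$screen) && !identical(config$screen, FALSE)) {
    sc <- if (is.list(config$screen)) config$screen else list()
    screen <- insilico_screen(ensemble, targets = sc$targets,
                              mode = sc$mode %||% "clamp",
                              strength = sc$strength %||% -1)
  }
  if (!is.null(out_dir)) {
    export_marginals(fit, file.path(out_dir, "marginals.tsv"))
    export_network(avg, file.path(out_dir, "average_network.sif"), "sif")
    export_network(avg, file.path(out_dir, "average_network.graphml"),
                   "graphml")
    write_ensemble(ensemble, file.path(out_dir, "ensemble"), config = config)
    if (!is.null(cv))
      utils::write.table(cv$pairs, file.path(out_dir, "cv_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(screen))
      utils::write.table(screen$ranking, file.path(out_dir, "screen.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed,
           config_hash = config_hash(config),
           grid = as.numeric(grid),
           beta = control$beta, lambda = control$lambda,
           n_models_kept = length(ensemble$models),
           cv_correlation = if (!is.null(cv)) cv$correlation else NULL,
           outputs = list.files(out_dir)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(data = data, control = control, fit = fit,
                 ensemble = ensemble, avg = avg, cv = cv, screen = screen))
}
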