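#' Average network over a model ensemble
#'
#' Entry-wise mean of the interaction matrices of the kept models, plus the
#' per-edge frequency of being nonzero. The average network is a summary
#' object for interpretation and export only: it is not executable, and
#' mutually exclusive interactions (present with opposite signs in
#' different models) average towards zero while keeping high frequency.
#'
#' @param x a [generate_ensemble()] ensemble.
#' @param ... unused.
#' @return object of class \code{"average_network"} with \code{mean_W},
#'   \code{edge_frequency}, \code{nodes}, \code{roles}, \code{n_models}.
#' @export
average_network <- function(x, ...) UseMethod("average_network")

#' @export
average_network.model_ensemble <- function(x, ...) {
  stopifnot(length(x$models) >= 1)
  Ws <- lapply(x$models, function(m) m$W)
  mean_W <- Reduce(`+`, Ws) / length(Ws)
  freq <- Reduce(`+`, lapply(Ws, function(w) (w != 0) * 1)) / length(Ws)
  structure(list(mean_W = mean_W, edge_frequency = freq,
                 nodes = x$models[[1]]$nodes, roles = x$models[[1]]$roles,
                 n_models = length(Ws)),
            class = "average_network")
}

#' @export
print.average_network <- function(x, threshold = 0.2, ...) {
  cat(sprintf("Average network over %d models: %d edges with |mean| >= %.2g\n",
              x$n_models, sum(abs(x$mean_W) >= threshold), threshold))
  invisible(x)
}

#' @export
plot.average_network <- function(x, threshold = 0.2, ...) {
  plot_signed_network(x$mean_W, x$nodes, x$roles, threshold = threshold,
                      main = "average network", ...)
}

infer_matrix <- function(inferred) {
  if (inherits(inferred, "bp_fit")) return(coef(inferred))
  if (inherits(inferred, "average_network")) return(inferred$mean_W)
  if (inherits(inferred, "network_model")) return(inferred$W)
  as.matrix(inferred)
}

#' Recall and precision against a data-generating network
#'
#' An edge is called when its inferred mean magnitude reaches
#' \code{threshold} (0.2 by default, the representative-network cut). A true
#' positive must also match the sign of the generating edge; a called edge
#' with the wrong sign counts as both a false positive and a false negative.
#' Recall = TP / (number of true edges); precision = TP / (number of calls);
#' with no calls at all, precision is reported as 1 with the
#' \code{no_calls} flag set.
#'
#' @param inferred inferred strengths: matrix, [bp_infer()] fit,
#'   [average_network()] or [network_model()].
#' @param truth the generating [network_model()] (or matrix).
#' @param threshold magnitude cut for calling an edge.
#' @return object of class \code{"benchmark_report"} with \code{recall},
#'   \code{precision}, counts, and \code{false_positives} /
#'   \code{false_negatives} edge tables (columns target, source).
#' @export
recall_precision <- function(inferred, truth, threshold = 0.2) {
  W_inf <- infer_matrix(inferred)
  W_true <- if (inherits(truth, "network_model")) truth$W else as.matrix(truth)
  if (!all(dim(W_inf) == dim(W_true))) stop("node sets differ")
  off <- row(W_true) != col(W_true)
  called <- off & abs(W_inf) >= threshold
  true_e <- off & W_true != 0
  sign_ok <- sign(W_inf) == sign(W_true)
  tp <- called & true_e & sign_ok
  fp <- called & !tp
  fn <- true_e & !tp
  n_true <- sum(true_e); n_called <- sum(called)
  no_calls <- n_called == 0
  report <- list(
    recall = if (n_true) sum(tp) / n_true else 1,
    precision = if (no_calls) 1 else sum(tp) / n_called,
    tp = sum(tp), fp = sum(fp), fn = sum(fn),
    n_true = n_true, n_called = n_called, no_calls = no_calls,
    false_positives = as.data.frame(which(fp, arr.ind = TRUE),
                                    row.names = FALSE),
    false_negatives = as.data.frame(which(fn, arr.ind = TRUE),
                                    row.names = FALSE),
    threshold = threshold, motif_labels = NULL)
  names(report$false_positives) <- names(report$false_negatives) <-
    c("target", "source")
  class(report) <- "benchmark_report"
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark: recall %.3f (%d/%d), precision %.3f (%d/%d calls)%s\n",
              x$recall, x$tp, x$n_true, x$precision, x$tp, x$n_called,
              if (x$no_calls) " [no calls]" else ""))
  if (!is.null(x$motif_labels)) {
    tab <- table(x$motif_labels$label)
    cat("  false-positive motifs:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify false-positive edges by compensatory motif
#'
#' Relates each false-positive inferred edge A -> C to the structure of the
#' generating network: \code{upstream} if the truth contains a two-step path
#' A -> B -> C; \code{symmetric} if the truth contains the reversed edge
#' C -> A; \code{co_regulation} if some node regulates both A and C;
#' \code{near_zero} if the marginal's mass at zero exceeds
#' \code{zero_mass_cut} (so the edge barely counts as called); otherwise
#' \code{unexplained}. Labels use that precedence.
#'
#' @param report a [recall_precision()] report.
#' @param truth the generating [network_model()].
#' @param fit optional [bp_infer()] fit supplying zero-probability masses.
#' @param zero_mass_cut threshold for the \code{near_zero} label.
#' @return the report with \code{motif_labels} filled (data.frame target,
#'   source, label).
#' @export
classify_compensatory_motifs <- function(report, truth, fit = NULL,
                                         zero_mass_cut = 0.5) {
  stopifnot(inherits(report, "benchmark_report"))
  W <- if (inherits(truth, "network_model")) truth$W else as.matrix(truth)
  A <- W != 0
  fp <- report$false_positives
  lab <- character(nrow(fp))
  for (r in seq_len(nrow(fp))) {
    ci <- fp$target[r]; ai <- fp$source[r]   # inferred edge ai -> ci
    two_step <- any(A[, ai] & A[ci, ])       # ai -> b and b -> ci
    if (two_step) { lab[r] <- "upstream"; next }
    if (A[ai, ci]) { lab[r] <- "symmetric"; next }
    if (any(A[ai, ] & A[ci, ])) { lab[r] <- "co_regulation"; next }
    if (!is.null(fit)) {
      p0 <- fit$P[ci, ai, which(as.numeric(fit$grid) == 0)]
      if (p0 > zero_mass_cut) { lab[r] <- "near_zero"; next }
    }
    lab[r] <- "unexplained"
  }
  report$motif_labels <- cbind(fp, label = lab)
  report
}

#' Leave-k-out cross-validation over drugs
#'
#' For each drug, withholds every condition involving it except its
#' low-dose single-agent condition (by default the high-dose single is also
#' withheld; set \code{keep_high_single} to restore it to the training set),
#' trains a fresh model ensemble on the remaining conditions, simulates the
#' withheld force columns with every kept model, and compares the
#' ensemble-averaged predictions with the withheld observations.
#'
#' @param data a [perturbation_data()] aligned with \code{design}.
#' @param design the [design_perturbations()] object describing which drugs
#'   each condition involves.
#' @param grid,control,n_generate,n_keep,refine,refine_ctl,seed ensemble
#'   training settings (see [generate_ensemble()]).
#' @param keep_high_single keep the high-dose single in training.
#' @param drugs optional subset of drug identifiers to hold out (default:
#'   every drug in the design).
#' @param sigma experimental standard deviation used to flag outliers;
#'   defaults to the standard deviation of the prediction deviations.
#' @return object of class \code{"cv_report"}: \code{pairs} (drug, node,
#'   condition, observed, predicted), pooled Pearson \code{correlation},
#'   \code{cv_error} (root mean squared prediction error per data point),
#'   \code{mae}, and \code{outliers}.
#' @export
leave_k_out_cv <- function(data, design, grid = value_grid(),
                           control = bp_control(), n_generate = 20,
                           n_keep = 10, refine = TRUE,
                           refine_ctl = refine_control(), seed = 1,
                           keep_high_single = FALSE, drugs = NULL,
                           sigma = NULL) {
  stopifnot(inherits(design, "perturbation_design"))
  cond <- design$conditions
  keep_cols <- match(data$conditions, cond$label)
  if (anyNA(keep_cols)) stop("dataset conditions not found in the design")
  cond <- cond[keep_cols, ]
  drug_ids <- sort(unique(unlist(strsplit(cond$drugs, ","))))
  if (!is.null(drugs)) {
    drugs <- as.character(drugs)
    if (!all(drugs %in% drug_ids)) stop("unknown drug identifiers")
    drug_ids <- drugs
  }
  measured <- data$roles != "activity"
  pairs <- list()
  for (d in drug_ids) {
    involves <- vapply(strsplit(cond$drugs, ","), function(z) d %in% z, TRUE)
    is_single <- cond$type == "single" & cond$drugs == d
    low_dose <- min(cond$dose[is_single])
    keep_solo <- is_single & cond$dose == low_dose
    if (keep_high_single) keep_solo <- is_single
    if (!any(keep_solo)) stop("drug ", d, " has no single-agent condition")
    test <- involves & !keep_solo
    if (!any(test)) next
    train <- !test
    train_data <- perturbation_data(data$X[, train, drop = FALSE],
                                    data$U[, train, drop = FALSE],
                                    roles = data$roles, nodes = data$nodes,
                                    conditions = data$conditions[train])
    ens <- generate_ensemble(train_data, grid, control,
                             n_generate = n_generate, n_keep = n_keep,
                             refine = refine, refine_ctl = refine_ctl,
                             seed = seed)
    pred <- predict(ens, u = data$U[, test, drop = FALSE])
    obs <- data$X[, test, drop = FALSE]
    pairs[[d]] <- data.frame(
      drug = d,
      node = rep(data$nodes[measured], sum(test)),
      condition = rep(data$conditions[test], each = sum(measured)),
      observed = as.vector(obs[measured, ]),
      predicted = as.vector(pred[measured, ]))
  }
  pairs <- do.call(rbind, c(pairs, make.row.names = FALSE))
  dev <- pairs$predicted - pairs$observed
  sigma <- sigma %||% stats::sd(dev)
  out <- list(pairs = pairs,
              correlation = stats::cor(pairs$observed, pairs$predicted),
              cv_error = sqrt(mean(dev^2)),
              mae = mean(abs(dev)),
              sigma = sigma,
              outliers = pairs[abs(dev) > sigma, ],
              n_drugs = length(drug_ids))
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Leave-k-out cross-validation over %d drugs: %d prediction pairs\n",
              x$n_drugs, nrow(x$pairs)))
  cat(sprintf("  pooled correlation %.3f; RMS error per point %.3f; MAE %.3f\n",
              x$correlation, x$cv_error, x$mae))
  cat(sprintf("  outliers beyond 1 sigma (%.3f): %d\n", x$sigma,
              nrow(x$outliers)))
  invisible(x)
}

#' In silico perturbation screen over a model ensemble
#'
#' Simulates, for each candidate target node and each ensemble model, a
#' virtual inhibition of that node and records the steady-state response of
#' the phenotype node(s). In \code{"clamp"} mode (default) the target is
#' held at \code{strength} (\eqn{-1}, the log2 of a 50\% knockdown)
#' throughout the simulation; in \code{"force"} mode a constant external
#' force \eqn{u = \mathrm{atanh}(strength \cdot \alpha/\epsilon)} is applied,
#' calibrated so an isolated node settles at \code{strength} (clamping is
#' the default because the saturating response cannot reach \eqn{-1} under
#' finite force when \eqn{\epsilon/\alpha = 1}). Targets are ranked by mean
#' predicted phenotype change; non-convergent simulations are excluded and
#' counted.
#'
#' @param ensemble a [generate_ensemble()] ensemble (refined, executable).
#' @param targets candidate nodes (names or indices); default all protein
#'   nodes.
#' @param mode \code{"clamp"} or \code{"force"}.
#' @param strength perturbed value (clamp) or calibrated response (force).
#' @param phenotype phenotype node(s); default all role == "phenotype".
#' @return object of class \code{"screen_report"}: \code{responses} (targets
#'   x models matrix of phenotype changes, one per phenotype node),
#'   \code{ranking} data.frame sorted by mean effect, \code{n_excluded}.
#' @export
insilico_screen <- function(ensemble, targets = NULL,
                            mode = c("clamp", "force"), strength = -1,
                            phenotype = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "model_ensemble"))
  proto <- ensemble$models[[1]]
  if (is.null(phenotype)) phenotype <- proto$nodes[proto$roles == "phenotype"]
  if (!length(phenotype)) stop("no phenotype node in the models")
  ph_idx <- match(phenotype, proto$nodes)
  if (is.null(targets)) targets <- proto$nodes[proto$roles == "protein"]
  tg_idx <- if (is.character(targets)) match(targets, proto$nodes)
            else as.integer(targets)
  if (anyNA(tg_idx)) stop("unknown target node")
  nm <- length(ensemble$models)
  res <- array(NA_real_, c(length(tg_idx), nm, length(ph_idx)),
               dimnames = list(proto$nodes[tg_idx], NULL, phenotype))
  n_excluded <- 0L
  for (g in seq_len(nm)) {
    mdl <- ensemble$models[[g]]
    for (t in seq_along(tg_idx)) {
      ti <- tg_idx[t]
      if (mode == "clamp") {
        cl <- stats::setNames(strength, mdl$nodes[ti])
        tr <- steady_state(mdl, u = 0, clamp = cl)
      } else {
        arg <- strength * mdl$alpha[ti] / mdl$epsilon[ti]
        if (abs(arg) >= 1)
          stop("force mode cannot reach the requested response (saturation)")
        u <- numeric(n_nodes(mdl)); u[ti] <- atanh(arg)
        tr <- steady_state(mdl, u = u)
      }
      if (tr$converged) res[t, g, ] <- tr$final[ph_idx]
      else n_excluded <- n_excluded + 1L
    }
  }
  mean_eff <- apply(res[, , 1, drop = FALSE], 1, mean, na.rm = TRUE)
  ranking <- data.frame(target = proto$nodes[tg_idx],
                        mean_change = mean_eff,
                        sd_change = apply(res[, , 1, drop = FALSE], 1,
                                          stats::sd, na.rm = TRUE))
  ranking <- ranking[order(ranking$mean_change), ]
  rownames(ranking) <- NULL
  structure(list(responses = res, ranking = ranking,
                 phenotype = phenotype, mode = mode, strength = strength,
                 n_excluded = n_excluded),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, n = 5, ...) {
  cat(sprintf("In silico screen (%s mode, strength %.2f): %d targets x %d models\n",
              x$mode, x$strength, nrow(x$ranking), dim(x$responses)[2]))
  if (x$n_excluded) cat("  excluded non-convergent simulations:",
                        x$n_excluded, "\n")
  cat("  strongest predicted phenotype reductions:\n")
  print(utils::head(x$ranking, n), digits = 3)
  invisible(x)
}
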