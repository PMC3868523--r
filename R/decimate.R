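#' Sample one (edge, value) pair from marginal mass
#'
#' Draws an (edge, value) pair with probability proportional to the joint
#' marginal mass \eqn{P(w_{ij} = \omega)} over all unfrozen edges. This is
#' the elementary move of BP-guided decimation; sampling the pair jointly
#' subsumes both the "edge first, then value" and the joint reading of the
#' procedure.
#'
#' @param P N x N x K array of edge marginals.
#' @param frozen N x N logical matrix; frozen edges are never selected.
#' @param grid the [value_grid()] matching the third dimension of \code{P}.
#' @return list with \code{i} (target), \code{j} (source), \code{k} (grid
#'   index) and \code{value}.
#' @export
sample_edge_value <- function(P, frozen, grid) {
  stopifnot(length(dim(P)) == 3, all(dim(P)[1:2] == dim(frozen)))
  sel <- !frozen
  if (!any(sel)) stop("no unfrozen edges remain")
  mass <- P
  mass[!array(sel, dim(P))] <- 0   # logical recycles over k
  tot <- sum(mass)
  if (tot <= 0) stop("all unfrozen mass is zero")
  idx <- sample.int(length(mass), 1, prob = as.vector(mass))
  ak <- arrayInd(idx, dim(P))
  list(i = ak[1], j = ak[2], k = ak[3], value = as.numeric(grid)[ak[3]])
}

#' One decimation step on a BP fit
#'
#' Samples an (edge, value) pair from the fit's marginals, freezes that edge
#' to a point mass at the sampled value, and returns the updated fit (marked
#' as needing a BP re-run).
#'
#' @param fit a [bp_infer()] fit.
#' @return list with \code{edge} (target, source), \code{value}, and the
#'   updated \code{fit}.
#' @export
decimation_step <- function(fit) {
  frozen <- !fit$edge_mask
  for (nm in names(fit$state$rows)) {
    row <- fit$state$rows[[nm]]
    frozen[row$target, row$sources[row$fixed]] <- TRUE
  }
  pick <- sample_edge_value(fit$P, frozen, fit$grid)
  nm <- fit$data$nodes[pick$i]
  row <- fit$state$rows[[nm]]
  s <- match(pick$j, row$sources)
  fit$state$rows[[nm]]$fixed[s] <- TRUE
  fit$state$rows[[nm]]$fixed_val[s] <- pick$value
  fit$P[pick$i, pick$j, ] <- as.numeric(fit$grid == pick$value)
  list(edge = c(target = pick$i, source = pick$j), value = pick$value,
       fit = fit)
}

# Decimate one row to a fully fixed configuration, re-running BP (warm
# started from the current factors) after every fix. Returns the fixed
# values, the trace and convergence bookkeeping.
decimate_row <- function(row, data, grid, control, gh) {
  trace_j <- integer(0); trace_w <- numeric(0); resweeps <- integer(0)
  flagged <- FALSE
  repeat {
    res <- bp_row_run(row, data, grid, control, gh)
    if (!res$converged && control$damping == 0) {
      ctl2 <- control; ctl2$damping <- 0.5
      res2 <- bp_row_run(row, data, grid, ctl2, gh)
      if (res2$converged) res <- res2 else flagged <- TRUE
    } else if (!res$converged) flagged <- TRUE
    row$logF <- array(res$logF, dim(row$logF))
    open <- which(!row$fixed)
    if (!length(open)) {
      return(list(values = row$fixed_val, sources = row$sources,
                  trace_j = trace_j, trace_w = trace_w,
                  resweeps = resweeps, flagged = flagged,
                  logF = row$logF))
    }
    mass <- res$marg[open, , drop = FALSE]
    idx <- sample.int(length(mass), 1, prob = as.vector(mass))
    s <- open[(idx - 1) %% length(open) + 1]
    k <- (idx - 1) %/% length(open) + 1
    row$fixed[s] <- TRUE
    row$fixed_val[s] <- as.numeric(grid)[k]
    trace_j <- c(trace_j, row$sources[s])
    trace_w <- c(trace_w, as.numeric(grid)[k])
    resweeps <- c(resweeps, res$sweeps)
  }
}

#' Instantiate one explicit network model by BP-guided decimation
#'
#' Alternates sampling an (edge, value) pair from the current marginals with
#' a warm-started BP re-run until every free edge is fixed, yielding one
#' discrete interaction matrix drawn from the high-probability region of
#' model space. Because rows are decoupled, decimation proceeds
#' row-independently, which factorizes the joint sampling process exactly.
#'
#' @param fit a converged [bp_infer()] fit.
#' @param seed seed for the decimation randomness (same seed, same model).
#' @param control a [bp_control()]; defaults to the fit's.
#' @return list with \code{model} (a [network_model()], \eqn{\alpha=\epsilon=1})
#'   and \code{trace} (data.frame with target, source, value in fixing order,
#'   BP re-convergence sweeps, and a non-convergence flag).
#' @export
instantiate_model <- function(fit, seed = 1, control = NULL) {
  stopifnot(inherits(fit, "bp_fit"))
  control <- control %||% fit$control
  gh <- gauss_hermite(control$quadrature_order)
  n <- length(fit$data$nodes)
  W <- matrix(0, n, n)
  trace <- list()
  for (nm in names(fit$state$rows)) {
    row <- fit$state$rows[[nm]]
    set.seed(row_seed(seed, row$target))
    dec <- decimate_row(row, fit$data, fit$grid, control, gh)
    W[row$target, dec$sources] <- dec$values
    trace[[nm]] <- data.frame(target = row$target, source = dec$trace_j,
                              value = dec$trace_w, sweeps = dec$resweeps,
                              flagged = dec$flagged)
  }
  trace <- do.call(rbind, c(trace, make.row.names = FALSE))
  model <- network_model(W, nodes = fit$data$nodes, roles = fit$data$roles)
  attr(model, "seed") <- seed
  list(model = model, trace = trace)
}

#' Generate a ranked ensemble of explicit network models
#'
#' Runs BP once, instantiates \code{n_generate} models by decimation with
#' distinct seeds, optionally refines each by gradient descent on the fully
#' simulated steady-state error, ranks models by training error and keeps the
#' best \code{n_keep}. The shipped protocol for real data generates 1000 and
#' keeps 100; scale down for toys.
#'
#' @param data a [perturbation_data()].
#' @param grid a [value_grid()].
#' @param control a [bp_control()].
#' @param n_generate number of models to instantiate.
#' @param n_keep number of lowest-error models to retain.
#' @param refine refine each model with [refine_model()]?
#' @param refine_ctl a [refine_control()].
#' @param seed base seed; member seeds are \code{seed + 1:n_generate}.
#' @param fit optional precomputed [bp_infer()] fit to decimate from.
#' @return object of class \code{"model_ensemble"}: kept \code{models},
#'   matching \code{train_errors} (non-decreasing), \code{traces},
#'   \code{seeds}, and the error of every generated model in
#'   \code{all_errors}.
#' @export
generate_ensemble <- function(data, grid = value_grid(),
                              control = bp_control(), n_generate = 20,
                              n_keep = 10, refine = TRUE,
                              refine_ctl = refine_control(), seed = 1,
                              fit = NULL) {
  stopifnot(n_keep <= n_generate, n_generate >= 1)
  fit <- fit %||% bp_infer(data, grid, control)
  seeds <- seed + seq_len(n_generate)
  models <- vector("list", n_generate)
  traces <- vector("list", n_generate)
  errors <- numeric(n_generate)
  for (g in seq_len(n_generate)) {
    inst <- instantiate_model(fit, seed = seeds[g], control = control)
    model <- inst$model
    if (refine) {
      ref <- refine_model(model, data, refine_ctl)
      model <- ref$model
      errors[g] <- ref$error
    } else {
      errors[g] <- ensemble_train_error(model, data)
    }
    models[[g]] <- model
    traces[[g]] <- inst$trace
  }
  ord <- order(errors)[seq_len(n_keep)]
  structure(list(models = models[ord], train_errors = errors[ord],
                 traces = traces[ord], seeds = seeds[ord],
                 all_errors = sort(errors), n_generate = n_generate,
                 refined = refine, ranked = TRUE, fit = fit),
            class = "model_ensemble")
}

# Training error of a model: squared error of the fully simulated steady
# states against the observed responses (the error term of the
# configuration cost, with full coupling).
ensemble_train_error <- function(model, data, tol = 1e-8) {
  pred <- simulate_all_conditions(model, data$U, tol = tol)
  sum((pred$X - data$X)^2)
}

# Steady-state simulation of every condition using the fast fixed-point
# solver with ODE fallback; returns predictions and convergence flags.
simulate_all_conditions <- function(model, U, tol = 1e-8) {
  m <- ncol(U)
  X <- matrix(NA_real_, n_nodes(model), m)
  conv <- logical(m)
  for (mu in seq_len(m)) {
    fp <- steady_state_fp(model, u = U[, mu], tol = tol * 1e-2)
    if (fp$converged) {
      X[, mu] <- fp$x
      conv[mu] <- TRUE
    } else {
      tr <- steady_state(model, u = U[, mu], tol = tol)
      X[, mu] <- tr$final
      conv[mu] <- tr$converged
    }
  }
  list(X = X, converged = conv)
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("Model ensemble: %d kept of %d generated (%s)\n",
              length(x$models), x$n_generate,
              if (x$refined) "refined" else "discrete"))
  cat(sprintf("  train errors: %.4g .. %.4g\n",
              min(x$train_errors), max(x$train_errors)))
  invisible(x)
}

#' Predict ensemble-averaged responses to perturbations
#'
#' Simulates each kept model to steady state under the given force columns
#' and averages the predictions across the ensemble.
#'
#' @param object a [generate_ensemble()] ensemble.
#' @param u N x M matrix of external forces (one column per condition).
#' @param ... unused.
#' @return N x M matrix of ensemble-mean predicted responses; per-model
#'   predictions in attribute \code{"members"}.
#' @export
predict.model_ensemble <- function(object, u, ...) {
  u <- as.matrix(u)
  preds <- lapply(object$models, function(mdl)
    simulate_all_conditions(mdl, u)$X)
  avg <- Reduce(`+`, preds) / length(preds)
  rownames(avg) <- object$models[[1]]$nodes
  colnames(avg) <- colnames(u)
  structure(avg, members = preds)
}
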