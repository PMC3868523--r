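#' Executable nonlinear network model
#'
#' Constructs the dynamical model
#' \deqn{dx_i/dt = \epsilon_i \tanh\Big(\sum_{j \ne i} w_{ij} x_j + u_i\Big) - \alpha_i x_i,}
#' where \eqn{x_i} is the log2-ratio response of node \eqn{i} relative to the
#' unperturbed control, \eqn{w_{ij}} the signed influence of node \eqn{j} on
#' the rate of change of node \eqn{i}, \eqn{u_i} a constant external force
#' encoding a drug perturbation, \eqn{\alpha_i > 0} the restoration rate
#' towards the unperturbed state and \eqn{\epsilon_i > 0} the saturation
#' scale of the sigmoidal response.
#'
#' Self-interactions are forbidden (\code{diag(W) == 0}); the decay term
#' \eqn{-\alpha_i x_i} plays that role. Activity nodes (unmeasured stand-ins
#' for the biochemical activity of a drug target) may not have upstream
#' regulators, so their rows of \code{W} must be identically zero.
#'
#' @param W N x N interaction matrix, \code{W[i, j]} = influence of node j on
#'   node i (units: inverse pseudo-time).
#' @param alpha,epsilon positive restoration rates / saturation scales,
#'   recycled to length N.
#' @param nodes node names; defaults to \code{rownames(W)} or \code{n1..nN}.
#' @param roles per-node role, one of \code{"protein"}, \code{"phenotype"},
#'   \code{"activity"}; defaults to all \code{"protein"}.
#' @return An object of class \code{"network_model"}.
#' @seealso [steady_state()], [predict.network_model()], [model_cost()]
#' @export
network_model <- function(W, alpha = 1, epsilon = 1, nodes = NULL, roles = NULL) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (ncol(W) != n) stop("W must be square")
  if (any(!is.finite(W))) stop("W must be finite")
  if (any(diag(W) != 0)) stop("self-interactions are forbidden: diag(W) must be 0")
  if (is.null(nodes)) nodes <- rownames(W)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  if (anyDuplicated(nodes)) stop("node names must be unique")
  if (length(nodes) != n) stop("length(nodes) must match nrow(W)")
  if (is.null(roles)) roles <- rep("protein", n)
  roles <- match.arg(as.character(roles), c("protein", "phenotype", "activity"),
                     several.ok = TRUE)
  if (length(roles) == 1L) roles <- rep(roles, n)
  if (length(roles) != n) stop("length(roles) must match nrow(W)")
  act <- roles == "activity"
  if (any(act) && any(W[act, , drop = FALSE] != 0))
    stop("activity nodes may not have incoming edges: rows of W must be 0")
  alpha <- rep_len(as.numeric(alpha), n)
  epsilon <- rep_len(as.numeric(epsilon), n)
  if (any(alpha <= 0) || any(epsilon <= 0)) stop("alpha and epsilon must be > 0")
  dimnames(W) <- list(nodes, nodes)
  structure(list(W = W, alpha = alpha, epsilon = epsilon,
                 nodes = nodes, roles = roles),
            class = "network_model")
}

n_nodes <- function(model) length(model$nodes)

#' @export
print.network_model <- function(x, ...) {
  nz <- sum(x$W != 0)
  cat(sprintf("Network model: %d nodes, %d edges (%.2f per node)\n",
              n_nodes(x), nz, nz / n_nodes(x)))
  tab <- table(factor(x$roles, c("protein", "phenotype", "activity")))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (all(x$alpha == 1) && all(x$epsilon == 1)) {
    cat("  alpha = epsilon = 1 (inference scale)\n")
  } else {
    cat(sprintf("  alpha in [%.3g, %.3g], epsilon in [%.3g, %.3g]\n",
                min(x$alpha), max(x$alpha), min(x$epsilon), max(x$epsilon)))
  }
  invisible(x)
}

#' @export
coef.network_model <- function(object, ...) object$W

#' Right-hand side of the network ODE
#'
#' Evaluates \eqn{dx_i/dt = \epsilon_i \tanh(\sum_j w_{ij} x_j + u_i) - \alpha_i x_i}.
#' The external force enters inside the sigmoid, so an isolated node under
#' constant force settles at \eqn{(\epsilon/\alpha)\tanh(u)}.
#'
#' @param model a [network_model()].
#' @param x numeric state vector of length N.
#' @param u external force vector, recycled to length N.
#' @return numeric vector \eqn{dx/dt}.
#' @export
model_rhs <- function(model, x, u = 0) {
  n <- n_nodes(model)
  if (length(x) != n) stop("length(x) must equal the number of nodes")
  u <- rep_len(u, n)
  if (any(!is.finite(x)) || any(!is.finite(u))) stop("x and u must be finite")
  unname(model$epsilon * tanh(drop(model$W %*% x) + u) - model$alpha * x)
}

#' Encode a drug's effect on an activity node
#'
#' Drug strength is quantified from the residual level of a presumed
#' downstream effector: if the effector retains a fraction \code{residual_fraction}
#' of its untreated level, the external force on the activity node is
#' \eqn{u = \log_2(\mathrm{residual})} and the node's basal perturbed value is
#' \eqn{x = (\epsilon/\alpha)\tanh(u)}. For a 55\% residual with
#' \eqn{\alpha = \epsilon = 1} this gives \eqn{u = -0.863}, \eqn{x = -0.697}.
#'
#' @param residual_fraction treated/untreated effector ratio in (0, 1].
#' @param alpha,epsilon node parameters (default 1).
#' @return list with components \code{u} and \code{x}.
#' @export
encode_activity_node <- function(residual_fraction, alpha = 1, epsilon = 1) {
  if (!is.numeric(residual_fraction) || any(residual_fraction <= 0))
    stop("residual_fraction must be > 0")
  u <- log2(residual_fraction)
  list(u = u, x = (epsilon / alpha) * tanh(u))
}

#' Assemble the node set for a drug-perturbation study
#'
#' Combines measured proteomic readouts, phenotype readouts and one
#' unmeasured activity node per drug into the node table of a model. A study
#' with 16 (phospho)protein readouts, one viability phenotype and 8 drugs
#' yields a 25-node model.
#'
#' @param readouts character vector of measured protein/phospho-protein names.
#' @param phenotypes character vector of phenotype readouts (e.g. "viability").
#' @param drugs character vector of drug/target names; each contributes an
#'   activity node exported with prefix \code{"a"}.
#' @return data.frame with columns \code{name}, \code{role}, \code{label}.
#' @export
build_node_set <- function(readouts, phenotypes = character(), drugs = character()) {
  df <- rbind(
    if (length(readouts)) data.frame(name = readouts, role = "protein",
                                     label = readouts),
    if (length(phenotypes)) data.frame(name = phenotypes, role = "phenotype",
                                       label = phenotypes),
    if (length(drugs)) data.frame(name = drugs, role = "activity",
                                  label = paste0("a", drugs))
  )
  if (anyDuplicated(df$name)) stop("node names must be unique")
  rownames(df) <- NULL
  df
}

#' Cost weights for model configurations
#'
#' Weights of the configuration cost
#' \eqn{C(W) = \beta \sum_{i,\mu} (\hat x_i^\mu - x_i^{\mu*})^2 + \lambda \,\#\{w_{ij} \ne 0\}},
#' i.e. a squared steady-state error term plus an L0 complexity penalty.
#' \code{error_weight} is the inverse temperature of the Boltzmann
#' probability model over configurations; \code{complexity_weight} is the
#' per-edge sparsity penalty.
#'
#' @param error_weight positive weight on the squared error term.
#' @param complexity_weight positive weight per nonzero edge.
#' @export
cost_config <- function(error_weight = 2, complexity_weight = 5) {
  stopifnot(error_weight > 0, complexity_weight > 0)
  structure(list(error_weight = error_weight,
                 complexity_weight = complexity_weight),
            class = "cost_config")
}

#' Configuration cost of a model on a perturbation dataset
#'
#' Computes the steady-state-approximation cost: squared residuals of the
#' decoupled fixed-point prediction (observed neighbour values substituted on
#' the right-hand side) plus the L0 penalty on nonzero off-diagonal entries.
#'
#' @param model a [network_model()].
#' @param data a [perturbation_data()] with matching nodes.
#' @param config a [cost_config()].
#' @return scalar cost.
#' @export
model_cost <- function(model, data, config = cost_config()) {
  xhat <- predict(model, newdata = data, type = "decoupled")
  err <- sum((xhat - data$X)^2)
  nz <- sum(model$W != 0)  # diagonal is structurally zero
  config$error_weight * err + config$complexity_weight * nz
}

#' Predict steady-state responses of a network model
#'
#' Two prediction modes. \code{type = "decoupled"} evaluates the approximate
#' fixed-point equation \eqn{\hat x_i = (\epsilon_i/\alpha_i)\tanh(\sum_j
#' w_{ij} x_j^{\mu*} + u_i^\mu)} using the \emph{observed} neighbour values
#' from \code{newdata} (the decoupling used during inference).
#' \code{type = "steady"} runs the fully coupled simulation to steady state
#' for each perturbation column and is self-consistent.
#'
#' @param object a [network_model()].
#' @param newdata a [perturbation_data()] (required for \code{"decoupled"});
#'   for \code{"steady"} either a dataset or a force matrix \code{u}.
#' @param type prediction mode.
#' @param u optional N x M force matrix for \code{"steady"} when no dataset
#'   is given.
#' @param tol,t_max steady-state tolerances passed to [steady_state()].
#' @param ... unused.
#' @return N x M matrix of predicted responses. For \code{"steady"} the
#'   attributes \code{converged} and \code{oscillatory} flag each column.
#' @export
predict.network_model <- function(object, newdata = NULL,
                                  type = c("decoupled", "steady"),
                                  u = NULL, tol = 1e-8, t_max = 1e4, ...) {
  type <- match.arg(type)
  if (type == "decoupled") {
    if (is.null(newdata)) stop("'decoupled' prediction needs observed data")
    stopifnot(inherits(newdata, "perturbation_data"))
    if (nrow(newdata$X) != n_nodes(object)) stop("node dimension mismatch")
    s <- object$W %*% newdata$X + newdata$U
    out <- (object$epsilon / object$alpha) * tanh(s)
    dimnames(out) <- dimnames(newdata$X)
    return(out)
  }
  U <- if (!is.null(newdata)) newdata$U else u
  if (is.null(U)) stop("'steady' prediction needs a dataset or a force matrix u")
  U <- as.matrix(U)
  if (nrow(U) != n_nodes(object)) stop("node dimension mismatch")
  m <- ncol(U)
  out <- matrix(NA_real_, n_nodes(object), m,
                dimnames = list(object$nodes, colnames(U)))
  conv <- osc <- logical(m)
  for (mu in seq_len(m)) {
    tr <- steady_state(object, u = U[, mu], tol = tol, t_max = t_max)
    out[, mu] <- tr$final
    conv[mu] <- tr$converged
    osc[mu] <- tr$oscillatory
  }
  structure(out, converged = conv, oscillatory = osc)
}

#' Residuals of a network model against observed responses
#'
#' @param object a [network_model()].
#' @param data a [perturbation_data()].
#' @param type \code{"decoupled"} (fixed-point with observed neighbours) or
#'   \code{"steady"} (full simulation).
#' @param ... passed to [predict.network_model()].
#' @return N x M matrix of residuals (predicted minus observed).
#' @export
residuals.network_model <- function(object, data, type = "decoupled", ...) {
  predict(object, newdata = data, type = type, ...) - data$X
}

#' Simulate measured responses from a network model
#'
#' Simulates steady-state responses to the perturbations in \code{u} and
#' optionally applies multiplicative measurement noise, producing \code{nsim}
#' replicate response matrices.
#'
#' @param object a [network_model()].
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param u N x M force matrix (one column per condition).
#' @param noise_cv coefficient of variation of multiplicative Gaussian noise
#'   (0 = noise-free).
#' @param ... passed to [predict.network_model()].
#' @return a list of \code{nsim} response matrices (a single matrix if
#'   \code{nsim = 1}).
#' @export
simulate.network_model <- function(object, nsim = 1, seed = NULL,
                                   u, noise_cv = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  clean <- predict(object, type = "steady", u = u, ...)
  if (noise_cv == 0 && nsim == 1) return(clean)
  reps <- lapply(seq_len(nsim), function(k) add_noise(clean, cv = noise_cv))
  if (nsim == 1) reps[[1]] else reps
}

#' @export
plot.network_model <- function(x, threshold = 0, ...) {
  plot_signed_network(x$W, x$nodes, x$roles, threshold = threshold, ...)
}

plot_signed_network <- function(W, nodes, roles, threshold = 0,
                                main = "network", ...) {
  keep <- which(abs(W) > threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(keep)) {
    # W[i, j] is j -> i
    g <- igraph::add_edges(g, rbind(keep[, 2], keep[, 1]))
    w <- W[keep]
    igraph::E(g)$color <- ifelse(w > 0, "forestgreen", "firebrick")
    igraph::E(g)$width <- 1 + 2 * abs(w) / max(abs(w))
  }
  shape <- c(protein = "circle", phenotype = "square", activity = "circle")
  igraph::V(g)$shape <- unname(shape[roles])
  igraph::V(g)$color <- ifelse(roles == "activity", "gold", "skyblue")
  plot(g, main = main, edge.arrow.size = 0.4, ...)
  invisible(g)
}
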