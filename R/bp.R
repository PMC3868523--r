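#' Control parameters for Belief Propagation
#'
#' @param beta inverse temperature of the Boltzmann probability model over
#'   configurations (weight on squared steady-state error). The shipped
#'   default operating point is \code{beta = 2}, \code{lambda = 5}.
#' @param lambda sparsity prior weight: each parameter carries a factor
#'   \eqn{e^{\lambda \delta(w = 0)}} favouring zero.
#' @param tol convergence threshold on the maximum absolute change of final
#'   marginals between consecutive sweeps.
#' @param max_sweeps maximum number of sweeps; one sweep visits every
#'   (source, condition) cavity of a row once, in seeded random order.
#' @param quadrature_order Gauss-Hermite order for the Gaussian cavity-field
#'   integral.
#' @param damping mixing weight in \eqn{[0, 1)} of the old factor into each
#'   update; 0 by default, useful as a rescue for non-convergent runs.
#' @param seed integer seed controlling factor initialization and update
#'   schedules; identical seed and configuration give identical marginals.
#' @param engine \code{"cpp"} (compiled sweep engine, default) or \code{"r"}
#'   (reference implementation, identical arithmetic).
#' @param forbid_phenotype_out if TRUE, phenotype nodes may not have outgoing
#'   edges; by default they may both receive and emit edges.
#' @return object of class \code{"bp_control"}.
#' @export
bp_control <- function(beta = 2, lambda = 5, tol = 1e-6, max_sweeps = 200,
                       quadrature_order = 20, damping = 0, seed = 1,
                       engine = c("cpp", "r"), forbid_phenotype_out = FALSE) {
  engine <- match.arg(engine)
  stopifnot(beta >= 0, lambda >= 0, tol > 0, max_sweeps >= 1,
            quadrature_order >= 1, quadrature_order <= 128,
            damping >= 0, damping < 1)
  structure(list(beta = beta, lambda = lambda, tol = tol,
                 max_sweeps = max_sweeps, quadrature_order = quadrature_order,
                 damping = damping, seed = as.integer(seed), engine = engine,
                 forbid_phenotype_out = forbid_phenotype_out),
            class = "bp_control")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gauss_hermite <- function(order) {
  gh <- pracma::gaussHermite(order)
  list(x = gh$x, w = gh$w)
}

row_seed <- function(seed, i) {
  (abs(seed) * 1009 + i * 7919) %% 2147483646 + 1
}

sparsity_prior <- function(grid, lambda) ifelse(grid == 0, lambda, 0)

#' Initialize a belief state
#'
#' Creates the per-(source, condition) factor tables \eqn{\rho^\mu(w_{ij})}
#' for every inferable row, drawn from a seeded uniform-random simplex.
#' Structural constraints are encoded by construction: no self-edges, no
#' edges into activity nodes (their rows are not represented at all) and,
#' optionally, no edges out of phenotype nodes.
#'
#' @param data a [perturbation_data()].
#' @param grid a [value_grid()].
#' @param seed RNG seed.
#' @param forbid_phenotype_out drop phenotype nodes from candidate sources.
#' @return object of class \code{"belief_state"}.
#' @export
init_beliefs <- function(data, grid = value_grid(), seed = 1,
                         forbid_phenotype_out = FALSE) {
  stopifnot(inherits(data, "perturbation_data"))
  grid <- as_grid(grid)
  n <- length(data$nodes); m <- length(data$conditions); K <- length(grid)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n)) {
    if (data$roles[i] == "activity") next
    src <- setdiff(seq_len(n), i)
    if (forbid_phenotype_out)
      src <- src[data$roles[src] != "phenotype"]
    S <- length(src)
    arr <- array(stats::runif(S * m * K), c(S, m, K))
    tot <- apply(arr, c(1, 2), sum)             # S x m
    logF <- log(arr / as.vector(tot))           # recycles over k
    if (m == 0) logF <- array(numeric(0), c(S, 0, K))
    rows[[data$nodes[i]]] <- list(target = i, sources = src, logF = logF,
                                  fixed = rep(FALSE, S),
                                  fixed_val = numeric(S))
  }
  structure(list(rows = rows, grid = grid, nodes = data$nodes,
                 roles = data$roles, conditions = data$conditions,
                 forbid_phenotype_out = forbid_phenotype_out, seed = seed),
            class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  nf <- sum(vapply(x$rows, function(r) sum(!r$fixed), 0L))
  cat(sprintf("Belief state: %d inferable rows, %d free edges, %d conditions, K = %d\n",
              length(x$rows), nf, length(x$conditions), length(x$grid)))
  invisible(x)
}

node_index <- function(state, node) {
  if (is.character(node)) {
    i <- match(node, state$nodes)
    if (is.na(i)) stop("unknown node: ", node)
    i
  } else as.integer(node)
}

#' Cavity marginal of an edge parameter
#'
#' The prior times the product of all factors of edge (source -> target),
#' optionally excluding one condition's factor (the "cavity" condition),
#' normalized. With no factors this reduces to the sparsity prior, which
#' puts mass \eqn{e^\lambda / (e^\lambda + K - 1)} on zero.
#'
#' @param state a [init_beliefs()] belief state.
#' @param target,source node names or indices (edge source -> target).
#' @param exclude_condition condition index to exclude, or NULL for the final
#'   marginal.
#' @param lambda sparsity prior weight.
#' @return length-K probability vector.
#' @export
cavity_marginal <- function(state, target, source, exclude_condition = NULL,
                            lambda = 5) {
  i <- node_index(state, target)
  row <- state$rows[[state$nodes[i]]]
  if (is.null(row)) stop("node ", state$nodes[i], " has no inferable row")
  s <- match(node_index(state, source), row$sources)
  if (is.na(s)) stop("not a candidate source for this row")
  K <- length(state$grid)
  if (row$fixed[s]) {
    p <- numeric(K)
    p[which.min(abs(state$grid - row$fixed_val[s]))] <- 1
    return(p)
  }
  if (any(!is.finite(row$logF[s, , ])) && dim(row$logF)[2] > 0)
    stop("factors contain non-finite values")
  q <- if (dim(row$logF)[2] == 0) numeric(K) else colSums(matrix(row$logF[s, , ],
                                                                 ncol = K))
  if (!is.null(exclude_condition))
    q <- q - row$logF[s, exclude_condition, ]
  q <- q + sparsity_prior(state$grid, lambda)
  p <- exp(q - max(q))
  p / sum(p)
}

#' Gaussian summary of the aggregate cavity field
#'
#' Mean and variance of \eqn{h = \sum_{t \ne i, t \ne j} w_{it} x_t^{\mu*}},
#' the aggregate contribution of the non-cavity parameters, with moments
#' taken under each parameter's cavity marginal (condition \eqn{\mu}
#' excluded). By the central limit theorem \eqn{h} is treated as Gaussian in
#' the local update integral.
#'
#' @param state a belief state.
#' @param target,cavity_source edge being updated (source -> target).
#' @param condition cavity condition index.
#' @param data the [perturbation_data()] providing observed values.
#' @param lambda sparsity prior weight.
#' @return list with \code{mean_h} and \code{var_h}.
#' @export
cavity_field_stats <- function(state, target, cavity_source, condition, data,
                               lambda = 5) {
  i <- node_index(state, target)
  row <- state$rows[[state$nodes[i]]]
  j <- node_index(state, cavity_source)
  mh <- 0; vh <- 0
  for (s in seq_along(row$sources)) {
    t <- row$sources[s]
    if (t == j) next
    p <- cavity_marginal(state, i, t, exclude_condition = condition,
                         lambda = lambda)
    m <- sum(p * state$grid)
    v <- max(sum(p * state$grid^2) - m^2, 0)
    x <- data$X[t, condition]
    mh <- mh + m * x
    vh <- vh + v * x^2
  }
  list(mean_h = mh, var_h = vh)
}

#' Local cavity update of one factor
#'
#' Computes the updated factor \eqn{\rho^\mu(w_{ij})} for the cavity edge
#' (source -> target) and condition \eqn{\mu}:
#' \deqn{\rho^\mu(\omega) \propto \int N(h; \bar h, \sigma_h^2)\,
#'   e^{-\beta (x_i^{\mu*} - \tanh(h + \omega x_j^{\mu*} + u_i^\mu))^2}\, dh,}
#' evaluated by Gauss-Hermite quadrature (point evaluation when the cavity
#' field is degenerate). This calls the same compiled kernel used by the
#' sweep engine.
#'
#' @param state a belief state.
#' @param target,cavity_source edge being updated.
#' @param condition cavity condition index.
#' @param data the [perturbation_data()].
#' @param control a [bp_control()].
#' @return length-K probability vector (the new factor; the state is not
#'   modified).
#' @export
factor_update <- function(state, target, cavity_source, condition, data,
                          control = bp_control()) {
  i <- node_index(state, target)
  row <- state$rows[[state$nodes[i]]]
  if (is.null(row)) stop("node has no inferable row")
  s <- match(node_index(state, cavity_source), row$sources)
  if (is.na(s) || row$fixed[s]) stop("edge is not free")
  gh <- gauss_hermite(control$quadrature_order)
  cpp_bp_update(data$X[row$sources, , drop = FALSE],
                data$X[i, ], data$U[i, ], as.numeric(state$grid),
                as.numeric(row$logF), as.integer(row$fixed), row$fixed_val,
                as.integer(s), as.integer(condition),
                control$beta, control$lambda, control$damping, gh$x, gh$w)
}

# Reference sweep engine in R; mirrors the arithmetic and schedule of
# cpp_bp_row exactly (shared sampler), used to validate the compiled path.
r_bp_row <- function(Xs, xi, ui, omega, logF, fixed, fixed_val, beta, lambda,
                     tol, max_sweeps, damping, ghx, ghw, sampler) {
  S <- nrow(Xs); M <- ncol(Xs); K <- length(omega)
  prior <- sparsity_prior(omega, lambda)
  logF <- array(logF, c(S, M, K))
  free_src <- which(!fixed)
  nfree <- length(free_src); npairs <- nfree * M
  rebuild <- function() {
    if (M == 0) return(matrix(0, S, K))
    apply(logF, c(1, 3), sum)
  }
  marg <- function(Ssum) {
    P <- matrix(0, S, K)
    for (t in seq_len(S)) {
      if (fixed[t]) {
        P[t, which.min(abs(omega - fixed_val[t]))] <- 1
      } else {
        z <- Ssum[t, ] + prior
        p <- exp(z - max(z))
        P[t, ] <- p / sum(p)
      }
    }
    P
  }
  lse <- function(l) { lm <- max(l); log(sum(exp(l - lm))) + lm }
  Ssum <- rebuild()
  Pprev <- marg(Ssum)
  converged <- npairs == 0
  sweeps <- 0L; delta <- 0
  sweep <- 0L
  while (sweep < max_sweeps && !converged) {
    sweep <- sweep + 1L
    Ssum <- rebuild()
    perm <- sampler(npairs)
    for (p in perm) {
      s <- free_src[(p - 1) %% nfree + 1]
      mu <- (p - 1) %/% nfree + 1
      mh <- 0; vh <- 0
      for (t in seq_len(S)) {
        if (t == s) next
        if (fixed[t]) { m <- fixed_val[t]; v <- 0 }
        else {
          q <- Ssum[t, ] - logF[t, mu, ] + prior
          pr <- exp(q - max(q)); Z <- sum(pr)
          m <- sum(pr * omega) / Z
          v <- max(sum(pr * omega^2) / Z - m^2, 0)
        }
        mh <- mh + m * Xs[t, mu]
        vh <- vh + v * Xs[t, mu]^2
      }
      if (vh < 1e-14) {
        L <- -beta * (xi[mu] - tanh(mh + omega * Xs[s, mu] + ui[mu]))^2
      } else {
        sv <- sqrt(2 * vh)
        L <- vapply(seq_len(K), function(k) {
          a <- -beta * (xi[mu] - tanh(mh + sv * ghx + omega[k] * Xs[s, mu] +
                                        ui[mu]))^2
          am <- max(a)
          log(sum(ghw * exp(a - am))) + am
        }, numeric(1))
      }
      L <- L - lse(L)
      if (damping > 0)
        L <- log((1 - damping) * exp(L) + damping * exp(logF[s, mu, ]))
      Ssum[s, ] <- Ssum[s, ] + L - logF[s, mu, ]
      logF[s, mu, ] <- L
    }
    P <- marg(Ssum)
    delta <- max(abs(P - Pprev))
    Pprev <- P
    sweeps <- sweep
    if (delta < tol) converged <- TRUE
  }
  list(logF = logF, marg = Pprev, sweeps = sweeps, converged = converged,
       delta = delta)
}

bp_row_run <- function(row, data, grid, control, gh) {
  Xs <- data$X[row$sources, , drop = FALSE]
  xi <- data$X[row$target, ]
  ui <- data$U[row$target, ]
  sampler <- function(n) sample.int(n)
  if (control$engine == "cpp") {
    cpp_bp_row(Xs, xi, ui, as.numeric(grid), as.numeric(row$logF),
               as.integer(row$fixed), row$fixed_val,
               control$beta, control$lambda, control$tol,
               as.integer(control$max_sweeps), control$damping,
               gh$x, gh$w, sampler)
  } else {
    r_bp_row(Xs, xi, ui, as.numeric(grid), row$logF, row$fixed,
             row$fixed_val, control$beta, control$lambda, control$tol,
             control$max_sweeps, control$damping, gh$x, gh$w, sampler)
  }
}

#' Infer edge-parameter marginals by Belief Propagation
#'
#' The main fitting function. Works in the steady-state decoupling: each row
#' of the interaction matrix is inferred independently, replacing
#' model-predicted neighbour values by the observed ones, with
#' \eqn{\alpha = \epsilon = 1}. Per row, per-condition factors over the
#' discrete value grid are updated in seeded random order with the Gaussian
#' mean-field cavity update until the final marginals change by less than
#' \code{control$tol} between consecutive sweeps.
#'
#' @param data a [perturbation_data()].
#' @param grid a [value_grid()] of allowed edge values.
#' @param control a [bp_control()].
#' @param init optional [init_beliefs()] state (e.g. a partially decimated
#'   one); defaults to a fresh seeded random initialization.
#' @return An object of class \code{"bp_fit"} with the per-edge marginals
#'   \code{P} (N x N x K array; structurally forbidden edges are point
#'   masses at zero), their means \code{mean_W} (extract with \code{coef()}),
#'   the final belief \code{state}, and per-row convergence diagnostics.
#' @seealso [coef.bp_fit()], [representative_network()], [marginal_entropy()],
#'   [instantiate_model()], [generate_ensemble()]
#' @export
bp_infer <- function(data, grid = value_grid(), control = bp_control(),
                     init = NULL) {
  stopifnot(inherits(data, "perturbation_data"))
  grid <- as_grid(grid)
  state <- init %||% init_beliefs(data, grid, seed = control$seed,
                                  forbid_phenotype_out = control$forbid_phenotype_out)
  if (!identical(as.numeric(state$grid), as.numeric(grid)))
    stop("grid of the initial belief state does not match")
  gh <- gauss_hermite(control$quadrature_order)
  n <- length(data$nodes); K <- length(grid)
  k0 <- which(grid == 0)
  P <- array(0, c(n, n, K), dimnames = list(data$nodes, data$nodes, NULL))
  P[, , k0] <- 1
  edge_mask <- matrix(FALSE, n, n, dimnames = list(data$nodes, data$nodes))
  converged <- sweeps <- stats::setNames(rep(NA, length(state$rows)),
                                         names(state$rows))
  for (nm in names(state$rows)) {
    row <- state$rows[[nm]]
    set.seed(row_seed(control$seed, row$target))
    res <- bp_row_run(row, data, grid, control, gh)
    state$rows[[nm]]$logF <- array(res$logF,
                                   dim(state$rows[[nm]]$logF))
    for (s in seq_along(row$sources))
      P[row$target, row$sources[s], ] <- res$marg[s, ]
    edge_mask[row$target, row$sources] <- TRUE
    converged[nm] <- res$converged
    sweeps[nm] <- res$sweeps
  }
  mean_W <- matrix(0, n, n, dimnames = list(data$nodes, data$nodes))
  for (k in seq_len(K)) mean_W <- mean_W + P[, , k] * grid[k]
  mean_W[!edge_mask] <- 0
  structure(list(P = P, mean_W = mean_W, edge_mask = edge_mask, grid = grid,
                 control = control, state = state, data = data,
                 converged = converged, sweeps = sweeps,
                 call = match.call()),
            class = "bp_fit")
}

#' @export
print.bp_fit <- function(x, threshold = 0.2, ...) {
  n <- length(x$data$nodes)
  called <- sum(abs(x$mean_W) >= threshold)
  cat(sprintf("BP fit: %d nodes, %d conditions, K = %d\n",
              n, length(x$data$conditions), length(x$grid)))
  cat(sprintf("  rows converged: %d / %d (max sweeps used: %d)\n",
              sum(x$converged), length(x$converged), max(x$sweeps, 0)))
  cat(sprintf("  edges with |mean| >= %.2g: %d (%.2f per inferable node)\n",
              threshold, called, called / max(length(x$converged), 1)))
  invisible(x)
}

#' Extract mean interaction strengths from a BP fit
#'
#' @param object a [bp_infer()] fit.
#' @param ... unused.
#' @return N x N matrix of marginal means \eqn{\sum_k \Omega_k P(w_{ij} = \Omega_k)}.
#' @export
coef.bp_fit <- function(object, ...) object$mean_W

#' @export
summary.bp_fit <- function(object, threshold = 0.2, ...) {
  H <- marginal_entropy(object)
  out <- list(n_nodes = length(object$data$nodes),
              n_conditions = length(object$data$conditions),
              K = length(object$grid),
              converged = object$converged,
              sweeps = object$sweeps,
              threshold = threshold,
              n_called = sum(abs(object$mean_W) >= threshold),
              connectivity = sum(abs(object$mean_W) >= threshold) /
                max(length(object$converged), 1),
              mean_entropy = mean(H[object$edge_mask]))
  class(out) <- "summary.bp_fit"
  out
}

#' @export
print.summary.bp_fit <- function(x, ...) {
  cat(sprintf("BP fit summary: %d nodes, %d conditions, K = %d\n",
              x$n_nodes, x$n_conditions, x$K))
  cat(sprintf("  converged rows: %d/%d; sweeps: %s\n", sum(x$converged),
              length(x$converged), paste(range(x$sweeps), collapse = "-")))
  cat(sprintf("  edges called at %.2g: %d (connectivity %.2f)\n",
              x$threshold, x$n_called, x$connectivity))
  cat(sprintf("  mean normalized marginal entropy: %.3f\n", x$mean_entropy))
  invisible(x)
}

#' @export
plot.bp_fit <- function(x, ...) {
  w <- x$mean_W
  lim <- max(abs(w), 1e-9)
  cols <- grDevices::colorRampPalette(c("firebrick", "white", "forestgreen"))(61)
  graphics::image(seq_len(ncol(w)), seq_len(nrow(w)),
                  t(w[rev(seq_len(nrow(w))), , drop = FALSE]),
                  zlim = c(-lim, lim), col = cols,
                  xlab = "source j", ylab = "target i",
                  main = "BP mean interaction strengths", axes = FALSE, ...)
  graphics::box()
  invisible(x)
}

#' @export
predict.bp_fit <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$data
  tanh(object$mean_W %*% newdata$X + newdata$U)
}

#' Shannon entropy of edge marginals
#'
#' Per-edge entropy of the BP marginals, normalized by \eqn{\log K} so a
#' point mass scores 0 and a uniform marginal scores 1. In \code{"sign"}
#' mode the marginal is first collapsed to (negative, zero, positive) masses
#' and normalized by \eqn{\log 3}.
#'
#' @param fit a [bp_infer()] fit.
#' @param collapse \code{"full"} or \code{"sign"}.
#' @return N x N matrix of normalized entropies (NA on structurally
#'   forbidden edges).
#' @export
marginal_entropy <- function(fit, collapse = c("full", "sign")) {
  collapse <- match.arg(collapse)
  grid <- fit$grid
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  n <- dim(fit$P)[1]
  H <- matrix(NA_real_, n, n, dimnames = dimnames(fit$mean_W))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!fit$edge_mask[i, j]) next
    p <- fit$P[i, j, ]
    if (collapse == "sign") {
      p <- c(sum(p[grid < 0]), sum(p[grid == 0]), sum(p[grid > 0]))
      H[i, j] <- ent(p) / log(3)
    } else {
      H[i, j] <- ent(p) / log(length(grid))
    }
  }
  H
}

#' Representative network from BP marginals
#'
#' Assigns each free edge its most probable grid value (ties broken towards
#' the smallest magnitude), then zeroes values with \eqn{|w| <} \code{threshold}.
#'
#' @param fit a [bp_infer()] fit.
#' @param threshold magnitude below which edges are set to zero (default 0.2).
#' @return a [network_model()] with \eqn{\alpha = \epsilon = 1}.
#' @export
representative_network <- function(fit, threshold = 0.2) {
  grid <- as.numeric(fit$grid)
  n <- dim(fit$P)[1]
  W <- matrix(0, n, n)
  ord <- order(abs(grid), grid)   # smallest |omega| first for tie-breaking
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!fit$edge_mask[i, j]) next
    p <- fit$P[i, j, ord]
    cand <- which(p >= max(p) - 1e-12)  # ties go to the smallest |omega|
    W[i, j] <- grid[ord][cand[1]]
  }
  W[abs(W) < threshold] <- 0
  network_model(W, nodes = fit$data$nodes, roles = fit$data$roles)
}

#' Select BP hyperparameters by target connectivity
#'
#' Runs BP on a lattice of \eqn{(\beta, \lambda)} values, builds the
#' representative network for each, and returns the configuration with the
#' lowest decoupled squared error among those whose connectivity (called
#' edges per inferable node) lies within \code{band} of
#' \code{target_connectivity} (about 1.5 edges per node for sparse signaling
#' networks). If no configuration lands in the band, the nearest-connectivity
#' one is returned with a warning.
#'
#' @param data a [perturbation_data()].
#' @param grid a [value_grid()].
#' @param beta_range,lambda_range candidate values (search lattice).
#' @param target_connectivity desired edges per node.
#' @param edge_threshold representative-network threshold.
#' @param band acceptable half-width around the target connectivity.
#' @param control base [bp_control()] supplying the remaining settings.
#' @return a [bp_control()] with \code{beta}, \code{lambda} set; the search
#'   table is attached as attribute \code{"search"}.
#' @export
select_hyperparameters <- function(data, grid = value_grid(),
                                   beta_range = 1:5, lambda_range = 1:5,
                                   target_connectivity = 1.5,
                                   edge_threshold = 0.2, band = 0.5,
                                   control = bp_control()) {
  stopifnot(length(beta_range) > 0, length(lambda_range) > 0)
  lattice <- expand.grid(beta = beta_range, lambda = lambda_range)
  res <- lapply(seq_len(nrow(lattice)), function(r) {
    ctl <- control
    ctl$beta <- lattice$beta[r]; ctl$lambda <- lattice$lambda[r]
    fit <- bp_infer(data, grid, ctl)
    rep_net <- representative_network(fit, threshold = edge_threshold)
    n_rows <- length(fit$converged)
    err <- sum(residuals(rep_net, data)^2)
    c(connectivity = sum(rep_net$W != 0) / max(n_rows, 1), error = err)
  })
  tab <- cbind(lattice, do.call(rbind, res))
  in_band <- abs(tab$connectivity - target_connectivity) <= band
  if (any(in_band)) {
    best <- which(in_band)[which.min(tab$error[in_band])]
  } else {
    warning("no (beta, lambda) reached the target connectivity band; ",
            "returning the nearest")
    best <- which.min(abs(tab$connectivity - target_connectivity))
  }
  out <- control
  out$beta <- tab$beta[best]; out$lambda <- tab$lambda[best]
  attr(out, "search") <- tab
  out
}
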