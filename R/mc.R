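#' Control parameters for the Metropolis Monte Carlo baseline
#'
#' @param grid a [value_grid()] of allowed edge values.
#' @param temperature Metropolis temperature; proposals increasing the
#'   configuration cost by \eqn{\Delta C} are accepted with probability
#'   \eqn{\min(1, e^{-\Delta C / T})}. At \eqn{T = 1} and with
#'   \code{cost = cost_config(beta, lambda)} the chain samples the Boltzmann
#'   posterior over discrete configurations. \eqn{T = 0} means downhill-only.
#' @param max_steps maximum proposals.
#' @param plateau stop when the running-minimum cost has not improved for
#'   this many proposals.
#' @param n_keep number of distinct lowest-cost configurations retained.
#' @param thin keep one sample every \code{thin} proposals (after one fifth
#'   of \code{max_steps} as burn-in) for empirical marginals.
#' @param n_chains number of independent chains; chain \code{k} uses seed
#'   \code{seed + k - 1} and results are pooled, identically to running the
#'   chains one at a time with those seeds.
#' @param cost a [cost_config()].
#' @param seed RNG seed (of the first chain).
#' @export
mc_control <- function(grid = value_grid(), temperature = 1,
                       max_steps = 1e5, plateau = 5000, n_keep = 50,
                       thin = 100, n_chains = 1, cost = cost_config(),
                       seed = 1) {
  stopifnot(temperature >= 0, max_steps >= 1, n_chains >= 1)
  structure(list(grid = as_grid(grid), temperature = temperature,
                 max_steps = as.integer(max_steps),
                 plateau = as.integer(plateau), n_keep = n_keep,
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 cost = cost, seed = seed),
            class = "mc_control")
}

#' Metropolis Monte Carlo search over discrete interaction matrices
#'
#' Baseline sampler for speed/accuracy comparison with Belief Propagation.
#' Starting from the empty network, single-entry proposals (one edge set to
#' a different grid value) are accepted by the Metropolis rule under the
#' configuration cost (decoupled squared error plus L0 penalty), so higher
#' cost configurations are occasionally accepted. Terminates on a cost
#' plateau or after \code{max_steps}.
#'
#' @param data a [perturbation_data()].
#' @param control an [mc_control()].
#' @param forbid_phenotype_out forbid edges out of phenotype nodes.
#' @return object of class \code{"mc_result"}: \code{best} (list of retained
#'   low-cost \code{W} matrices), \code{best_costs}, \code{samples} (thinned
#'   chain states), \code{trace} (running-minimum cost), \code{steps}.
#' @export
mc_search <- function(data, control = mc_control(),
                      forbid_phenotype_out = FALSE) {
  stopifnot(inherits(data, "perturbation_data"))
  if (control$n_chains > 1) {
    chains <- lapply(seq_len(control$n_chains) - 1L, function(k) {
      ctl <- control; ctl$n_chains <- 1L; ctl$seed <- control$seed + k
      mc_search(data, ctl, forbid_phenotype_out)
    })
    merged <- chains[[1]]
    for (ch in chains[-1]) {
      merged$best <- c(merged$best, ch$best)
      merged$best_costs <- c(merged$best_costs, ch$best_costs)
      merged$samples <- c(merged$samples, ch$samples)
      merged$steps <- merged$steps + ch$steps
    }
    ord <- order(merged$best_costs)[seq_len(min(control$n_keep,
                                                length(merged$best)))]
    merged$best <- merged$best[ord]
    merged$best_costs <- merged$best_costs[ord]
    merged$trace <- lapply(chains, `[[`, "trace")
    merged$control <- control
    return(merged)
  }
  set.seed(control$seed)
  grid <- control$grid
  n <- length(data$nodes); m <- length(data$conditions)
  ew <- control$cost$error_weight; cw <- control$cost$complexity_weight
  free <- which(outer(seq_len(n), seq_len(n), "!=") &
                  data$roles[row(matrix(0, n, n))] != "activity" &
                  (!forbid_phenotype_out |
                     data$roles[col(matrix(0, n, n))] != "phenotype"),
                arr.ind = FALSE)
  free_ij <- arrayInd(free, c(n, n))
  W <- matrix(0, n, n)
  # per-row linear predictors s_i^mu, updated incrementally
  S <- W %*% data$X + data$U
  row_err <- rowSums((data$X - tanh(S))^2)
  cost <- ew * sum(row_err) + cw * sum(W != 0)
  best_min <- cost
  trace <- numeric(0)
  since_improve <- 0L
  retained <- list(); retained_cost <- numeric(0)
  samples <- list()
  burn <- control$max_steps %/% 5L
  keep_state <- function(Wc, cc) {
    key <- paste(Wc[free], collapse = ",")
    if (!key %in% names(retained_cost)) {
      retained[[key]] <<- Wc
      retained_cost[key] <<- cc
      if (length(retained_cost) > control$n_keep) {
        drop <- which.max(retained_cost)
        retained[[names(retained_cost)[drop]]] <<- NULL
        retained_cost <<- retained_cost[-drop]
      }
    }
  }
  keep_state(W, cost)
  steps <- 0L
  for (step in seq_len(control$max_steps)) {
    steps <- step
    e <- sample.int(length(free), 1)
    i <- free_ij[e, 1]; j <- free_ij[e, 2]
    old <- W[i, j]
    cand <- grid[grid != old]
    new <- cand[sample.int(length(cand), 1)]
    s_new <- S[i, ] + (new - old) * data$X[j, ]
    err_new <- sum((data$X[i, ] - tanh(s_new))^2)
    dC <- ew * (err_new - row_err[i]) + cw * ((new != 0) - (old != 0))
    accept <- if (control$temperature == 0) dC < 0 else
      dC <= 0 || stats::runif(1) < exp(-dC / control$temperature)
    if (accept) {
      W[i, j] <- new
      S[i, ] <- s_new
      row_err[i] <- err_new
      cost <- cost + dC
      keep_state(W, cost)
    }
    if (cost < best_min - 1e-12) {
      best_min <- cost
      since_improve <- 0L
    } else since_improve <- since_improve + 1L
    trace[step] <- best_min
    if (step > burn && step %% control$thin == 0L)
      samples[[length(samples) + 1L]] <- W
    if (since_improve >= control$plateau) break
  }
  ord <- order(retained_cost)
  structure(list(best = unname(retained[ord]),
                 best_costs = unname(retained_cost[ord]),
                 samples = samples, trace = trace[seq_len(steps)],
                 steps = steps, control = control,
                 nodes = data$nodes, free = free),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("MC search: %d proposals, best cost %.4g, %d retained, %d samples\n",
              x$steps, min(x$best_costs), length(x$best), length(x$samples)))
  invisible(x)
}

#' Empirical edge marginals from retained MC configurations
#'
#' Per-edge value frequencies across a set of configurations, normalized per
#' edge, in the same array layout as BP marginals.
#'
#' @param mc an [mc_search()] result.
#' @param use \code{"samples"} (thinned posterior chain, default when
#'   available) or \code{"best"} (retained low-cost set).
#' @return list with \code{P} (N x N x K frequency array), \code{mean_W} and
#'   the \code{grid}.
#' @export
mc_marginals <- function(mc, use = c("samples", "best")) {
  use <- match.arg(use)
  set <- if (use == "samples" && length(mc$samples)) mc$samples else mc$best
  if (!length(set)) stop("no retained configurations")
  grid <- as.numeric(mc$control$grid)
  n <- length(mc$nodes); K <- length(grid)
  P <- array(0, c(n, n, K), dimnames = list(mc$nodes, mc$nodes, NULL))
  for (Wc in set) {
    kidx <- matrix(match(Wc, grid), n, n)   # every entry lies on the grid
    for (k in seq_len(K)) P[, , k] <- P[, , k] + (kidx == k)
  }
  P <- P / length(set)
  mean_W <- matrix(0, n, n, dimnames = list(mc$nodes, mc$nodes))
  for (k in seq_len(K)) mean_W <- mean_W + P[, , k] * grid[k]
  list(P = P, mean_W = mean_W, grid = mc$control$grid, n_models = length(set))
}
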