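# Synthetic benchmarks: the package's own re-creations of the standard
# toy-network performance experiments, used both by the test suite and by
# scripts/acceptance.R.

#' Recall/precision benchmark on motif-rich toy generators
#'
#' For each seed: generate a cascade-like, motif-rich network; design a
#' panel of inhibitory in silico drugs (strong main target, up to four
#' weaker off-target effects) applied singly and in all pairs; simulate
#' noise-free steady-state responses (dropping oscillatory conditions); run
#' BP with full off-target knowledge; and score the thresholded mean
#' parameter matrix against the generator.
#'
#' @param n_nodes,n_edges generator size (default 40 nodes, 60 edges:
#'   the ~1.5 edges per node of empirical signaling maps).
#' @param n_drugs in silico drug count (default 14: 14 singles + 91 pairs).
#' @param seeds generator/inference seeds; results are averaged over seeds.
#' @param grid,control BP settings.
#' @param threshold edge-calling threshold.
#' @param noise_cv measurement noise level (0 = noise-free).
#' @param known_off_targets expose off-target forces to the inference.
#' @return data.frame with one row per seed plus attributes \code{recall}
#'   and \code{precision} (means over seeds, in percent).
#' @export
benchmark_recovery <- function(n_nodes = 40, n_edges = 60, n_drugs = 14,
                               seeds = 1:3, grid = value_grid(),
                               control = bp_control(), threshold = 0.2,
                               noise_cv = 0, known_off_targets = TRUE) {
  rows <- lapply(seeds, function(sd) {
    gen <- toy_topology(n_nodes, n_edges, seed = sd)
    panel <- drug_panel(n_drugs, main_target_strength = 2,
                        seed = sd + 1000)
    design <- design_perturbations(gen, panel, pairing = "singles_pairs",
                                   known_off_targets = known_off_targets)
    data <- simulate_responses(gen, design)
    if (noise_cv > 0) data <- add_noise(data, cv = noise_cv, seed = sd + 2000)
    ctl <- control; ctl$seed <- sd
    fit <- bp_infer(data, grid, ctl)
    rep <- recall_precision(fit, gen, threshold = threshold)
    data.frame(seed = sd, n_conditions = ncol(data$X),
               recall = rep$recall, precision = rep$precision,
               tp = rep$tp, fp = rep$fp, fn = rep$fn)
  })
  out <- do.call(rbind, rows)
  attr(out, "recall") <- 100 * mean(out$recall)
  attr(out, "precision") <- 100 * mean(out$precision)
  out
}

#' Parameter-correlation benchmark over generator sizes
#'
#' Builds one toy generator per size with twice as many edges as nodes,
#' trains BP with as many random multi-target perturbation patterns as nodes
#' (M = N) on a 41-value grid over [-2, 2], and pools the true nonzero
#' parameters against the BP marginal means across all sizes.
#'
#' @param sizes generator sizes.
#' @param grid,control BP settings.
#' @param seed base seed.
#' @return list with pooled Pearson \code{correlation}, the \code{pairs}
#'   data.frame (size, true, inferred) and a per-size correlation table.
#' @export
benchmark_parameter_correlation <- function(sizes = c(10, 20, 30, 40),
                                            grid = value_grid(-2, 2, 0.1),
                                            control = bp_control(),
                                            seed = 1) {
  pairs <- lapply(sizes, function(n) {
    gen <- toy_topology(n, 2 * n, seed = seed + n)
    U <- random_perturbations(gen, m = n, seed = seed + n + 500)
    data <- simulate_responses(gen, U)
    ctl <- control; ctl$seed <- seed + n
    fit <- bp_infer(data, grid, ctl)
    nz <- which(gen$W != 0)
    data.frame(size = n, true = gen$W[nz], inferred = fit$mean_W[nz])
  })
  pairs <- do.call(rbind, pairs)
  per_size <- vapply(split(pairs, pairs$size), function(df)
    stats::cor(df$true, df$inferred), numeric(1))
  list(correlation = stats::cor(pairs$true, pairs$inferred),
       pairs = pairs, per_size = per_size)
}

#' Timing comparison of BP and Monte Carlo
#'
#' Reports wall-clock times to convergence for BP and the Metropolis
#' baseline on matched toy problems (M = N patterns per size). Timings are
#' hardware-dependent and are reported for information only; nothing in the
#' package asserts them.
#'
#' @param sizes generator sizes.
#' @param grid shared value grid.
#' @param control BP settings.
#' @param mc_steps Monte Carlo proposal budget per size.
#' @param seed base seed.
#' @return data.frame with size, bp_seconds, mc_seconds, and the final
#'   errors of each method's mean network.
#' @export
benchmark_speed <- function(sizes = c(10, 20), grid = value_grid(-2, 2, 0.1),
                            control = bp_control(), mc_steps = 2e4,
                            seed = 1) {
  rows <- lapply(sizes, function(n) {
    gen <- toy_topology(n, 2 * n, seed = seed + n)
    U <- random_perturbations(gen, m = n, seed = seed + n + 500)
    data <- simulate_responses(gen, U)
    ctl <- control; ctl$seed <- seed + n
    t_bp <- system.time(fit <- bp_infer(data, grid, ctl))[["elapsed"]]
    mctl <- mc_control(grid = grid, max_steps = mc_steps,
                       cost = cost_config(ctl$beta, ctl$lambda),
                       seed = seed + n)
    t_mc <- system.time(mc <- mc_search(data, mctl))[["elapsed"]]
    err <- function(W) sum((data$X - tanh(W %*% data$X + data$U))^2)
    data.frame(size = n, bp_seconds = t_bp, mc_seconds = t_mc,
               bp_error = err(fit$mean_W),
               mc_error = err(mc_marginals(mc)$mean_W))
  })
  do.call(rbind, rows)
}
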