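# Shared fixtures, all generated in code.

# A tiny two-node chain n1 -> n2 with weight w21.
chain2 <- function(w21 = 0.5, alpha = 1, epsilon = 1) {
  W <- matrix(0, 2, 2)
  W[2, 1] <- w21
  network_model(W, alpha = alpha, epsilon = epsilon)
}

# Small random dataset (not simulated from any model) for exercising BP
# machinery on arbitrary numbers.
random_dataset <- function(n, m, seed = 1, roles = NULL) {
  set.seed(seed)
  perturbation_data(X = matrix(round(stats::rnorm(n * m), 3), n, m),
                    U = matrix(round(stats::rnorm(n * m), 3), n, m),
                    roles = roles)
}

# Noise-free dataset simulated from a toy generator under random rich
# perturbations.
generator_dataset <- function(n = 6, e = 9, m = 18, seed = 1) {
  gen <- toy_topology(n, e, seed = seed)
  U <- random_perturbations(gen, m = m, seed = seed + 100)
  data <- suppressWarnings(simulate_responses(gen, U))
  list(gen = gen, data = data)
}

# Brute-force posterior marginals of one row of W by exhaustive enumeration
# of all K^S configurations: the independent oracle for BP.
# Likelihood per condition: exp(-beta * (x_i - tanh(sum_j w_j x_j + u_i))^2);
# prior: exp(lambda) per zero entry.
enumerate_row_marginals <- function(Xs, xi, ui, grid, beta, lambda) {
  S <- nrow(Xs); K <- length(grid)
  configs <- as.matrix(expand.grid(rep(list(seq_len(K)), S)))
  logw <- apply(configs, 1, function(kk) {
    w <- grid[kk]
    pred <- tanh(drop(w %*% Xs) + ui)
    -beta * sum((xi - pred)^2) + lambda * sum(w == 0)
  })
  p <- exp(logw - max(logw))
  p <- p / sum(p)
  marg <- matrix(0, S, K)
  for (r in seq_len(nrow(configs)))
    for (s in seq_len(S))
      marg[s, configs[r, s]] <- marg[s, configs[r, s]] + p[r]
  marg
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# Melanoma-shaped synthetic study: 16 protein readouts, 1 viability
# phenotype, 8 drugs acting on activity nodes (25 nodes), 8 drugs at two
# doses plus all low-dose pairs (44 conditions). Entirely synthetic.
melanoma_shaped_fixture <- function(seed = 42) {
  nodes <- build_node_set(readouts = sprintf("prot%02d", 1:16),
                          phenotypes = "viability",
                          drugs = sprintf("drug%d", 1:8))
  n <- nrow(nodes)
  set.seed(seed)
  W <- matrix(0, n, n)
  act <- which(nodes$role == "activity")
  meas <- which(nodes$role != "activity")
  # each activity node drives 1-2 measured nodes; measured layer is a cascade
  for (a in act) {
    tg <- sample(meas, 2)
    W[tg, a] <- stats::runif(2, 0.5, 1.5) * sample(c(-1, 1), 2, TRUE)
  }
  for (k in seq_len(20)) {
    ij <- sample(meas, 2)
    W[ij[2], ij[1]] <- stats::runif(1, 0.3, 1.2) * sample(c(-1, 1), 1)
  }
  gen <- network_model(W, nodes = nodes$name, roles = nodes$role)
  panel <- drug_panel(8, main_target_strength = 1.2, max_off_targets = 0,
                      dose_levels = c(1, 2), seed = seed)
  # force drugs onto the activity nodes
  design <- design_perturbations(gen, panel, "singles_pairs")
  U <- design$U_true * 0
  for (d in 1:8) {
    cols <- grepl(sprintf("d%02d", d), colnames(U))
    dose <- ifelse(grepl("hi", colnames(U)[cols]), 2, 1)
    U[act[d], cols] <- -1.2 * dose
  }
  design$U_true <- design$U_obs <- U
  data <- suppressWarnings(simulate_responses(gen, design))
  list(gen = gen, data = data, design = design, nodes = nodes)
}
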