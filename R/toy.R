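#' Generate a motif-rich signaling topology
#'
#' Builds a cascade-like hierarchical generator network: a backbone of serial
#' chains through an ordered node hierarchy, extended with parallel chains,
#' feed-forward motifs, feedback loops and multiple-input motifs in
#' proportions given by \code{motif_mix}, until the requested edge count is
#' reached. Weight magnitudes are drawn uniformly on \code{weight_range}
#' (from 0 up to a maximum strength, default 2) and negated with probability
#' \code{neg_prob}. Scale-free wiring, typical of transcriptional but not of
#' signal-transduction networks, is deliberately not emulated.
#'
#' @param n_nodes number of nodes.
#' @param n_edges number of directed edges (at most \code{n_nodes * (n_nodes - 1)}).
#' @param motif_mix named weights over \code{chain}, \code{parallel},
#'   \code{feedforward}, \code{feedback}, \code{multi_input}.
#' @param weight_range interval (0, max] of weight magnitudes.
#' @param neg_prob probability that an edge is inhibitory.
#' @param roles optional per-node roles (default all protein).
#' @param seed RNG seed; same seed, same generator.
#' @return a [network_model()] with \eqn{\alpha = \epsilon = 1}.
#' @export
toy_topology <- function(n_nodes, n_edges,
                         motif_mix = c(chain = 3, parallel = 2,
                                       feedforward = 2, feedback = 0.5,
                                       multi_input = 1.5),
                         weight_range = c(0, 2), neg_prob = 0.25,
                         roles = NULL, seed = 1) {
  if (n_edges > n_nodes * (n_nodes - 1))
    stop("n_edges exceeds the number of possible directed edges")
  stopifnot(n_nodes >= 2, n_edges >= 1, weight_range[2] > 0)
  set.seed(seed)
  A <- matrix(FALSE, n_nodes, n_nodes)  # A[i, j]: edge j -> i
  can_add <- function(i, j) i != j && !A[i, j]
  add <- function(i, j) { A[i, j] <<- TRUE }
  # backbone: a serial chain through the node hierarchy 1 -> 2 -> ... -> N
  for (v in seq_len(n_nodes - 1)) {
    if (sum(A) >= n_edges) break
    add(v + 1, v)
  }
  types <- names(motif_mix)[motif_mix > 0]
  wts <- motif_mix[motif_mix > 0]
  attempts <- 0
  while (sum(A) < n_edges && attempts < 50 * n_edges) {
    attempts <- attempts + 1
    ty <- sample(types, 1, prob = wts)
    ok <- FALSE
    if (ty == "chain") {
      j <- sample(n_nodes, 1)
      down <- which(seq_len(n_nodes) > j)
      if (length(down)) {
        i <- down[sample.int(length(down), 1)]
        if (can_add(i, j)) { add(i, j); ok <- TRUE }
      }
    } else if (ty == "parallel") {
      # a second route alongside an existing edge j -> i via a new relay
      e <- which(A, arr.ind = TRUE)
      if (nrow(e)) {
        pick <- e[sample.int(nrow(e), 1), ]
        relay <- setdiff(seq_len(n_nodes), pick)
        relay <- relay[sample.int(length(relay), 1)]
        if (can_add(relay, pick[2])) { add(relay, pick[2]); ok <- TRUE }
        else if (can_add(pick[1], relay)) { add(pick[1], relay); ok <- TRUE }
      }
    } else if (ty == "feedforward") {
      # close a two-step path j -> b -> i with a direct shortcut j -> i
      e <- which(A, arr.ind = TRUE)
      if (nrow(e)) {
        pick <- e[sample.int(nrow(e), 1), ]   # b <- j
        b <- pick[1]; j <- pick[2]
        outs <- which(A[, b])
        if (length(outs)) {
          i <- outs[sample.int(length(outs), 1)]
          if (can_add(i, j)) { add(i, j); ok <- TRUE }
        }
      }
    } else if (ty == "feedback") {
      # close a multi-step loop: where a path a -> b -> c exists, add the
      # returning edge c -> a (direct reciprocal pairs are not generated:
      # signaling feedback acts through intermediates)
      reach2 <- (A %*% A) > 0
      cand <- which(reach2 & !t(A), arr.ind = TRUE)  # rows: c, cols: a
      cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
      if (nrow(cand)) {
        pick <- cand[sample.int(nrow(cand), 1), ]
        if (can_add(pick[2], pick[1])) { add(pick[2], pick[1]); ok <- TRUE }
      }
    } else if (ty == "multi_input") {
      tgt <- which(rowSums(A) > 0)
      if (length(tgt)) {
        i <- tgt[sample.int(length(tgt), 1)]
        cand <- which(!A[i, ] & seq_len(n_nodes) != i)
        if (length(cand)) {
          j <- cand[sample.int(length(cand), 1)]
          add(i, j); ok <- TRUE
        }
      }
    }
    if (!ok) next
  }
  while (sum(A) < n_edges) {   # fill any remainder with random edges
    i <- sample(n_nodes, 1); j <- sample(n_nodes, 1)
    if (can_add(i, j)) add(i, j)
  }
  W <- matrix(0, n_nodes, n_nodes)
  ne <- sum(A)
  mag <- stats::runif(ne, max(weight_range[1], 1e-6), weight_range[2])
  sgn <- ifelse(stats::runif(ne) < neg_prob, -1, 1)
  W[which(A)] <- mag * sgn
  model <- network_model(W, roles = roles)
  attr(model, "seed") <- seed
  model
}

#' Census of signaling motifs in a network
#'
#' Exhaustive small-subgraph scan counting feed-forward motifs (a direct
#' edge shortcutting a two-step path), feedback loops of length 2 and 3, and
#' multiple-input nodes (in-degree >= 2).
#'
#' @param x a [network_model()] or interaction matrix.
#' @return named integer vector.
#' @export
motif_census <- function(x) {
  W <- if (inherits(x, "network_model")) x$W else as.matrix(x)
  A <- (W != 0) * 1
  two_step <- (A %*% A) > 0
  ff <- sum(A == 1 & two_step)
  fb2 <- sum(A == 1 & t(A) == 1) / 2
  A3 <- A %*% A %*% A
  fb3 <- sum(diag(A3)) / 3
  c(feedforward = ff, feedback2 = fb2, feedback3 = fb3,
    feedback = fb2 + fb3, multi_input = sum(rowSums(A) >= 2))
}

#' Design an in silico drug panel
#'
#' Specifies a panel of inhibitors: each drug strongly inhibits one main
#' target (a negative external force of magnitude
#' \code{main_target_strength}) and has up to \code{max_off_targets} weaker
#' off-target effects of either sign, with magnitudes uniform on a fraction
#' (at most \code{off_target_frac}) of the main strength.
#'
#' @param n_drugs number of drugs.
#' @param main_target_strength magnitude of the main-target force
#'   (log2-ratio scale; the default 1 corresponds to 50\% inhibition of the
#'   presumed downstream effector, the scale at which drug doses are chosen).
#' @param max_off_targets maximum off-target count per drug (uniform 0..max).
#' @param off_target_frac maximum off-target strength as a fraction of the
#'   main-target strength.
#' @param dose_levels multipliers applied to all of a drug's forces; e.g.
#'   \code{c(1, 2)} for low and high doses.
#' @param seed seed for target assignment in [design_perturbations()].
#' @return object of class \code{"drug_panel"}.
#' @export
drug_panel <- function(n_drugs, main_target_strength = 1, max_off_targets = 4,
                       off_target_frac = 0.5, dose_levels = 1, seed = 1) {
  stopifnot(n_drugs >= 1, max_off_targets >= 0, main_target_strength > 0)
  structure(list(n_drugs = n_drugs,
                 main_target_strength = main_target_strength,
                 max_off_targets = max_off_targets,
                 off_target_frac = off_target_frac,
                 dose_levels = dose_levels, seed = seed),
            class = "drug_panel")
}

#' Design perturbation conditions for a drug panel
#'
#' Assigns distinct main targets to each drug, draws off-target effects, and
#' lays out the condition columns: singles at each dose level and, for
#' \code{pairing = "singles_pairs"}, all drug pairs at the first (low) dose.
#' Combination forces are element-wise sums of the single-drug force
#' vectors. Two force matrices are returned: \code{U_true} containing all
#' effects (used to simulate the system), and \code{U_obs} which omits the
#' off-target entries unless \code{known_off_targets} is TRUE, mimicking
#' inference on drugs with unknown off-target effects.
#'
#' @param model the generator [network_model()] (targets are drawn from its
#'   non-phenotype nodes).
#' @param panel a [drug_panel()].
#' @param pairing \code{"singles"} or \code{"singles_pairs"}.
#' @param known_off_targets expose off-target forces to the inference?
#' @return object of class \code{"perturbation_design"} with \code{U_true},
#'   \code{U_obs} and a \code{conditions} data.frame (label, drugs, dose).
#' @examples
#' m <- toy_topology(10, 20, seed = 1)
#' d <- design_perturbations(m, drug_panel(8, dose_levels = c(1, 2)),
#'                           pairing = "singles_pairs")
#' ncol(d$U_true)  # 8 * 2 + choose(8, 2) = 44
#' @export
design_perturbations <- function(model, panel,
                                 pairing = c("singles_pairs", "singles"),
                                 known_off_targets = TRUE) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(panel, "drug_panel"))
  n <- n_nodes(model)
  nd <- panel$n_drugs
  eligible <- which(model$roles != "phenotype")
  if (nd > length(eligible)) stop("more drugs than eligible target nodes")
  set.seed(panel$seed)
  targets <- sample(eligible, nd)
  u_true <- u_obs <- matrix(0, n, nd)
  for (d in seq_len(nd)) {
    u_true[targets[d], d] <- -panel$main_target_strength
    if (panel$max_off_targets > 0) {
      k <- sample(0:panel$max_off_targets, 1)
      if (k > 0) {
        off <- sample(setdiff(seq_len(n), targets[d]), k)
        str <- stats::runif(k, 0, panel$off_target_frac *
                              panel$main_target_strength)
        sgn <- ifelse(stats::runif(k) < 0.5, -1, 1)
        u_true[off, d] <- str * sgn
      }
    }
    u_obs[, d] <- if (known_off_targets) u_true[, d] else
      ifelse(seq_len(n) == targets[d], u_true[, d], 0)
  }
  doses <- panel$dose_levels
  cols_true <- list(); cols_obs <- list(); meta <- list()
  for (lv in seq_along(doses)) {
    for (d in seq_len(nd)) {
      lab <- if (length(doses) > 1)
        sprintf("d%02d.%s", d, c("lo", "hi", "x3", "x4")[lv]) else
          sprintf("d%02d", d)
      cols_true[[lab]] <- u_true[, d] * doses[lv]
      cols_obs[[lab]] <- u_obs[, d] * doses[lv]
      meta[[lab]] <- data.frame(label = lab, drugs = as.character(d),
                                dose = doses[lv], type = "single")
    }
  }
  if (pairing == "singles_pairs" && nd >= 2) {
    for (a in seq_len(nd - 1)) for (b in (a + 1):nd) {
      lab <- sprintf("d%02d+d%02d", a, b)
      cols_true[[lab]] <- (u_true[, a] + u_true[, b]) * doses[1]
      cols_obs[[lab]] <- (u_obs[, a] + u_obs[, b]) * doses[1]
      meta[[lab]] <- data.frame(label = lab,
                                drugs = paste(a, b, sep = ","),
                                dose = doses[1], type = "pair")
    }
  }
  U_true <- do.call(cbind, cols_true)
  U_obs <- do.call(cbind, cols_obs)
  rownames(U_true) <- rownames(U_obs) <- model$nodes
  structure(list(U_true = U_true, U_obs = U_obs,
                 conditions = do.call(rbind, c(meta, make.row.names = FALSE)),
                 targets = stats::setNames(targets, paste0("d", seq_len(nd))),
                 panel = panel, known_off_targets = known_off_targets),
            class = "perturbation_design")
}

#' @export
print.perturbation_design <- function(x, ...) {
  cat(sprintf("Perturbation design: %d drugs, %d conditions (%d singles, %d pairs)\n",
              x$panel$n_drugs, nrow(x$conditions),
              sum(x$conditions$type == "single"),
              sum(x$conditions$type == "pair")))
  invisible(x)
}

#' Random multi-target perturbation patterns
#'
#' Training patterns for benchmark generators: each condition applies
#' external forces of random sign and uniform magnitude to a few randomly
#' chosen nodes.
#'
#' @param model a [network_model()] (or node count).
#' @param m number of conditions.
#' @param n_targets perturbed nodes per condition.
#' @param strength_range magnitude interval.
#' @param seed RNG seed.
#' @return N x M force matrix.
#' @export
random_perturbations <- function(model, m, n_targets = 3,
                                 strength_range = c(0.5, 2), seed = 1) {
  n <- if (inherits(model, "network_model")) n_nodes(model) else model
  set.seed(seed)
  U <- matrix(0, n, m)
  for (mu in seq_len(m)) {
    tg <- sample(n, min(n_targets, n))
    U[tg, mu] <- stats::runif(length(tg), strength_range[1], strength_range[2]) *
      sample(c(-1, 1), length(tg), replace = TRUE)
  }
  colnames(U) <- sprintf("p%03d", seq_len(m))
  U
}

#' Simulate steady-state response profiles for a design
#'
#' Runs the generator model to steady state for every condition column,
#' records the steady states as the response matrix, and drops conditions
#' whose simulation is flagged oscillatory (their labels are kept in the
#' \code{"excluded"} attribute so the response and force matrices stay
#' column-aligned). The simulation is purely deterministic; measurement
#' noise is applied afterwards with [add_noise()].
#'
#' @param model the generator [network_model()].
#' @param design a [design_perturbations()] object or a force matrix
#'   (N x M); for a design, simulation uses \code{U_true} and the returned
#'   dataset carries \code{U_obs} as the force matrix seen by inference.
#' @param tol,t_max steady-state settings (see [steady_state()]).
#' @return a [perturbation_data()] with the excluded condition labels in
#'   \code{attr(, "excluded")}.
#' @export
simulate_responses <- function(model, design, tol = 1e-8, t_max = 1e4) {
  if (inherits(design, "perturbation_design")) {
    U_sim <- design$U_true; U_out <- design$U_obs
  } else {
    U_sim <- U_out <- as.matrix(design)
  }
  if (is.null(colnames(U_sim)))
    colnames(U_sim) <- colnames(U_out) <- paste0("c", seq_len(ncol(U_sim)))
  pred <- predict(model, type = "steady", u = U_sim, tol = tol, t_max = t_max)
  osc <- attr(pred, "oscillatory")
  keep <- !osc
  if (!any(keep)) stop("all conditions are oscillatory")
  out <- perturbation_data(X = pred[, keep, drop = FALSE],
                           U = U_out[, keep, drop = FALSE],
                           roles = model$roles, nodes = model$nodes,
                           conditions = colnames(U_sim)[keep])
  attr(out, "excluded") <- colnames(U_sim)[osc]
  out
}
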