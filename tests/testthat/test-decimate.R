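test_that("edge-value sampling follows marginal mass and respects freezes", {
  g <- value_grid(-1, 1, 1)
  P <- array(0, c(2, 2, 3))
  P[, , 2] <- 1                      # everything delta at zero
  frozen <- matrix(TRUE, 2, 2)
  frozen[1, 2] <- FALSE
  P[1, 2, ] <- c(0, 0, 1)            # single unfrozen edge, delta at +1
  set.seed(1)
  pick <- sample_edge_value(P, frozen, g)
  expect_identical(c(pick$i, pick$j), c(1L, 2L))
  expect_identical(pick$value, 1)

  # two unfrozen single-value edges with masses 0.75 / 0.25
  P2 <- array(0, c(2, 2, 3))
  P2[1, 2, 3] <- 0.75
  P2[2, 1, 1] <- 0.25
  frozen2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  set.seed(42)
  picks <- replicate(10000, sample_edge_value(P2, frozen2, g)$i)
  expect_equal(mean(picks == 1), 0.75, tolerance = 0.02)

  # frozen edges are never selected
  expect_true(all(picks %in% c(1L, 2L)))
  expect_error(sample_edge_value(P2, matrix(TRUE, 2, 2), g), "unfrozen")
})

test_that("decimation_step freezes the sampled edge in the fit", {
  gd <- generator_dataset(n = 4, e = 5, m = 8, seed = 23)
  fit <- bp_infer(gd$data, value_grid(-1, 1, 0.5), bp_control(seed = 2))
  set.seed(9)
  st <- decimation_step(fit)
  i <- st$edge["target"]; j <- st$edge["source"]
  expect_equal(sum(st$fit$P[i, j, ]), 1)
  expect_identical(max(st$fit$P[i, j, ]), 1)
  row <- st$fit$state$rows[[gd$data$nodes[i]]]
  s <- match(j, row$sources)
  expect_true(row$fixed[s])
  expect_identical(row$fixed_val[s], st$value)
})

test_that("instantiated models are deterministic, complete and on-grid", {
  gd <- generator_dataset(n = 5, e = 8, m = 12, seed = 24)
  g <- value_grid(-1, 1, 0.5)
  fit <- bp_infer(gd$data, g, bp_control(seed = 3))
  m1 <- instantiate_model(fit, seed = 7)
  m2 <- instantiate_model(fit, seed = 7)
  expect_identical(m1$model$W, m2$model$W)
  m3 <- instantiate_model(fit, seed = 8)
  # the trace covers every free edge exactly once
  expect_identical(nrow(m1$trace), sum(fit$edge_mask))
  expect_false(any(duplicated(m1$trace[c("target", "source")])))
  # every fixed value lies on the grid
  expect_true(all(m1$model$W[fit$edge_mask] %in% as.numeric(g)))
  expect_true(all(m1$model$W[!fit$edge_mask] == 0))
})

test_that("most instantiated models carry the strong true edges", {
  # noise-free rich data, moderate weights (so that no node saturates and
  # the marginals concentrate) and a sharp likelihood
  gen <- toy_topology(5, 7, weight_range = c(0.3, 1.2), seed = 26)
  U <- random_perturbations(gen, m = 25, n_targets = 3,
                            strength_range = c(0.5, 2), seed = 126)
  data <- suppressWarnings(simulate_responses(gen, U))
  fit <- bp_infer(data, value_grid(-2, 2, 0.2),
                  bp_control(beta = 4, lambda = 1, seed = 1))
  strong <- which(abs(gen$W) >= 0.5)
  hits <- vapply(1:50, function(sd) {
    W <- instantiate_model(fit, seed = sd)$model$W
    all(abs(W[strong]) >= 0.2 & sign(W[strong]) == sign(gen$W[strong]))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("ensembles rank by training error and keep a sorted prefix", {
  gd <- generator_dataset(n = 4, e = 6, m = 10, seed = 27)
  g <- value_grid(-1, 1, 0.5)
  ens <- generate_ensemble(gd$data, g, bp_control(seed = 2),
                           n_generate = 6, n_keep = 6, refine = FALSE)
  expect_length(ens$models, 6)
  expect_true(!is.unsorted(ens$train_errors))
  ens2 <- generate_ensemble(gd$data, g, bp_control(seed = 2),
                            n_generate = 6, n_keep = 3, refine = FALSE)
  expect_identical(ens2$train_errors, ens$train_errors[1:3])
  expect_identical(ens2$all_errors, ens$all_errors)
  expect_error(generate_ensemble(gd$data, g, n_generate = 2, n_keep = 3),
               "n_keep")
})

test_that("pooled ensemble edge histograms track BP marginals", {
  gd <- generator_dataset(n = 4, e = 6, m = 12, seed = 28)
  g <- value_grid(-1, 1, 0.5)
  fit <- bp_infer(gd$data, g, bp_control(lambda = 2, seed = 2))
  ens <- generate_ensemble(gd$data, g, bp_control(lambda = 2, seed = 2),
                           n_generate = 40, n_keep = 40, refine = FALSE,
                           fit = fit)
  # frequency of nonzero assignment per edge across models, against the
  # nonzero marginal mass before decimation
  freq <- Reduce(`+`, lapply(ens$models, function(m) (m$W != 0) * 1)) / 40
  pnz <- 1 - apply(fit$P, c(1, 2), function(p) p[as.numeric(g) == 0])
  idx <- which(fit$edge_mask)
  expect_gt(stats::cor(freq[idx], pnz[idx], method = "spearman"), 0)
})
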