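test_that("value grids are symmetric, zero-centred, and sized correctly", {
  expect_length(value_grid(-1, 1, 0.2), 11)
  expect_length(value_grid(-2, 2, 0.1), 41)
  expect_identical(as.numeric(value_grid(-1, 1, 1)), c(-1, 0, 1))
  g <- value_grid(-1, 1, 0.2)
  expect_identical(sum(g == 0), 1L)
  expect_equal(as.numeric(g), -rev(as.numeric(g)))
  expect_error(value_grid(-1, 2, 0.2), "symmetric")
  expect_error(value_grid(0.2, 1, 0.2), "straddle")
  expect_error(value_grid(-0.5, 0.5, 0.2), "integer|zero")
})

test_that("search-space arithmetic matches the motivating example", {
  expect_identical(search_space_order(20, 3), 190)
})

test_that("model construction enforces structural invariants", {
  W <- matrix(0, 3, 3); W[1, 1] <- 0.5
  expect_error(network_model(W), "self-interactions")
  W <- matrix(0, 3, 3); W[2, 1] <- 1
  expect_error(network_model(W, roles = c("protein", "activity", "protein")),
               "activity")
  expect_error(network_model(matrix(0, 2, 2), alpha = c(1, -1)), "alpha")
  expect_error(network_model(matrix(0, 2, 2), nodes = c("a", "a")), "unique")
})

test_that("rhs follows the saturating force-inside form", {
  # isolated node under the worked drug-encoding force
  m1 <- network_model(matrix(0, 1, 1))
  expect_equal(model_rhs(m1, x = 0, u = -0.863), tanh(-0.863),
               tolerance = 1e-12)
  expect_equal(tanh(-0.863), -0.697, tolerance = 2e-3)
  # unperturbed origin is a fixed point
  m <- chain2(0.5)
  expect_identical(model_rhs(m, x = c(0, 0), u = c(0, 0)), c(0, 0))
  # two-node chain arithmetic
  expect_equal(model_rhs(m, x = c(0.4, 0.1), u = 0)[2], tanh(0.2) - 0.1,
               tolerance = 1e-12)
  expect_error(model_rhs(m, x = 1), "nodes")
})

test_that("activity-node encoding reproduces the worked quantification", {
  enc <- encode_activity_node(0.55)
  expect_equal(enc$u, -0.863, tolerance = 1e-3)
  expect_equal(enc$x, -0.697, tolerance = 1e-3)
  expect_identical(encode_activity_node(1), list(u = 0, x = 0))
  enc25 <- encode_activity_node(0.25)
  expect_equal(enc25$u, -2)
  expect_equal(enc25$x, tanh(-2))
  expect_error(encode_activity_node(0), "> 0")
  # alpha/epsilon scaling
  expect_equal(encode_activity_node(0.5, alpha = 2, epsilon = 1)$x,
               0.5 * tanh(-1))
})

test_that("node assembly counts readouts, phenotypes and activity nodes", {
  nodes <- build_node_set(readouts = sprintf("p%02d", 1:16),
                          phenotypes = "viability",
                          drugs = sprintf("drug%d", 1:8))
  expect_identical(nrow(nodes), 25L)
  expect_identical(sum(nodes$role == "activity"), 8L)
  expect_true(all(startsWith(nodes$label[nodes$role == "activity"], "a")))
})

test_that("decoupled prediction uses observed neighbours", {
  # no interactions: xhat = tanh(u)
  m0 <- network_model(matrix(0, 3, 3))
  d <- random_dataset(3, 4, seed = 7)
  expect_equal(predict(m0, d, type = "decoupled"), tanh(d$U),
               tolerance = 1e-12, ignore_attr = TRUE)
  # single-weight row: xhat_1 = tanh(1 * x2)
  W <- matrix(0, 3, 3); W[1, 2] <- 1
  m <- network_model(W)
  d2 <- perturbation_data(X = matrix(c(0.1, 0.5, -0.2), 3, 1),
                          U = matrix(0, 3, 1))
  expect_equal(predict(m, d2, type = "decoupled")[1, 1], tanh(0.5),
               tolerance = 1e-12)
  expect_equal(tanh(0.5), 0.462, tolerance = 1e-3)
})

test_that("model cost decomposes into error and complexity terms", {
  d0 <- perturbation_data(X = matrix(0, 3, 2), U = matrix(0, 3, 2))
  m0 <- network_model(matrix(0, 3, 3))
  expect_identical(model_cost(m0, d0), 0)
  # generator on its own noise-free, self-consistent data: cost is exactly
  # lambda * (number of edges)
  gd <- generator_dataset(n = 5, e = 7, m = 10, seed = 3)
  cfg <- cost_config(error_weight = 2, complexity_weight = 5)
  cost <- model_cost(gd$gen, gd$data, cfg)
  err <- cost - 5 * sum(gd$gen$W != 0)
  expect_lt(err, 1e-10)  # decoupled residuals vanish at the fixed point
  # perturbing a true edge strictly increases the cost
  mod <- gd$gen
  nz <- which(mod$W != 0)[1]
  mod$W[nz] <- mod$W[nz] + 0.3
  expect_gt(model_cost(mod, gd$data, cfg), cost)
  # complexity_weight = 0 leaves the pure squared decoupled error
  expect_equal(model_cost(gd$gen, gd$data, cost_config(1, 1e-12)),
               sum(residuals(gd$gen, gd$data)^2), tolerance = 1e-9)
})

test_that("perturbation datasets validate alignment and finiteness", {
  expect_error(perturbation_data(matrix(0, 2, 2), matrix(0, 2, 3)),
               "dimensions")
  expect_error(perturbation_data(matrix(c(1, NA), 1, 2), matrix(0, 1, 2)),
               "non-finite")
  X <- matrix(0, 2, 2, dimnames = list(NULL, c("a", "b")))
  U <- matrix(0, 2, 2, dimnames = list(NULL, c("b", "a")))
  expect_error(perturbation_data(X, U), "mismatch")
})
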