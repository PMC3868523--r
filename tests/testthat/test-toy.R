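test_that("topology generation hits the edge count and contains motifs", {
  gen <- toy_topology(20, 60, seed = 5)
  expect_identical(sum(gen$W != 0), 60L)
  expect_identical(sum(diag(gen$W) != 0), 0L)
  cen <- motif_census(gen)
  expect_gte(cen[["feedback"]], 1)
  expect_gte(cen[["feedforward"]], 1)
  # magnitudes within (0, 2]
  mags <- abs(gen$W[gen$W != 0])
  expect_true(all(mags > 0 & mags <= 2))
  # reproducible
  expect_identical(toy_topology(20, 60, seed = 5)$W, gen$W)
  # complete digraph minus diagonal at the maximum
  full <- toy_topology(4, 12, seed = 1)
  expect_identical(sum(full$W != 0), 12L)
  expect_error(toy_topology(4, 13), "exceeds")
})

test_that("drug designs produce the documented condition counts", {
  m <- toy_topology(30, 50, seed = 2)
  # 8 drugs: singles at two doses plus all low-dose pairs = 44
  d8 <- design_perturbations(m, drug_panel(8, dose_levels = c(1, 2), seed = 3),
                             "singles_pairs")
  expect_identical(ncol(d8$U_true), as.integer(8 * 2 + choose(8, 2)))
  expect_identical(ncol(d8$U_true), 44L)
  # 14 drugs singles+pairs at one dose = 105
  d14 <- design_perturbations(m, drug_panel(14, seed = 3), "singles_pairs")
  expect_identical(ncol(d14$U_true), as.integer(14 + choose(14, 2)))
  # singles only
  d5 <- design_perturbations(m, drug_panel(5, seed = 3), "singles")
  expect_identical(ncol(d5$U_true), 5L)
})

test_that("pair conditions are element-wise sums of single-drug forces", {
  m <- toy_topology(12, 20, seed = 6)
  d <- design_perturbations(m, drug_panel(4, seed = 7), "singles_pairs")
  U <- d$U_true
  expect_equal(U[, "d01+d02"], U[, "d01"] + U[, "d02"])
  # main targets distinct, inhibitory
  expect_identical(anyDuplicated(d$targets), 0L)
  for (dr in seq_len(4))
    expect_lt(U[d$targets[dr], dr], 0)
})

test_that("off-target effects can be hidden from the inference view", {
  m <- toy_topology(15, 25, seed = 8)
  d <- design_perturbations(m, drug_panel(6, max_off_targets = 4, seed = 9),
                            known_off_targets = FALSE)
  # observed forces only touch main targets; true forces may touch more
  expect_true(all(which(d$U_obs[, "d01"] != 0) == d$targets[1]))
  expect_gte(sum(d$U_true != 0), sum(d$U_obs != 0))
  d2 <- design_perturbations(m, drug_panel(6, max_off_targets = 4, seed = 9),
                             known_off_targets = TRUE)
  expect_identical(d2$U_obs, d2$U_true)
})

test_that("response simulation excludes oscillatory columns with bookkeeping", {
  # build a model with one oscillating subsystem and drive it in one condition
  W <- matrix(0, 4, 4)
  W[2, 1] <- -3; W[3, 2] <- -3; W[1, 3] <- -3  # repressilator core
  W[4, 3] <- 0.5
  mdl <- network_model(W)
  U <- matrix(0, 4, 3)
  U[1, 2] <- 0.5          # kicks the unstable cycle
  U[4, 3] <- 1            # benign downstream perturbation
  colnames(U) <- c("ref", "kick", "mild")
  data <- simulate_responses(mdl, U, t_max = 2000)
  expect_identical(attr(data, "excluded"), "kick")
  expect_identical(colnames(data$X), colnames(data$U))
  expect_identical(ncol(data$X), 2L)
  # the zero-force reference column responds with zeros
  expect_equal(max(abs(data$X[, "ref"])), 0, tolerance = 1e-8)
})

test_that("stronger forcing of an isolated node gives a larger response", {
  m1 <- network_model(matrix(0, 1, 1))
  u <- c(0.4, 0.8)
  r <- vapply(u, function(z) abs(steady_state(m1, u = z)$final), numeric(1))
  expect_gte(r[2], r[1])
})

test_that("multiplicative noise has the declared coefficient of variation", {
  X <- matrix(1 + stats::runif(1e5), 500, 200)
  noisy <- add_noise(X, cv = 0.15, seed = 99)
  rel <- noisy / X - 1
  expect_equal(stats::sd(rel), 0.15, tolerance = 0.01)
  expect_equal(mean(rel), 0, tolerance = 0.005)
  # cv = 0 is the identity; the worst-case 30% path works; additive mode
  expect_identical(add_noise(X, cv = 0), X)
  noisy30 <- add_noise(X, cv = 0.30, seed = 1)
  expect_equal(stats::sd(noisy30 / X - 1), 0.30, tolerance = 0.01)
  addv <- add_noise(X, cv = 0.2, seed = 2, mode = "additive")
  expect_equal(stats::sd(addv - X), 0.2, tolerance = 0.01)
})

test_that("the seeded generation chain is bit-reproducible", {
  run <- function() {
    gen <- toy_topology(8, 14, seed = 3)
    des <- design_perturbations(gen, drug_panel(5, seed = 4), "singles_pairs")
    data <- suppressWarnings(simulate_responses(gen, des))
    add_noise(data, cv = 0.15, seed = 5)$X
  }
  expect_identical(run(), run())
})
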