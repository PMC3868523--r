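test_that("belief initialization is seeded, normalized and structural", {
  d <- random_dataset(4, 3, seed = 2,
                      roles = c("protein", "protein", "activity", "phenotype"))
  g <- value_grid(-1, 1, 0.5)
  s1 <- init_beliefs(d, g, seed = 7)
  s2 <- init_beliefs(d, g, seed = 7)
  expect_identical(s1, s2)
  # activity node n3 has no row at all (no upstream regulators)
  expect_null(s1$rows[["n3"]])
  expect_identical(length(s1$rows), 3L)
  # every factor normalizes to 1
  for (row in s1$rows) {
    p <- exp(row$logF)
    sums <- apply(p, c(1, 2), sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
  }
  # forbidding phenotype sources drops node n4 from source lists
  s3 <- init_beliefs(d, g, seed = 7, forbid_phenotype_out = TRUE)
  expect_false(4 %in% s3$rows[["n1"]]$sources)
})

test_that("cavity marginal follows the closed-form prior limit", {
  d <- random_dataset(3, 2, seed = 3)
  g <- value_grid(-1, 1, 0.2)  # K = 11
  s <- init_beliefs(d, g, seed = 1)
  # make all factors of edge 2 -> 1 uniform
  s$rows[["n1"]]$logF[1, , ] <- log(1 / 11)
  K <- 11
  # lambda = 0: uniform in, uniform out
  p0 <- cavity_marginal(s, "n1", "n2", lambda = 0)
  expect_equal(p0, rep(1 / K, K), tolerance = 1e-12)
  # lambda > 0: mass at zero is exp(lambda) / (exp(lambda) + K - 1)
  lam <- 1.7
  p1 <- cavity_marginal(s, "n1", "n2", lambda = lam)
  expect_equal(p1[g == 0], exp(lam) / (exp(lam) + K - 1), tolerance = 1e-12)
  # M = 2: excluding condition 1 leaves exactly factor 2 times the prior
  s$rows[["n1"]]$logF[1, 2, ] <- log(seq_len(K) / sum(seq_len(K)))
  p2 <- cavity_marginal(s, "n1", "n2", exclude_condition = 1, lambda = 0)
  expect_equal(p2, seq_len(K) / sum(seq_len(K)), tolerance = 1e-12)
})

test_that("cavity field statistics match single-term and sampling oracles", {
  d <- random_dataset(4, 2, seed = 4)
  g <- value_grid(-1, 1, 0.5)
  s <- init_beliefs(d, g, seed = 1)
  # all non-cavity marginals delta at 0 -> (0, 0)
  for (j in 1:3) {
    sl <- s$rows[["n4"]]
    kk <- match(j, sl$sources)
    s$rows[["n4"]]$logF[kk, , ] <-
      matrix(log(as.numeric(g == 0) + 1e-300), 2, 5, byrow = TRUE)
  }
  st <- cavity_field_stats(s, "n4", "n1", condition = 1, data = d, lambda = 0)
  expect_equal(st$mean_h, 0, tolerance = 1e-9)
  expect_equal(st$var_h, 0, tolerance = 1e-9)
  # one deterministic neighbour with w = 0.5 and x = 1 -> (0.5, 0)
  d$X[2, 1] <- 1
  kk <- match(2, s$rows[["n4"]]$sources)
  s$rows[["n4"]]$logF[kk, , ] <-
    matrix(log(as.numeric(g == 0.5) + 1e-300), 2, 5, byrow = TRUE)
  st2 <- cavity_field_stats(s, "n4", "n1", condition = 1, data = d, lambda = 0)
  expect_equal(st2$mean_h, 0.5, tolerance = 1e-9)
  expect_equal(st2$var_h, 0, tolerance = 1e-9)
  # two independent random neighbours: moments add; Monte Carlo oracle
  s2 <- init_beliefs(d, g, seed = 99)
  st3 <- cavity_field_stats(s2, "n4", "n1", condition = 1, data = d, lambda = 0.5)
  p2 <- cavity_marginal(s2, "n4", "n2", exclude_condition = 1, lambda = 0.5)
  p3 <- cavity_marginal(s2, "n4", "n3", exclude_condition = 1, lambda = 0.5)
  set.seed(123)
  draws <- sample(as.numeric(g), 1e5, TRUE, p2) * d$X[2, 1] +
    sample(as.numeric(g), 1e5, TRUE, p3) * d$X[3, 1]
  expect_equal(st3$mean_h, mean(draws), tolerance = 0.01)
  expect_equal(st3$var_h, stats::var(draws), tolerance = 0.02)
})

test_that("factor update matches exact enumeration of the local integral", {
  # one non-cavity source: the Gaussian is degenerate if that source is
  # fixed; in general compare against explicit enumeration over the single
  # non-cavity parameter
  d <- random_dataset(3, 3, seed = 6)
  g <- value_grid(-1, 1, 1)  # K = 3
  s <- init_beliefs(d, g, seed = 2)
  ctl <- bp_control(beta = 1.3, lambda = 0.8)
  row <- s$rows[["n1"]]  # sources 2, 3
  upd <- factor_update(s, "n1", "n2", condition = 2, data = d, control = ctl)
  # oracle: rho(omega) = sum_w3 P^{cav}(w3) exp(-beta (x1 - tanh(w3 x3 +
  # omega x2 + u1))^2), with P^{cav} the cavity marginal of edge 3 -> 1
  p3 <- cavity_marginal(s, "n1", "n3", exclude_condition = 2,
                        lambda = ctl$lambda)
  om <- as.numeric(g)
  oracle <- vapply(om, function(w2) {
    sum(p3 * exp(-ctl$beta * (d$X[1, 2] -
      tanh(om * d$X[3, 2] + w2 * d$X[2, 2] + d$U[1, 2]))^2))
  }, numeric(1))
  oracle <- oracle / sum(oracle)
  # Gaussian mean-field with one non-cavity source: exact only when the
  # source distribution is concentrated; tolerance reflects the CLT
  # approximation on a 3-point distribution
  expect_lt(total_variation(upd, oracle), 0.05)

  # with the non-cavity source frozen, the update is exact point evaluation
  s$rows[["n1"]]$fixed[2] <- TRUE     # freeze source node 3 (slot 2)
  s$rows[["n1"]]$fixed_val[2] <- 1
  upd2 <- factor_update(s, "n1", "n2", condition = 2, data = d, control = ctl)
  exact <- exp(-ctl$beta * (d$X[1, 2] -
    tanh(1 * d$X[3, 2] + om * d$X[2, 2] + d$U[1, 2]))^2)
  exact <- exact / sum(exact)
  expect_equal(upd2, exact, tolerance = 1e-12)

  # beta -> 0 flattens the likelihood: uniform factor
  ctl0 <- bp_control(beta = 0, lambda = 0.8)
  upd0 <- factor_update(s, "n1", "n2", condition = 1, data = d, control = ctl0)
  expect_equal(upd0, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("compiled and reference engines produce identical results", {
  d <- random_dataset(4, 5, seed = 8)
  g <- value_grid(-1, 1, 0.5)
  run <- function(engine) {
    ctl <- bp_control(beta = 2, lambda = 1, seed = 42, engine = engine,
                      max_sweeps = 30)
    bp_infer(d, g, ctl)
  }
  f_cpp <- run("cpp")
  f_r <- run("r")
  expect_equal(f_cpp$P, f_r$P, tolerance = 1e-10)
  expect_identical(as.integer(f_cpp$sweeps), as.integer(f_r$sweeps))
})

test_that("BP marginals equal brute-force posteriors on small systems", {
  # single free parameter per row: agreement to 1e-6 (the update is exact)
  d <- random_dataset(2, 3, seed = 10)
  g <- value_grid(-1, 1, 1)
  ctl <- bp_control(beta = 2, lambda = 1, seed = 5)
  fit <- bp_infer(d, g, ctl)
  for (i in 1:2) {
    j <- 3 - i
    oracle <- enumerate_row_marginals(d$X[j, , drop = FALSE], d$X[i, ],
                                      d$U[i, ], as.numeric(g), 2, 1)
    expect_equal(fit$P[i, j, ], oracle[1, ], tolerance = 1e-6)
  }
  # rows with 3 free parameters, K = 5, on realistically scaled responses
  # (tanh-bounded steady states). In the weak-coupling regime, where row
  # posteriors are unimodal and the Gaussian cavity-field summary is valid,
  # every marginal agrees with enumeration within total variation 0.05; at
  # the operating coupling the full distributions can deviate (the
  # factorized updates are overconfident on multi-modal rows) but the
  # marginal means still track the enumeration means closely.
  g5 <- value_grid(-1, 1, 0.5)
  om <- as.numeric(g5)
  for (sd in 11:14) {
    d4 <- generator_dataset(n = 4, e = 6, m = 8, seed = sd)$data
    fitw <- bp_infer(d4, g5, bp_control(beta = 0.25, lambda = 1, seed = 5))
    fito <- bp_infer(d4, g5, bp_control(beta = 2, lambda = 1, seed = 5))
    for (i in 1:4) {
      src <- setdiff(1:4, i)
      or_w <- enumerate_row_marginals(d4$X[src, , drop = FALSE], d4$X[i, ],
                                      d4$U[i, ], om, 0.25, 1)
      or_o <- enumerate_row_marginals(d4$X[src, , drop = FALSE], d4$X[i, ],
                                      d4$U[i, ], om, 2, 1)
      for (s in seq_along(src)) {
        expect_lt(total_variation(fitw$P[i, src[s], ], or_w[s, ]), 0.05)
        expect_lt(abs(sum(fito$P[i, src[s], ] * om) - sum(or_o[s, ] * om)),
                  0.1)
      }
    }
  }
})

test_that("no data and zero temperature reduce to the prior", {
  g <- value_grid(-1, 1, 0.2)
  K <- 11
  lam <- 5
  d0 <- perturbation_data(X = matrix(numeric(0), 3, 0),
                          U = matrix(numeric(0), 3, 0))
  fit0 <- bp_infer(d0, g, bp_control(lambda = lam, seed = 1))
  prior <- exp(pertnet:::sparsity_prior(g, lam))
  prior <- prior / sum(prior)
  expect_equal(fit0$P[1, 2, ], prior, tolerance = 1e-12)
  expect_equal(fit0$P[1, 2, g == 0], exp(lam) / (exp(lam) + K - 1),
               tolerance = 1e-12)
  # beta = 0 with data: marginals equal the prior too
  d <- random_dataset(3, 4, seed = 14)
  fitb <- bp_infer(d, g, bp_control(beta = 0, lambda = lam, seed = 1))
  expect_equal(fitb$P[2, 3, ], prior, tolerance = 1e-9)
})

test_that("marginals stay normalized and runs are deterministic", {
  gd <- generator_dataset(n = 5, e = 8, m = 10, seed = 15)
  g <- value_grid(-1, 1, 0.2)
  f1 <- bp_infer(gd$data, g, bp_control(seed = 33))
  f2 <- bp_infer(gd$data, g, bp_control(seed = 33))
  expect_identical(f1$P, f2$P)
  sums <- apply(f1$P, c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-9)
  # structural zeros: diagonal marginals are deltas at zero
  expect_equal(f1$P[1, 1, ], as.numeric(g == 0))
})

test_that("edge count responds monotonically to the sparsity weight", {
  gd <- generator_dataset(n = 5, e = 8, m = 12, seed = 16)
  g <- value_grid(-1, 1, 0.2)
  called <- vapply(c(0.5, 2, 5, 8), function(lam) {
    fit <- bp_infer(gd$data, g, bp_control(lambda = lam, seed = 3))
    sum(representative_network(fit)$W != 0)
  }, numeric(1))
  expect_true(all(diff(called) <= 0))
  # very large lambda empties the representative network
  fit_big <- bp_infer(gd$data, g, bp_control(lambda = 50, seed = 3))
  expect_identical(sum(representative_network(fit_big)$W != 0), 0L)
})

test_that("marginal entropy is 0 for deltas, 1 for uniform", {
  gd <- generator_dataset(n = 4, e = 5, m = 8, seed = 17)
  g <- value_grid(-1, 1, 0.2)
  fit <- bp_infer(gd$data, g, bp_control(seed = 2))
  fit$P[1, 2, ] <- as.numeric(g == 0.4)
  fit$P[1, 3, ] <- rep(1 / 11, 11)
  H <- marginal_entropy(fit)
  expect_equal(H[1, 2], 0)
  expect_equal(H[1, 3], 1, tolerance = 1e-12)
  expect_true(is.na(H[1, 1]))
  Hs <- marginal_entropy(fit, collapse = "sign")
  expect_equal(Hs[1, 2], 0)
  expect_true(all(Hs[fit$edge_mask] <= 1 + 1e-12))
})

test_that("coarse grids yield overconfident (low-entropy) marginals", {
  gd <- generator_dataset(n = 5, e = 8, m = 12, seed = 18)
  f3 <- bp_infer(gd$data, value_grid(-1, 1, 1), bp_control(seed = 4))
  f11 <- bp_infer(gd$data, value_grid(-1, 1, 0.2), bp_control(seed = 4))
  h3 <- mean(marginal_entropy(f3)[f3$edge_mask])
  h11 <- mean(marginal_entropy(f11)[f11$edge_mask])
  expect_lt(h3, h11)
})

test_that("hyperparameter selection honours the connectivity band", {
  gd <- generator_dataset(n = 5, e = 7, m = 12, seed = 19)
  g <- value_grid(-1, 1, 0.2)
  ctl <- select_hyperparameters(gd$data, g, beta_range = 2,
                                lambda_range = c(1, 3, 5, 10),
                                target_connectivity = 7 / 5, band = 0.7,
                                control = bp_control(seed = 6))
  tab <- attr(ctl, "search")
  expect_true(all(c("beta", "lambda", "connectivity", "error") %in%
                    colnames(tab)))
  in_band <- abs(tab$connectivity - 7 / 5) <= 0.7
  if (any(in_band)) {
    expect_equal(min(tab$error[in_band]),
                 tab$error[tab$lambda == ctl$lambda & tab$beta == ctl$beta])
  }
  # the shipped default operating point is expressible
  def <- bp_control()
  expect_identical(c(def$beta, def$lambda), c(2, 5))
})
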