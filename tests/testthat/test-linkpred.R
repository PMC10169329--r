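test_that("integrated adjacency is the symmetric block stack", {
  a <- integrate_network(matrix(1, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1))
  expect_equal(unname(a), matrix(1, 2, 2))

  ds <- random_dataset(4, 6, seed = 2)
  m <- length(ds$mirna_ids); l <- length(ds$lncrna_ids)
  sims <- network_similarities(ds$adj)
  ap <- integrate_network(sims$mirna, sims$lncrna, ds$adj)
  expect_equal(unname(ap), unname(t(ap)))
  expect_equal(unname(ap[seq_len(m), m + seq_len(l)]), unname(ds$adj))

  idn <- integrate_network(diag(3), diag(2), matrix(0, 3, 2))
  expect_equal(unname(idn), diag(5))
  expect_error(integrate_network(diag(3), diag(2), matrix(0, 2, 3)),
               "mismatch")
})

test_that("objective has its ridge form and is minimized at the closed form", {
  set.seed(5)
  a <- random_symmetric(6, 5)
  expect_equal(linkpred_objective(a, matrix(0, 6, 6), 0.3), 0.3 * sum(a^2))
  expect_equal(linkpred_objective(diag(6), diag(6), 7), 6)

  cs <- solve_contribution(a, 0.05)
  f0 <- linkpred_objective(a, cs, 0.05)
  for (i in 1:100) {
    e <- matrix(rnorm(36, sd = 0.01), 6)
    expect_gte(linkpred_objective(a, cs + e, 0.05), f0)
  }
})

test_that("closed-form contribution solves the normal equations", {
  # identity adjacency, alpha = 1: C* = alpha/(1+alpha) I = I/2
  expect_equal(solve_contribution(diag(4), 1), diag(0.5, 4), tolerance = 1e-12)
  expect_equal(solve_contribution(diag(3), 0), matrix(0, 3, 3))

  # stationarity: alpha(2 A'A C - 2 A'A) + 2C ~ 0 relative to gradient at 0
  for (seed in 1:4) {
    a <- random_symmetric(8, seed)
    for (alpha in c(0.007, 0.1)) {
      cs <- solve_contribution(a, alpha)
      ata <- crossprod(a)
      grad <- alpha * (2 * ata %*% cs - 2 * ata) + 2 * cs
      grad0 <- alpha * (-2 * ata)
      expect_lt(norm(grad, "F"), 1e-8 * norm(grad0, "F"))
    }
  }
})

test_that("contribution matches an independent iterative minimizer", {
  for (seed in 1:3) {
    a <- random_symmetric(8, seed + 20)
    cs <- solve_contribution(a, 0.01)
    oracle <- solve_contribution_oracle(a, 0.01)
    expect_lt(norm(cs - oracle, "F") / norm(oracle, "F"), 1e-4)
  }
})

test_that("contribution eigenvalues follow alpha*lambda^2 / (1 + alpha*lambda^2)", {
  for (seed in 1:4) {
    a <- random_symmetric(10, seed + 40)
    lam <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    for (alpha in c(0.007, 0.2)) {
      cs <- solve_contribution(a, alpha)
      mu <- eigen(cs, symmetric = TRUE, only.values = TRUE)$values
      expected <- sort(alpha * lam^2 / (1 + alpha * lam^2), decreasing = TRUE)
      expect_equal(mu, expected, tolerance = 1e-8)
      expect_true(all(mu >= -1e-12 & mu < 1))
    }
  }
})

test_that("rating matrix inherits symmetry and yields consistent score blocks", {
  # hand-worked 2x2 case: all-ones A', alpha = 0.5
  a <- matrix(1, 2, 2)
  cs <- solve_contribution(a, 0.5)
  expect_equal(cs, matrix(1 / 3, 2, 2), tolerance = 1e-12)
  rs <- rate_network(a, cs)
  expect_equal(rs, matrix(2 / 3, 2, 2), tolerance = 1e-12)
  expect_equal(extract_scores(rs, 1, 1)[1, 1], 2 / 3, tolerance = 1e-12)

  expect_equal(rate_network(diag(3), solve_contribution(diag(3), 1)),
               diag(0.5, 3))
  expect_equal(rate_network(diag(3), solve_contribution(diag(3), 0)),
               matrix(0, 3, 3))
  # diagonal rating matrix has zero cross-block scores
  expect_equal(unname(extract_scores(diag(0.5, 3), 1, 2)),
               matrix(0, 1, 2))

  for (seed in 1:4) {
    a <- random_symmetric(9, seed + 60)
    rs <- rate_network(a, solve_contribution(a, 0.05))
    expect_lt(max(abs(rs - t(rs))), 1e-8 * max(abs(rs)))
  }
  expect_error(extract_scores(matrix(c(0, 1, 0, 0), 2), 1, 1), "symmetry")
})

test_that("the fitted model ranks a masked planted edge and enriches positives", {
  # single observed interaction: its cell must be the unique score maximum
  ds2 <- gklink:::new_dataset(c("a", "b"), c("X", "Y"),
                              matrix(c(1, 0, 0, 0), 2, 2,
                                     dimnames = list(c("a", "b"), c("X", "Y"))))
  fit <- gklink(ds2, profile = "none", alpha = 0.01)
  expect_equal(which.max(fit$scores), 1L)

  # symmetric 2x2 network: simultaneous row/col swap leaves scores invariant
  dsym <- gklink:::new_dataset(c("a", "b"), c("X", "Y"), diag(2))
  fsym <- gklink(dsym, profile = "network", alpha = 0.007)
  expect_equal(unname(fsym$scores), unname(fsym$scores[2:1, 2:1]),
               tolerance = 1e-12)

  # alpha = 0 gives the zero model
  f0 <- gklink(dsym, profile = "network", alpha = 0)
  expect_equal(unname(f0$scores), matrix(0, 2, 2))

  # planted structure: known cells outscore unknown cells on average
  net <- planted_block_network(planted_spec(m = 20, l = 30, n_blocks = 4,
                                            seed = 5))
  fitp <- gklink(net$dataset, profile = "network")
  expect_gt(mean(fitp$scores[net$dataset$adj == 1]),
            mean(fitp$scores[net$dataset$adj == 0]))
})

test_that("profile dispatch wires side data through and errors when absent", {
  net <- planted_block_network(planted_spec(m = 10, l = 12, n_blocks = 2,
                                            seed = 3))
  blocks <- c(net$blocks$mirna, net$blocks$lncrna)
  seqs <- synth_sequences(blocks, length = 30, mutation_rate = 0.1, seed = 4)
  expr <- synth_expression(blocks, n_conditions = 6, noise_sd = 0.2, seed = 4)
  ann <- synth_annotations(blocks, seed = 4)

  for (args in list(list(profile = "sequence", sequences = seqs),
                    list(profile = "expression", expression = expr),
                    list(profile = "function", annotations = ann),
                    list(profile = "none"))) {
    fit <- do.call(gklink, c(list(dataset = net$dataset), args))
    expect_true(all(is.finite(fit$scores)))
    expect_equal(dim(fit$scores), c(10L, 12L))
  }
  expect_error(gklink(net$dataset, profile = "sequence"), "requires")
  expect_error(gklink(net$dataset, profile = "expression"), "requires")
  expect_error(gklink(net$dataset, profile = "function"), "requires")
})

test_that("fit object methods are coherent", {
  net <- planted_block_network(planted_spec(m = 12, l = 15, n_blocks = 3,
                                            seed = 2))
  fit <- gklink(net$dataset)
  expect_s3_class(fit, "gklink")
  expect_output(print(fit), "profile: network")
  sm <- summary(fit)
  expect_lt(sm$spectral_norm_c, 1)
  expect_gt(sm$insample_auc, 0.5)
  expect_output(print(sm), "in-sample AUC")

  expect_equal(fitted(fit), fit$rating)
  expect_equal(residuals(fit), fit$adj_prime - fit$rating, tolerance = 1e-12)
  expect_equal(coef(fit), fit$contribution)

  pr <- predict(fit, top = 5)
  expect_equal(nrow(pr), 5L)
  expect_true(all(pr$known == 0L))
  pr_all <- predict(fit, candidates_only = FALSE)
  expect_equal(nrow(pr_all), 12L * 15L)
  expect_equal(pr_all$rank, seq_len(nrow(pr_all)))

  tf <- tempfile(fileext = ".png")
  grDevices::png(tf)
  expect_invisible(plot(fit))
  grDevices::dev.off()
  unlink(tf)
})
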