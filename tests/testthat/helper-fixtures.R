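# Shared fixtures and independent oracles. Oracles deliberately use the
# dumbest correct formulation (double loops, generic optimizers) so they
# cannot share a defect with the implementation under test.

tiny_dataset <- function() {
  tab <- data.frame(mirna_id = c("a", "a", "b"),
                    lncrna_id = c("X", "Y", "X"))
  build_dataset(tab)
}

random_dataset <- function(m, l, density = 0.2, seed = 1) {
  set.seed(seed)
  adj <- matrix(as.numeric(runif(m * l) < density), m, l)
  if (sum(adj) == 0) adj[1, 1] <- 1
  mir <- sprintf("m%02d", seq_len(m)); lnc <- sprintf("L%02d", seq_len(l))
  pos <- which(adj == 1, arr.ind = TRUE)
  build_dataset(data.frame(mirna_id = mir[pos[, 1]],
                           lncrna_id = lnc[pos[, 2]]))
}

# brute-force AUC: count every (positive, negative) pair
auc_bruteforce <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# brute-force Ochiai set similarity
ochiai_bruteforce <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0)
  length(intersect(a, b)) / sqrt(length(a) * length(b))
}

# generic-optimizer oracle for the contribution matrix: minimize the
# ridge-type objective over vec(C) with analytic gradient
solve_contribution_oracle <- function(adj_prime, alpha) {
  n <- nrow(adj_prime)
  ata <- crossprod(adj_prime)
  fn <- function(v) {
    C <- matrix(v, n, n)
    alpha * sum((adj_prime - adj_prime %*% C)^2) + sum(C^2)
  }
  gr <- function(v) {
    C <- matrix(v, n, n)
    as.vector(alpha * (2 * ata %*% C - 2 * ata) + 2 * C)
  }
  res <- optim(rep(0, n * n), fn, gr, method = "L-BFGS-B",
               control = list(maxit = 2000, factr = 10))
  matrix(res$par, n, n)
}

random_symmetric <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  (a + t(a)) / 2
}

expect_similarity_contract <- function(s) {
  expect_true(is.matrix(s))
  expect_equal(nrow(s), ncol(s))
  expect_lt(max(abs(s - t(s))), 1e-10)
  expect_true(all(s >= -1e-12 & s <= 1 + 1e-12))
  expect_equal(unname(diag(s)), rep(1, nrow(s)))
}
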