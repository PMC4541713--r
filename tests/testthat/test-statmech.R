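test_that("Z(0) counts all configurations exactly", {
  for (seed in 1:6) {
    N <- sample(2:10, 1)
    m <- random_coupling_model(N, 0.5, seed = 400 + seed)
    expect_identical(partition_function(m, NULL, 0)$Z, 2^N)
  }
})

test_that("single-coupling Z matches the closed form on a grid", {
  J <- 0.7
  m <- pair_model(J)
  cc <- clique_complex(rbind(c(1, 2)), 2)
  for (x in seq(0, 4, length.out = 20))
    expect_equal(partition_function(m, cc, x)$Z, 3 + exp(-2 * x * J),
                 tolerance = 1e-12)
})

test_that("zero-valued couplings leave Z unchanged", {
  m <- pair_model(0.6)
  cc3 <- k3_complex()
  m3 <- coupling_model(3, S = 0,
                       pairwise = rbind(c(0, 0.6, 0), c(0.6, 0, 0), c(0, 0, 0)),
                       higher = list(list(simplex = c(1, 2, 3), J = 0)))
  for (x in c(0, 0.7, 2))
    expect_equal(partition_function(m3, cc3, x)$Z,
                 2 * partition_function(m, NULL, x)$Z,  # extra free antibody doubles Z
                 tolerance = 1e-12)
})

test_that("enumeration engine agrees with the naive nested-loop oracle", {
  for (seed in 1:8) {
    N <- sample(3:6, 1)
    fix <- random_multilinear_model(N, 0.6, seed = 500 + seed)
    for (x in c(0, 0.4, 1.5)) {
      expect_equal(partition_function(fix$model, fix$complex, x)$Z,
                   naive_partition(fix$model, fix$complex, x),
                   tolerance = 1e-12)
      idx <- sort(sample(N, min(2, N)))
      expect_equal(correlation(fix$model, fix$complex, x, idx),
                   naive_correlation(fix$model, fix$complex, x, idx),
                   tolerance = 1e-12)
    }
  }
})

test_that("correlations obey the uniform-measure and monotonicity laws", {
  m <- random_coupling_model(6, 0.5, seed = 600)
  for (k in 1:3) {
    idx <- sort(sample(6, k))
    expect_equal(correlation(m, NULL, 0, idx), 2^-k, tolerance = 1e-12)
  }
  # closed form for the single-coupling pair and its x -> Inf limit
  J <- 0.9
  mp <- pair_model(J)
  for (x in c(0.3, 1, 3)) {
    g1 <- correlation(mp, NULL, x, 1)
    expect_equal(g1, (1 + exp(-2 * x * J)) / (3 + exp(-2 * x * J)),
                 tolerance = 1e-12)
  }
  expect_equal(correlation(mp, NULL, 60, 1), 1 / 3, tolerance = 1e-10)
  # superset correlation never exceeds subset correlation
  set.seed(61)
  for (rep in 1:15) {
    m2 <- random_coupling_model(5, 0.6, seed = 700 + rep)
    x <- runif(1, 0, 2)
    sub <- sort(sample(5, 2)); sup <- sort(union(sub, sample(5, 1)))
    expect_lte(correlation(m2, NULL, x, sup),
               correlation(m2, NULL, x, sub) + 1e-12)
    g <- correlation(m2, NULL, x, sub)
    expect_gte(g, 0); expect_lte(g, 1)
  }
  expect_error(correlation(m, NULL, 1, c(2, 2)), "duplicate")
})

test_that("observable sweep reports uniform baseline and crossover candidate", {
  m <- random_coupling_model(5, 0.5, seed = 800)
  s0 <- observable_sweep(m, NULL, 0)
  expect_equal(s0$m, 0.5, tolerance = 1e-12)
  expect_identical(s0$Z, 2^5)
  # all-zero couplings: E = 0, uniform at every x
  m0 <- random_coupling_model(4, 0, seed = 1)
  sw0 <- observable_sweep(m0, NULL, c(0, 1, 2))
  expect_true(all(abs(sw0$m - 0.5) < 1e-12))
  expect_true(all(sw0$Z == 2^4))
  # positive single coupling: m strictly decreasing in x
  sw <- observable_sweep(pair_model(0.8), NULL, seq(0, 3, by = 0.5))
  expect_true(all(diff(sw$m) < 0))
  expect_equal(sum(sw$crossover_flag), 1L)
  expect_error(observable_sweep(m, NULL, c(1, 0.5)), "ascending")
})

test_that("Z and correlations are invariant under vertex relabeling", {
  fix <- random_multilinear_model(5, 0.7, seed = 900)
  p <- c(3L, 5L, 1L, 2L, 4L)
  Jp <- fix$model$pairwise; Jp[p, p] <- Jp
  verts <- attr(fix$model$higher, "vertices")
  higher_p <- lapply(seq_along(fix$model$higher), function(k)
    list(simplex = sort(p[verts[[k]]]), J = fix$model$higher[[k]]))
  mp <- coupling_model(5, S = fix$model$S, pairwise = Jp, higher = higher_p)
  ccp <- clique_complex(which(upper.tri(Jp) & Jp != 0, arr.ind = TRUE), 5,
                        max_dim = 3)
  for (x in c(0.5, 1.5)) {
    expect_equal(partition_function(fix$model, fix$complex, x)$Z,
                 partition_function(mp, ccp, x)$Z, tolerance = 1e-12)
    expect_equal(correlation(fix$model, fix$complex, x, c(1, 4)),
                 correlation(mp, ccp, x, sort(p[c(1, 4)])), tolerance = 1e-12)
  }
})

test_that("the global-flip quotient sums half the valuations", {
  m <- random_coupling_model(5, 0.4, seed = 950)
  r <- partition_function(m, NULL, 0, identify_global_flip = TRUE)
  expect_identical(r$Z, 2^4)
  expect_identical(r$n_configs, 16L)
  expect_error(partition_function(random_coupling_model(21, 0.1, seed = 1),
                                  NULL, 0), "cap")
})
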