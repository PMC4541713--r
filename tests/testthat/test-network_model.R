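test_that("heaviside follows the threshold convention", {
  expect_identical(heaviside(-0.5), 0L)
  expect_identical(heaviside(2.0), 1L)
  expect_identical(heaviside(0), 1L)            # tie-break: produced
  expect_identical(heaviside(0, zero_value = 0L), 0L)
  expect_identical(heaviside(c(-1, 0, 1)), c(0L, 1L, 1L))
  expect_error(heaviside(NaN))
  expect_error(heaviside(Inf))
})

test_that("coupling_model enforces its invariants", {
  expect_error(coupling_model(2, pairwise = matrix(c(1, 0, 0, 0), 2)),
               "diagonal")
  expect_error(coupling_model(2, pairwise = matrix(c(0, 1, 0.5, 0), 2)),
               "symmetric")
  expect_error(coupling_model(3, higher = list(list(simplex = c(3, 2, 1), J = 1))),
               "increasing")
  expect_error(coupling_model(3, higher = list(list(simplex = c(1, 2), J = 1))),
               ">= 3")
  expect_error(coupling_model(3, higher = list(list(simplex = c(1, 2, 4), J = 1))),
               "range")
  expect_error(coupling_model(2, pairwise = matrix(c(0, 2, 2, 0), 2),
                              strict_range = TRUE),
               "\\[-1, 1\\]")
  # the [-1, 1] interval is the sampling convention, not a hard constraint
  expect_s3_class(coupling_model(2, pairwise = matrix(c(0, 2, 2, 0), 2)),
                  "coupling_model")
})

test_that("immune_state validates binary vectors", {
  expect_identical(immune_state(c(1, 0, 1)), c(1L, 0L, 1L))
  expect_error(immune_state(c(0.5, 1)), "0 or 1")
  expect_error(immune_state(c(1, 0), N = 3), "length")
})

test_that("linear mean field matches hand evaluation", {
  m <- pair_model(0.5)
  expect_equal(linear_mean_field(c(1, 1), m), c(0.5, 0.5))
  m2 <- pair_model(1, S = -0.2)
  expect_equal(linear_mean_field(c(0, 1), m2), c(0.8, -0.2))
  # empty sum: all-zero state gives h = S everywhere
  m3 <- random_coupling_model(6, 0.5, seed = 3, S = 0.7)
  expect_equal(linear_mean_field(rep(0, 6), m3), rep(0.7, 6))
  expect_error(linear_mean_field(c(1, 1, 1), m), "length")
})

test_that("multilinear mean field reduces to the linear one for pairwise models", {
  set.seed(11)
  m <- random_coupling_model(7, 0.6, seed = 12)
  edges <- which(upper.tri(m$pairwise) & m$pairwise != 0, arr.ind = TRUE)
  cc <- clique_complex(edges, 7)
  for (r in 1:10) {
    s <- sample(0:1, 7, replace = TRUE)
    expect_equal(multilinear_mean_field(s, m, cc), linear_mean_field(s, m))
  }
})

test_that("higher-order couplings contribute the product over the other vertices", {
  m <- coupling_model(3, S = 0, higher = list(list(simplex = c(1, 2, 3), J = -1)))
  cc <- k3_complex()
  expect_equal(multilinear_mean_field(c(1, 1, 1), m, cc), c(-1, -1, -1))
  # a zero concentration annihilates the product
  h <- multilinear_mean_field(c(1, 0, 1), m, cc)
  expect_equal(h[1], 0)
  expect_equal(h[2], -1)
  # key must be a simplex of the complex
  path3 <- clique_complex(rbind(c(1, 2), c(2, 3)), 3)
  expect_error(multilinear_mean_field(c(1, 1, 1), m, path3), "not a simplex")
})

test_that("energy matches hand-derived values", {
  m <- pair_model(0.8)
  cc <- clique_complex(rbind(c(1, 2)), 2)
  expect_equal(energy(c(0, 0), m, cc), 0)
  expect_equal(energy(c(1, 1), m, cc), 2 * 0.8)
  m1 <- coupling_model(1, S = 0.3)
  expect_equal(energy(c(1), m1), 0.3)
})

test_that("pairwise energy satisfies the symmetry double-count identity", {
  for (seed in 1:5) {
    N <- 5L
    m <- random_coupling_model(N, 0.7, seed = seed)
    states <- as.matrix(expand.grid(rep(list(0:1), N)))
    for (r in seq_len(nrow(states))) {
      s <- as.integer(states[r, ])
      direct <- 0
      for (i in 1:(N - 1)) for (k in (i + 1):N)
        direct <- direct + 2 * m$pairwise[i, k] * s[i] * s[k]
      expect_equal(energy(s, m), direct, tolerance = 1e-12)
    }
  }
})

test_that("mean field is equivariant under vertex relabeling", {
  set.seed(21)
  for (rep in 1:5) {
    fix <- random_multilinear_model(6, 0.7, seed = 30 + rep)
    s <- sample(0:1, 6, replace = TRUE)
    h <- multilinear_mean_field(s, fix$model, fix$complex)
    p <- sample(6)  # p maps old vertex i to new label p[i]
    Jp <- fix$model$pairwise
    Jp[p, p] <- Jp
    verts <- attr(fix$model$higher, "vertices")
    higher_p <- lapply(seq_along(fix$model$higher), function(k)
      list(simplex = sort(p[verts[[k]]]), J = fix$model$higher[[k]]))
    mp <- coupling_model(6, S = fix$model$S, pairwise = Jp, higher = higher_p)
    edges_p <- which(upper.tri(Jp) & Jp != 0, arr.ind = TRUE)
    ccp <- clique_complex(edges_p, 6, max_dim = 3)
    sp <- integer(6); sp[p] <- s
    hp <- multilinear_mean_field(sp, mp, ccp)
    expect_equal(hp[p], h, tolerance = 1e-12)
  }
})
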