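test_that("support inference returns verified witnesses", {
  g1 <- infer_coupling_support(4, c(1, 1), budget = 500, seed = 42)
  b1 <- as.integer(betti_numbers(clique_complex(g1, 4, max_dim = 3)))
  expect_true(compare_betti(b1, c(1, 1))$match)

  g2 <- infer_coupling_support(3, c(1, 0), budget = 100, seed = 1)
  b2 <- as.integer(betti_numbers(clique_complex(g2, 3, max_dim = 3)))
  expect_true(compare_betti(b2, c(1, 0))$match)

  g3 <- infer_coupling_support(6, c(1, 0, 1), budget = 2000, seed = 7)
  b3 <- as.integer(betti_numbers(clique_complex(g3, 6, max_dim = 4)))
  expect_true(compare_betti(b3, c(1, 0, 1))$match)
})

test_that("inference is reproducible and annealing alone can solve easy targets", {
  ga <- infer_coupling_support(4, c(1, 1), budget = 500, seed = 42,
                               init = "random")
  gb <- infer_coupling_support(4, c(1, 1), budget = 500, seed = 42,
                               init = "random")
  expect_identical(ga, gb)
  expect_true(compare_betti(attr(ga, "betti"), c(1, 1))$match)
})

test_that("unsatisfiable-by-construction targets are rejected before searching", {
  expect_error(infer_coupling_support(4, c(0, 1)), "b_0")
  expect_error(infer_coupling_support(3, c(5)), "more than N")
  expect_error(infer_coupling_support(4, c(-1, 1)), "non-negative")
})

test_that("budget exhaustion reports an honest failure with the search state", {
  err <- tryCatch(
    infer_coupling_support(3, c(1, 1, 1), budget = 40, seed = 5),
    error = function(e) e)
  expect_s3_class(err, "idionet_inference_failure")
  expect_true(!is.null(err$report$best_edges))
  expect_gte(err$report$evaluations, 1L)
  expect_equal(err$report$target, c(1L, 1L, 1L))
})

test_that("geometric coupling values follow the volume/curvature rule", {
  k3 <- k3_complex()
  m10 <- assign_coupling_values(k3, a = 1, b = 0)
  expect_equal(m10$pairwise[1, 2], -1)
  expect_equal(m10$higher[[1]], -sqrt(3) / 4, tolerance = 1e-12)
  m00 <- assign_coupling_values(k3, a = 0, b = 0)
  expect_true(all(m00$pairwise == 0))
  expect_true(all(unlist(m00$higher) == 0))
  # curvature term: triangle boundary = 3 points of unit volume
  m01 <- assign_coupling_values(k3, a = 0, b = 1)
  expect_equal(m01$higher[[1]], -3)
  expect_error(assign_coupling_values(k3, a = -1), ">= 0")
})

test_that("coupling values are monotone in the volume and curvature weights", {
  oct <- planted_model("octahedron")$complex
  grid <- expand.grid(a = c(0, 0.5, 1), b = c(0, 0.5, 1))
  vals <- lapply(seq_len(nrow(grid)), function(r) {
    m <- assign_coupling_values(oct, grid$a[r], grid$b[r])
    c(m$pairwise[upper.tri(m$pairwise)], unlist(m$higher))
  })
  for (r in seq_len(nrow(grid))) for (s in seq_len(nrow(grid))) {
    if (grid$a[r] <= grid$a[s] && grid$b[r] <= grid$b[s])
      expect_true(all(vals[[s]] <= vals[[r]] + 1e-15))
  }
})

test_that("S[B] systems validate their defining invariants", {
  p <- planted_model("cycle")
  sys <- sb_system(p$model, p$complex)
  chk <- check_sb(sys)
  expect_true(chk$ok)
  expect_length(chk$violations, 0)
  # undefined observation
  broken <- sys
  broken$S$observation <- NULL
  expect_false(check_sb(broken)$ok)
  expect_match(check_sb(broken)$violations, "observation")
  # initial constraint violated
  broken2 <- sys
  broken2$S$contexts[[1]] <- c(3L, 3L)
  chk2 <- check_sb(broken2)
  expect_false(chk2$ok)
  expect_match(chk2$violations, "initial-constraint")
})

test_that("adaptation is a no-op when the topologies already match", {
  p <- planted_model("cycle")
  sys <- sb_system(p$model, p$complex)
  res <- sb_adapt(sys, p$model, p$complex, c(1, 1), seed = 3)
  expect_false(res$adapted)
  expect_identical(res$model, p$model)
  expect_identical(res$system, sys)
})

test_that("adaptation rebuilds the model to match the data topology", {
  tree <- clique_complex(rbind(c(1, 2), c(2, 3), c(3, 4)), 4)
  tm <- assign_coupling_values(tree, 1, 0)
  sys <- sb_system(tm, tree)
  expect_true(compare_betti(betti_numbers(tree), c(1, 0))$match)
  res <- sb_adapt(sys, tm, tree, c(1, 1), seed = 42, budget = 500)
  expect_true(res$adapted)
  expect_true(compare_betti(betti_numbers(res$complex), c(1, 1))$match)
  expect_true(check_sb(res$system)$ok)
  # contexts accumulate, the prior context is preserved
  expect_equal(length(res$system$S$contexts), 2L)
  expect_equal(res$system$S$contexts[[1]], as.integer(betti_numbers(tree)))
  # idempotent once adapted
  res2 <- sb_adapt(res$system, res$model, res$complex, c(1, 1), seed = 9)
  expect_false(res2$adapted)
})
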