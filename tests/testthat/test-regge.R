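test_that("triangle geometry matches closed forms and flags degeneracies", {
  g <- triangle_geometry(1, 1, 1)
  expect_equal(g$area, sqrt(3) / 4, tolerance = 1e-12)
  expect_equal(g$angles, rep(pi / 3, 3), tolerance = 1e-12)
  g2 <- triangle_geometry(1, 1, 2)
  expect_equal(g2$area, 0.5, tolerance = 1e-12)
  expect_equal(sort(g2$angles), c(pi / 4, pi / 4, pi / 2), tolerance = 1e-12)
  expect_equal(sum(g2$angles), pi, tolerance = 1e-12)
  expect_error(triangle_geometry(1, 1, 4), "triangle inequality")
  expect_error(triangle_geometry(0, 1, 1), "positive")
})

test_that("preset triangulations are closed surfaces with the right topology", {
  tet <- triangulation_preset("tetrahedron")
  expect_equal(c(tet$n_vertices, nrow(tet$edges), nrow(tet$triangles)),
               c(4L, 6L, 4L))
  expect_equal(tet$chi, 2L)
  oct <- triangulation_preset("octahedron")
  expect_equal(c(oct$n_vertices, nrow(oct$edges), nrow(oct$triangles)),
               c(6L, 12L, 8L))
  expect_equal(oct$chi, 2L)
  tor <- triangulation_preset("torus16")
  expect_equal(nrow(tor$triangles), 16L)
  expect_equal(tor$chi, 0L)
  # an open surface is rejected
  expect_error(triangulation2d(rbind(c(1, 2, 3)), 3), "closed surface")
})

test_that("edge configurations validate sigma, amplitude and triangle inequalities", {
  tet <- triangulation_preset("tetrahedron")
  cfg <- z2_edge_config(tet, rep(1L, 6), 0.3)
  expect_true(cfg$valid)
  expect_equal(cfg$q, rep(1.3, 6))
  expect_error(z2_edge_config(tet, rep(1L, 5), 0.3), "edge count")
  expect_error(z2_edge_config(tet, rep(2L, 6), 0.3), "\\+1 or -1")
  expect_error(z2_edge_config(tet, rep(1L, 6), 1), "\\[0, 1\\)")
  # large amplitude with mixed signs can violate the triangle inequality
  bad <- z2_edge_config(tet, c(1L, -1L, -1L, -1L, -1L, 1L), 0.95)
  expect_false(bad$valid)
  expect_error(deficit_angles(tet, bad), "violates")
})

test_that("deficit angles recover the curvature of the equilateral sphere", {
  tet <- triangulation_preset("tetrahedron")
  cfg <- z2_edge_config(tet, rep(1L, 6), 0)
  expect_equal(deficit_angles(tet, cfg), rep(pi, 4), tolerance = 1e-12)
})

test_that("Gauss-Bonnet holds for random valid configurations on all fixtures", {
  set.seed(123)
  fixtures <- list(triangulation_preset("tetrahedron"),
                   triangulation_preset("octahedron"),
                   triangulation_preset("torus16"))
  for (tri in fixtures) {
    for (rep in 1:20) {
      cfg <- random_valid_config(tri, 0.3)
      expect_equal(sum(deficit_angles(tri, cfg)), 2 * pi * tri$chi,
                   tolerance = 1e-9)
    }
  }
})

test_that("the action combines areas and deficits linearly", {
  tet <- triangulation_preset("tetrahedron")
  cfg <- z2_edge_config(tet, rep(1L, 6), 0)
  expect_equal(regge_action(tet, cfg, 1, 1), sqrt(3) - 4 * pi,
               tolerance = 1e-12)
  expect_equal(regge_action(tet, cfg, 2, 1), 2 * regge_action(tet, cfg, 1, 1),
               tolerance = 1e-12)
  expect_equal(regge_action(tet, cfg, 1.7, 0), 1.7 * 4 * sqrt(3) / 4,
               tolerance = 1e-12)
  cfg3 <- z2_edge_config(tet, rep(1L, 6), 0.3)
  a <- sum(vapply(1:4, function(t) triangle_geometry(1.3, 1.3, 1.3)$area, 0))
  expect_equal(regge_action(tet, cfg3, 1, 0), a, tolerance = 1e-12)
})

test_that("the Z2 state sum matches the brute-force oracle on the tetrahedron", {
  tet <- triangulation_preset("tetrahedron")
  for (params in list(c(0.3, 1, 1, 0), c(0.3, 1, 1, 0.7), c(0.6, 0.5, 2, 0))) {
    got <- z2_regge_partition(tet, params[1], params[2], params[3], params[4])
    want <- naive_regge_partition(tet, params[1], params[2], params[3],
                                  params[4])
    expect_equal(got$Z, want$Z, tolerance = 1e-12)
    expect_equal(got$n_valid, want$n_valid)
  }
})

test_that("zero amplitude collapses the state sum to a single geometry", {
  tet <- triangulation_preset("tetrahedron")
  cfg <- z2_edge_config(tet, rep(1L, 6), 0)
  got <- z2_regge_partition(tet, 0, 1, 1, 0)
  expect_equal(got$Z, 2^6 * exp(-regge_action(tet, cfg, 1, 1)),
               tolerance = 1e-9)
  expect_equal(got$n_valid, 64L)
})

test_that("near-unit amplitudes exclude configurations via F(q)", {
  tet <- triangulation_preset("tetrahedron")
  got <- z2_regge_partition(tet, 0.95, 1, 1, 0)
  expect_lt(got$n_valid, got$n_total)
  expect_error(z2_regge_partition(triangulation_preset("torus16"),
                                  0.3, 1, 1, 0, cap = 20L), "cap")
})

test_that("Z is monotone decreasing in x for positive-action geometries", {
  tet <- triangulation_preset("tetrahedron")
  # zeta = 0 keeps the action positive (pure area term)
  Zs <- vapply(c(0.5, 1, 2, 4),
               function(x) z2_regge_partition(tet, 0.3, x, 0, 0)$Z, 0)
  expect_true(all(diff(Zs) < 0))
})

test_that("global sigma flip is a symmetry of the alpha = 0 state sum terms", {
  oct <- triangulation_preset("octahedron")
  set.seed(8)
  for (rep in 1:5) {
    cfg <- random_valid_config(oct, 0.4)
    flipped <- z2_edge_config(oct, -cfg$sigma, 0.4)
    if (flipped$valid) {
      # both orientations contribute, with actions exchanged under q -> 2 - q
      expect_equal(sum(deficit_angles(oct, cfg)),
                   sum(deficit_angles(oct, flipped)), tolerance = 1e-9)
    }
  }
})

test_that("sigma/concentration conversion is the stated bijection", {
  s <- c(1L, 0L, 0L, 1L)
  expect_equal(sigma_from_state(s), c(1L, -1L, -1L, 1L))
  expect_equal(state_from_sigma(sigma_from_state(s)), s)
  expect_error(state_from_sigma(c(0L, 1L)), "\\+/-1")
})
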