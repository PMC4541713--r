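# Shared fixtures and independent brute-force oracles.

# N = 2 model with a single symmetric coupling J and threshold S
pair_model <- function(J, S = 0) {
  coupling_model(2L, S = S, pairwise = matrix(c(0, J, J, 0), 2L))
}

k3_complex <- function() clique_complex(rbind(c(1, 2), c(2, 3), c(1, 3)), 3L)

# Independent energy: explicit nested loops straight from the definitions,
# sharing no code with the package's vectorized enumeration path.
naive_energy <- function(state, model, complex = NULL) {
  N <- model$N
  E <- 0
  for (i in seq_len(N)) {
    h <- model$S
    for (k in seq_len(N)) if (k != i) h <- h + model$pairwise[i, k] * state[k]
    if (length(model$higher)) {
      verts <- attr(model$higher, "vertices")
      for (s in seq_along(model$higher)) {
        v <- verts[[s]]
        if (i %in% v) {
          p <- 1
          for (j in v) if (j != i) p <- p * state[j]
          h <- h + model$higher[[s]] * p
        }
      }
    }
    E <- E + h * state[i]
  }
  E
}

naive_partition <- function(model, complex = NULL, x) {
  N <- model$N
  Z <- 0
  for (idx in 0:(2^N - 1)) {
    state <- as.integer((idx %/% 2^(0:(N - 1))) %% 2)
    Z <- Z + exp(-x * naive_energy(state, model, complex))
  }
  Z
}

naive_correlation <- function(model, complex = NULL, x, indices) {
  N <- model$N
  num <- 0; Z <- 0
  for (idx in 0:(2^N - 1)) {
    state <- as.integer((idx %/% 2^(0:(N - 1))) %% 2)
    w <- exp(-x * naive_energy(state, model, complex))
    Z <- Z + w
    num <- num + prod(state[indices]) * w
  }
  num / Z
}

# Random model with both pairwise and (where triangles exist) higher-order
# couplings attached to clique-complex cells.
random_multilinear_model <- function(N, edge_prob, seed, n_higher = 2L) {
  m <- random_coupling_model(N, edge_prob, seed)
  edges <- which(upper.tri(m$pairwise) & m$pairwise != 0, arr.ind = TRUE)
  cc <- clique_complex(edges, N, max_dim = 3L)
  tris <- if (cc$max_dim >= 2L) cc$simplices[[3L]] else
    matrix(integer(0), 0, 3)
  higher <- list()
  if (nrow(tris) > 0) {
    set.seed(seed + 1L)
    take <- seq_len(min(n_higher, nrow(tris)))
    vals <- stats::runif(length(take), -1, 1)
    higher <- lapply(seq_along(take), function(k)
      list(simplex = tris[take[k], ], J = vals[k]))
  }
  list(model = coupling_model(N, S = m$S, pairwise = m$pairwise,
                              higher = higher),
       complex = cc)
}

# Brute-force Z2 Regge partition sum: one nested loop per configuration,
# using only triangle_geometry and hand-summed deficits.
naive_regge_partition <- function(tri, l_amp, x, zeta, alpha) {
  nE <- nrow(tri$edges)
  Z <- 0; n_valid <- 0L
  for (idx in 0:(2^nE - 1)) {
    sigma <- 2L * as.integer((idx %/% 2^(0:(nE - 1))) %% 2) - 1L
    q <- 1 + l_amp * sigma
    areas <- 0; angle_sum <- 0; ok <- TRUE
    for (t in seq_len(nrow(tri$triangles))) {
      e <- tri$triangle_edges[t, ]
      g <- tryCatch(triangle_geometry(q[e[1]], q[e[2]], q[e[3]]),
                    error = function(err) NULL)
      if (is.null(g)) { ok <- FALSE; break }
      areas <- areas + g$area
      angle_sum <- angle_sum + sum(g$angles)
    }
    if (!ok) next
    n_valid <- n_valid + 1L
    deficit_total <- 2 * pi * tri$n_vertices - angle_sum
    A <- x * (areas - zeta * deficit_total)
    Z <- Z + prod(q^(-alpha)) * exp(-A)
  }
  list(Z = Z, n_valid = n_valid)
}

# Independent state enumeration (expand.grid, not the package's bit loop)
enumerate_states_for_test <- function(N) {
  m <- as.matrix(expand.grid(rep(list(0:1), N)))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# Random sigma configuration guaranteed valid (rejection sampling)
random_valid_config <- function(tri, l_amp) {
  repeat {
    sigma <- sample(c(-1L, 1L), nrow(tri$edges), replace = TRUE)
    cfg <- z2_edge_config(tri, sigma, l_amp)
    if (cfg$valid) return(cfg)
  }
}
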