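#' Random idiotypic coupling model
#'
#' Erdős–Rényi coupling support with i.i.d. uniform[-1, 1] coupling values
#' (the interval the influence couplings are drawn from), symmetrized, zero
#' diagonal. Fully reproducible from the seed.
#'
#' @param N number of antibodies.
#' @param edge_prob probability of each pairwise coupling being present.
#' @param seed RNG seed.
#' @param S threshold parameter (default 0, the regime where couplings are
#'   not uniformly small).
#' @return a \code{coupling_model}.
#' @export
random_coupling_model <- function(N, edge_prob, seed, S = 0) {
  if (edge_prob < 0 || edge_prob > 1)
    stop("random_coupling_model: edge_prob must be in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  J <- matrix(0, N, N)
  if (N >= 2) {
    pairs <- which(upper.tri(J), arr.ind = TRUE)
    present <- stats::runif(nrow(pairs)) < edge_prob
    vals <- stats::runif(nrow(pairs), -1, 1) * present
    J[pairs] <- vals
    J <- J + t(J)
  }
  coupling_model(N, S = S, pairwise = J)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Planted topological fixtures
#'
#' Named graphs with known clique-complex topology, used as ground truth by
#' the Betti-recovery loop and the test-suite: \code{cycle} (4-cycle, Betti
#' (1,1)), \code{octahedron} (K_{2,2,2}, Betti (1,0,1): a triangulated
#' 2-sphere), \code{two_components} (two disjoint triangles, Betti (2,0)).
#' \code{torus16} returns a closed 16-triangle torus
#' \code{\link{triangulation2d}} instead of a coupling model.
#'
#' @param preset one of "cycle", "octahedron", "two_components", "torus16".
#' @return for graph presets, a list with \code{model} (unit couplings on
#'   the preset edges), \code{complex} and \code{betti}; for "torus16", a
#'   \code{triangulation2d}.
#' @export
planted_model <- function(preset = c("cycle", "octahedron", "two_components",
                                     "torus16")) {
  preset <- match.arg(preset)
  if (preset == "torus16") return(triangulation_preset("torus16"))
  def <- switch(preset,
    cycle = list(N = 4L, edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)),
                 betti = c(1L, 1L)),
    octahedron = {
      ed <- t(utils::combn(6L, 2L))
      drop <- (ed[, 1] == 1 & ed[, 2] == 2) | (ed[, 1] == 3 & ed[, 2] == 4) |
        (ed[, 1] == 5 & ed[, 2] == 6)
      list(N = 6L, edges = ed[!drop, , drop = FALSE], betti = c(1L, 0L, 1L))
    },
    two_components = list(
      N = 6L,
      edges = rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
      betti = c(2L, 0L)))
  J <- matrix(0, def$N, def$N)
  J[def$edges] <- 1
  J <- pmax(J, t(J))
  complex <- clique_complex(def$edges, def$N)
  list(model = coupling_model(def$N, S = 0, pairwise = J),
       complex = complex, betti = def$betti)
}

#' Noisy concentration trajectories
#'
#' Runs the deterministic dynamics and adds i.i.d. Gaussian observation
#' noise to the 0/1 concentration matrix, emulating measured antibody
#' concentration time series. Rows are antibodies, columns time points.
#'
#' @inheritParams simulate_dynamics
#' @param noise_sd standard deviation of the observation noise (>= 0).
#' @param seed RNG seed for the noise.
#' @return numeric matrix, antibodies x (steps + 1) time points.
#' @export
noisy_trajectories <- function(model, complex = NULL, init, steps, noise_sd,
                               seed, mode = "synchronous") {
  if (noise_sd < 0) stop("noisy_trajectories: noise_sd must be >= 0")
  if (steps < 3) stop("noisy_trajectories: need steps >= 3")
  tr <- simulate_dynamics(model, complex, init, steps, mode)
  mat <- t(unclass(tr))  # antibodies x timepoints
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    mat <- mat + matrix(stats::rnorm(length(mat), sd = noise_sd),
                        nrow(mat), ncol(mat))
  }
  mat
}

#' Jittered circle point cloud
#'
#' Euclidean distance matrix of n points equally spaced on a circle with
#' Gaussian positional jitter: the canonical fixture with one persistent
#' loop (H1 class).
#'
#' @param n_points number of points (>= 4).
#' @param radius circle radius.
#' @param jitter_sd standard deviation of the coordinate jitter.
#' @param seed RNG seed.
#' @return distance matrix (n_points x n_points).
#' @export
circle_cloud <- function(n_points, radius = 1, jitter_sd = 0, seed = 1L) {
  if (n_points < 4) stop("circle_cloud: need at least 4 points")
  theta <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  pts <- radius * cbind(cos(theta), sin(theta))
  if (jitter_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    pts <- pts + matrix(stats::rnorm(2L * n_points, sd = jitter_sd),
                        n_points, 2L)
  }
  as.matrix(stats::dist(pts))
}

#' Two well-separated point clusters
#'
#' Distance matrix of two Gaussian clusters whose separation is about ten
#' times the intra-cluster spread: the canonical (2, 0) Betti fixture.
#'
#' @param n_per_cluster points per cluster.
#' @param separation distance between cluster centres.
#' @param spread_sd intra-cluster standard deviation.
#' @param seed RNG seed.
#' @return distance matrix.
#' @export
two_cluster_cloud <- function(n_per_cluster = 15L, separation = 10,
                              spread_sd = 1, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- 2L * n_per_cluster
  centers <- rbind(c(0, 0), c(separation, 0))
  pts <- centers[rep(1:2, each = n_per_cluster), ] +
    matrix(stats::rnorm(2L * n, sd = spread_sd), n, 2L)
  as.matrix(stats::dist(pts))
}
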