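#' Closed 2-D triangulation (Regge skeleton)
#'
#' A combinatorial closed surface: every edge belongs to exactly two
#' triangles, so the Euler characteristic V - E + F is even. Edges are
#' derived from the triangle list and stored in lexicographic order; all
#' edge-indexed quantities (sigma configurations, squared lengths) follow
#' that order.
#'
#' @param triangles matrix with 3 columns of 1-based vertex indices, one row
#'   per triangle.
#' @param n_vertices vertex count.
#' @return object of class \code{triangulation2d} with fields
#'   \code{n_vertices}, \code{triangles}, \code{edges},
#'   \code{triangle_edges} (index of each triangle's 3 edges) and
#'   \code{chi}.
#' @export
triangulation2d <- function(triangles, n_vertices) {
  triangles <- matrix(as.integer(triangles), ncol = 3)
  triangles <- t(apply(triangles, 1L, sort))
  if (any(triangles < 1) || any(triangles > n_vertices))
    stop("triangulation2d: vertex index out of range")
  if (any(triangles[, 1] == triangles[, 2] | triangles[, 2] == triangles[, 3]))
    stop("triangulation2d: degenerate triangle")
  all_edges <- rbind(triangles[, c(1, 2)], triangles[, c(1, 3)],
                     triangles[, c(2, 3)])
  key <- paste(all_edges[, 1], all_edges[, 2])
  tab <- table(key)
  if (any(tab != 2))
    stop("triangulation2d: not a closed surface (every edge must lie in exactly 2 triangles)")
  edges <- unique(all_edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  ekey <- paste(edges[, 1], edges[, 2])
  te <- cbind(match(paste(triangles[, 1], triangles[, 2]), ekey),
              match(paste(triangles[, 1], triangles[, 3]), ekey),
              match(paste(triangles[, 2], triangles[, 3]), ekey))
  chi <- n_vertices - nrow(edges) + nrow(triangles)
  if (chi %% 2 != 0)
    stop("triangulation2d: odd Euler characteristic; not a closed surface")
  structure(list(n_vertices = as.integer(n_vertices), triangles = triangles,
                 edges = edges, triangle_edges = te, chi = as.integer(chi)),
            class = "triangulation2d")
}

#' @export
print.triangulation2d <- function(x, ...) {
  cat(sprintf("Closed 2-D triangulation: V = %d, E = %d, F = %d, chi = %d\n",
              x$n_vertices, nrow(x$edges), nrow(x$triangles), x$chi))
  invisible(x)
}

#' Preset closed triangulations
#'
#' \code{tetrahedron} (4 triangles, chi = 2), \code{octahedron} (8
#' triangles, chi = 2) and \code{torus16}, a 16-triangle torus (chi = 0)
#' obtained by one edge subdivision of the 7-vertex Moebius torus.
#'
#' @param name preset name.
#' @return a \code{triangulation2d}.
#' @export
triangulation_preset <- function(name = c("tetrahedron", "octahedron",
                                          "torus16")) {
  name <- match.arg(name)
  if (name == "tetrahedron")
    return(triangulation2d(t(utils::combn(4L, 3L)), 4L))
  if (name == "octahedron") {
    # antipodal pairs (1,2), (3,4), (5,6); faces pick one of each pair
    tri <- as.matrix(expand.grid(1:2, 3:4, 5:6))
    return(triangulation2d(tri, 6L))
  }
  # 7-vertex torus: triangles {i, i+1, i+3} and {i, i+2, i+3} mod 7,
  # then subdivide edge {0, 1} with a new vertex (8 vertices, 16 triangles)
  base <- NULL
  for (i in 0:6) {
    base <- rbind(base,
                  c(i, (i + 1) %% 7, (i + 3) %% 7),
                  c(i, (i + 2) %% 7, (i + 3) %% 7))
  }
  base <- base + 1L  # 1-based
  has01 <- apply(base, 1L, function(t) all(c(1L, 2L) %in% t))
  kept <- base[!has01, , drop = FALSE]
  split <- base[has01, , drop = FALSE]
  w <- 8L
  subdivided <- do.call(rbind, lapply(seq_len(nrow(split)), function(r) {
    opp <- setdiff(split[r, ], c(1L, 2L))
    rbind(c(1L, w, opp), c(w, 2L, opp))
  }))
  triangulation2d(rbind(kept, subdivided), 8L)
}

#' Z2 edge-length configuration
#'
#' Squared link lengths restricted to two values: \code{q_l = 1 + l_amp *
#' sigma_l} with \code{sigma_l = +/-1}. The configuration is valid (its
#' measure factor F(q) = 1) when every triangle satisfies the strict
#' triangle inequality on the lengths sqrt(q).
#'
#' @param tri a \code{triangulation2d}.
#' @param sigma vector of +/-1 over the edges (in the triangulation's edge
#'   order).
#' @param l_amp length amplitude in [0, 1).
#' @return object of class \code{z2_edge_config} with fields \code{sigma},
#'   \code{l_amp}, \code{q} and \code{valid}.
#' @export
z2_edge_config <- function(tri, sigma, l_amp) {
  sigma <- as.integer(sigma)
  if (length(sigma) != nrow(tri$edges))
    stop("z2_edge_config: sigma length must equal the edge count")
  if (!all(sigma %in% c(-1L, 1L)))
    stop("z2_edge_config: sigma entries must be +1 or -1")
  if (l_amp < 0 || l_amp >= 1)
    stop("z2_edge_config: l_amp must lie in [0, 1) so that q > 0")
  q <- 1 + l_amp * sigma
  valid <- all(apply(tri$triangle_edges, 1L, function(e) {
    l <- sort(sqrt(q[e]))
    l[1] + l[2] > l[3]
  }))
  structure(list(sigma = sigma, l_amp = l_amp, q = q, valid = valid),
            class = "z2_edge_config")
}

#' Sigma/concentration conversion
#'
#' The dictionary between binary antibody concentrations and Z2 edge signs:
#' \code{sigma = 2c - 1}. Exposes the structural correspondence between the
#' immune model's binary states and the Z2 Regge configurations when the
#' edge count equals N; no physical equivalence is asserted.
#'
#' @param state binary 0/1 vector.
#' @return +/-1 vector (and conversely for \code{state_from_sigma}).
#' @export
sigma_from_state <- function(state) 2L * immune_state(state) - 1L

#' @rdname sigma_from_state
#' @param sigma +/-1 vector.
#' @export
state_from_sigma <- function(sigma) {
  sigma <- as.integer(sigma)
  if (!all(sigma %in% c(-1L, 1L))) stop("state_from_sigma: entries must be +/-1")
  (sigma + 1L) %/% 2L
}

#' Triangle geometry from squared edge lengths
#'
#' Area by Heron's formula and interior angles by the law of cosines, from
#' the three squared edge lengths. Errors when the strict triangle
#' inequality fails (the F(q) = 0 case).
#'
#' @param q1,q2,q3 positive squared edge lengths.
#' @return list with \code{area} and \code{angles} (opposite q1, q2, q3;
#'   they sum to pi).
#' @export
triangle_geometry <- function(q1, q2, q3) {
  q <- c(q1, q2, q3)
  if (any(q <= 0)) stop("triangle_geometry: squared lengths must be positive")
  l <- sqrt(q)
  s <- sort(l)
  if (s[1] + s[2] <= s[3])
    stop("triangle_geometry: triangle inequality violated (F(q) = 0)")
  # Heron, numerically stable form
  area <- 0.25 * sqrt((s[1] + s[2] + s[3]) * (s[3] + s[2] - s[1]) *
                        (s[3] + s[1] - s[2]) * (s[1] + s[2] - s[3]))
  ang <- c(acos((q2 + q3 - q1) / (2 * l[2] * l[3])),
           acos((q1 + q3 - q2) / (2 * l[1] * l[3])),
           acos((q1 + q2 - q3) / (2 * l[1] * l[2])))
  list(area = area, angles = ang)
}

# per-triangle geometry for a config; angle j is at the vertex opposite... we
# need angles AT vertices: angle at vertex v of triangle (a,b,c) is opposite
# the edge not containing v.
triangle_data <- function(tri, q) {
  nT <- nrow(tri$triangles)
  areas <- numeric(nT)
  angles <- matrix(0, nT, 3)  # column j: angle at vertex triangles[,j]
  for (t in seq_len(nT)) {
    e <- tri$triangle_edges[t, ]  # edges (v1,v2), (v1,v3), (v2,v3)
    g <- triangle_geometry(q[e[3]], q[e[2]], q[e[1]])
    # angle at v1 is opposite edge (v2,v3) = q[e[3]] -> g$angles[1]
    areas[t] <- g$area
    angles[t, ] <- g$angles
  }
  list(areas = areas, angles = angles)
}

#' Deficit angles of a Z2 configuration
#'
#' The discrete curvature of the piecewise-flat surface: at each vertex,
#' 2*pi minus the sum of the interior angles of the incident triangles. For
#' any valid configuration on a closed triangulation the deficits sum to
#' 2*pi*chi (combinatorial Gauss-Bonnet).
#'
#' @param tri a \code{triangulation2d}.
#' @param config a valid \code{z2_edge_config}.
#' @return numeric vector of deficits over vertices.
#' @export
deficit_angles <- function(tri, config) {
  if (!config$valid)
    stop("deficit_angles: configuration violates triangle inequalities")
  td <- triangle_data(tri, config$q)
  around <- numeric(tri$n_vertices)
  for (t in seq_len(nrow(tri$triangles)))
    for (j in 1:3)
      around[tri$triangles[t, j]] <- around[tri$triangles[t, j]] + td$angles[t, j]
  2 * pi - around
}

#' Discretized 2-D Regge action
#'
#' \code{A = x (sum of triangle areas - zeta * sum of vertex deficits)},
#' with the point volume attached to each vertex set to 1. Lower volumes
#' and higher curvature lower the action (x, zeta > 0).
#'
#' @param tri a \code{triangulation2d}.
#' @param config a valid \code{z2_edge_config}.
#' @param x,zeta positive action constants.
#' @return scalar action.
#' @export
regge_action <- function(tri, config, x, zeta) {
  if (x <= 0 || zeta < 0) stop("regge_action: require x > 0 and zeta >= 0")
  if (!config$valid)
    stop("regge_action: configuration violates triangle inequalities")
  td <- triangle_data(tri, config$q)
  x * (sum(td$areas) - zeta * sum(deficit_angles(tri, config)))
}

#' Z2 Regge partition function by exact enumeration
#'
#' \code{Z = sum over sigma in \{+/-1\}^E of F(q) prod_l q_l^(-alpha)
#' exp(-A(q))}: the discrete state sum over the two-valued squared edge
#' lengths, with the simplicial measure weight per edge and the
#' triangle-inequality indicator F.
#'
#' @param tri a \code{triangulation2d}.
#' @param l_amp length amplitude in [0, 1).
#' @param x,zeta action constants (x > 0, zeta >= 0).
#' @param alpha measure exponent.
#' @param cap refuse enumeration above this edge count (default 24).
#' @return list with \code{Z}, \code{n_valid} (configurations with F = 1)
#'   and \code{n_total} = 2^E.
#' @export
z2_regge_partition <- function(tri, l_amp, x, zeta, alpha = 0, cap = 24L) {
  nE <- nrow(tri$edges)
  if (nE > cap)
    stop(sprintf("z2_regge_partition: %d edges exceed enumeration cap %d", nE, cap))
  # per-triangle lookup over the 8 sign patterns of its three edges
  nT <- nrow(tri$triangles)
  patt <- enumerate_states(3L)               # 8 x 3 of 0/1
  tri_ok <- matrix(FALSE, nT, 8L)
  tri_contrib <- matrix(0, nT, 8L)           # area + zeta * sum(angles)
  for (t in seq_len(nT)) {
    for (p in seq_len(8L)) {
      sg <- 2L * patt[p, ] - 1L
      q <- 1 + l_amp * sg                    # q of edges e1,e2,e3 of triangle t
      g <- tryCatch(triangle_geometry(q[3], q[2], q[1]), error = function(e) NULL)
      if (!is.null(g)) {
        tri_ok[t, p] <- TRUE
        tri_contrib[t, p] <- g$area + zeta * sum(g$angles)
      }
    }
  }
  M <- 2L^nE
  Z <- 0
  n_valid <- 0L
  block <- 2L^min(nE, 14L)
  for (start in seq(0L, M - 1L, by = block)) {
    idx <- start:(min(start + block, M) - 1L)
    bits <- matrix(0L, length(idx), nE)
    for (j in seq_len(nE)) bits[, j] <- bitwAnd(idx %/% 2L^(j - 1L), 1L)
    ok <- rep(TRUE, length(idx))
    contrib <- numeric(length(idx))
    for (t in seq_len(nT)) {
      e <- tri$triangle_edges[t, ]
      p <- 1L + bits[, e[1]] + 2L * bits[, e[2]] + 4L * bits[, e[3]]
      ok <- ok & tri_ok[t, p]
      contrib <- contrib + tri_contrib[t, p]
    }
    # A = x * (sum areas - zeta * (2 pi V - sum all angles))
    #   = x * sum_t (area_t + zeta * angles_t) - x * zeta * 2 pi V
    A <- x * contrib - x * zeta * 2 * pi * tri$n_vertices
    logmeasure <- if (alpha == 0) 0 else
      -alpha * (rowSums(bits) * log1p(l_amp) +
                  (nE - rowSums(bits)) * log1p(-l_amp))
    w <- exp(logmeasure - A)
    Z <- Z + sum(w[ok])
    n_valid <- n_valid + sum(ok)
  }
  list(Z = Z, n_valid = as.integer(n_valid), n_total = M)
}
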