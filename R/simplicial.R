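#' Construct a simplicial complex from explicit simplices
#'
#' Internal-facing constructor: simplices are supplied per dimension as
#' matrices (one row per simplex, 1-based sorted vertex indices). Use
#' \code{\link{clique_complex}} to build the flag complex of a coupling
#' graph.
#'
#' @param simplices list indexed by dimension + 1; element d+1 is a matrix
#'   with d+1 columns whose rows are the d-simplices (sorted vertices).
#' @param n_vertices vertex count N.
#' @return object of class \code{simplicial_complex}.
#' @export
simplicial_complex <- function(simplices, n_vertices) {
  n_vertices <- as.integer(n_vertices)
  simplices <- lapply(seq_along(simplices), function(k) {
    m <- simplices[[k]]
    if (is.null(m) || length(m) == 0) return(matrix(integer(0), 0, k))
    m <- matrix(as.integer(m), ncol = k)
    if (any(m < 1) || any(m > n_vertices))
      stop("simplicial_complex: vertex index out of range")
    if (k > 1 && any(t(apply(m, 1, diff)) <= 0))
      stop("simplicial_complex: simplex vertices must be strictly increasing")
    # lexicographic row order for reproducible boundary matrices
    m[do.call(order, lapply(seq_len(k), function(j) m[, j])), , drop = FALSE]
  })
  obj <- structure(list(simplices = simplices, n_vertices = n_vertices,
                        max_dim = length(simplices) - 1L),
                   class = "simplicial_complex")
  check_face_closure(obj)
  obj
}

check_face_closure <- function(complex) {
  for (d in seq_len(complex$max_dim)) {
    keys <- simplex_keys(complex, d - 1L)
    m <- complex$simplices[[d + 1L]]
    if (nrow(m) == 0) next
    for (drop in seq_len(d + 1L)) {
      face_keys <- apply(m[, -drop, drop = FALSE], 1L, canonical_simplex_key)
      if (!all(face_keys %in% keys))
        stop("simplicial_complex: not closed under faces")
    }
  }
  invisible(TRUE)
}

simplex_keys <- function(complex, d) {
  m <- complex$simplices[[d + 1L]]
  if (nrow(m) == 0) return(character(0))
  apply(m, 1L, canonical_simplex_key)
}

n_simplices <- function(complex) {
  vapply(complex$simplices, nrow, integer(1))
}

#' Test whether a vertex tuple is a simplex of the complex
#' @param complex a \code{simplicial_complex}.
#' @param v sorted vertex vector (1-based).
#' @return logical.
#' @export
has_simplex <- function(complex, v) {
  d <- length(v) - 1L
  if (d > complex$max_dim) return(FALSE)
  canonical_simplex_key(v) %in% simplex_keys(complex, d)
}

#' @export
print.simplicial_complex <- function(x, ...) {
  cat(sprintf("Simplicial complex on %d vertices, max dimension %d\n",
              x$n_vertices, x$max_dim))
  cat("  simplex counts by dimension:", paste(n_simplices(x), collapse = ", "),
      "\n")
  invisible(x)
}

#' Clique (flag) complex of a graph
#'
#' The simplicial complex whose n-simplices are the (n+1)-cliques of the
#' graph, truncated at \code{max_dim}; the graph is its 1-skeleton. This is
#' the "completion" of the coupling graph whose cells carry the n-body
#' interactions of the multilinear model. Truncation at max_dim silently
#' drops larger cliques; Betti numbers above max_dim - 1 may be affected,
#' which the caller can detect by raising max_dim.
#'
#' @param edges two-column matrix of edges (1-based vertex indices), or an
#'   \code{igraph} graph.
#' @param n_vertices vertex count (required for an edge matrix).
#' @param max_dim maximum simplex dimension to enumerate (default 4).
#' @return a \code{simplicial_complex}.
#' @examples
#' cc <- clique_complex(rbind(c(1, 2), c(2, 3), c(1, 3)), n_vertices = 3)
#' betti_numbers(cc)
#' @export
clique_complex <- function(edges, n_vertices = NULL, max_dim = 4L) {
  if (max_dim < 1) stop("clique_complex: max_dim must be >= 1")
  if (inherits(edges, "igraph")) {
    g <- edges
    if (is.null(n_vertices)) n_vertices <- igraph::vcount(g)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2)
    if (is.null(n_vertices)) stop("clique_complex: n_vertices required")
    if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2]))
      stop("clique_complex: self-loops are not allowed")
    g <- igraph::make_empty_graph(n = n_vertices, directed = FALSE)
    if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
    g <- igraph::simplify(g)
  }
  cl <- igraph::cliques(g, min = 1, max = max_dim + 1L)
  sizes <- lengths(cl)
  simplices <- lapply(seq_len(max_dim + 1L), function(k) {
    sel <- cl[sizes == k]
    if (length(sel) == 0) return(matrix(integer(0), 0, k))
    m <- do.call(rbind, lapply(sel, function(s) sort(as.integer(s))))
    m
  })
  # trim trailing empty dimensions (keep at least dims 0..1)
  top <- max(c(2L, which(vapply(simplices, nrow, integer(1)) > 0)))
  simplicial_complex(simplices[seq_len(top)], n_vertices)
}

#' Boundary matrix of a simplicial complex
#'
#' Matrix of the boundary operator from n-chains to (n-1)-chains. Over GF(2)
#' entries are 0/1 (each column marks the n+1 facets of its simplex); over
#' the rationals facets carry the alternating orientation signs. Rows and
#' columns follow the complex's lexicographic simplex order, so the matrix
#' is reproducible bit-for-bit.
#'
#' @param complex a \code{simplicial_complex}.
#' @param n chain dimension, 1 <= n <= max_dim.
#' @param field "GF2" (default) or "rationals".
#' @return numeric matrix, (number of (n-1)-simplices) x (number of
#'   n-simplices).
#' @export
boundary_matrix <- function(complex, n, field = c("GF2", "rationals")) {
  field <- match.arg(field)
  if (n < 1 || n > complex$max_dim)
    stop("boundary_matrix: n out of range")
  rows <- simplex_keys(complex, n - 1L)
  cols <- complex$simplices[[n + 1L]]
  B <- matrix(0, length(rows), nrow(cols))
  if (nrow(cols) == 0) return(B)
  for (j in seq_len(nrow(cols))) {
    s <- cols[j, ]
    for (drop in seq_len(n + 1L)) {
      key <- canonical_simplex_key(s[-drop])
      i <- match(key, rows)
      B[i, j] <- if (field == "GF2") 1 else (-1)^(drop - 1)
    }
  }
  B
}

# Rank of a 0/1 matrix over GF(2) by Gaussian elimination.
gf2_rank <- function(M) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  M <- M %% 2
  rank <- 0L
  nr <- nrow(M); nc <- ncol(M)
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(M[row:nr, col] == 1)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    hits <- which(M[, col] == 1)
    hits <- hits[hits != row]
    if (length(hits))
      M[hits, ] <- (M[hits, , drop = FALSE] +
                      matrix(M[row, ], length(hits), nc, byrow = TRUE)) %% 2
    rank <- rank + 1L
    row <- row + 1L
    if (row > nr) break
  }
  rank
}

matrix_rank <- function(M, field) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  if (field == "GF2") gf2_rank(M) else qr(M)$rank
}

#' Betti numbers of a simplicial complex
#'
#' Ranks of the homology groups, computed from boundary-matrix ranks:
#' \code{b_n = dim ker d_n - rank d_{n+1}}. b_0 counts connected components,
#' b_1 independent loops, b_2 enclosed voids. Default coefficients GF(2);
#' rational coefficients detect the same ranks on torsion-free complexes.
#'
#' @param complex a \code{simplicial_complex}.
#' @param field "GF2" (default) or "rationals".
#' @return integer vector \code{b_0 ... b_max_dim} with attribute
#'   \code{field}.
#' @export
betti_numbers <- function(complex, field = c("GF2", "rationals")) {
  field <- match.arg(field)
  counts <- n_simplices(complex)
  D <- complex$max_dim
  ranks <- integer(D + 1L)  # ranks[n+1] = rank of boundary_n, rank d_0 = 0
  for (n in seq_len(D))
    ranks[n + 1L] <- matrix_rank(boundary_matrix(complex, n, field), field)
  b <- integer(D + 1L)
  for (n in 0:D) {
    kern <- counts[n + 1L] - ranks[n + 1L]
    img <- if (n < D) ranks[n + 2L] else 0L
    b[n + 1L] <- kern - img
  }
  structure(as.integer(b), field = field)
}

#' Euler characteristic from simplex counts
#' @param complex a \code{simplicial_complex}.
#' @return integer alternating sum of simplex counts.
#' @export
euler_characteristic <- function(complex) {
  counts <- n_simplices(complex)
  sum((-1)^(seq_along(counts) - 1L) * counts)
}

#' Poincare polynomial of a Betti vector
#'
#' Generating polynomial of the Betti numbers: coefficient of t^n is b_n.
#' Evaluation at t = 1 gives the total Betti number, at t = -1 the Euler
#' characteristic.
#'
#' @param betti integer vector of Betti numbers (b_0 first).
#' @return integer coefficient vector, class \code{poincare_polynomial}.
#' @export
poincare_polynomial <- function(betti) {
  if (any(betti < 0)) stop("poincare_polynomial: Betti numbers must be >= 0")
  structure(as.integer(betti), class = "poincare_polynomial")
}

#' Evaluate a Poincare polynomial
#' @param p a \code{poincare_polynomial}.
#' @param t evaluation point(s).
#' @return numeric value(s).
#' @export
eval_poincare <- function(p, t) {
  vapply(t, function(tt) sum(unclass(p) * tt^(seq_along(p) - 1L)), numeric(1))
}

#' @export
print.poincare_polynomial <- function(x, ...) {
  b <- unclass(x)
  terms <- character(0)
  for (n in seq_along(b) - 1L) {
    if (b[n + 1L] == 0) next
    terms <- c(terms, if (n == 0) as.character(b[1]) else
      if (b[n + 1L] == 1) sprintf("t^%d", n) else sprintf("%d t^%d", b[n + 1L], n))
  }
  if (length(terms) == 0) terms <- "0"
  cat("P(t) =", paste(terms, collapse = " + "), "\n")
  invisible(x)
}
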