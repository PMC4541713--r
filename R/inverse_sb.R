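#' Volume of the regular unit-edge n-simplex
#' @param n simplex dimension (0 = point, volume 1 by convention).
#' @return numeric volume.
#' @export
regular_simplex_volume <- function(n) {
  if (n == 0) return(1)
  sqrt(n + 1) / (factorial(n) * 2^(n / 2))
}

validate_betti_target <- function(target, N) {
  target <- as.integer(target)
  if (length(target) < 1 || any(target < 0))
    stop("target Betti vector must be non-negative with b_0 first")
  if (target[1] < 1)
    stop("unsatisfiable target: b_0 must be >= 1 (a non-empty complex has a component)")
  if (target[1] > N)
    stop(sprintf("unsatisfiable target: b_0 = %d components need more than N = %d vertices",
                 target[1], N))
  target
}

# Deterministic witness construction: wedge of cross-polytope gadgets at a
# hub vertex. The flag complex of the (k+1)-partite graph K_{2,...,2} is the
# k-sphere, so one gadget per unit of b_k adds exactly one k-dimensional
# class; extra components give b_0, leftover vertices hang as pendants
# (homotopy-irrelevant). Returns NULL when N has too few vertices.
construct_witness_graph <- function(N, target) {
  b0 <- target[1]
  bk <- if (length(target) > 1) target[-1] else integer(0)
  n_gadget_vertices <- sum(bk * (2L * seq_along(bk) + 1L))
  main_needed <- if (sum(bk) > 0) 1L + n_gadget_vertices else 1L
  if (main_needed + (b0 - 1L) > N) return(NULL)
  edges <- matrix(integer(0), 0, 2)
  hub <- 1L
  nxt <- 2L
  for (k in seq_along(bk)) {
    for (rep in seq_len(bk[k])) {
      v <- nxt:(nxt + 2L * k)       # 2k+1 new vertices
      nxt <- nxt + 2L * k + 1L
      verts <- c(hub, v)
      # antipodal pairs: (hub, v[1]), (v[2], v[3]), ...
      pair_id <- c(1L, 1L, rep(2L:(k + 1L), each = 2L))
      for (i in seq_along(verts)) for (j in seq_along(verts)) {
        if (i < j && pair_id[i] != pair_id[j])
          edges <- rbind(edges, c(verts[i], verts[j]))
      }
    }
  }
  singles <- if (b0 > 1L) nxt:(nxt + b0 - 2L) else integer(0)
  nxt <- nxt + length(singles)
  if (nxt <= N)  # pendant leftovers on the hub keep the main component a wedge
    edges <- rbind(edges, cbind(hub, nxt:N))
  edges
}

betti_of_edges <- function(edges, N, max_dim) {
  cc <- clique_complex(edges, N, max_dim = max_dim)
  as.integer(betti_numbers(cc))
}

#' Infer a coupling support graph with a target topology
#'
#' Searches for a graph on N vertices whose clique complex has exactly the
#' target Betti vector. The search is seeded simulated annealing over
#' single-edge toggles with the L1 Betti mismatch as cost; when the vertex
#' budget allows, the annealer is initialized at a constructed witness (a
#' wedge of cross-polytope spheres), which typically verifies immediately.
#' Every returned graph is re-verified through \code{\link{betti_numbers}}
#' before being returned; at budget exhaustion the failure is reported as an
#' error of class \code{idionet_inference_failure} carrying the best graph
#' found.
#'
#' @param N number of vertices.
#' @param target desired Betti vector (b_0 >= 1).
#' @param budget maximum number of cost evaluations (>= 1).
#' @param seed RNG seed for the annealer.
#' @param init "construct" (default; constructed witness when feasible,
#'   random otherwise) or "random".
#' @return two-column edge matrix with attributes \code{betti} (verified
#'   vector) and \code{evaluations}.
#' @export
infer_coupling_support <- function(N, target, budget = 2000L, seed = 1L,
                                   init = c("construct", "random")) {
  init <- match.arg(init)
  target <- validate_betti_target(target, N)
  if (budget < 1) stop("infer_coupling_support: budget must be >= 1")
  max_dim <- length(target) + 1L
  pad_target <- c(target, integer(max_dim + 1L - length(target)))
  cost_of <- function(edges) {
    b <- betti_of_edges(edges, N, max_dim)
    compare_betti(b, pad_target)$distance
  }
  edges_from_vec <- function(vec, pairs) pairs[vec, , drop = FALSE]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  pairs <- if (N >= 2) which(upper.tri(matrix(0, N, N)), arr.ind = TRUE) else
    matrix(integer(0), 0, 2)
  n_pairs <- nrow(pairs)
  evals <- 0L

  if (init == "construct") {
    witness <- construct_witness_graph(N, target)
    if (!is.null(witness)) {
      evals <- evals + 1L
      if (cost_of(witness) == 0L) {
        b <- betti_of_edges(witness, N, max_dim)  # self-audit
        stopifnot(compare_betti(b, pad_target)$match)
        return(structure(witness, betti = b, evaluations = evals))
      }
      cur_vec <- logical(n_pairs)
      key <- paste(pairs[, 1], pairs[, 2])
      cur_vec[match(paste(witness[, 1], witness[, 2]), key)] <- TRUE
    } else cur_vec <- stats::runif(n_pairs) < 0.5
  } else cur_vec <- stats::runif(n_pairs) < 0.5

  cur_cost <- cost_of(edges_from_vec(cur_vec, pairs)); evals <- evals + 1L
  best_vec <- cur_vec; best_cost <- cur_cost
  T0 <- 2; T_end <- 0.05
  while (evals < budget && best_cost > 0L && n_pairs > 0L) {
    temp <- T0 * (T_end / T0)^(evals / budget)
    flip <- sample.int(n_pairs, 1L)
    cand <- cur_vec
    cand[flip] <- !cand[flip]
    cand_cost <- cost_of(edges_from_vec(cand, pairs)); evals <- evals + 1L
    if (cand_cost <= cur_cost ||
        stats::runif(1) < exp(-(cand_cost - cur_cost) / temp)) {
      cur_vec <- cand; cur_cost <- cand_cost
      if (cur_cost < best_cost) { best_cost <- cur_cost; best_vec <- cur_vec }
    }
  }
  edges <- edges_from_vec(best_vec, pairs)
  b <- betti_of_edges(edges, N, max_dim)
  if (!compare_betti(b, pad_target)$match) {
    cond <- structure(
      class = c("idionet_inference_failure", "error", "condition"),
      list(message = sprintf(
        "coupling-support inference failed after %d evaluations (best Betti distance %d)",
        evals, best_cost),
        call = NULL,
        report = list(best_edges = edges, best_betti = b,
                      target = target, evaluations = evals)))
    stop(cond)
  }
  structure(edges, betti = b, evaluations = evals)
}

#' Geometric coupling values for a clique complex
#'
#' Attaches to every simplex of dimension >= 1 the coupling
#' \code{J = -(a V_n + b kappa_n W_n)}: a negative linear combination of the
#' regular unit-edge n-simplex volume V_n and the total volume W_n of its
#' (n-2)-dimensional boundary faces weighted by a curvature factor kappa_n
#' (W = 0 below dimension 2). Larger cells therefore couple more
#' negatively. Edges become the pairwise matrix; higher cells become
#' higher-order couplings.
#'
#' @param complex a \code{simplicial_complex}.
#' @param a,b non-negative volume and curvature weights.
#' @param kappa per-dimension curvature weights (recycled; default 1).
#' @param S,tau threshold and time step for the returned model.
#' @return a \code{coupling_model} on the complex's vertex set.
#' @export
assign_coupling_values <- function(complex, a = 1, b = 1, kappa = 1,
                                   S = 0, tau = 1) {
  if (a < 0 || b < 0) stop("assign_coupling_values: a and b must be >= 0")
  D <- complex$max_dim
  kappa <- rep_len(kappa, max(D, 1L))
  N <- complex$n_vertices
  J <- matrix(0, N, N)
  higher <- list()
  for (n in seq_len(D)) {
    m <- complex$simplices[[n + 1L]]
    if (nrow(m) == 0) next
    V <- regular_simplex_volume(n)
    W <- if (n >= 2) choose(n + 1L, n - 1L) * regular_simplex_volume(n - 2L) else 0
    val <- -(a * V + b * kappa[n] * W)
    if (n == 1L) {
      J[m] <- val
      J <- pmin(J, t(J))
    } else {
      for (r in seq_len(nrow(m)))
        higher[[length(higher) + 1L]] <- list(simplex = m[r, ], J = val)
    }
  }
  coupling_model(N, S = S, pairwise = J, higher = higher, tau = tau)
}

#' Construct an S[B] system
#'
#' Couples a behavioural machine B (the attractor states and transitions of
#' the network dynamics) with a structural controller S whose states are
#' contexts labelled by Betti-vector constraints. The observation function O
#' maps every behavioural state to the topological invariant of the current
#' model — the Betti vector of its clique complex.
#'
#' @param model a \code{coupling_model}.
#' @param complex its clique complex.
#' @param context_betti constraint of the initial S-state (default: the
#'   complex's own Betti vector, so the initial state satisfies it).
#' @return object of class \code{sb_system}.
#' @export
sb_system <- function(model, complex, context_betti = NULL) {
  obs <- as.integer(betti_numbers(complex))
  if (is.null(context_betti)) context_betti <- obs
  ar <- attractors(model, complex)
  Q <- do.call(rbind, lapply(ar$attractors, function(a) a$cycle))
  q0 <- Q[1L, ]
  structure(list(
    B = list(Q = Q, q0 = q0, mode = ar$mode),
    S = list(contexts = list(as.integer(context_betti)), r0 = 1L,
             transitions = list(), observation = obs),
    model = model, complex = complex),
    class = "sb_system")
}

#' @export
print.sb_system <- function(x, ...) {
  cat(sprintf("S[B] system: |Q| = %d behavioural states, %d context(s), current context #%d\n",
              nrow(x$B$Q), length(x$S$contexts), x$S$r0))
  cat("  current constraint (Betti):",
      paste(x$S$contexts[[x$S$r0]], collapse = " "), "\n")
  invisible(x)
}

#' Check the S[B] well-formedness invariants
#'
#' Verifies that the observation function is defined on every behavioural
#' state, that the initial behavioural state satisfies the constraint of the
#' initial S-state, and that every S-state constraint is a well-formed Betti
#' vector (hence denotes a subset of Q).
#'
#' @param system an \code{sb_system}.
#' @return list with \code{ok} (logical) and \code{violations} (character).
#' @export
check_sb <- function(system) {
  v <- character(0)
  if (is.null(system$B$Q) || nrow(system$B$Q) == 0)
    v <- c(v, "B has no states")
  if (is.null(system$S$observation) || anyNA(system$S$observation))
    v <- c(v, "observation function undefined on some behavioural state")
  for (k in seq_along(system$S$contexts)) {
    L <- system$S$contexts[[k]]
    if (length(L) < 1 || any(L < 0) || any(L != as.integer(L)))
      v <- c(v, sprintf("context #%d label is not a Betti vector", k))
  }
  if (length(v) == 0) {
    L0 <- system$S$contexts[[system$S$r0]]
    if (!compare_betti(system$S$observation, L0)$match)
      v <- c(v, "initial-constraint violation: q0 does not satisfy L(r0)")
  }
  list(ok = length(v) == 0, violations = v)
}

#' Betti-driven adaptation step (S[B] loop)
#'
#' Compares the Betti vector of the current model's clique complex with the
#' Betti vector measured from data. If they match there is no new knowledge
#' and everything is returned unchanged. Otherwise a new coupling support
#' with the data topology is inferred, geometric coupling values are
#' attached to all cells of its clique complex, and the controller S
#' accumulates the new context (prior contexts are never deleted). All
#' S[B] invariants are re-established on the returned system.
#'
#' @param system an \code{sb_system}.
#' @param model,complex the current model and its complex.
#' @param data_betti Betti vector measured from data (e.g. via
#'   \code{\link{betti_at_plateau}}).
#' @param seed RNG seed for the support search.
#' @param budget annealing budget for \code{\link{infer_coupling_support}}.
#' @param a,b coupling-geometry weights for
#'   \code{\link{assign_coupling_values}}.
#' @return list with elements \code{system}, \code{model}, \code{complex}
#'   and \code{adapted} (logical).
#' @export
sb_adapt <- function(system, model, complex, data_betti, seed = 1L,
                     budget = 2000L, a = 1, b = 1) {
  b_model <- as.integer(betti_numbers(complex))
  if (compare_betti(b_model, data_betti)$match)
    return(list(system = system, model = model, complex = complex,
                adapted = FALSE))
  edges <- infer_coupling_support(model$N, data_betti, budget = budget,
                                  seed = seed)
  new_complex <- clique_complex(edges, model$N,
                                max_dim = length(data_betti) + 1L)
  new_model <- assign_coupling_values(new_complex, a = a, b = b,
                                      S = model$S, tau = model$tau)
  new_system <- sb_system(new_model, new_complex,
                          context_betti = as.integer(data_betti))
  # contexts accumulate: prepend the history, keep the new context current
  new_system$S$contexts <- c(system$S$contexts, new_system$S$contexts)
  new_system$S$r0 <- length(new_system$S$contexts)
  new_system$S$transitions <- c(system$S$transitions,
                                list(c(system$S$r0, new_system$S$r0)))
  chk <- check_sb(new_system)
  if (!chk$ok)
    stop("sb_adapt: adapted system violates S[B] invariants: ",
         paste(chk$violations, collapse = "; "))
  list(system = new_system, model = new_model, complex = new_complex,
       adapted = TRUE)
}
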