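#' Heaviside step function
#'
#' The threshold nonlinearity of the binary antibody update rule: an antibody
#' is produced (concentration 1) exactly when its mean field is
#' non-suppressive. The value at 0 is a convention; the default 1 keeps
#' \code{c_i = heaviside(h_i)} consistent with a deterministic update on
#' \{0, 1\}.
#'
#' @param x numeric vector; must be finite.
#' @param zero_value value returned where \code{x == 0}; 1 (default) or 0.
#' @return integer vector of 0s and 1s, same length as \code{x}.
#' @examples
#' heaviside(c(-0.5, 0, 2))
#' @export
heaviside <- function(x, zero_value = 1L) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("heaviside: 'x' must be finite numeric")
  if (!zero_value %in% c(0L, 1L)) stop("heaviside: zero_value must be 0 or 1")
  out <- as.integer(x > 0)
  if (zero_value == 1L) out[x == 0] <- 1L
  out
}

#' Validate a binary immune state
#'
#' An immune state is the vector of antibody concentrations, each 0 (absent /
#' suppressed) or 1 (produced).
#'
#' @param c numeric or integer vector of 0/1 entries.
#' @param N expected length (optional).
#' @return the state as an integer vector, invisibly checked.
#' @export
immune_state <- function(c, N = NULL) {
  if (!is.numeric(c) || any(!(c %in% c(0, 1))))
    stop("immune_state: entries must be exactly 0 or 1")
  if (!is.null(N) && length(c) != N)
    stop(sprintf("immune_state: length %d != N = %d", length(c), N))
  as.integer(c)
}

canonical_simplex_key <- function(v) paste(v, collapse = ",")

normalize_higher <- function(higher, N) {
  if (length(higher) == 0) return(structure(list(), names = character(0)))
  keys <- character(length(higher))
  vals <- numeric(length(higher))
  verts <- vector("list", length(higher))
  for (i in seq_along(higher)) {
    entry <- higher[[i]]
    if (is.list(entry) && !is.null(entry$simplex)) {
      v <- as.integer(entry$simplex); J <- as.numeric(entry$J)
    } else {
      # named list "i,j,k" -> value
      v <- as.integer(strsplit(names(higher)[i], ",", fixed = TRUE)[[1]])
      J <- as.numeric(higher[[i]])
    }
    if (length(v) < 3)
      stop("coupling_model: higher-order keys must have >= 3 vertices")
    if (any(diff(v) <= 0))
      stop("coupling_model: higher-order keys must be strictly increasing")
    if (any(v < 1) || any(v > N))
      stop("coupling_model: higher-order vertex index out of range")
    keys[i] <- canonical_simplex_key(v)
    vals[i] <- J
    verts[[i]] <- v
  }
  if (anyDuplicated(keys)) stop("coupling_model: duplicate higher-order keys")
  structure(as.list(vals), names = keys, vertices = verts)
}

#' Construct an idiotypic coupling model
#'
#' Holds the threshold S, the symmetric pairwise influence matrix J
#' (\code{J[i,i] = 0}), and any higher-order couplings attached to simplices
#' of the clique complex of the pairwise support graph. Higher-order
#' couplings are supplied as a list of \code{list(simplex = c(i, j, k, ...),
#' J = value)} with 1-based, strictly increasing vertex indices.
#'
#' @param N number of antibodies.
#' @param S threshold parameter (stimulation offset common to all
#'   antibodies); the model's dynamics are governed by its sign when
#'   couplings are small.
#' @param pairwise N x N symmetric numeric matrix with zero diagonal, or
#'   NULL for no pairwise couplings.
#' @param higher list of higher-order couplings (see above).
#' @param tau time step metadata (one immune-response time), default 1.
#' @param strict_range if TRUE, require all couplings in [-1, 1].
#' @return an object of class \code{coupling_model}.
#' @export
coupling_model <- function(N, S = 0, pairwise = NULL, higher = list(),
                           tau = 1, strict_range = FALSE) {
  N <- as.integer(N)
  if (N < 1) stop("coupling_model: N must be positive")
  if (is.null(pairwise)) pairwise <- matrix(0, N, N)
  pairwise <- as.matrix(pairwise)
  if (!all(dim(pairwise) == c(N, N)))
    stop("coupling_model: pairwise must be N x N")
  if (any(diag(pairwise) != 0))
    stop("coupling_model: pairwise diagonal must be zero (J_ii = 0)")
  if (!isTRUE(all.equal(pairwise, t(pairwise), tolerance = 1e-12)))
    stop("coupling_model: pairwise must be symmetric (J_ik = J_ki)")
  if (tau <= 0) stop("coupling_model: tau must be positive")
  higher <- normalize_higher(higher, N)
  if (strict_range) {
    vals <- c(pairwise[upper.tri(pairwise)], unlist(higher))
    if (length(vals) && any(abs(vals) > 1))
      stop("coupling_model: couplings outside [-1, 1] in strict_range mode")
  }
  structure(list(N = N, S = as.numeric(S), pairwise = pairwise,
                 higher = higher, tau = as.numeric(tau),
                 strict_range = isTRUE(strict_range)),
            class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  n_pair <- sum(x$pairwise[upper.tri(x$pairwise)] != 0)
  cat(sprintf(
    "Idiotypic coupling model: N = %d antibodies, S = %g, tau = %g\n",
    x$N, x$S, x$tau))
  cat(sprintf("  pairwise couplings: %d non-zero; higher-order: %d\n",
              n_pair, length(x$higher)))
  invisible(x)
}

#' Linear (pairwise) mean field
#'
#' The classical mean field: \code{h_i = S + sum_{k != i} J_ik c_k}. The sign
#' of \code{h_i} is the net stimulatory (positive) or suppressive (negative)
#' effect of the whole network on antibody i. Higher-order couplings in the
#' model are ignored by this operation.
#'
#' @param state binary state vector (length N).
#' @param model a \code{coupling_model}.
#' @return numeric vector h of length N.
#' @export
linear_mean_field <- function(state, model) {
  state <- immune_state(state, model$N)
  as.numeric(model$S + model$pairwise %*% state)
}

#' Multilinear (n-body) mean field
#'
#' Generalizes the pairwise mean field to n-body interactions carried by the
#' simplices of the clique complex of the coupling graph: every simplex
#' sigma with an attached coupling J_sigma and containing antibody i
#' contributes \code{J_sigma * prod(c_j : j in sigma, j != i)} to
#' \code{h_i}. With only pairwise couplings this reduces exactly to
#' \code{linear_mean_field}.
#'
#' @param state binary state vector.
#' @param model a \code{coupling_model}.
#' @param complex the \code{simplicial_complex} carrying the higher-order
#'   couplings; every higher-order key of the model must be one of its
#'   simplices.
#' @return numeric vector h of length N.
#' @export
multilinear_mean_field <- function(state, model, complex = NULL) {
  state <- immune_state(state, model$N)
  h <- as.numeric(model$S + model$pairwise %*% state)
  if (length(model$higher) == 0) return(h)
  if (is.null(complex))
    stop("multilinear_mean_field: a complex is required for higher-order couplings")
  verts <- attr(model$higher, "vertices")
  for (k in seq_along(model$higher)) {
    v <- verts[[k]]
    if (!has_simplex(complex, v))
      stop(sprintf("multilinear_mean_field: higher-order key {%s} is not a simplex of the complex",
                   canonical_simplex_key(v)))
    J <- model$higher[[k]]
    cs <- state[v]
    tot <- prod(cs)
    for (pos in seq_along(v)) {
      i <- v[pos]
      # product over the simplex vertices other than i
      contrib <- if (cs[pos] == 1L) tot else prod(cs[-pos])
      h[i] <- h[i] + J * contrib
    }
  }
  h
}

#' Global energy (cost) functional
#'
#' \code{E(c) = sum_i h_i(c) c_i} with h the multilinear mean field evaluated
#' on the supplied configuration. E is defined for arbitrary binary
#' configurations; the threshold self-consistency condition characterizes
#' fixed points of the dynamics, not the ensemble support.
#'
#' @inheritParams multilinear_mean_field
#' @return scalar energy.
#' @export
energy <- function(state, model, complex = NULL) {
  state <- immune_state(state, model$N)
  sum(multilinear_mean_field(state, model, complex) * state)
}

# Energies of all 2^N configurations (rows of `states`), vectorized.
# Used by the enumeration engines (statmech, attractors).
energy_all <- function(states, model, complex = NULL) {
  h <- field_all(states, model, complex)
  rowSums(h * states)
}

# Mean-field vectors for a batch of states (rows), vectorized over states.
field_all <- function(states, model, complex = NULL) {
  h <- matrix(model$S, nrow(states), model$N) + states %*% model$pairwise
  if (length(model$higher)) {
    verts <- attr(model$higher, "vertices")
    for (k in seq_along(model$higher)) {
      v <- verts[[k]]
      if (!is.null(complex) && !has_simplex(complex, v))
        stop(sprintf("field_all: higher-order key {%s} is not a simplex of the complex",
                     canonical_simplex_key(v)))
      J <- model$higher[[k]]
      sub <- states[, v, drop = FALSE]
      tot <- apply(sub, 1L, prod)
      for (pos in seq_along(v)) {
        others <- apply(sub[, -pos, drop = FALSE], 1L, prod)
        h[, v[pos]] <- h[, v[pos]] + J * others
      }
    }
  }
  h
}

# All 2^N binary states as a (2^N x N) integer matrix; row r encodes r-1 in
# binary, vertex 1 = least significant bit. Deterministic ordering shared by
# statmech and dynamics.
enumerate_states <- function(N) {
  if (N > 24) stop("enumerate_states: N too large to enumerate")
  M <- 2L^N
  idx <- 0:(M - 1L)
  out <- matrix(0L, M, N)
  for (j in seq_len(N)) out[, j] <- bitwAnd(idx %/% 2L^(j - 1L), 1L)
  out
}
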