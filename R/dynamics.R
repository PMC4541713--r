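#' One step of the threshold dynamics
#'
#' Applies \code{c_i(t + tau) = heaviside(h_i(t))} with the multilinear mean
#' field. Synchronous mode updates all antibodies from the same snapshot;
#' asynchronous sweep updates them in index order, each seeing the freshest
#' values.
#'
#' @param state binary state vector.
#' @param model a \code{coupling_model}.
#' @param complex clique complex carrying higher-order couplings (may be
#'   NULL for pairwise-only models).
#' @param mode "synchronous" (default) or "asynchronous_sweep".
#' @return the next state (integer 0/1 vector).
#' @export
step_state <- function(state, model, complex = NULL,
                       mode = c("synchronous", "asynchronous_sweep")) {
  mode <- match.arg(mode)
  state <- immune_state(state, model$N)
  if (mode == "synchronous") {
    heaviside(multilinear_mean_field(state, model, complex))
  } else {
    s <- state
    for (i in seq_len(model$N)) {
      h <- multilinear_mean_field(s, model, complex)
      s[i] <- heaviside(h[i])
    }
    s
  }
}

#' Simulate a trajectory of the network dynamics
#'
#' Deterministic iteration of \code{\link{step_state}} from an initial
#' state.
#'
#' @inheritParams step_state
#' @param init initial binary state.
#' @param steps number of update steps (>= 0).
#' @return object of class \code{trajectory}: a (steps + 1) x N integer
#'   matrix of states, one row per time point, with attributes \code{mode}
#'   and \code{tau}.
#' @export
simulate_dynamics <- function(model, complex = NULL, init, steps,
                              mode = c("synchronous", "asynchronous_sweep")) {
  mode <- match.arg(mode)
  if (steps < 0) stop("simulate_dynamics: steps must be >= 0")
  init <- immune_state(init, model$N)
  out <- matrix(0L, steps + 1L, model$N)
  out[1L, ] <- init
  s <- init
  if (steps > 0) for (t in seq_len(steps)) {
    s <- step_state(s, model, complex, mode)
    out[t + 1L, ] <- s
  }
  structure(out, mode = mode, tau = model$tau, class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d time points, %d antibodies, %s update\n",
              nrow(x), ncol(x), attr(x, "mode")))
  invisible(x)
}

state_to_index <- function(states) {
  # rows of a 0/1 matrix -> 1-based integer codes (vertex 1 = LSB)
  as.integer(states %*% 2L^(seq_len(ncol(states)) - 1L)) + 1L
}

#' Exhaustive attractor analysis
#'
#' Enumerates all 2^N initial states, follows the deterministic dynamics,
#' and reports every attractor (fixed point or cycle) with the size of its
#' basin of attraction. Basin sizes always sum to 2^N.
#'
#' @inheritParams step_state
#' @param cap refuse enumeration above this N (default 16); for larger
#'   networks sample trajectories instead.
#' @return object of class \code{attractor_report}: list with \code{N},
#'   \code{mode} and \code{attractors}, a list of
#'   \code{list(cycle = <matrix of states>, basin_size = <int>)} entries.
#' @export
attractors <- function(model, complex = NULL,
                       mode = c("synchronous", "asynchronous_sweep"),
                       cap = 16L) {
  mode <- match.arg(mode)
  N <- model$N
  if (N > cap)
    stop(sprintf("attractors: N = %d exceeds cap %d; enumeration of 2^N states is infeasible, sample trajectories instead", N, cap))
  states <- enumerate_states(N)
  M <- nrow(states)
  if (mode == "synchronous") {
    h <- field_all(states, model, complex)
    nxt <- matrix(heaviside(as.vector(h)), M, N)
    succ <- state_to_index(nxt)
  } else {
    succ <- integer(M)
    for (r in seq_len(M))
      succ[r] <- state_to_index(matrix(
        step_state(states[r, ], model, complex, mode), 1L))
  }
  # functional-graph decomposition: find cycles, then basin sizes
  color <- integer(M)           # 0 unseen, -1 on current path, >0 cycle id
  attractor_of <- integer(M)    # cycle id each state falls into
  cycles <- list()
  for (start in seq_len(M)) {
    if (color[start] != 0L) next
    path <- integer(0)
    v <- start
    while (color[v] == 0L) {
      color[v] <- -1L
      path <- c(path, v)
      v <- succ[v]
    }
    if (color[v] == -1L) {
      # new cycle: the tail of `path` starting at v
      pos <- match(v, path)
      cyc <- path[pos:length(path)]
      cid <- length(cycles) + 1L
      cycles[[cid]] <- cyc
      attractor_of[cyc] <- cid
      color[cyc] <- cid
      if (pos > 1L) {
        pre <- path[seq_len(pos - 1L)]
        attractor_of[pre] <- cid
        color[pre] <- cid
      }
    } else {
      cid <- attractor_of[v]
      attractor_of[path] <- cid
      color[path] <- cid
    }
  }
  basin <- tabulate(attractor_of, nbins = length(cycles))
  atts <- lapply(seq_along(cycles), function(k) {
    list(cycle = states[cycles[[k]], , drop = FALSE],
         basin_size = basin[k])
  })
  structure(list(N = N, mode = mode, attractors = atts),
            class = "attractor_report")
}

#' @export
print.attractor_report <- function(x, ...) {
  lens <- vapply(x$attractors, function(a) nrow(a$cycle), integer(1))
  cat(sprintf("Attractor report: N = %d (%s update), %d attractor(s)\n",
              x$N, x$mode, length(x$attractors)))
  for (k in seq_along(x$attractors))
    cat(sprintf("  #%d: cycle length %d, basin %d\n", k, lens[k],
                x$attractors[[k]]$basin_size))
  invisible(x)
}

#' Fixed-point test by self-consistency
#'
#' Checks the equilibrium condition \code{c_i = heaviside(h_i(c))} for all i
#' directly, independently of the attractor search.
#'
#' @inheritParams step_state
#' @return logical.
#' @export
is_fixed_point <- function(state, model, complex = NULL) {
  state <- immune_state(state, model$N)
  all(heaviside(multilinear_mean_field(state, model, complex)) == state)
}
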