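#' Correlation distance between antibody trajectories
#'
#' Turns a concentration matrix (rows = antibodies, columns = time points)
#' into a distance matrix \code{d_ij = 1 - rho_ij}, rho the sample Pearson
#' correlation, clipped to [0, 2]. Anti-correlated antibodies are maximally
#' far; with \code{method = "absolute"}, \code{d = 1 - |rho|} treats them as
#' close instead. Constant (zero-variance) rows get rho = 0 against every
#' other row, with a warning.
#'
#' @param trajectories numeric matrix, antibodies x timepoints (>= 3
#'   timepoints).
#' @param method "signed" (default) or "absolute".
#' @return symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(trajectories, method = c("signed", "absolute")) {
  method <- match.arg(method)
  trajectories <- as.matrix(trajectories)
  if (nrow(trajectories) < 2)
    stop("correlation_distance: need at least 2 antibodies")
  if (ncol(trajectories) < 3)
    stop("correlation_distance: need at least 3 timepoints")
  sds <- apply(trajectories, 1L, stats::sd)
  flat <- sds == 0
  if (any(flat))
    warning(sprintf("correlation_distance: %d constant row(s); correlation set to 0 for them", sum(flat)))
  rho <- suppressWarnings(stats::cor(t(trajectories)))
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  if (method == "absolute") rho <- abs(rho)
  d <- 1 - rho
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  (d + t(d)) / 2
}

validate_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Vietoris-Rips persistent homology
#'
#' Computes the persistence diagram of the Rips filtration of a finite
#' metric space over GF(2): simplices enter at the scale of their longest
#' pairwise distance, and homology classes are tracked as birth/death
#' scales. The reduction runs in compiled code; output is deterministic for
#' fixed input.
#'
#' @param d distance matrix (symmetric, non-negative, zero diagonal).
#' @param max_dim highest homology dimension to compute (default 2).
#' @param threshold optional maximal filtration scale (default Inf: the
#'   filtration ends at the complete complex, which is contractible).
#' @return object of class \code{persistence_diagram}: data.frame with
#'   columns dim, birth, death (Inf for essential classes).
#' @export
rips_persistence <- function(d, max_dim = 2L, threshold = Inf) {
  if (max_dim < 0) stop("rips_persistence: max_dim must be >= 0")
  d <- validate_distance_matrix(d)
  out <- cpp_rips_persistence(d, as.integer(max_dim), threshold)
  out <- out[order(out$dim, out$birth, out$death), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("persistence_diagram", "data.frame"),
            max_dim = as.integer(max_dim))
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("Persistence diagram: %d bars (max dim %d)\n",
              nrow(x), attr(x, "max_dim")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Betti numbers at a fixed filtration scale
#'
#' Counts bars alive at scale t (birth <= t < death).
#'
#' @param diagram a \code{persistence_diagram}.
#' @param t filtration scale.
#' @param max_dim pad/truncate the result to dimensions 0..max_dim (default:
#'   the diagram's max_dim).
#' @return integer vector b_0 ... b_max_dim.
#' @export
betti_at_scale <- function(diagram, t, max_dim = NULL) {
  if (is.null(max_dim)) max_dim <- attr(diagram, "max_dim")
  alive <- diagram$birth <= t & diagram$death > t
  b <- integer(max_dim + 1L)
  if (any(alive)) {
    tab <- table(factor(diagram$dim[alive], levels = 0:max_dim))
    b <- as.integer(tab)
  }
  b
}

#' Betti vector at the dominant plateau
#'
#' Reads off an empirical Betti vector from a persistence diagram by the
#' plateau rule: among the finite filtration scales, find the longest
#' interval on which the full Betti vector is constant, and report the
#' vector at its midpoint. The scan stops at the last finite event (beyond
#' it a complete Rips filtration is contractible forever, which carries no
#' information). Ties go to the smallest scale.
#'
#' @param diagram a \code{persistence_diagram} (must be non-empty).
#' @param max_dim dimensions 0..max_dim are reported (default: the
#'   diagram's).
#' @return list with \code{betti} (integer vector), \code{interval}
#'   (c(lo, hi)) and \code{scale} (the midpoint used).
#' @export
betti_at_plateau <- function(diagram, max_dim = NULL) {
  if (nrow(diagram) == 0) stop("betti_at_plateau: empty diagram")
  if (is.null(max_dim)) max_dim <- attr(diagram, "max_dim")
  events <- sort(unique(c(diagram$birth, diagram$death[is.finite(diagram$death)])))
  if (length(events) <= 1) {
    b <- betti_at_scale(diagram, events[1], max_dim)
    return(list(betti = b, interval = c(events[1], Inf), scale = events[1]))
  }
  # Betti vector is constant on [events[k], events[k+1]); evaluate at left ends
  vecs <- lapply(events, function(t) betti_at_scale(diagram, t, max_dim))
  # merge adjacent intervals with identical vectors
  lo <- events[1]; best_len <- -1; best <- NULL
  k <- 1L
  n_ev <- length(events)
  while (k <= n_ev - 1L) {
    j <- k
    while (j + 1L <= n_ev - 1L && identical(vecs[[j + 1L]], vecs[[k]])) j <- j + 1L
    len <- events[j + 1L] - events[k]
    if (len > best_len + 1e-15) {
      best_len <- len
      best <- list(betti = vecs[[k]], interval = c(events[k], events[j + 1L]))
    }
    k <- j + 1L
  }
  best$scale <- mean(best$interval)
  best
}

#' Compare model and data Betti vectors
#'
#' L1 distance after zero-padding the shorter vector; a match is distance 0.
#' This is the comparison step of the adaptation loop: the model's clique
#' complex against the topology measured from data.
#'
#' @param b_model,b_data integer Betti vectors.
#' @return list with \code{distance} (integer) and \code{match} (logical).
#' @export
compare_betti <- function(b_model, b_data) {
  b_model <- as.integer(b_model); b_data <- as.integer(b_data)
  L <- max(length(b_model), length(b_data))
  pad <- function(b) c(b, integer(L - length(b)))
  dist <- sum(abs(pad(b_model) - pad(b_data)))
  list(distance = as.integer(dist), match = dist == 0L)
}
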