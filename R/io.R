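# Readers and writers for the toolkit's plain-text formats. Vertex ids are
# 0-based on disk (interoperable convention) and 1-based in memory.

#' Write / read a coupling model
#'
#' Pairwise couplings go to a TSV with header \code{i j J} (0-based vertex
#' ids, i < j); N, S, tau go to a JSON sidecar (same path with extension
#' \code{.json}); higher-order couplings, if any, to a JSON list of
#' \code{\{"simplex": [...], "J": ...\}} at \code{<path>.higher.json}.
#'
#' @param model a \code{coupling_model}.
#' @param path TSV file path.
#' @return \code{path}, invisibly; \code{read_coupling_model} returns the
#'   model.
#' @export
write_coupling_model <- function(model, path) {
  up <- which(upper.tri(model$pairwise) & model$pairwise != 0, arr.ind = TRUE)
  df <- data.frame(i = up[, 1] - 1L, j = up[, 2] - 1L,
                   J = model$pairwise[up])
  df <- df[order(df$i, df$j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(N = model$N, S = model$S, tau = model$tau),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (length(model$higher)) {
    verts <- attr(model$higher, "vertices")
    entries <- lapply(seq_along(model$higher), function(k)
      list(simplex = verts[[k]] - 1L, J = model$higher[[k]]))
    jsonlite::write_json(entries, paste0(path, ".higher.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_coupling_model
#' @export
read_coupling_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  J <- matrix(0, meta$N, meta$N)
  if (nrow(df)) {
    if (any(df$i >= df$j)) stop("read_coupling_model: require i < j")
    J[cbind(df$i + 1L, df$j + 1L)] <- df$J
    J <- J + t(J)
  }
  higher <- list()
  hp <- paste0(path, ".higher.json")
  if (file.exists(hp)) {
    entries <- jsonlite::read_json(hp, simplifyVector = FALSE)
    higher <- lapply(entries, function(e)
      list(simplex = unlist(e$simplex) + 1L, J = e$J))
  }
  coupling_model(meta$N, S = meta$S, pairwise = J, higher = higher,
                 tau = meta$tau)
}

#' Write / read binary states
#'
#' CSV, one row per state, one 0/1 column per antibody.
#' @param states matrix (rows = states) or a single state vector.
#' @param path CSV path.
#' @return \code{path} invisibly; the reader returns an integer matrix.
#' @export
write_states <- function(states, path) {
  if (is.null(dim(states))) states <- matrix(states, 1L)
  utils::write.table(states, path, sep = ",", row.names = FALSE,
                     col.names = paste0("c", seq_len(ncol(states)) - 1L))
  invisible(path)
}

#' @rdname write_states
#' @export
read_states <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  storage.mode(m) <- "integer"
  apply(m, 1L, immune_state)  # validate
  dimnames(m) <- NULL
  m
}

#' Write / read a trajectory
#'
#' CSV with one row per time step and one column per antibody.
#' @param trajectory a \code{trajectory} (or state matrix).
#' @param path CSV path.
#' @export
write_trajectory <- function(trajectory, path) {
  write_states(unclass(trajectory), path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) read_states(path)

#' Write / read a simplicial complex as JSON
#'
#' JSON object mapping dimension (as a string) to a list of simplices,
#' 0-based sorted vertex lists.
#' @param complex a \code{simplicial_complex}.
#' @param path JSON path.
#' @export
write_complex <- function(complex, path) {
  obj <- list()
  for (d in 0:complex$max_dim) {
    m <- complex$simplices[[d + 1L]]
    obj[[as.character(d)]] <- lapply(seq_len(nrow(m)),
                                     function(r) m[r, ] - 1L)
  }
  obj[["n_vertices"]] <- complex$n_vertices
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_complex
#' @export
read_complex <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nv <- obj$n_vertices
  dims <- sort(as.integer(names(obj)[names(obj) != "n_vertices"]))
  simplices <- lapply(dims + 1L, function(k) {
    entries <- obj[[as.character(k - 1L)]]
    if (length(entries) == 0) return(matrix(integer(0), 0, k))
    do.call(rbind, lapply(entries, function(s) unlist(s) + 1L))
  })
  simplicial_complex(simplices, nv)
}

#' Write / read a Betti vector
#' @param betti integer vector.
#' @param path JSON path.
#' @export
write_betti <- function(betti, path) {
  jsonlite::write_json(as.integer(betti), path, digits = NA)
  invisible(path)
}

#' @rdname write_betti
#' @export
read_betti <- function(path) {
  as.integer(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write / read a persistence diagram
#'
#' CSV with columns dim, birth, death; infinite deaths written as the
#' literal \code{inf}.
#' @param diagram a \code{persistence_diagram}.
#' @param path CSV path.
#' @export
write_diagram <- function(diagram, path) {
  df <- as.data.frame(diagram)
  df$death <- ifelse(is.infinite(df$death), "inf",
                     format(df$death, digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "numeric", "character"))
  df$death <- ifelse(df$death == "inf", Inf, as.numeric(df$death))
  structure(df, class = c("persistence_diagram", "data.frame"),
            max_dim = max(df$dim, 0L))
}

#' Write / read a distance matrix as CSV
#' @param d distance matrix.
#' @param path CSV path.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(d, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  validate_distance_matrix(unname(as.matrix(utils::read.csv(path,
                                                            header = FALSE))))
}

#' Write / read a triangulation as an OFF file
#'
#' Standard OFF: header, counts, vertex coordinates, triangular faces
#' (0-based). The triangulation is combinatorial; coordinates default to
#' zeros unless supplied and are ignored on read.
#'
#' @param tri a \code{triangulation2d}.
#' @param path OFF file path.
#' @param coords optional n_vertices x 3 coordinate matrix.
#' @export
write_off <- function(tri, path, coords = NULL) {
  if (is.null(coords)) coords <- matrix(0, tri$n_vertices, 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d %d", tri$n_vertices, nrow(tri$triangles),
                     nrow(tri$edges)), con)
  writeLines(apply(coords, 1L, function(r) paste(r, collapse = " ")), con)
  writeLines(apply(tri$triangles, 1L, function(t)
    paste(c(3L, t - 1L), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("read_off: missing OFF header in ", path)
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  face_lines <- lines[(3 + nv):(2 + nv + nf)]
  faces <- do.call(rbind, lapply(face_lines, function(l) {
    f <- as.integer(strsplit(l, "\\s+")[[1]])
    if (f[1] != 3L) stop("read_off: only triangular faces are supported")
    f[2:4] + 1L
  }))
  triangulation2d(faces, nv)
}
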