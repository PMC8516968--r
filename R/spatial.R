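#' Queen contiguity adjacency from area polygons
#'
#' Two areas are neighbours if their boundaries share any point, including
#' a single corner vertex ("queen" contiguity). Weights are binary: 1 for
#' a shared border point, 0 otherwise. Contact is detected by computing
#' the minimum distance between boundary segments of each polygon pair
#' (with a bounding-box prefilter) and comparing it to `tol`.
#'
#' @param x a `lattice_geography`, the result of [read_geojson()], a path
#'   to a GeoJSON file, or a named list of polygon coordinate matrices.
#' @param tol numeric, maximum boundary distance treated as contact.
#' @return An `adjacency_graph`: list with `ids` (area identifiers), `nb`
#'   (list of integer neighbour indices), `m` (neighbour counts), and
#'   `edges` (two-column matrix of unique undirected edges, i < k).
#'   Isolated areas are permitted and reported via `message()`.
#' @examples
#' g <- queen_contiguity(make_lattice(3, 3, 1))
#' g$m  # corner cells have 3 neighbours, the centre has 8
#' @export
queen_contiguity <- function(x, tol = 1e-8) {
  if (is.character(x) && length(x) == 1L) x <- read_geojson(x)
  if (inherits(x, "lattice_geography")) {
    polys <- x$polygons
  } else if (is.list(x) && !is.null(x$polygons)) {
    polys <- x$polygons
  } else if (is.list(x) && all(vapply(x, is.matrix, TRUE))) {
    polys <- x
  } else {
    stop_spzip("cannot extract polygons from input", "spzip_invalid_argument")
  }
  n <- length(polys)
  if (n == 0L) stop_spzip("empty polygon set", "spzip_invalid_argument")
  ids <- names(polys) %||% paste0("a", seq_len(n))
  for (i in seq_len(n)) {
    p <- polys[[i]]
    if (!is.matrix(p) || ncol(p) < 2 || nrow(p) < 3 || anyNA(p)) {
      stop_spzip(sprintf("invalid geometry for feature '%s'", ids[i]),
                 "spzip_geometry_error")
    }
  }
  bb <- t(vapply(polys, function(p)
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2])), numeric(4)))
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (k in (i + 1):n) {
        # bounding boxes must touch (within tol) for contact to be possible
        if (bb[i, 1] > bb[k, 2] + tol || bb[k, 1] > bb[i, 2] + tol ||
            bb[i, 3] > bb[k, 4] + tol || bb[k, 3] > bb[i, 4] + tol) next
        if (polygon_boundary_dist(polys[[i]], polys[[k]], tol) <= tol) {
          nb[[i]] <- c(nb[[i]], k)
          nb[[k]] <- c(nb[[k]], i)
        }
      }
    }
  }
  build_adjacency(ids, nb)
}

# minimum distance between the boundaries of two polygons, early-exiting
# once a distance <= tol is found
polygon_boundary_dist <- function(a, b, tol = 0) {
  best <- Inf
  na <- nrow(a) - 1L; nbv <- nrow(b) - 1L
  for (i in seq_len(na)) {
    for (j in seq_len(nbv)) {
      d <- segment_dist(a[i, 1:2], a[i + 1L, 1:2], b[j, 1:2], b[j + 1L, 1:2])
      if (d < best) best <- d
      if (best <= tol) return(best)
    }
  }
  best
}

point_segment_dist <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab * ab)
  t <- if (denom == 0) 0 else max(0, min(1, sum((p - a) * ab) / denom))
  q <- a + t * ab
  sqrt(sum((p - q)^2))
}

segment_dist <- function(p1, p2, q1, q2) {
  d1 <- (p2 - p1); d2 <- (q2 - q1)
  r <- q1 - p1
  cr <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(cr) > 1e-14) {
    t <- (r[1] * d2[2] - r[2] * d2[1]) / cr
    u <- (r[1] * d1[2] - r[2] * d1[1]) / cr
    if (t >= 0 && t <= 1 && u >= 0 && u <= 1) return(0)
  }
  min(point_segment_dist(q1, p1, p2), point_segment_dist(q2, p1, p2),
      point_segment_dist(p1, q1, q2), point_segment_dist(p2, q1, q2))
}

build_adjacency <- function(ids, nb) {
  n <- length(ids)
  nb <- lapply(nb, function(v) sort(unique(as.integer(v))))
  for (i in seq_len(n)) {
    if (any(nb[[i]] == i)) stop_spzip("self-loop in adjacency",
                                      "spzip_invalid_argument")
    for (k in nb[[i]]) {
      if (!(i %in% nb[[k]])) {
        stop_spzip(sprintf("asymmetric adjacency between '%s' and '%s'",
                           ids[i], ids[k]), "spzip_invalid_argument")
      }
    }
  }
  m <- lengths(nb)
  if (any(m == 0L)) {
    message("adjacency has ", sum(m == 0L), " isolated area(s): ",
            paste(ids[m == 0L], collapse = ", "))
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    ks <- nb[[i]][nb[[i]] > i]
    if (length(ks)) cbind(i, ks) else NULL
  }))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  colnames(edges) <- c("i", "k")
  structure(list(ids = ids, nb = nb, m = m, edges = edges),
            class = "adjacency_graph")
}

#' Construct an adjacency graph from an explicit neighbour list
#'
#' Bypasses geometry entirely: supply the neighbour structure directly
#' (as indices into `ids` or as id character vectors). Symmetry and
#' absence of self-loops are validated.
#'
#' @param ids character vector of area identifiers.
#' @param nb list (one element per area) of neighbour indices or ids.
#' @return an `adjacency_graph`.
#' @export
adjacency_graph <- function(ids, nb) {
  stopifnot(length(ids) == length(nb))
  nb <- lapply(nb, function(v) {
    if (is.character(v)) {
      idx <- match(v, ids)
      if (anyNA(idx)) {
        stop_spzip("unknown neighbour id", "spzip_invalid_argument")
      }
      idx
    } else {
      as.integer(v)
    }
  })
  build_adjacency(as.character(ids), nb)
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d areas, %d edges, neighbour counts %d-%d\n",
              length(x$ids), nrow(x$edges), min(x$m), max(x$m)))
  invisible(x)
}

#' Read or write a plain-text neighbour list
#'
#' Format: one line per area, `area_id: id1 id2 ...` (ids separated by
#' whitespace; an area with no neighbours has an empty right-hand side).
#' Symmetry is validated, not silently repaired.
#'
#' @param path text file path.
#' @return [read_adjacency()] returns an `adjacency_graph`;
#'   [write_adjacency()] returns `path` invisibly.
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) {
    stop_spzip(paste0("file not found: ", path), "spzip_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  ids <- trimws(vapply(parts, `[`, "", 1))
  if (anyDuplicated(ids)) {
    stop_spzip("duplicate area id in adjacency file", "spzip_io_error")
  }
  nb_ids <- lapply(parts, function(p) {
    rhs <- if (length(p) > 1) p[[2]] else ""
    v <- strsplit(trimws(rhs), "\\s+")[[1]]
    v[nzchar(v)]
  })
  nb <- lapply(nb_ids, function(v) {
    idx <- match(v, ids)
    if (anyNA(idx)) {
      stop_spzip(paste0("unknown neighbour id(s): ",
                        paste(v[is.na(idx)], collapse = ", ")),
                 "spzip_io_error")
    }
    idx
  })
  build_adjacency(ids, nb)
}

#' @rdname read_adjacency
#' @param graph an `adjacency_graph`.
#' @export
write_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  lines <- vapply(seq_along(graph$ids), function(i) {
    paste0(graph$ids[i], ": ", paste(graph$ids[graph$nb[[i]]], collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' ICAR pairwise-difference quadratic form
#'
#' Computes `sum over neighbour pairs i<k of (v_i - v_k)^2`, the quadratic
#' form `v' (D - W) v` of the graph Laplacian. The intrinsic CAR
#' log-density kernel is `-(tau/2)` times this value; it is invariant to
#' adding a constant to `values` (the ICAR prior is improper along
#' constants), which is why structured effects carry a sum-to-zero
#' constraint during sampling.
#'
#' @param values numeric vector, one entry per area (graph order).
#' @param graph an `adjacency_graph`.
#' @return a single non-negative number.
#' @export
icar_quadform <- function(values, graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (length(values) != length(graph$ids)) {
    stop_spzip("values length must equal the number of areas",
               "spzip_invalid_argument")
  }
  if (nrow(graph$edges) == 0L) return(0)
  sum((values[graph$edges[, 1]] - values[graph$edges[, 2]])^2)
}

#' ICAR full conditional of one area effect
#'
#' Under the intrinsic CAR prior with precision `tau`, the conditional
#' distribution of area `i` given all other effects is Gaussian with mean
#' the average of its neighbours' values and variance `1 / (tau * m_i)`.
#'
#' @param area integer index of the area.
#' @param values per-area effect vector.
#' @param tau positive precision.
#' @param graph an `adjacency_graph`.
#' @return list with `mean` and `variance`.
#' @export
icar_full_conditional <- function(area, values, tau, graph) {
  stopifnot(inherits(graph, "adjacency_graph"), tau > 0)
  if (length(values) != length(graph$ids)) {
    stop_spzip("values length must equal the number of areas",
               "spzip_invalid_argument")
  }
  if (area < 1 || area > length(graph$ids)) {
    stop_spzip("area index out of range", "spzip_invalid_argument")
  }
  mi <- graph$m[area]
  if (mi == 0L) {
    stop_spzip("isolated area has no ICAR full conditional (island rule applies)",
               "spzip_undefined_conditional")
  }
  list(mean = mean(values[graph$nb[[area]]]), variance = 1 / (tau * mi))
}

# connected components; rank of the ICAR Gaussian kernel when islands are
# modelled as proper zero-mean Gaussians is n - (# non-singleton components)
graph_components <- function(graph) {
  n <- length(graph$ids)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in graph$nb[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

icar_rank <- function(graph) {
  comp <- graph_components(graph)
  sizes <- tabulate(comp)
  length(graph$ids) - sum(sizes >= 2L)
}

#' Draw one realization from the ICAR prior
#'
#' Samples a zero-mean intrinsic CAR field with precision `tau` by
#' spectral decomposition of the graph Laplacian: independent Gaussians on
#' the non-null eigenvectors with variance `1/(tau * lambda)`, giving a
#' sum-to-zero draw on each connected component. Isolated areas receive
#' independent `N(0, 1/tau)` values (the island rule used in fitting).
#' Used by the synthetic-data generator for structured effects and
#' spatially smooth trend slopes.
#'
#' @param graph an `adjacency_graph`.
#' @param tau positive precision of the pairwise-difference kernel.
#' @return numeric vector, one value per area, mean zero on each
#'   non-singleton component.
#' @export
sample_icar <- function(graph, tau) {
  stopifnot(inherits(graph, "adjacency_graph"), tau > 0)
  n <- length(graph$ids)
  W <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    W[graph$edges] <- 1
    W[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  L <- diag(graph$m) - W
  eig <- eigen(L, symmetric = TRUE)
  lam <- eig$values
  keep <- lam > 1e-9
  x <- numeric(n)
  if (any(keep)) {
    z <- rnorm(sum(keep), 0, 1 / sqrt(tau * lam[keep]))
    x <- as.numeric(eig$vectors[, keep, drop = FALSE] %*% z)
  }
  isl <- which(graph$m == 0L)
  if (length(isl)) x[isl] <- rnorm(length(isl), 0, 1 / sqrt(tau))
  x
}
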