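#' Build a rectangular lattice geography
#'
#' Creates an abstract planar study region of `n_rows * n_cols` unit-square
#' areas, numbered row-major (`a1`, `a2`, ...), and partitions them into
#' `n_districts` contiguous row-major blocks of as-equal-as-possible size
#' (`d1`, `d2`, ...). The lattice is a stand-in for an administrative map
#' of sub-districts nested in districts; district membership drives the
#' climate join (climate is measured at district level) and the polygons
#' drive queen contiguity.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param n_districts positive integer, number of contiguous district
#'   blocks; must not exceed the number of areas.
#' @return An object of class `lattice_geography`: a list with elements
#'   `n_rows`, `n_cols`, `areas` (character ids, row-major order),
#'   `district_of` (named character vector, area -> district) and
#'   `polygons` (named list of closed coordinate rings, one 5 x 2 matrix
#'   per area).
#' @examples
#' geo <- make_lattice(5, 8, 4)
#' length(geo$areas)            # 40
#' table(geo$district_of)       # 4 districts of 10 areas
#' @export
make_lattice <- function(n_rows, n_cols, n_districts) {
  for (v in list(n_rows, n_cols, n_districts)) {
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v)) {
      stop_spzip("n_rows, n_cols and n_districts must be positive integers",
                 "spzip_invalid_argument")
    }
  }
  n_area <- n_rows * n_cols
  if (n_districts > n_area) {
    stop_spzip("n_districts cannot exceed the number of areas",
               "spzip_invalid_argument")
  }
  areas <- paste0("a", seq_len(n_area))
  # contiguous row-major blocks, sizes differing by at most one
  block <- sort(rep_len(seq_len(n_districts), n_area))
  district_of <- setNames(paste0("d", block), areas)

  polygons <- vector("list", n_area)
  k <- 1L
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      x0 <- c - 1; y0 <- n_rows - r  # row 1 on top
      polygons[[k]] <- cbind(
        x = c(x0, x0 + 1, x0 + 1, x0, x0),
        y = c(y0, y0, y0 + 1, y0 + 1, y0))
      k <- k + 1L
    }
  }
  names(polygons) <- areas
  structure(list(n_rows = n_rows, n_cols = n_cols, areas = areas,
                 district_of = district_of, polygons = polygons),
            class = "lattice_geography")
}

#' @export
print.lattice_geography <- function(x, ...) {
  cat(sprintf("lattice_geography: %d x %d grid, %d areas in %d districts\n",
              x$n_rows, x$n_cols, length(x$areas),
              length(unique(x$district_of))))
  invisible(x)
}

#' Write a geography as a GeoJSON FeatureCollection
#'
#' Each area becomes one `Polygon` feature carrying `area_id` and
#' `district_id` properties; extra per-area properties (posterior summaries,
#' SMRs) can be supplied as a data frame keyed by `area_id`.
#'
#' @param geography a `lattice_geography`, or a feature list as returned by
#'   [read_geojson()].
#' @param path file to write; the `.geojson`/`.json` suffix is up to the
#'   caller.
#' @param properties optional data frame with an `area_id` column; remaining
#'   columns are written as feature properties.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(geography, path, properties = NULL) {
  feats <- as_features(geography)
  if (!is.null(properties)) {
    stopifnot(is.data.frame(properties), "area_id" %in% names(properties))
    idx <- match(vapply(feats, function(f) f$properties$area_id, ""),
                 properties$area_id)
    for (i in seq_along(feats)) {
      if (!is.na(idx[i])) {
        for (nm in setdiff(names(properties), "area_id")) {
          feats[[i]]$properties[[nm]] <- properties[[nm]][idx[i]]
        }
      }
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# normalize geography-like inputs to a list of GeoJSON feature lists
as_features <- function(x) {
  if (inherits(x, "lattice_geography")) {
    return(lapply(x$areas, function(a) {
      ring <- lapply(seq_len(nrow(x$polygons[[a]])),
                     function(i) as.numeric(x$polygons[[a]][i, ]))
      list(type = "Feature",
           properties = list(area_id = a,
                             district_id = unname(x$district_of[[a]])),
           geometry = list(type = "Polygon", coordinates = list(ring)))
    }))
  }
  if (is.list(x) && !is.null(x$features)) return(x$features)
  if (is.list(x) && length(x) && !is.null(x[[1]]$geometry)) return(x)
  stop_spzip("cannot interpret input as a geography or GeoJSON features",
             "spzip_invalid_argument")
}

#' Read a GeoJSON FeatureCollection of area polygons
#'
#' @param path file containing a FeatureCollection of `Polygon` features
#'   with `area_id` (and optionally `district_id`) properties.
#' @return list with `features` (raw feature lists), `area_id`,
#'   `district_id` (character vectors) and `polygons` (list of coordinate
#'   matrices of the outer ring).
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) {
    stop_spzip(paste0("file not found: ", path), "spzip_io_error")
  }
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- fc$features
  if (is.null(feats)) stop_spzip("not a FeatureCollection", "spzip_io_error")
  polys <- lapply(feats, function(f) {
    g <- f$geometry
    if (is.null(g) || !identical(g$type, "Polygon")) {
      stop_spzip(sprintf("feature '%s' is not a Polygon",
                         f$properties$area_id %||% "?"),
                 "spzip_geometry_error")
    }
    ring <- g$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    colnames(m) <- c("x", "y")
    m
  })
  ids <- vapply(feats, function(f) as.character(f$properties$area_id), "")
  dst <- vapply(feats, function(f)
    as.character(f$properties$district_id %||% NA_character_), "")
  names(polys) <- ids
  list(features = feats, area_id = ids, district_id = dst, polygons = polys)
}
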