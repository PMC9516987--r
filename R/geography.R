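#' Simulate a ward geography with queen-contiguity adjacency
#'
#' Builds a synthetic small-area geography standing in for a city's electoral
#' wards: a set of non-overlapping polygons tiling the unit square, a binary
#' symmetric queen-contiguity adjacency matrix (areas sharing a border segment
#' or a corner point are neighbours), and per-ward population weights used to
#' allocate children.
#'
#' Two layouts are available. `"grid"` arranges the wards on a regular
#' rectangular grid (falling back to a strip when the ward count is prime).
#' `"tessellation"` recursively splits the unit square into axis-aligned
#' rectangles at random positions, giving irregular ward sizes and an
#' irregular neighbourhood graph closer to a real administrative map.
#'
#' @param n_wards Number of wards (>= 2); 21 mirrors the number of electoral
#'   wards of a mid-size UK city.
#' @param layout `"tessellation"` (default) or `"grid"`.
#' @param pop_weights Optional simplex of ward population weights. Default:
#'   normalised Gamma(5, 1) draws, so ward populations vary by roughly
#'   two-fold, as administrative areas do.
#' @param seed Integer seed; identical seeds give identical geographies.
#' @return A `ward_geography` object: list with `wards` (tibble: `ward_id`,
#'   `pop_weight`), `polygons` (tibble: `ward_id`, `vertex`, `x`, `y`),
#'   and `adjacency` (n x n binary matrix with zero diagonal).
#' @export
#' @examples
#' geo <- simulate_geography(n_wards = 9, layout = "grid", seed = 1)
#' rowSums(geo$adjacency)
simulate_geography <- function(n_wards = 21,
                               layout = c("tessellation", "grid"),
                               pop_weights = NULL,
                               seed = NULL) {
  layout <- match.arg(layout)
  if (!is.numeric(n_wards) || length(n_wards) != 1L || n_wards < 2 ||
      n_wards != floor(n_wards)) {
    abort("`n_wards` must be an integer >= 2.")
  }
  n_wards <- as.integer(n_wards)
  with_seed(seed, {
    rects <- switch(layout,
      grid = grid_rectangles(n_wards),
      tessellation = bsp_rectangles(n_wards)
    )
    W <- rect_queen_adjacency(rects)
    if (is.null(pop_weights)) {
      w <- rgamma(n_wards, shape = 5, rate = 1)
      pop_weights <- w / sum(w)
    }
    if (length(pop_weights) != n_wards || any(pop_weights < 0) ||
        abs(sum(pop_weights) - 1) > 1e-8) {
      abort("`pop_weights` must be a simplex of length `n_wards`.")
    }
    poly <- rects_to_polygons(rects)
    out <- list(
      wards = tibble::tibble(ward_id = seq_len(n_wards),
                             pop_weight = as.numeric(pop_weights)),
      polygons = poly,
      adjacency = W
    )
    class(out) <- "ward_geography"
    out
  })
}

#' @export
print.ward_geography <- function(x, ...) {
  cat(sprintf("<ward_geography> %d wards, %d adjacency links, layout area [0,1]^2\n",
              nrow(x$wards), sum(x$adjacency) / 2))
  invisible(x)
}

# rectangles as a tibble ward_id, xmin, xmax, ymin, ymax
grid_rectangles <- function(n) {
  div <- which(n %% seq_len(floor(sqrt(n))) == 0)
  nr <- max(div)               # largest divisor <= sqrt(n); 1 when n prime
  nc <- n %/% nr
  idx <- seq_len(n) - 1L
  row <- idx %/% nc
  col <- idx %% nc
  tibble::tibble(
    ward_id = seq_len(n),
    xmin = col / nc, xmax = (col + 1) / nc,
    ymin = row / nr, ymax = (row + 1) / nr
  )
}

# binary space partition of the unit square: repeatedly split the largest
# rectangle at a uniform position along its longer side
bsp_rectangles <- function(n) {
  rects <- list(c(xmin = 0, xmax = 1, ymin = 0, ymax = 1))
  while (length(rects) < n) {
    areas <- vapply(rects, function(r) (r["xmax"] - r["xmin"]) * (r["ymax"] - r["ymin"]),
                    numeric(1))
    i <- which.max(areas)
    r <- rects[[i]]
    wx <- r["xmax"] - r["xmin"]
    wy <- r["ymax"] - r["ymin"]
    frac <- runif(1, 0.35, 0.65)
    if (wx >= wy) {
      cut <- r["xmin"] + frac * wx
      a <- r; a["xmax"] <- cut
      b <- r; b["xmin"] <- cut
    } else {
      cut <- r["ymin"] + frac * wy
      a <- r; a["ymax"] <- cut
      b <- r; b["ymin"] <- cut
    }
    rects[[i]] <- a
    rects[[length(rects) + 1L]] <- b
  }
  m <- do.call(rbind, rects)
  tibble::tibble(ward_id = seq_len(n),
                 xmin = m[, "xmin"], xmax = m[, "xmax"],
                 ymin = m[, "ymin"], ymax = m[, "ymax"])
}

# queen contiguity for axis-aligned non-overlapping rectangles: neighbours iff
# the closed intervals intersect in both dimensions (edge or corner contact)
rect_queen_adjacency <- function(rects, tol = 1e-9) {
  n <- nrow(rects)
  W <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      touch_x <- rects$xmin[i] <= rects$xmax[j] + tol &&
        rects$xmin[j] <= rects$xmax[i] + tol
      touch_y <- rects$ymin[i] <= rects$ymax[j] + tol &&
        rects$ymin[j] <= rects$ymax[i] + tol
      if (touch_x && touch_y) W[i, j] <- W[j, i] <- 1L
    }
  }
  dimnames(W) <- list(rects$ward_id, rects$ward_id)
  W
}

rects_to_polygons <- function(rects) {
  purrr::pmap_dfr(rects, function(ward_id, xmin, xmax, ymin, ymax) {
    tibble::tibble(
      ward_id = ward_id,
      vertex = 1:5,
      x = c(xmin, xmax, xmax, xmin, xmin),
      y = c(ymin, ymin, ymax, ymax, ymin)
    )
  })
}

#' Recompute queen adjacency from polygon geometry
#'
#' Independent geometric contiguity test: two wards are neighbours when their
#' polygon boundaries share at least one point (a border segment or a corner).
#' Works on any simple polygons keyed by `ward_id`, e.g. parsed from GeoJSON,
#' by testing every pair of boundary edges for intersection (including
#' collinear overlap and endpoint contact).
#'
#' @param polygons Tibble with columns `ward_id`, `x`, `y`, vertices in ring
#'   order (first vertex repeated last is accepted but not required).
#' @param tol Geometric tolerance.
#' @return Binary symmetric adjacency matrix with zero diagonal, ordered by
#'   sorted `ward_id`.
#' @export
adjacency_from_polygons <- function(polygons, tol = 1e-9) {
  ids <- sort(unique(polygons$ward_id))
  rings <- lapply(ids, function(id) {
    p <- polygons[polygons$ward_id == id, c("x", "y")]
    m <- as.matrix(p)
    if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
    m
  })
  n <- length(ids)
  W <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (polygons_touch(rings[[i]], rings[[j]], tol)) W[i, j] <- W[j, i] <- 1L
    }
  }
  W
}

polygons_touch <- function(a, b, tol) {
  na <- nrow(a) - 1L
  nb <- nrow(b) - 1L
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (segments_intersect(a[i, ], a[i + 1L, ], b[j, ], b[j + 1L, ], tol)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# segment intersection including collinear overlap and endpoint contact
segments_intersect <- function(p1, p2, p3, p4, tol) {
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  on_seg <- function(p, q, r) {
    min(p[1], r[1]) - tol <= q[1] && q[1] <= max(p[1], r[1]) + tol &&
      min(p[2], r[2]) - tol <= q[2] && q[2] <= max(p[2], r[2]) + tol
  }
  d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
  d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
  if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
      ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol))) return(TRUE)
  (abs(d1) <= tol && on_seg(p3, p1, p4)) ||
    (abs(d2) <= tol && on_seg(p3, p2, p4)) ||
    (abs(d3) <= tol && on_seg(p1, p3, p2)) ||
    (abs(d4) <= tol && on_seg(p1, p4, p2))
}

# breadth-first connectivity of the contiguity graph
adjacency_is_connected <- function(W) {
  n <- nrow(W)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(W[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Write / read ward geometry as GeoJSON
#'
#' Serialises a `ward_geography` as a GeoJSON FeatureCollection with one
#' Polygon feature per ward carrying `ward_id` and `pop_weight` properties.
#' `read_geography_geojson()` parses any such file (including user-supplied
#' ward boundary files) and recomputes queen adjacency from the geometry.
#'
#' @param geo A `ward_geography`.
#' @param path Output (input) file path.
#' @return `write_geography_geojson()`: `path`, invisibly.
#'   `read_geography_geojson()`: a `ward_geography`.
#' @export
write_geography_geojson <- function(geo, path) {
  features <- purrr::map(seq_len(nrow(geo$wards)), function(i) {
    id <- geo$wards$ward_id[i]
    ring <- geo$polygons[geo$polygons$ward_id == id, c("x", "y")]
    list(
      type = "Feature",
      properties = list(ward_id = id, pop_weight = geo$wards$pop_weight[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(unname(apply(as.matrix(ring), 1, as.list)))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geography_geojson
#' @export
read_geography_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    abort("Expected a GeoJSON FeatureCollection.")
  }
  polys <- purrr::map_dfr(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    tibble::tibble(
      ward_id = f$properties$ward_id,
      vertex = seq_along(ring),
      x = purrr::map_dbl(ring, function(p) as.numeric(p[[1]])),
      y = purrr::map_dbl(ring, function(p) as.numeric(p[[2]]))
    )
  })
  weights <- purrr::map_dbl(fc$features, function(f) {
    as.numeric(f$properties$pop_weight %||% NA_real_)
  })
  ids <- purrr::map_int(fc$features, function(f) as.integer(f$properties$ward_id))
  ord <- order(ids)
  out <- list(
    wards = tibble::tibble(ward_id = ids[ord], pop_weight = weights[ord]),
    polygons = polys,
    adjacency = adjacency_from_polygons(polys)
  )
  class(out) <- "ward_geography"
  out
}

#' Write / read a binary adjacency matrix as CSV
#'
#' @param W Square binary matrix.
#' @param path File path.
#' @return `read_adjacency_csv()` returns the matrix with ward ids as
#'   dimnames.
#' @export
write_adjacency_csv <- function(W, path) {
  df <- as.data.frame(W)
  utils::write.csv(cbind(ward_id = rownames(W), df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_csv
#' @export
read_adjacency_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df$ward_id
  storage.mode(W) <- "integer"
  W
}
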