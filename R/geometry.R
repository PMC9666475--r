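#' Nest geometry
#'
#' Bundles the planar description of an observation nest: its boundary
#' polygon, the entrance point, an optional brood outline, the mean worker
#' body length, and the number of comb faces (1 for ant nests, 2 for
#' double-sided honeybee combs).
#'
#' All coordinates are in millimetres, with the origin at the lower left,
#' x increasing rightward and y upward. Orientations elsewhere in the
#' package are radians in [-pi, pi), 0 along +x.
#'
#' @param boundary numeric matrix (n x 2) of polygon vertices (mm), open
#'   ring (first vertex not repeated).
#' @param entrance length-2 numeric, entrance point (mm); must lie on or
#'   inside the boundary.
#' @param body_length positive scalar, mean worker body length (mm).
#' @param brood optional numeric matrix (n x 2), brood outline polygon (mm).
#' @param sides 1 or 2, number of comb faces.
#' @return An object of class `nest_geometry`.
#' @examples
#' nest <- nest_geometry(rbind(c(0, 0), c(60, 0), c(60, 40), c(0, 40)),
#'                       entrance = c(60, 20), body_length = 4)
#' @export
nest_geometry <- function(boundary, entrance, body_length, brood = NULL,
                          sides = 1L) {
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2 || nrow(boundary) < 3)
    stop("`boundary` must be an (n >= 3) x 2 matrix of vertices")
  if (abs(.polygon_area(boundary)) <= 0)
    stop("degenerate nest boundary polygon (zero area)")
  entrance <- as.numeric(entrance)
  if (length(entrance) != 2 || !all(is.finite(entrance)))
    stop("`entrance` must be a finite (x, y) pair")
  if (!.points_in_polygon(entrance[1], entrance[2], boundary))
    stop("entrance must lie on or inside the nest boundary")
  if (!is.numeric(body_length) || length(body_length) != 1 || body_length <= 0)
    stop("`body_length` must be a positive scalar (mm)")
  sides <- as.integer(sides)
  if (!sides %in% c(1L, 2L)) stop("`sides` must be 1 or 2")
  if (!is.null(brood)) {
    brood <- as.matrix(brood)
    if (ncol(brood) != 2 || nrow(brood) < 3)
      stop("`brood` must be an (n >= 3) x 2 matrix of vertices")
  }
  structure(list(boundary = boundary, entrance = entrance, brood = brood,
                 body_length = body_length, sides = sides),
            class = "nest_geometry")
}

#' @export
print.nest_geometry <- function(x, ...) {
  bb <- apply(x$boundary, 2, range)
  cat(sprintf("Nest geometry: %.1f x %.1f mm, body length %.2f mm, %d side(s)%s\n",
              diff(bb[, 1]), diff(bb[, 2]), x$body_length, x$sides,
              if (is.null(x$brood)) "" else ", brood outline present"))
  invisible(x)
}

# shoelace area (signed)
.polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

# boundary-inclusive point-in-polygon
.points_in_polygon <- function(x, y, poly) {
  res <- pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
  as.logical(res)
}

# distance from points (x, y) to a polygon's boundary segments
.dist_to_polygon_boundary <- function(x, y, poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  d <- rep(Inf, length(x))
  for (k in seq_len(n)) {
    ax <- poly[k, 1]; ay <- poly[k, 2]
    bx <- poly[j[k], 1]; by <- poly[j[k], 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    if (L2 == 0) {
      dk <- sqrt((x - ax)^2 + (y - ay)^2)
    } else {
      t <- pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / L2))
      dk <- sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
    }
    d <- pmin(d, dk)
  }
  d
}

#' Discretise the nest interior into a hexagonal lattice
#'
#' Tiles the nest with pointy-top hexagons of the given flat-to-flat width
#' (default one quarter of the worker body length) and keeps every hexagon
#' whose centre falls on or inside the nest boundary. Two-sided nests get
#' one site layer per comb face, sharing x/y geometry; site ids on side 2
#' continue after those of side 1.
#'
#' The lattice origin sits at the lower-left corner of the nest bounding
#' box. Every interior point maps to exactly one (site, side); points whose
#' nearest lattice centre was not kept (possible in concave boundary
#' pockets) map to no site.
#'
#' @param nest a [nest_geometry()] object.
#' @param width hexagon flat-to-flat width in mm; default `body_length / 4`.
#' @return An object of class `hex_grid` with fields `centers` (per-side
#'   base sites), `side`, `width`, `n_base` (sites per side) and the
#'   lattice lookup used for point location.
#' @examples
#' nest <- nest_geometry(rbind(c(0, 0), c(60, 0), c(60, 40), c(0, 40)),
#'                       entrance = c(60, 20), body_length = 4)
#' grid <- build_hex_grid(nest)
#' @export
build_hex_grid <- function(nest, width = nest$body_length / 4) {
  stopifnot(inherits(nest, "nest_geometry"))
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("`width` must be a positive scalar (mm)")
  R <- width / sqrt(3)               # circumradius
  bb <- apply(nest$boundary, 2, range)
  x0 <- bb[1, 1]; y0 <- bb[1, 2]
  nrow_l <- floor((bb[2, 2] - y0) / (1.5 * R)) + 1L
  ncol_l <- floor((bb[2, 1] - x0) / width) + 1L
  rows <- rep(seq_len(nrow_l) - 1L, each = ncol_l)
  cols <- rep(seq_len(ncol_l) - 1L, times = nrow_l)
  cx <- x0 + width * (cols + 0.5 * (rows %% 2))
  cy <- y0 + 1.5 * R * rows
  keep <- .points_in_polygon(cx, cy, nest$boundary)
  if (!any(keep)) stop("no hexagon centres fall inside the nest boundary")
  lookup <- matrix(0L, nrow_l, ncol_l)
  lookup[cbind(rows[keep] + 1L, cols[keep] + 1L)] <- seq_len(sum(keep))
  g <- structure(list(
    centers = cbind(x = cx[keep], y = cy[keep]),
    row = rows[keep], col = cols[keep],
    width = width, size = R, origin = c(x0, y0),
    lookup = lookup, n_base = sum(keep), sides = nest$sides,
    body_length = nest$body_length), class = "hex_grid")
  g
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("Hexagonal grid: %d sites per side x %d side(s), width %.3f mm\n",
              x$n_base, x$sides, x$width))
  invisible(x)
}

#' Number of sites in a hex grid (all sides)
#' @param grid a `hex_grid`.
#' @return integer site count.
#' @export
n_sites <- function(grid) grid$n_base * grid$sides

#' Site centre coordinates
#'
#' @param grid a `hex_grid`.
#' @param sites integer site ids (default all sites on all sides).
#' @return matrix with columns x, y (mm); side-2 sites share the x/y of
#'   their side-1 counterparts.
#' @export
site_centers <- function(grid, sites = seq_len(n_sites(grid))) {
  base <- ((sites - 1L) %% grid$n_base) + 1L
  grid$centers[base, , drop = FALSE]
}

#' Side index of each site
#' @param grid a `hex_grid`.
#' @param sites integer site ids.
#' @return integer vector of comb-face indices.
#' @export
site_side <- function(grid, sites = seq_len(n_sites(grid))) {
  ((sites - 1L) %/% grid$n_base) + 1L
}

#' Locate points on the hexagonal grid
#'
#' Maps planar points to the hexagonal site containing them (the Voronoi
#' cell of the nearest kept lattice centre). Points equidistant from
#' several centres resolve to the lowest site id; points outside the grid
#' (or in unkept cells) give `NA`.
#'
#' @param grid a `hex_grid`.
#' @param x,y numeric vectors of coordinates (mm).
#' @param side integer scalar or vector of comb faces (default 1).
#' @return integer vector of site ids (`NA` when no site contains a point).
#' @export
locate_site <- function(grid, x, y, side = 1L) {
  stopifnot(inherits(grid, "hex_grid"))
  base <- hex_locate_cpp(as.numeric(x), as.numeric(y),
                         grid$origin[1], grid$origin[2], grid$size,
                         grid$lookup)
  if (grid$sides == 1L) return(base)
  side <- as.integer(side)
  if (length(side) == 1L) side <- rep(side, length(base))
  base + (side - 1L) * grid$n_base
}

#' Hexagonal adjacency list
#'
#' @param grid a `hex_grid`.
#' @return list of integer vectors; element `s` holds the site ids of the
#'   (up to six) lattice neighbours of base site `s` on side 1. Side-2
#'   neighbourhoods are the same sites shifted by `n_base`.
#' @export
hex_neighbours <- function(grid) {
  dq <- c(1L, 1L, 0L, -1L, -1L, 0L)
  dr <- c(0L, -1L, -1L, 0L, 1L, 1L)
  q <- grid$col - (grid$row - grid$row %% 2L) %/% 2L
  r <- grid$row
  nrow_l <- nrow(grid$lookup); ncol_l <- ncol(grid$lookup)
  lapply(seq_len(grid$n_base), function(s) {
    qq <- q[s] + dq; rr <- r[s] + dr
    cc <- qq + (rr - rr %% 2L) %/% 2L
    ok <- rr >= 0L & rr < nrow_l & cc >= 0L & cc < ncol_l
    ids <- grid$lookup[cbind(rr[ok] + 1L, cc[ok] + 1L)]
    ids[ids > 0L]
  })
}

#' Distance from site centres to a nest feature
#'
#' Euclidean distance (in body lengths) from each site centre to the
#' nearest point of a feature: the nest `entrance`, the `brood` outline
#' (0 for sites inside it), the nest `wall` (boundary polygon), or the
#' boundary of a spatial module (`module_boundary`, measured to the
#' nearest boundary-site centre; boundary sites are sites whose primary
#' module is the focal module and that are lattice-adjacent to a site with
#' a different primary module).
#'
#' @param grid a `hex_grid`.
#' @param nest the matching [nest_geometry()].
#' @param feature one of "entrance", "brood", "wall", "module_boundary".
#' @param sites site ids to evaluate (default all).
#' @param module_map integer vector of primary-module indices per site
#'   (required for "module_boundary").
#' @param module focal module index (required for "module_boundary").
#' @return numeric vector of distances in body lengths.
#' @export
distance_to_feature <- function(grid, nest,
                                feature = c("entrance", "brood", "wall",
                                            "module_boundary"),
                                sites = seq_len(n_sites(grid)),
                                module_map = NULL, module = NULL) {
  feature <- match.arg(feature)
  ctr <- site_centers(grid, sites)
  bl <- nest$body_length
  if (feature == "entrance") {
    d <- sqrt((ctr[, 1] - nest$entrance[1])^2 + (ctr[, 2] - nest$entrance[2])^2)
  } else if (feature == "brood") {
    if (is.null(nest$brood))
      stop("nest has no brood outline; brood distance undefined")
    d <- .dist_to_polygon_boundary(ctr[, 1], ctr[, 2], nest$brood)
    d[.points_in_polygon(ctr[, 1], ctr[, 2], nest$brood)] <- 0
  } else if (feature == "wall") {
    d <- .dist_to_polygon_boundary(ctr[, 1], ctr[, 2], nest$boundary)
  } else {
    if (is.null(module_map) || is.null(module))
      stop("module_boundary distance needs `module_map` and `module`")
    bs <- module_boundary_sites(grid, module_map, module)
    if (length(bs) == 0) return(rep(NA_real_, length(sites)))
    bctr <- site_centers(grid, bs)
    d <- vapply(seq_len(nrow(ctr)), function(i)
      min(sqrt((bctr[, 1] - ctr[i, 1])^2 + (bctr[, 2] - ctr[i, 2])^2)),
      numeric(1))
  }
  unname(d) / bl
}

#' Boundary sites of a spatial module
#'
#' Sites whose primary module is `module` and that have at least one
#' lattice neighbour with a different primary module (or that sit on the
#' edge of the occupied map).
#'
#' @param grid a `hex_grid`.
#' @param module_map integer vector, primary module per site (`NA` for
#'   unmapped sites).
#' @param module focal module index.
#' @return integer vector of boundary site ids.
#' @export
module_boundary_sites <- function(grid, module_map, module) {
  nb <- hex_neighbours(grid)
  member <- which(!is.na(module_map) & module_map == module)
  member_base <- ((member - 1L) %% grid$n_base) + 1L
  off <- (member - 1L) %/% grid$n_base * grid$n_base
  is_boundary <- vapply(seq_along(member), function(k) {
    ids <- nb[[member_base[k]]] + off[k]
    mm <- module_map[ids]
    any(is.na(mm)) || any(mm != module) || length(ids) < 6L
  }, logical(1))
  member[is_boundary]
}

#' Sites table
#'
#' @param x a `hex_grid`.
#' @param ... unused.
#' @return data.frame with columns `site_id`, `side`, `x_mm`, `y_mm`.
#' @export
as.data.frame.hex_grid <- function(x, ...) {
  ids <- seq_len(n_sites(x))
  ctr <- site_centers(x, ids)
  data.frame(site_id = ids, side = site_side(x, ids),
             x_mm = ctr[, 1], y_mm = ctr[, 2])
}

#' Write the sites table to CSV
#' @param grid a `hex_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sites_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}
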