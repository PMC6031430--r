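#' Fixed analysis grid over the behavior space
#'
#' Square grid spanning the training embedding's bounding box padded by
#' `pad` on each side. All densities, significance maps and regions of a
#' given embedding share one grid. The default resolution of 210 cells per
#' side matches the standard map rendering; reduced grids are appropriate
#' for small synthetic analyses.
#'
#' @param points data frame with `x`, `y` (typically the training
#'   embedding positions), or a 2-column matrix.
#' @param resolution cells per side.
#' @param pad fractional padding of the bounding box.
#' @return `map_grid` object: `xlim`, `ylim`, `n`.
#' @export
map_grid <- function(points, resolution = 210, pad = 0.1) {
  xy <- if (is.data.frame(points)) cbind(points$x, points$y) else points
  xy <- xy[complete.cases(xy), , drop = FALSE]
  stop_if_not(nrow(xy) > 0, "no finite points to define a grid")
  half <- max(diff(range(xy[, 1])), diff(range(xy[, 2])), 1e-9) * (1 + 2 * pad) / 2
  cx <- mean(range(xy[, 1])); cy <- mean(range(xy[, 2]))
  structure(list(xlim = c(cx - half, cx + half),
                 ylim = c(cy - half, cy + half),
                 n = as.integer(resolution)),
            class = "map_grid")
}

#' Cell-center coordinates of a map grid
#'
#' @param grid a [map_grid()].
#' @return list with numeric vectors `x` and `y` (length `grid$n`).
#' @export
grid_cell_centers <- function(grid) {
  w <- diff(grid$xlim) / grid$n
  list(x = grid$xlim[1] + (seq_len(grid$n) - 0.5) * w,
       y = grid$ylim[1] + (seq_len(grid$n) - 0.5) * diff(grid$ylim) / grid$n)
}

#' Map points to grid cells
#'
#' @param points data frame with `x`, `y`.
#' @param grid a [map_grid()].
#' @return integer matrix with columns `ix`, `iy`; `NA` for points outside
#'   the grid or with missing coordinates.
#' @export
point_to_cell <- function(points, grid) {
  n <- grid$n
  ix <- ceiling((points$x - grid$xlim[1]) / diff(grid$xlim) * n)
  iy <- ceiling((points$y - grid$ylim[1]) / diff(grid$ylim) * n)
  ix[ix == 0] <- 1L; iy[iy == 0] <- 1L  # points exactly on the lower edge
  out <- ix < 1 | ix > n | iy < 1 | iy > n
  ix[out] <- NA_integer_; iy[out] <- NA_integer_
  cbind(ix = as.integer(ix), iy = as.integer(iy))
}

#' Behavior-space density map
#'
#' 2D histogram of embedded points on the grid, normalized, convolved with
#' an isotropic Gaussian of width `sigma` (grid cells), and renormalized.
#'
#' @param points data frame with `x`, `y` (and optionally `valid`).
#' @param grid a [map_grid()].
#' @param sigma smoothing width in grid cells (1.5 for maps and the
#'   significance analysis; 2 for entropy curves).
#' @return `grid$n x grid$n` matrix summing to 1 (attribute `n_points`);
#'   an all-zero matrix with attribute `empty = TRUE` when no point falls
#'   on the grid.
#' @export
density_map <- function(points, grid, sigma = 1.5) {
  if (!is.null(points$valid)) points <- points[points$valid, , drop = FALSE]
  cells <- point_to_cell(points, grid)
  cells <- cells[complete.cases(cells), , drop = FALSE]
  n <- grid$n
  H <- matrix(0, n, n)
  if (nrow(cells) == 0) {
    attr(H, "empty") <- TRUE
    attr(H, "n_points") <- 0L
    return(H)
  }
  counts <- tabulate((cells[, 2] - 1L) * n + cells[, 1], nbins = n * n)
  H <- matrix(counts, n, n)
  H <- smooth2d(H, sigma)
  H <- H / sum(H)
  attr(H, "n_points") <- nrow(cells)
  attr(H, "sigma") <- sigma
  H
}

#' Watershed regionization of a density map
#'
#' Segments the map into regions around density maxima: cells below the
#' `min_density_quantile` of the map are background, and the watershed
#' transform of the remaining density assigns each cell to the basin of a
#' local maximum. Regions are connected components by construction and
#' are relabeled in decreasing size order.
#'
#' @param density a [density_map()] matrix.
#' @param min_density_quantile background threshold quantile.
#' @param tolerance minimum peak height (fraction of the map maximum)
#'   separating two regions; shallower maxima are merged.
#' @param names optional character vector of human-curated region names
#'   (recycled / defaulted to `R1..Rm`).
#' @return `region_set`: `labels` (integer matrix, 0 = background),
#'   `n_regions`, `sizes`, `names`, `threshold`.
#' @export
watershed_regions <- function(density, min_density_quantile = 0.75,
                              tolerance = 0.01, names = NULL) {
  stop_if_not(abs(sum(density) - 1) < 1e-6 || sum(density) == 0,
              "density must be normalized")
  thr <- quantile(density, min_density_quantile)
  masked <- density
  masked[density <= thr] <- 0
  if (max(masked) <= 0 || diff(range(density)) < 1e-15) {
    warning("flat density map; returning a single region")
    labels <- matrix(1L, nrow(density), ncol(density))
    return(structure(list(labels = labels, n_regions = 1L,
                          sizes = length(labels), names = names %||% "R1",
                          threshold = thr), class = "region_set"))
  }
  ws <- EBImage::watershed(EBImage::Image(masked),
                           tolerance = tolerance * max(masked))
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(density))
  sizes <- tabulate(lab[lab > 0])
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(ord)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- relab[lab[lab > 0]]
  m <- length(sizes)
  structure(list(labels = out, n_regions = m, sizes = sizes[ord],
                 names = names %||% paste0("R", seq_len(m)), threshold = thr),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d region(s) on a %dx%d grid\n", x$n_regions,
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Euclidean distance maps to each region
#'
#' @param regions a `region_set`.
#' @return list of matrices; entry `k` gives, for every grid cell, the
#'   Euclidean distance in cells to the nearest cell of region `k`
#'   (0 inside; `Inf` everywhere for an empty region).
#' @export
region_distance_maps <- function(regions) {
  lapply(seq_len(regions$n_regions), function(k) {
    mask <- regions$labels == k
    if (!any(mask)) {
      return(matrix(Inf, nrow(regions$labels), ncol(regions$labels)))
    }
    m <- EBImage::distmap(EBImage::Image(1 - mask), metric = "euclidean")
    matrix(as.numeric(EBImage::imageData(m)), nrow(regions$labels))
  })
}

#' Distance from a grid cell to a region
#'
#' @param cell integer vector `c(ix, iy)`.
#' @param region region id.
#' @param regions a `region_set`.
#' @param distance_maps optional precomputed [region_distance_maps()].
#' @return Euclidean distance in grid cells (0 if the cell is inside).
#' @export
distance_to_region <- function(cell, region, regions, distance_maps = NULL) {
  dm <- if (is.null(distance_maps)) region_distance_maps(regions)[[region]]
        else distance_maps[[region]]
  dm[cell[1], cell[2]]
}

#' Region set from known state territories
#'
#' Builds the ground-truth regionization of a synthetic embedded session:
#' each state's region is the disc of `radius_mult * scatter_sd` around
#' its center. Used to compare detected significant regions against the
#' generator's truth.
#'
#' @param centers state-center matrix.
#' @param scatter_sd territory scatter, map units.
#' @param grid a [map_grid()].
#' @param radius_mult disc radius in units of `scatter_sd`.
#' @return `region_set` with one region per state (state k = region k).
#' @export
territory_regions <- function(centers, scatter_sd, grid, radius_mult = 3) {
  cc <- grid_cell_centers(grid)
  lab <- matrix(0L, grid$n, grid$n)
  r2 <- (radius_mult * scatter_sd)^2
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((cc$x - centers[k, 1])^2, (cc$y - centers[k, 2])^2, `+`)
    lab[d2 <= r2] <- k
  }
  structure(list(labels = lab, n_regions = nrow(centers),
                 sizes = tabulate(lab[lab > 0], nrow(centers)),
                 names = paste0("S", seq_len(nrow(centers))), threshold = 0),
            class = "region_set")
}
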