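#' Build a hypsographic vertical grid
#'
#' Discretises the water column into `n_layers` equal-thickness layers with
#' a power-law depth-area relation
#' `A(z) = A0 (1 - z/z_max)^p`, `p = z_max/z_mean - 1`,
#' which integrates to total volume `A0 * z_mean` exactly. Layer volumes are
#' obtained by analytic integration between interfaces, so they telescope:
#' any refinement sums to the same total volume.
#'
#' @param surface_area lake surface area A0 (m^2). Default is the
#'   "barleber" morphometry, 1.03e6 m^2 (103 ha).
#' @param max_depth maximum depth z_max (m), default 11.
#' @param mean_depth mean depth (m), default 6.7; must satisfy
#'   `0 < mean_depth < max_depth`.
#' @param n_layers number of layers (>= 5), default 22 (0.5 m resolution).
#' @return An object of class `"lake_grid"`: interface depths `z` (length
#'   `n_layers + 1`, 0 at the surface), interface areas `area`, layer
#'   volumes `volume`, layer mid-depths `z_mid`, layer thickness `dz`,
#'   sediment contact area per layer `sed_area` (the annulus between
#'   consecutive interface areas; sums to `surface_area`), and scalars
#'   `surface_area`, `max_depth`, `mean_depth`, `p`.
#' @examples
#' g <- build_grid()
#' sum(g$volume) / g$surface_area  # mean depth, 6.7 m
#' @export
build_grid <- function(surface_area = 1.03e6, max_depth = 11,
                       mean_depth = 6.7, n_layers = 22) {
  if (!(mean_depth > 0 && mean_depth < max_depth))
    stop("require 0 < mean_depth < max_depth")
  if (n_layers < 5) stop("n_layers must be >= 5")
  p <- max_depth / mean_depth - 1
  z <- seq(0, max_depth, length.out = n_layers + 1)
  area <- surface_area * (1 - z / max_depth)^p
  ## integral of A(z) dz from z1 to z2, closed form
  vol_to <- function(zz) surface_area * max_depth / (p + 1) *
    (1 - (1 - zz / max_depth)^(p + 1))
  volume <- diff(vol_to(z))
  grid <- list(
    n_layers = n_layers,
    z = z,
    area = area,
    volume = volume,
    z_mid = (z[-1] + z[-(n_layers + 1)]) / 2,
    dz = diff(z),
    sed_area = area[-(n_layers + 1)] - area[-1],
    surface_area = surface_area,
    max_depth = max_depth,
    mean_depth = mean_depth,
    p = p
  )
  class(grid) <- "lake_grid"
  grid
}

#' @export
print.lake_grid <- function(x, ...) {
  cat(sprintf(
    "Hypsographic lake grid: %d layers, z_max %.1f m, A0 %.3g m^2\n",
    x$n_layers, x$max_depth, x$surface_area))
  cat(sprintf("  total volume %.4g m^3 (mean depth %.2f m), p = %.4f\n",
              sum(x$volume), sum(x$volume) / x$surface_area, x$p))
  invisible(x)
}

#' Volume-weighted mean of a per-layer field over a depth band
#'
#' Averages a per-layer scalar (or each row of a days-by-layers matrix)
#' over the layers intersecting `[depth_range[1], depth_range[2]]`,
#' weighting partial layers by the hypsographic partial volume.
#'
#' @param x numeric vector of length `n_layers`, or a matrix with
#'   `n_layers` columns (one row per time step).
#' @param grid a [build_grid()] object.
#' @param depth_range numeric length-2, metres below surface, within
#'   `[0, max_depth]`. `c(0, max_depth)` gives the whole-lake mean.
#' @return scalar (or vector, one per row of `x`).
#' @export
extract_band <- function(x, grid, depth_range = c(0, grid$max_depth)) {
  z1 <- max(0, min(depth_range)); z2 <- min(grid$max_depth, max(depth_range))
  if (z2 <= z1) stop("empty depth band")
  vol_to <- function(zz) grid$surface_area * grid$max_depth / (grid$p + 1) *
    (1 - (1 - zz / grid$max_depth)^(grid$p + 1))
  lo <- pmax(grid$z[-length(grid$z)], z1)
  hi <- pmin(grid$z[-1], z2)
  w <- ifelse(hi > lo, vol_to(pmin(hi, z2)) - vol_to(pmax(lo, z1)), 0)
  w <- pmax(0, w)
  if (is.matrix(x)) {
    as.numeric(x %*% w) / sum(w)
  } else {
    sum(x * w) / sum(w)
  }
}
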