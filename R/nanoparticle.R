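#' Specify a spherical fcc nanoparticle cut
#'
#' The particle is cut from a face-centered cubic lattice whose conventional
#' cubic cell has edge `lattice_constant`; the sphere is centered on a lattice
#' atom at the origin and every lattice atom with distance `<= radius`
#' (inclusive boundary, with a 1e-9 nm tolerance against floating-point ties)
#' is retained. The default lattice constant 0.4078 nm is the conventional
#' value for gold; nearest neighbours then sit at `a/sqrt(2) ~ 0.2884` nm.
#'
#' @param radius sphere radius (nm), `>= 0`.
#' @param lattice_constant conventional fcc cell edge (nm), `> 0`.
#' @return A list of class `fcc_sphere_spec`.
#' @export
fcc_sphere_spec <- function(radius, lattice_constant = 0.4078) {
  if (!is.finite(radius) || radius < 0) abort("radius must be >= 0")
  if (!is.finite(lattice_constant) || lattice_constant <= 0) {
    abort("lattice_constant must be > 0")
  }
  structure(list(radius = radius, lattice_constant = lattice_constant),
            class = "fcc_sphere_spec")
}

#' Cut a spherical gold nanoparticle from the fcc lattice
#'
#' Generates the fcc lattice (conventional cubic cell with atoms at the corner
#' and the three face centers) over a bounding cube of side `2r + 2a` centered
#' on an atom at the origin and keeps every atom with `|p| <= r`. The result is
#' inversion-symmetric about the center, so the atom count is always odd.
#'
#' @param spec an [fcc_sphere_spec()], or a radius in nm (then
#'   `lattice_constant` applies).
#' @param lattice_constant used when `spec` is a bare radius.
#' @return A list of class `nanoparticle_coords`: `coords` (`n x 3` matrix,
#'   nm, center at the origin), `center_index`, `spec`.
#' @export
#' @examples
#' np <- build_fcc_sphere(1.0)
#' nrow(np$coords)  # 249 gold atoms for the 2 nm particle
build_fcc_sphere <- function(spec, lattice_constant = 0.4078) {
  if (!inherits(spec, "fcc_sphere_spec")) {
    spec <- fcc_sphere_spec(spec, lattice_constant)
  }
  a <- spec$lattice_constant
  r <- spec$radius
  n_cell <- ceiling((r + a) / a)
  idx <- seq(-n_cell, n_cell)
  cells <- as.matrix(expand.grid(i = idx, j = idx, k = idx)) * a
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5)) * a
  pts <- do.call(rbind, lapply(seq_len(nrow(basis)), function(b) {
    sweep(cells, 2, basis[b, ], "+")
  }))
  keep <- rowSums(pts^2) <= r^2 + 1e-9
  coords <- pts[keep, , drop = FALSE]
  dimnames(coords) <- NULL
  center_index <- which(rowSums(coords^2) == 0)
  structure(list(coords = coords, center_index = center_index, spec = spec),
            class = "nanoparticle_coords")
}

#' @export
print.nanoparticle_coords <- function(x, ...) {
  cat(sprintf("<nanoparticle_coords> %d atoms, r = %g nm, a = %g nm\n",
              nrow(x$coords), x$spec$radius, x$spec$lattice_constant))
  invisible(x)
}

#' @export
tidy.nanoparticle_coords <- function(x, ...) {
  tibble(atom = seq_len(nrow(x$coords)),
         x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3],
         surface = FALSE) |>
    mutate(surface = .data$atom %in% identify_surface_gold(x))
}

#' Histogram of all unique pairwise distances in a point set
#'
#' Counts are normalized to unit area (a probability density over distance).
#'
#' @param coords `n x 3` matrix (nm) or a `nanoparticle_coords`.
#' @param bin_width bin width (nm), `> 0`.
#' @param max_distance histogram upper limit (nm); defaults to the largest
#'   pair distance.
#' @return A tibble of class `md_histogram` with `bin_left`, `bin_center`,
#'   `bin_right`, `density`.
#' @export
pairwise_distance_distribution <- function(coords, bin_width = 0.02,
                                           max_distance = NULL) {
  if (inherits(coords, "nanoparticle_coords")) coords <- coords$coords
  if (nrow(coords) < 2) abort("need at least 2 atoms")
  if (!is.finite(bin_width) || bin_width <= 0) abort("bin_width must be > 0")
  d <- as.numeric(stats::dist(coords))
  if (is.null(max_distance)) max_distance <- max(d) + bin_width
  d <- d[d <= max_distance]
  new_histogram(d, bin_width, max_distance, normalization = "unit_area")
}

#' Total site count of a bilayer/nanoparticle/water system
#'
#' @param n_gold gold atoms.
#' @param n_lipids lipid molecules.
#' @param sites_per_lipid united-atom sites per lipid (56 for AOPC).
#' @param n_waters water molecules.
#' @param water_sites interaction sites per water (3 for SPC).
#' @return Total site count (numeric).
#' @export
#' @examples
#' system_composition(249, 128, 56, 11008)  # 40441, the 2 nm AuNP system
system_composition <- function(n_gold, n_lipids, sites_per_lipid, n_waters,
                               water_sites = 3) {
  args <- c(n_gold, n_lipids, sites_per_lipid, n_waters, water_sites)
  if (any(args < 0)) abort("all counts must be >= 0")
  n_gold + n_lipids * sites_per_lipid + n_waters * water_sites
}

#' Identify surface atoms of a nanoparticle
#'
#' Bulk fcc atoms have exactly 12 nearest neighbours at `a/sqrt(2)`; atoms with
#' coordination number below 12 at the cutoff are classified as surface.
#'
#' @param coords `n x 3` matrix (nm) or a `nanoparticle_coords`.
#' @param neighbor_cutoff neighbour-counting cutoff (nm); the default 0.35 nm
#'   sits between the first (0.288 nm) and second (0.408 nm) fcc shells.
#' @return Integer indices of surface atoms.
#' @export
identify_surface_gold <- function(coords, neighbor_cutoff = 0.35) {
  if (inherits(coords, "nanoparticle_coords")) coords <- coords$coords
  if (nrow(coords) < 1) abort("need at least 1 atom")
  if (nrow(coords) == 1) return(1L)
  d <- as.matrix(stats::dist(coords))
  coordination <- rowSums(d > 0 & d <= neighbor_cutoff)
  which(coordination < 12)
}
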