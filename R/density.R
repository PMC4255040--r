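#' Partial density profile along the bilayer normal
#'
#' Bins the selected sites along z, weights by site mass (or counts), divides
#' by the bin volume `lx * ly * dz` and averages over the frames of the
#' window. Mass densities are reported in kg/m^3 (conversion 1.66054 from
#' u/nm^3, the convention of GROMACS-style partial density plots); number
#' densities in nm^-3.
#'
#' @param traj an [md_trajectory()].
#' @param selection integer site ids (e.g. from [select_sites()]).
#' @param n_bins number of z bins (default 100).
#' @param window analysis window, see [window_frames()].
#' @param mode `"mass"` (default) or `"number"`.
#' @param label selection label carried into the result.
#' @return A tibble of class `density_profile`: `z` (bin center, nm),
#'   `density`, plus `bin_left`/`bin_right`; attributes `mode`, `label`,
#'   `total_mass`.
#' @export
partial_density_profile <- function(traj, selection, n_bins = 100,
                                    window = NULL, mode = c("mass", "number"),
                                    label = "selection") {
  mode <- match.arg(mode)
  if (length(selection) == 0) abort("empty selection")
  frames <- window_frames(traj, window)
  box <- frame_box(traj, frames[1])
  edges <- seq(0, box[3], length.out = n_bins + 1)
  dz <- diff(edges)[1]
  w <- if (mode == "mass") traj$topology$mass[selection] else rep(1, length(selection))
  acc <- rep(0, n_bins)
  for (f in frames) {
    z <- frame_coords(traj, f)[selection, 3]
    z <- z - box[3] * floor(z / box[3])
    idx <- pmin(pmax(findInterval(z, edges, rightmost.closed = TRUE), 1L), n_bins)
    acc <- acc + as.numeric(tapply(w, factor(idx, levels = seq_len(n_bins)), sum,
                                   default = 0))
  }
  vol <- box[1] * box[2] * dz
  dens <- acc / (length(frames) * vol)
  if (mode == "mass") dens <- dens * .MASS_DENSITY_FACTOR
  out <- tibble(z = edges[-length(edges)] + dz / 2,
                bin_left = edges[-length(edges)], bin_right = edges[-1],
                density = dens)
  attr(out, "mode") <- mode
  attr(out, "label") <- label
  attr(out, "total_mass") <- sum(traj$topology$mass[selection])
  attr(out, "box") <- box
  class(out) <- c("density_profile", class(out))
  out
}

#' Two-dimensional number-density map in the x-z plane
#'
#' Counts of the selected sites are binned in (x, z), averaged over y and the
#' frames of the window, and divided by the bin volume `dx * ly * dz`,
#' yielding a number density in nm^-3. The default window is the last 10 ns,
#' the convention for the penetrating-water density maps.
#'
#' @param traj an [md_trajectory()].
#' @param selection site ids; defaults to the water oxygens.
#' @param window analysis window (default last 10 ns).
#' @param bin bin width (nm) in both x and z.
#' @return A tibble of class `density_map_2d` with `x`, `z` (bin centers) and
#'   `density` (nm^-3); attributes `bin`, `window_frames`.
#' @export
density_map_2d <- function(traj, selection = NULL, window = 10, bin = 0.1) {
  if (is.null(selection)) {
    selection <- select_sites(traj$topology, molecule_type = "SOL",
                              site_name = "OW")
  }
  if (length(selection) == 0) abort("empty selection")
  frames <- window_frames(traj, window)
  box <- frame_box(traj, frames[1])
  xe <- seq(0, box[1] + bin * 1e-9, by = bin)
  if (xe[length(xe)] < box[1] - 1e-9) xe <- c(xe, xe[length(xe)] + bin)
  ze <- seq(0, box[3] + bin * 1e-9, by = bin)
  if (ze[length(ze)] < box[3] - 1e-9) ze <- c(ze, ze[length(ze)] + bin)
  nx <- length(xe) - 1; nz <- length(ze) - 1
  acc <- matrix(0, nx, nz)
  for (f in frames) {
    co <- frame_coords(traj, f)[selection, , drop = FALSE]
    x <- co[, 1] - box[1] * floor(co[, 1] / box[1])
    z <- co[, 3] - box[3] * floor(co[, 3] / box[3])
    ix <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1L), nx)
    iz <- pmin(pmax(findInterval(z, ze, rightmost.closed = TRUE), 1L), nz)
    acc <- acc + as.matrix(table(factor(ix, seq_len(nx)), factor(iz, seq_len(nz))))
  }
  out <- tibble(x = rep(xe[-length(xe)] + bin / 2, times = nz),
                z = rep(ze[-length(ze)] + bin / 2, each = nx),
                density = as.numeric(acc) / (length(frames) * bin * box[2] * bin))
  attr(out, "bin") <- bin
  attr(out, "window_frames") <- length(frames)
  attr(out, "box") <- box
  class(out) <- c("density_map_2d", class(out))
  out
}
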