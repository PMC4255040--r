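#' Grid-based bilayer thickness (GridMAT-style)
#'
#' The xy box is divided into a `grid[1] x grid[2]` mesh. Per frame, the
#' head-group N sites of each leaflet are binned into cells; the cell
#' thickness is `mean(upper N z) - mean(lower N z)`. Cells empty in one
#' leaflet are filled from the nearest occupied cell of that leaflet (cell
#' centers compared with minimum-image xy distance, so filling works across
#' the periodic boundary). The long-range mask keeps cells whose center lies
#' at least `d_buf` (in xy) from the nanoparticle center of mass; without a
#' nanoparticle all cells are kept. The normalized thickness distribution is
#' accumulated over masked cells and frames.
#'
#' @param traj an [md_trajectory()].
#' @param grid mesh dimensions (default `c(50, 50)`).
#' @param boundaries optional [region_boundaries()]; enables the LR mask.
#' @param region `"LR"` (cells beyond `d_buf`; default) or `"SR"` (cells
#'   within `d_sr`) for the masked distribution.
#' @param bin thickness-distribution bin width (nm).
#' @param window analysis window (default last 20 ns).
#' @param leaflets optional [assign_leaflets()] result.
#' @return A list of class `thickness_field`: `cell_means` (grid matrix of
#'   time-averaged thickness, nm), `mask` (logical grid), `distribution`
#'   (unit-area `md_histogram` over masked cell values), `mean` (masked mean
#'   thickness, nm).
#' @export
grid_thickness <- function(traj, grid = c(50, 50), boundaries = NULL,
                           region = c("LR", "SR"), bin = 0.05, window = 20,
                           leaflets = NULL) {
  region <- match.arg(region)
  top <- traj$topology
  frames <- window_frames(traj, window)
  if (is.null(leaflets)) leaflets <- assign_leaflets(traj, frames[1])
  n_idx <- select_sites(top, molecule_type = "AOPC", site_name = "N")
  n_mol <- top$molecule_id[n_idx]
  lf <- leaflets$leaflet[match(n_mol, leaflets$molecule_id)]
  up_idx <- n_idx[lf == "upper"]
  lo_idx <- n_idx[lf == "lower"]
  if (length(up_idx) == 0 || length(lo_idx) == 0) {
    abort("a leaflet has no head-group N sites")
  }
  box <- frame_box(traj, frames[1])
  nx <- grid[1]; ny <- grid[2]
  cx <- (seq_len(nx) - 0.5) * box[1] / nx
  cy <- (seq_len(ny) - 0.5) * box[2] / ny
  cell_xy <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  leaflet_grid <- function(co, idx) {
    x <- co[idx, 1] %% box[1]
    y <- co[idx, 2] %% box[2]
    ix <- pmin(pmax(ceiling(x / box[1] * nx), 1L), nx)
    iy <- pmin(pmax(ceiling(y / box[2] * ny), 1L), ny)
    cell <- ix + (iy - 1L) * nx
    z <- co[idx, 3]
    means <- rep(NA_real_, nx * ny)
    agg <- tapply(z, cell, mean)
    means[as.integer(names(agg))] <- agg
    occupied <- which(!is.na(means))
    if (length(occupied) == 0) abort("a leaflet is entirely empty")
    if (length(occupied) < nx * ny) {
      emptyc <- which(is.na(means))
      d <- .cross_distances(cbind(cell_xy[emptyc, 1], cell_xy[emptyc, 2], 0),
                            cbind(cell_xy[occupied, 1], cell_xy[occupied, 2], 0),
                            c(box[1], box[2], 1e9))
      nearest <- occupied[apply(d, 1, which.min)]
      means[emptyc] <- means[nearest]
    }
    means
  }
  acc <- rep(0, nx * ny)
  samples <- numeric(0)
  np_xy <- NULL
  au <- select_sites(top, molecule_type = "AU")
  if (length(au) > 0) np_xy <- center_of_mass(traj, au, frames[1])[1:2]
  mask <- rep(TRUE, nx * ny)
  if (!is.null(boundaries) && !is.null(np_xy)) {
    d_cell <- minimum_image_distance(cbind(cell_xy, 0),
                                     matrix(c(np_xy, 0), 1, 3),
                                     c(box[1], box[2], 1e9))
    mask <- if (region == "LR") d_cell >= boundaries$d_buf else
      d_cell <= boundaries$d_sr
  }
  if (!any(mask)) {
    abort(sprintf("no grid cells in the %s mask: box too small for these boundaries",
                  region))
  }
  for (f in frames) {
    co <- frame_coords(traj, f)
    th <- leaflet_grid(co, up_idx) - leaflet_grid(co, lo_idx)
    acc <- acc + th
    samples <- c(samples, th[mask])
  }
  cell_means <- matrix(acc / length(frames), nx, ny)
  hi <- max(samples) + bin
  dist <- new_histogram(samples, bin, hi, lo = max(0, min(samples) - bin),
                        normalization = "unit_area")
  structure(list(cell_means = cell_means, mask = matrix(mask, nx, ny),
                 distribution = dist, mean = mean(samples),
                 grid = grid, box = box, region = region),
            class = "thickness_field")
}

#' @export
print.thickness_field <- function(x, ...) {
  cat(sprintf("<thickness_field> %dx%d grid, %s-masked mean %.3f nm\n",
              x$grid[1], x$grid[2], x$region, x$mean))
  invisible(x)
}

#' @export
tidy.thickness_field <- function(x, ...) {
  nx <- x$grid[1]; ny <- x$grid[2]
  tibble(
    cell_x = rep((seq_len(nx) - 0.5) * x$box[1] / nx, times = ny),
    cell_y = rep((seq_len(ny) - 0.5) * x$box[2] / ny, each = nx),
    thickness = as.numeric(x$cell_means),
    masked = as.logical(x$mask)
  )
}

#' @export
glance.thickness_field <- function(x, ...) {
  tibble(mean_thickness = x$mean, region = x$region,
         n_masked_cells = sum(x$mask), grid_x = x$grid[1], grid_y = x$grid[2])
}

#' Area per lipid of the long-range region
#'
#' Per frame, the nanoparticle-affected area is modelled as the projected
#' disc of radius `d_buf = r + 2` nm around the nanoparticle (the geometric
#' realization of the SR+buffer classification boundary):
#' `A_LR = (lx*ly - pi*d_buf^2) / n_LR`, with `n_LR` the long-range lipid
#' count of the interacting leaflet in the frame's epoch. Without a
#' nanoparticle the plain `lx*ly / n_leaflet` is returned. Alternatively the
#' excluded area can be taken as the convex hull of the SR+buffer head-group
#' N sites (`excluded = "hull"`).
#'
#' @param traj an [md_trajectory()].
#' @param tags `epoch_tags` from [tag_trajectory()] (may be `NULL` for the
#'   reference system).
#' @param boundaries a [region_boundaries()] (or `NULL` without a
#'   nanoparticle).
#' @param window analysis window (default last 20 ns).
#' @param excluded `"disc"` (default) or `"hull"`.
#' @return A tibble of class `apl_series`: `time` (ns), `area_per_lipid`
#'   (nm^2), `n_LR`; attribute `mean`.
#' @export
area_per_lipid_lr <- function(traj, tags = NULL, boundaries = NULL,
                              window = 20, excluded = c("disc", "hull")) {
  excluded <- match.arg(excluded)
  frames <- window_frames(traj, window)
  top <- traj$topology
  out <- purrr::map(frames, function(f) {
    box <- frame_box(traj, f)
    area_box <- box[1] * box[2]
    t <- traj$times[f]
    if (is.null(boundaries)) {
      lip <- unique(top$molecule_id[top$molecule_type == "AOPC"])
      n_leaf <- length(lip) / 2
      return(tibble(time = t, area_per_lipid = area_box / n_leaf,
                    n_LR = as.integer(n_leaf)))
    }
    et <- .tags_at_time(tags, t)
    n_lr <- sum(et$region == "LR")
    if (n_lr == 0) abort(sprintf("no LR lipids at t = %g ns", t))
    a_excl <- if (excluded == "disc") {
      pi * boundaries$d_buf^2
    } else {
      ids <- et$molecule_id[et$region %in% c("SR", "BUFFER")]
      if (length(ids) < 3) 0 else {
        n_idx <- select_sites(top, molecule_type = "AOPC", site_name = "N")
        n_idx <- n_idx[top$molecule_id[n_idx] %in% ids]
        xy <- frame_coords(traj, f)[n_idx, 1:2, drop = FALSE]
        hull <- grDevices::chull(xy)
        hx <- xy[hull, 1]; hy <- xy[hull, 2]
        abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
      }
    }
    tibble(time = t, area_per_lipid = (area_box - a_excl) / n_lr,
           n_LR = as.integer(n_lr))
  })
  out <- bind_rows(out)
  if (any(out$area_per_lipid <= 0)) {
    abort("non-positive area per lipid: excluded disc exceeds the box area")
  }
  attr(out, "mean") <- mean(out$area_per_lipid)
  attr(out, "excluded") <- excluded
  class(out) <- c("apl_series", class(out))
  out
}

#' @export
glance.apl_series <- function(x, ...) {
  tibble(mean_area_per_lipid = attr(x, "mean"),
         n_frames = nrow(x), excluded = attr(x, "excluded"))
}
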