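#' Distance distribution between head-group sites and surface gold atoms
#'
#' For every frame, the nanoparticle's surface atoms (coordination number
#' below 12, see [identify_surface_gold()]) are restricted to those in the
#' vicinity of the membrane (within `vicinity` of any lipid head-group site).
#' Each head-group site of the named type whose minimum distance to that
#' surface set is within `contact_cutoff` contributes that minimum distance to
#' the histogram. Heights are divided by the number of contributing sites
#' accumulated over frames and by the bin width, so a delta fixture with every
#' site at one distance has height `1/bin`.
#'
#' @param traj an [md_trajectory()].
#' @param site_name head-group site name(s), e.g. `"N"`, `c("CN1","CN2","CN3")`
#'   or `c("O4","O5")`.
#' @param surface_gold optional precomputed surface-atom site ids; recomputed
#'   per frame from the `AU` sites by default.
#' @param contact_cutoff maximum distance recorded (nm).
#' @param vicinity gold-near-membrane restriction distance (nm).
#' @param bin histogram bin width (nm).
#' @param window analysis window (default last 10 ns).
#' @param all_pairs record all site-gold pair distances within the cutoff
#'   instead of the per-site minimum (`FALSE` by default: the contact-layer
#'   measure).
#' @return An `md_histogram` tibble (per-contributing-atom normalization) with
#'   attribute `n_contributing`.
#' @export
distance_distribution <- function(traj, site_name, surface_gold = NULL,
                                  contact_cutoff = 1.0, vicinity = 0.6,
                                  bin = 0.02, window = 10, all_pairs = FALSE) {
  top <- traj$topology
  au_idx <- select_sites(top, molecule_type = "AU")
  if (length(au_idx) == 0) abort("no gold atoms in topology")
  site_idx <- select_sites(top, molecule_type = "AOPC", site_name = site_name)
  if (length(site_idx) == 0) abort(sprintf("no sites named %s",
                                           paste(site_name, collapse = "/")))
  head_idx <- select_sites(top, molecule_type = "AOPC",
                           site_name = aopc_head_site_names())
  frames <- window_frames(traj, window)
  vals <- numeric(0)
  n_contrib <- 0L
  for (f in frames) {
    co <- frame_coords(traj, f)
    box <- frame_box(traj, f)
    surf_local <- if (is.null(surface_gold)) {
      au_idx[identify_surface_gold(co[au_idx, , drop = FALSE])]
    } else surface_gold
    if (length(surf_local) == 0) abort("no surface gold atoms found")
    # restrict to surface gold near any head-group site
    d_gh <- .cross_distances(co[surf_local, , drop = FALSE],
                             co[head_idx, , drop = FALSE], box)
    near <- surf_local[apply(d_gh, 1, min) <= vicinity]
    if (length(near) == 0) next
    d_sg <- .cross_distances(co[site_idx, , drop = FALSE],
                             co[near, , drop = FALSE], box)
    if (all_pairs) {
      keep <- d_sg[d_sg <= contact_cutoff]
      contributing <- sum(apply(d_sg, 1, min) <= contact_cutoff)
    } else {
      mins <- apply(d_sg, 1, min)
      keep <- mins[mins <= contact_cutoff]
      contributing <- length(keep)
    }
    vals <- c(vals, keep)
    n_contrib <- n_contrib + contributing
  }
  new_histogram(vals, bin, contact_cutoff,
                normalization = "per_contributing_atom",
                n_contributing = n_contrib,
                extra = list(site_name = paste(site_name, collapse = "+"),
                             n_frames = length(frames)))
}

#' Radial distribution function g(r)
#'
#' Standard pair correlation between a reference and a target selection,
#' normalized by the ideal-gas shell count at the target's mean number
#' density, so `g -> 1` at large separation. Self pairs (shared site ids) are
#' excluded. `r_max` beyond half the smallest box edge is clipped with a
#' warning, since minimum-image distances are only unique below it.
#'
#' @param traj an [md_trajectory()].
#' @param ref_selection,target_selection site id vectors.
#' @param bin bin width (nm).
#' @param r_max maximum distance (nm); default half the smallest box edge.
#' @param window analysis window (default all frames).
#' @return A tibble of class `rdf_result`: `r` (bin center), `g`.
#' @export
rdf <- function(traj, ref_selection, target_selection, bin = 0.02,
                r_max = NULL, window = NULL) {
  if (length(ref_selection) == 0 || length(target_selection) == 0) {
    abort("both selections must be non-empty")
  }
  frames <- window_frames(traj, window)
  box <- frame_box(traj, frames[1])
  half <- min(box) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9) {
    warn(sprintf("r_max %.3f nm exceeds half the smallest box edge; clipped to %.3f nm",
                 r_max, half))
    r_max <- half
  }
  nb <- max(1L, ceiling(r_max / bin - 1e-9))
  edges <- bin * (0:nb)
  acc <- rep(0, nb)
  n_pairs_total <- 0
  for (f in frames) {
    co <- frame_coords(traj, f)
    d <- .cross_distances(co[ref_selection, , drop = FALSE],
                          co[target_selection, , drop = FALSE],
                          frame_box(traj, f))
    self <- outer(ref_selection, target_selection, "==")
    d <- d[!self]
    idx <- findInterval(d[d < r_max], edges, rightmost.closed = TRUE)
    idx <- idx[idx >= 1 & idx <= nb]
    acc <- acc + tabulate(idx, nbins = nb)
  }
  vol <- prod(box)
  rho_target <- length(target_selection) / vol
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  n_ref_pairs <- length(ref_selection) * length(frames)
  g <- acc / (n_ref_pairs * shell * rho_target)
  out <- tibble(r = edges[-length(edges)] + bin / 2, g = g)
  attr(out, "rho_target") <- rho_target
  class(out) <- c("rdf_result", class(out))
  out
}

# positions of one named site for all lipids of given molecule ids, one frame,
# molecules re-wrapped whole
.site_positions <- function(co_whole, top, site_name, mol_ids) {
  idx <- which(top$molecule_type == "AOPC" & top$site_name == site_name &
                 top$molecule_id %in% mol_ids)
  if (length(idx) == 0) abort(sprintf("unknown site name '%s'", site_name))
  idx <- idx[order(top$molecule_id[idx])]
  co_whole[idx, , drop = FALSE]
}

# split region tags into the lipid-id sets analysed region by region
.region_sets <- function(traj, tags, regions) {
  if (is.null(tags)) {
    ids <- unique(traj$topology$molecule_id[traj$topology$molecule_type == "AOPC"])
    return(list(all = ids))
  }
  t1 <- if ("epoch" %in% names(tags)) tags[tags$epoch == max(tags$epoch), ] else tags
  sets <- lapply(regions, function(r) sort(t1$molecule_id[t1$region == r]))
  names(sets) <- regions
  sets[vapply(sets, length, 1L) > 0]
}

#' Head-group angle distribution
#'
#' Interior angle at the middle site of a bonded triplet (e.g. N-C25-C24),
#' computed from minimum-image displacement vectors, binned per region and
#' normalized to unit area. The default window is the last 10 ns.
#'
#' @param traj an [md_trajectory()].
#' @param site_triplet character vector of three site names.
#' @param tags optional `epoch_tags`/`region_tags`; when supplied, separate
#'   histograms for the given `regions` are returned, otherwise one histogram
#'   over all lipids.
#' @param regions regions analysed when `tags` is given (buffer excluded by
#'   default, per the analysis convention).
#' @param bin bin width (degrees).
#' @param window analysis window (default last 10 ns).
#' @return A tibble of class `angle_distribution`: `region`, `bin_center`
#'   (deg), `density` (deg^-1).
#' @export
angle_distribution <- function(traj, site_triplet, tags = NULL,
                               regions = c("SR", "LR"), bin = 2, window = 10) {
  stopifnot(length(site_triplet) == 3)
  frames <- window_frames(traj, window)
  sets <- .region_sets(traj, tags, regions)
  top <- traj$topology
  out <- purrr::map(names(sets), function(rg) {
    ids <- sets[[rg]]
    vals <- numeric(0)
    for (f in frames) {
      box <- frame_box(traj, f)
      co <- rewrap_molecules(frame_coords(traj, f), top, box)
      A <- .site_positions(co, top, site_triplet[1], ids)
      B <- .site_positions(co, top, site_triplet[2], ids)
      C <- .site_positions(co, top, site_triplet[3], ids)
      v1 <- A - B
      v2 <- C - B
      cosang <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      vals <- c(vals, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
    }
    h <- new_histogram(vals, bin, 180, normalization = "unit_area")
    tibble(region = rg, bin_left = h$bin_left, bin_center = h$bin_center,
           bin_right = h$bin_right, density = h$density)
  })
  out <- bind_rows(out)
  attr(out, "triplet") <- site_triplet
  class(out) <- c("angle_distribution", class(out))
  out
}

#' Head-group dihedral distribution
#'
#' Signed dihedral of a bonded quadruplet (IUPAC convention, cis = 0, range
#' (-180, 180]), from minimum-image vectors, per region, unit-area
#' normalized. Frames where a bonded triple is collinear (undefined dihedral)
#' are skipped and counted in the `n_degenerate` attribute.
#'
#' @inheritParams angle_distribution
#' @param site_quadruplet character vector of four site names.
#' @param bin bin width (degrees).
#' @return A tibble of class `dihedral_distribution`: `region`, `bin_center`
#'   (deg), `density` (deg^-1); attribute `n_degenerate`.
#' @export
dihedral_distribution <- function(traj, site_quadruplet, tags = NULL,
                                  regions = c("SR", "LR"), bin = 5,
                                  window = 10) {
  stopifnot(length(site_quadruplet) == 4)
  frames <- window_frames(traj, window)
  sets <- .region_sets(traj, tags, regions)
  top <- traj$topology
  n_degenerate <- 0L
  out <- purrr::map(names(sets), function(rg) {
    ids <- sets[[rg]]
    vals <- numeric(0)
    for (f in frames) {
      box <- frame_box(traj, f)
      co <- rewrap_molecules(frame_coords(traj, f), top, box)
      P1 <- .site_positions(co, top, site_quadruplet[1], ids)
      P2 <- .site_positions(co, top, site_quadruplet[2], ids)
      P3 <- .site_positions(co, top, site_quadruplet[3], ids)
      P4 <- .site_positions(co, top, site_quadruplet[4], ids)
      b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
      n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
                  b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
                  b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
      n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
                  b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
                  b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
      nn1 <- sqrt(rowSums(n1^2)); nn2 <- sqrt(rowSums(n2^2))
      degen <- nn1 < 1e-9 | nn2 < 1e-9
      if (any(degen)) n_degenerate <<- n_degenerate + sum(degen)
      b2n <- b2 / sqrt(rowSums(b2^2))
      m1 <- cbind(n1[, 2] * b2n[, 3] - n1[, 3] * b2n[, 2],
                  n1[, 3] * b2n[, 1] - n1[, 1] * b2n[, 3],
                  n1[, 1] * b2n[, 2] - n1[, 2] * b2n[, 1])
      xcomp <- rowSums(n1 * n2)
      ycomp <- rowSums(m1 * n2)
      # IUPAC: atan2 of these components gives cis = 0, trans = 180
      ang <- atan2(ycomp, xcomp) * 180 / pi
      ang <- ifelse(ang <= -180, ang + 360, ang)
      vals <- c(vals, ang[!degen])
    }
    h <- new_histogram(vals, bin, 180, lo = -180, normalization = "unit_area")
    tibble(region = rg, bin_left = h$bin_left, bin_center = h$bin_center,
           bin_right = h$bin_right, density = h$density)
  })
  out <- bind_rows(out)
  attr(out, "quadruplet") <- site_quadruplet
  attr(out, "n_degenerate") <- n_degenerate
  class(out) <- c("dihedral_distribution", class(out))
  out
}
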