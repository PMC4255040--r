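#' SR / buffer / LR classification boundaries
#'
#' Around a nanoparticle of radius `r`, the short-range (SR) region extends to
#' `d_sr = r + 1.5` nm from the nanoparticle center of mass (the 1.5 nm margin
#' reflects the simulations' short-range interaction cutoff), the buffer
#' occupies the next 0.5 nm shell, and everything beyond
#' `d_buf = r + 2.0` nm is long-range (LR). For the 2 nm particle (r = 1 nm)
#' the SR cutoff is therefore 2.5 nm.
#'
#' @param r nanoparticle radius (nm), `> 0`.
#' @param sr_margin SR margin beyond the radius (nm, default 1.5).
#' @param buffer_width buffer shell width (nm, default 0.5).
#' @return A list of class `region_boundaries` with `r`, `d_sr`, `d_buf`.
#' @export
#' @examples
#' region_boundaries(1.0)$d_sr  # 2.5 nm
region_boundaries <- function(r, sr_margin = 1.5, buffer_width = 0.5) {
  if (!is.finite(r) || r <= 0) abort("nanoparticle radius must be > 0")
  if (sr_margin <= 0 || buffer_width <= 0) {
    abort("sr_margin and buffer_width must be > 0")
  }
  structure(list(r = r, d_sr = r + sr_margin, d_buf = r + sr_margin + buffer_width),
            class = "region_boundaries")
}

#' @export
print.region_boundaries <- function(x, ...) {
  cat(sprintf("<region_boundaries> r = %g nm, SR <= %g nm, buffer < %g nm, LR >= %g nm\n",
              x$r, x$d_sr, x$d_buf, x$d_buf))
  invisible(x)
}

#' Classify interacting-leaflet lipids into SR / buffer / LR (single epoch)
#'
#' For each lipid of the interacting leaflet, the 3D minimum-image distance
#' from its head-group N site to the nanoparticle center of mass decides the
#' region: SR for `d <= d_sr`, buffer for `d_sr < d < d_buf`, LR for
#' `d >= d_buf` (ties at the exact boundaries go to the non-buffer region).
#' Lipids of the other leaflet are labelled `OTHER_LEAFLET`. Without a
#' nanoparticle every lipid is LR by convention (reference-system behaviour).
#'
#' @param traj an [md_trajectory()].
#' @param frame frame index evaluated.
#' @param boundaries a [region_boundaries()], or `NULL` when no nanoparticle
#'   is present.
#' @param np_com nanoparticle center of mass; computed from `AU` sites by
#'   default.
#' @param leaflets a [assign_leaflets()] result; computed on `frame` by
#'   default.
#' @return A tibble of class `region_tags` with `molecule_id`, `region`, and
#'   the distance `d_np` (NA for the other leaflet); attributes `boundaries`
#'   and `interacting_leaflet`.
#' @export
classify_lipids <- function(traj, frame = 1, boundaries = NULL, np_com = NULL,
                            leaflets = NULL) {
  top <- traj$topology
  lipid_ids <- unique(top$molecule_id[top$molecule_type == "AOPC"])
  if (length(lipid_ids) == 0) abort("no lipids in topology")
  au <- select_sites(top, molecule_type = "AU")
  has_np <- length(au) > 0 || !is.null(np_com)
  if (!has_np) {
    out <- tibble(molecule_id = lipid_ids, region = "LR", d_np = NA_real_)
    attr(out, "boundaries") <- NULL
    attr(out, "interacting_leaflet") <- NA_character_
    class(out) <- c("region_tags", class(out))
    return(out)
  }
  if (is.null(np_com)) np_com <- center_of_mass(traj, au, frame)
  if (is.null(boundaries)) abort("boundaries required when a nanoparticle is present")
  if (is.null(leaflets)) leaflets <- assign_leaflets(traj, frame, np_com = np_com)
  n_idx <- select_sites(top, molecule_type = "AOPC", site_name = "N")
  n_mols <- top$molecule_id[n_idx]
  missing_n <- setdiff(lipid_ids, n_mols)
  if (length(missing_n) > 0) {
    abort(sprintf("lipid %d has no head-group N site", missing_n[1]))
  }
  box <- frame_box(traj, frame)
  d <- minimum_image_distance(frame_coords(traj, frame)[n_idx, , drop = FALSE],
                              matrix(np_com, 1, 3), box)
  d <- d[match(lipid_ids, n_mols)]
  interacting <- leaflets$interacting[match(lipid_ids, leaflets$molecule_id)]
  region <- ifelse(!interacting, "OTHER_LEAFLET", .region_of(d, boundaries))
  out <- tibble(molecule_id = lipid_ids, region = region,
                d_np = ifelse(interacting, d, NA_real_))
  attr(out, "boundaries") <- boundaries
  attr(out, "interacting_leaflet") <- attr(leaflets, "interacting_leaflet")
  class(out) <- c("region_tags", class(out))
  out
}

#' Tag a trajectory epoch by epoch
#'
#' The trajectory is cut into consecutive epochs of `epoch_length_ns`
#' (default 10 ns, the re-tagging interval). Region boundaries are evaluated
#' on the first frame at or after each epoch start — with the nanoparticle
#' center of mass recomputed there — and tags are held constant within the
#' epoch. A final frame landing exactly on the last epoch's right boundary
#' belongs to that epoch.
#'
#' @param traj an [md_trajectory()].
#' @param boundaries a [region_boundaries()] (or `NULL` for the reference
#'   system without a nanoparticle).
#' @param epoch_length_ns epoch length (ns), `> 0`.
#' @return A tibble of class `epoch_tags`: one row per (epoch, lipid) with
#'   `epoch`, `epoch_start`, `epoch_end`, `molecule_id`, `region`, `d_np`;
#'   attribute `boundaries`.
#' @export
tag_trajectory <- function(traj, boundaries = NULL, epoch_length_ns = 10) {
  if (!is.finite(epoch_length_ns) || epoch_length_ns <= 0) {
    abort("epoch_length_ns must be > 0")
  }
  t0 <- traj$times[1]
  t_end <- traj$times[n_frames(traj)]
  n_epochs <- max(1L, ceiling((t_end - t0) / epoch_length_ns - 1e-9))
  out <- purrr::map(seq_len(n_epochs), function(e) {
    start <- t0 + (e - 1) * epoch_length_ns
    f <- which(traj$times >= start - 1e-9)[1]
    tags <- classify_lipids(traj, frame = f, boundaries = boundaries)
    tibble(epoch = e, epoch_start = start,
           epoch_end = start + epoch_length_ns,
           molecule_id = tags$molecule_id, region = tags$region,
           d_np = tags$d_np)
  })
  out <- bind_rows(out)
  attr(out, "boundaries") <- boundaries
  attr(out, "epoch_length_ns") <- epoch_length_ns
  class(out) <- c("epoch_tags", class(out))
  out
}

#' Per-epoch region counts
#'
#' @param tags an `epoch_tags` (or single-epoch `region_tags`) tibble.
#' @return A tibble with one row per epoch: `epoch`, `n_SR`, `n_BUFFER`,
#'   `n_LR` (interacting-leaflet lipids only; they sum to that leaflet's
#'   lipid count).
#' @export
region_counts <- function(tags) {
  if (!"epoch" %in% names(tags)) tags$epoch <- 1L
  tags |>
    dplyr::filter(.data$region != "OTHER_LEAFLET") |>
    dplyr::count(.data$epoch, .data$region) |>
    tidyr::pivot_wider(names_from = "region", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      for (r in c("SR", "BUFFER", "LR")) if (!r %in% names(d)) d[[r]] <- 0L
      d
    })() |>
    dplyr::transmute(.data$epoch, n_SR = .data$SR, n_BUFFER = .data$BUFFER,
                     n_LR = .data$LR)
}

# region labels for the epoch covering time t
.tags_at_time <- function(tags, t) {
  e <- tags[tags$epoch_start - 1e-9 <= t & t < tags$epoch_end - 1e-9, ]
  if (nrow(e) == 0) e <- tags[tags$epoch == max(tags$epoch), ]
  e
}
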