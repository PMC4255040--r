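#' Assign lipids to leaflets and identify the interacting leaflet
#'
#' Each lipid is assigned to the upper or lower leaflet by the sign of
#' `z_P - z_mid`, where `z_mid` is the median of all phosphorus z coordinates
#' in the frame. A lipid whose P sits exactly at the midplane goes to the
#' upper leaflet (documented tie rule). When a nanoparticle is present, the
#' interacting leaflet is the one whose mean P z is nearer the nanoparticle
#' center of mass along z; an exact tie is broken to the upper leaflet.
#'
#' @param traj an [md_trajectory()].
#' @param frame frame index used for the assignment.
#' @param np_com optional nanoparticle center of mass (length-3, nm). Computed
#'   from the `AU` sites when present and not supplied.
#' @return A tibble of class `leaflet_assignment` with one row per lipid:
#'   `molecule_id`, `leaflet` (`"upper"`/`"lower"`), `interacting` (logical);
#'   attribute `interacting_leaflet` names the leaflet (or `NA` without a
#'   nanoparticle).
#' @export
assign_leaflets <- function(traj, frame = 1, np_com = NULL) {
  top <- traj$topology
  p_idx <- select_sites(top, molecule_type = "AOPC", site_name = "P")
  if (length(p_idx) == 0) abort("no AOPC phosphorus sites in topology")
  co <- frame_coords(traj, frame)
  zP <- co[p_idx, 3]
  z_mid <- median(zP)
  leaflet <- ifelse(zP >= z_mid, "upper", "lower")
  if (length(unique(leaflet)) == 1) {
    abort("monolayer detected: all P sites on one side of the midplane")
  }
  if (is.null(np_com)) {
    au <- select_sites(top, molecule_type = "AU")
    if (length(au) > 0) np_com <- center_of_mass(traj, au, frame)
  }
  interacting_leaflet <- NA_character_
  if (!is.null(np_com)) {
    mean_up <- mean(zP[leaflet == "upper"])
    mean_lo <- mean(zP[leaflet == "lower"])
    d_up <- abs(mean_up - np_com[3])
    d_lo <- abs(mean_lo - np_com[3])
    interacting_leaflet <- if (d_up <= d_lo) "upper" else "lower"
  }
  out <- tibble(
    molecule_id = top$molecule_id[p_idx],
    leaflet = leaflet,
    interacting = !is.na(interacting_leaflet) & leaflet == interacting_leaflet
  )
  attr(out, "interacting_leaflet") <- interacting_leaflet
  class(out) <- c("leaflet_assignment", class(out))
  out
}
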