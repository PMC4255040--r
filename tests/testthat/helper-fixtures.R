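# Independent oracle for the fcc sphere: enumerate integer triples (i, j, k)
# with i + j + k even; scaled by a/2 these are exactly the fcc lattice points.
# Count those with i^2 + j^2 + k^2 <= (2r/a)^2. Implementation-independent of
# build_fcc_sphere(), which assembles the lattice from the 4-atom cubic basis.
fcc_count_oracle <- function(r, a = 0.4078) {
  m <- ceiling(2 * r / a) + 2
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  g <- g[(g$i + g$j + g$k) %% 2 == 0, ]
  sum((g$i^2 + g$j^2 + g$k^2) * (a / 2)^2 <= r^2 + 1e-9)
}

# Minimal single-site-per-molecule trajectory: one molecule per row of each
# frame matrix. `frames` is a list of n x 3 matrices.
point_trajectory <- function(frames, box, times = seq_along(frames) - 1,
                             molecule_type = "TRC", site_name = "T",
                             mass = NULL) {
  n <- nrow(frames[[1]])
  top <- md_topology(1:n, rep(molecule_type, n), rep(site_name, n),
                     mass %||% rep(1, n))
  coords <- array(unlist(frames), dim = c(n, 3, length(frames)))
  md_trajectory(top, coords, times, box)
}

# A rigid rod "lipid" stub with only the sites needed by head-group analyses
# (N and P), pointing down from the given N position.
stub_lipid_frame <- function(n_xy, leaflet_z, box) {
  n_lip <- nrow(n_xy)
  pos <- matrix(0, 2 * n_lip, 3)
  for (i in seq_len(n_lip)) {
    pos[2 * i - 1, ] <- c(n_xy[i, 1], n_xy[i, 2], leaflet_z[i])
    pos[2 * i, ] <- c(n_xy[i, 1], n_xy[i, 2],
                      leaflet_z[i] - 0.1 * sign(leaflet_z[i] - box[3] / 2))
  }
  pos
}

stub_lipid_topology <- function(n_lip) {
  md_topology(rep(seq_len(n_lip), each = 2), rep("AOPC", 2 * n_lip),
              rep(c("N", "P"), n_lip), rep(c(14.0067, 30.9738), n_lip),
              chains = NULL)
}

# small generated bilayer reused across structure tests
small_bilayer <- function(...) {
  args <- utils::modifyList(
    list(n_lipids_per_leaflet = 16, n_frames = 3, dt = 0.1,
         water_number_density = 2, cluster_waters_near_np = 4, seed = 42),
    list(...))
  generate_trajectory(do.call(generator_config, args))
}
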