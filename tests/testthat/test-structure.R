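test_that("density profiles conserve mass and flatten for uniform gases", {
  set.seed(2)
  n <- 2000
  box <- c(4, 4, 5)
  frames <- replicate(3, cbind(runif(n, 0, 4), runif(n, 0, 4), runif(n, 0, 5)),
                      simplify = FALSE)
  tr <- point_trajectory(frames, box, mass = rep(18, n))
  p <- partial_density_profile(tr, 1:n, n_bins = 10, window = NULL)
  expected <- n * 18 * 1.66054 / prod(box)
  expect_equal(mean(p$density), expected, tolerance = 1e-9)
  expect_lt(sd(p$density) / mean(p$density), 0.1)
  # mass conservation: integral x area = total mass
  dz <- p$bin_right[1] - p$bin_left[1]
  expect_equal(sum(p$density) * dz * box[1] * box[2] / 1.66054,
               n * 18, tolerance = 1e-9)
})

test_that("a one-slab point mass lands in a single bin with the exact density", {
  box <- c(2, 2, 10)
  co <- cbind(rep(1, 5), rep(1, 5), rep(5.05, 5))
  tr <- point_trajectory(list(co), box, mass = rep(10, 5))
  p <- partial_density_profile(tr, 1:5, n_bins = 100, window = NULL)
  hot <- which(p$density > 0)
  expect_length(hot, 1)
  expect_equal(p$density[hot], 50 * 1.66054 / (2 * 2 * 0.1), tolerance = 1e-9)
  # number mode
  pn <- partial_density_profile(tr, 1:5, n_bins = 100, window = NULL,
                                mode = "number")
  expect_equal(pn$density[hot], 5 / (2 * 2 * 0.1), tolerance = 1e-9)
})

test_that("generated symmetric bilayers give near-symmetric lipid profiles", {
  sim <- small_bilayer(n_lipids_per_leaflet = 400, n_frames = 1,
                       water_number_density = 0, np_radius = 0,
                       z_fluctuation_sigma = 0, seed = 12)
  sel <- select_sites(sim$trajectory$topology, molecule_type = "AOPC")
  # 30 bins over lz = 8 nm keeps bin edges off the exact N planes, so the
  # mirror comparison measures sampling noise rather than edge roundoff
  p <- partial_density_profile(sim$trajectory, sel, n_bins = 30, window = NULL)
  mid <- attr(p, "box")[3] / 2
  # compare mirrored halves over the occupied region
  occ <- p$density > 0
  flip <- rev(p$density)
  rel <- abs(p$density[occ] - flip[occ]) /
    max(p$density)
  expect_lt(max(rel), 0.05)
})

test_that("2D water maps localize the nanoparticle-adjacent cluster", {
  sim <- small_bilayer(n_lipids_per_leaflet = 16, n_frames = 3,
                       water_number_density = 4, cluster_waters_near_np = 25,
                       np_z_start = 6.4, np_z_end = 6.4, seed = 14)
  m <- density_map_2d(sim$trajectory, window = NULL, bin = 0.2)
  cfg <- sim$truth$config
  # inside the slab (away from the NP) water density is zero; near the NP
  # center the cluster shows up
  slab <- m[m$z > 2.2 & m$z < 5.8, ]
  near <- slab[abs(slab$x - cfg$lx / 2) < 1.7, ]
  far <- slab[abs(slab$x - cfg$lx / 2) >= 1.7, ]
  expect_gt(sum(near$density), 0)
  expect_equal(sum(far$density), 0)
})

test_that("uniform gases give flat 2D maps at the known number density", {
  set.seed(3)
  n <- 5000
  box <- c(3, 3, 3)
  frames <- replicate(2, matrix(runif(n * 3, 0, 3), n, 3), simplify = FALSE)
  tr <- point_trajectory(frames, box, molecule_type = "SOL", site_name = "OW",
                         mass = rep(18, n))
  m <- density_map_2d(tr, window = NULL, bin = 0.5)
  expect_equal(mean(m$density), n / 27, tolerance = 0.02)
  expect_true(all(m$density >= 0))
})

test_that("gold contact distances give exact deltas and the O-before-N ordering", {
  # one gold atom at the origin of a large box; head sites at fixed distances
  b <- 20
  np <- build_fcc_sphere(0.05)  # single atom
  n_lip <- 6
  sites <- aopc_sites()
  top_tbl <- bilayer_topology(n_lip, n_gold = 1)
  k <- nrow(sites)
  co <- matrix(5, nrow(top_tbl), 3)
  # scatter lipids far, then pin O4 at 0.25 nm and N at 0.45 nm from the gold
  gold_row <- n_lip * k + 1
  co[gold_row, ] <- c(10, 10, 10)
  for (i in seq_len(n_lip)) {
    rows <- (i - 1) * k + seq_len(k)
    co[rows, ] <- cbind(runif(k, 0, 3), runif(k, 0, 3), runif(k, 0, 3))
    co[rows[sites$site_name == "O4"], ] <- c(10, 10, 10 - 0.25)
    # N sites spread over 0.45-0.60 nm: a broadened, farther, lower peak
    co[rows[sites$site_name == "N"], ] <- c(10, 10, 10 + 0.45 + (i - 1) * 0.03)
  }
  tr <- md_trajectory(top_tbl, co, 0, c(b, b, b))
  hO <- distance_distribution(tr, c("O4", "O5"), bin = 0.02, window = NULL)
  hN <- distance_distribution(tr, "N", bin = 0.02, window = NULL)
  # every O4 contributes a delta at 0.25 (O5s sit far away beyond the cutoff)
  peakO <- hO$bin_center[which.max(hO$density)]
  peakN <- hN$bin_center[which.max(hN$density)]
  expect_true(hO$bin_left[which.max(hO$density)] <= 0.25 &&
                0.25 <= hO$bin_right[which.max(hO$density)])
  expect_true(peakO < peakN)
  expect_gt(max(hO$density), max(hN$density))
  # all-at-one-distance normalization: height = 1/bin width
  expect_equal(max(hO$density), 1 / 0.02, tolerance = 1e-9)
})

test_that("contact histogram is empty when all sites are beyond the cutoff", {
  n_lip <- 2
  top_tbl <- bilayer_topology(n_lip, n_gold = 1)
  k <- nrow(aopc_sites())
  co <- matrix(2, nrow(top_tbl), 3)
  co[seq_len(n_lip * k), ] <- matrix(runif(n_lip * k * 3, 0, 3),
                                     ncol = 3)
  co[n_lip * k + 1, ] <- c(15, 15, 15)
  tr <- md_trajectory(top_tbl, co, 0, c(30, 30, 30))
  h <- distance_distribution(tr, "N", window = NULL)
  expect_equal(sum(h$count), 0)
  expect_equal(attr(h, "n_contributing"), 0)
})

test_that("rdf is 1 for ideal gases, 0 inside exclusion zones, and 1 at r_max", {
  set.seed(4)
  n <- 700
  box <- c(4, 4, 4)
  frames <- replicate(4, matrix(runif(n * 3, 0, 4), n, 3), simplify = FALSE)
  tr <- point_trajectory(frames, box)
  g <- rdf(tr, 1:350, 351:700, bin = 0.05)
  beyond <- g$g[g$r > 0.15]
  expect_equal(mean(beyond), 1, tolerance = 0.05)
  expect_equal(mean(g$g[g$r > max(g$r) - 0.2]), 1, tolerance = 0.05)

  # hard exclusion: shift target points out of a 0.3 nm shell around refs
  ref <- matrix(2, 1, 3)
  tgt <- matrix(runif(3000, 0, 4), ncol = 3)
  d <- sqrt(rowSums(sweep(tgt, 2, ref[1, ])^2))
  tgt <- tgt[d > 0.3, ]
  co <- rbind(ref, tgt)
  tr2 <- point_trajectory(list(co), box)
  g2 <- rdf(tr2, 1, 2:nrow(co), bin = 0.02)
  expect_true(all(g2$g[g2$r < 0.29] == 0))
  expect_warning(rdf(tr2, 1, 2:nrow(co), r_max = 5), "clipped")
})

test_that("angle distributions hit constructed fixtures exactly", {
  # collinear and right-angle three-site molecules
  top <- md_topology(rep(1:2, each = 3), rep("AOPC", 6),
                     rep(c("N", "C25", "C24"), 2),
                     rep(c(14, 14, 14), 2), chains = NULL)
  co <- rbind(c(1, 1, 3), c(1, 1, 2), c(1, 1, 1),      # collinear: 180
              c(4, 4, 4), c(4, 4, 3), c(5, 4, 3))      # right angle: 90
  tr <- md_trajectory(top, co, 0, c(10, 10, 10))
  a <- angle_distribution(tr, c("N", "C25", "C24"), bin = 2, window = NULL)
  hot <- a$bin_center[a$density > 0]
  expect_length(hot, 2)
  # 90 sits exactly on a bin edge and goes to the right-hand bin (center 91)
  expect_true(any(abs(hot - 179) <= 1) && any(abs(hot - 91) <= 1))
  expect_error(angle_distribution(tr, c("N", "XX", "C24"), window = NULL),
               "unknown site")
})

test_that("generated head geometry gives delta angle/dihedral distributions", {
  sim <- small_bilayer(n_lipids_per_leaflet = 12, n_frames = 2,
                       water_number_density = 0, np_radius = 0, seed = 16)
  a <- angle_distribution(sim$trajectory, c("N", "C25", "C24"), bin = 2,
                          window = NULL)
  expect_equal(sum(a$density > 0), 1)
  expect_true(a$bin_left[a$density > 0] <= 111 &
                111 <= a$bin_right[a$density > 0])
  dh <- dihedral_distribution(sim$trajectory, c("N", "C25", "C24", "O6"),
                              bin = 5, window = NULL)
  expect_equal(sum(dh$density > 0), 1)
  hot <- which(dh$density > 0)
  expect_true(dh$bin_left[hot] <= 180 & dh$bin_right[hot] >= 175)
  bw <- 5
  expect_equal(sum(dh$density) * bw, 1, tolerance = 1e-9)
})

test_that("dihedrals follow the IUPAC sign convention and flip under mirroring", {
  top <- md_topology(rep(1, 4), rep("AOPC", 4), c("N", "C25", "C24", "O6"),
                     rep(14, 4), chains = NULL)
  gauche <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                  c(1.3, 0.5, 0.6))
  tr <- md_trajectory(top, gauche, 0, c(20, 20, 20))
  d1 <- dihedral_distribution(tr, c("N", "C25", "C24", "O6"), bin = 5,
                              window = NULL)
  mirrored <- gauche %*% diag(c(1, 1, -1)) + matrix(rep(c(0, 0, 5), each = 4), 4)
  tr2 <- md_trajectory(top, mirrored, 0, c(20, 20, 20))
  d2 <- dihedral_distribution(tr2, c("N", "C25", "C24", "O6"), bin = 5,
                              window = NULL)
  ang1 <- d1$bin_center[which.max(d1$density)]
  ang2 <- d2$bin_center[which.max(d2$density)]
  expect_equal(ang1, -ang2)
  expect_true(sign(ang1) != sign(ang2))
})

test_that("planar-trans and +60 gauche fixtures measure 180 and +60 degrees", {
  top <- md_topology(rep(1, 4), rep("AOPC", 4), c("N", "C25", "C24", "O6"),
                     rep(14, 4), chains = NULL)
  place <- function(dih) {
    A <- c(0, 1, 5); B <- c(0, 0, 5); C <- c(1, 0, 5)
    D <- npbilayer:::place_next(A, B, C, 0.153, 111, dih)
    rbind(A, B, C, D)
  }
  for (target in c(180, 60, -60)) {
    tr <- md_trajectory(top, place(target), 0, c(20, 20, 20))
    d <- dihedral_distribution(tr, c("N", "C25", "C24", "O6"), bin = 5,
                               window = NULL)
    hot <- which(d$density > 0)
    expect_true(d$bin_left[hot] < target + 1e-9 & target <= d$bin_right[hot] + 1e-9,
                label = sprintf("dihedral %d in its bin", target))
  }
})
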