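test_that("flat bilayers give a delta thickness distribution at h in every cell", {
  sim <- small_bilayer(n_lipids_per_leaflet = 25, lx = 10, ly = 10,
                       area_per_lipid = 2, n_frames = 2,
                       z_fluctuation_sigma = 0, D_lateral = 0,
                       water_number_density = 0, np_radius = 0, seed = 23)
  tf <- grid_thickness(sim$trajectory, grid = c(20, 20), window = NULL)
  expect_equal(as.numeric(tf$cell_means), rep(4, 400), tolerance = 1e-9)
  dist <- tf$distribution
  expect_equal(sum(dist$density > 0), 1)
  hot <- which(dist$density > 0)
  expect_true(dist$bin_left[hot] <= 4 & 4 <= dist$bin_right[hot])
  bw <- dist$bin_right[1] - dist$bin_left[1]
  expect_equal(sum(dist$density) * bw, 1, tolerance = 1e-9)
})

test_that("noisy bilayers recover the configured thickness within 0.02 nm", {
  sim <- small_bilayer(n_lipids_per_leaflet = 100, lx = 10, ly = 10,
                       area_per_lipid = 1, n_frames = 10,
                       z_fluctuation_sigma = 0.1, water_number_density = 0,
                       np_radius = 0, seed = 24)
  tf <- grid_thickness(sim$trajectory, window = NULL)
  expect_equal(tf$mean, 4.0, tolerance = 0.02 / 4)
})

test_that("the LR mask excludes exactly the cells within d_buf of the particle", {
  sim <- small_bilayer(n_lipids_per_leaflet = 25, lx = 10, ly = 10,
                       area_per_lipid = 2, n_frames = 2,
                       water_number_density = 0, seed = 25)
  b <- region_boundaries(1.0)
  tf <- grid_thickness(sim$trajectory, grid = c(20, 20), boundaries = b,
                       window = NULL)
  cells <- tidy(tf)
  np_xy <- c(5, 5)  # particle is centered in xy by construction
  d <- sqrt((cells$cell_x - np_xy[1])^2 + (cells$cell_y - np_xy[2])^2)
  expect_equal(cells$masked, d >= b$d_buf)
  # SR mask is the complementary inner disc
  tf_sr <- grid_thickness(sim$trajectory, grid = c(20, 20), boundaries = b,
                          region = "SR", window = NULL)
  expect_equal(as.logical(tf_sr$mask), d <= b$d_sr)
})

test_that("area per lipid matches hand arithmetic with and without the particle", {
  # no particle: box area over lipids per leaflet
  sim <- small_bilayer(n_lipids_per_leaflet = 50, lx = 10, ly = 10,
                       area_per_lipid = 2, n_frames = 2,
                       water_number_density = 0, np_radius = 0, seed = 26)
  ap <- area_per_lipid_lr(sim$trajectory, window = NULL)
  expect_equal(attr(ap, "mean"), 2.0, tolerance = 1e-12)

  # disc subtraction: (100 - pi 3^2) / n_LR
  simN <- small_bilayer(n_lipids_per_leaflet = 50, lx = 10, ly = 10,
                        area_per_lipid = 2, n_frames = 2, D_lateral = 0,
                        water_number_density = 0, seed = 26)
  b <- region_boundaries(1.0)
  tags <- tag_trajectory(simN$trajectory, b)
  ap2 <- area_per_lipid_lr(simN$trajectory, tags, b, window = NULL)
  n_lr <- region_counts(tags)$n_LR[1]
  expect_equal(attr(ap2, "mean"), (100 - 9 * pi) / n_lr, tolerance = 1e-12)
  expect_true(all(ap2$area_per_lipid > 0))
})

test_that("the fixture arithmetic (100 - 9 pi)/20 is honored for 20 LR lipids", {
  # hand-built: 20 LR lipids in the interacting leaflet of a 10x10 box
  box <- c(10, 10, 10)
  n <- 25
  xy <- cbind(rep(seq(1, 9, length.out = 5), 5),
              rep(seq(1, 9, length.out = 5), each = 5))
  frame <- stub_lipid_frame(rbind(xy, xy), c(rep(7, n), rep(3, n)), box)
  top <- stub_lipid_topology(2 * n)
  tr <- md_trajectory(top, frame, 0, box)
  b <- region_boundaries(1.0)
  # particle over the upper leaflet center: lipids within 3 nm are SR/buffer
  tags <- tag_trajectory(tr, b)
  # classify against a nanoparticle com supplied via classify_lipids
  t1 <- classify_lipids(tr, boundaries = b, np_com = c(5, 5, 8))
  n_lr <- sum(t1$region == "LR")
  fake_tags <- tibble::tibble(epoch = 1, epoch_start = 0, epoch_end = 10,
                              molecule_id = t1$molecule_id, region = t1$region)
  ap <- area_per_lipid_lr(tr, fake_tags, b, window = NULL)
  expect_equal(n_lr, 20)
  expect_equal(attr(ap, "mean"), (100 - 9 * pi) / 20, tolerance = 1e-12)
  expect_equal(attr(ap, "mean"), 3.586, tolerance = 1e-3)
})

test_that("generated area per lipid is recovered exactly without a particle", {
  sim <- small_bilayer(n_lipids_per_leaflet = 32, area_per_lipid = 0.62,
                       lx = NULL, ly = NULL, n_frames = 3,
                       water_number_density = 0, np_radius = 0, seed = 27)
  ap <- area_per_lipid_lr(sim$trajectory, window = NULL)
  expect_equal(attr(ap, "mean"), sim$truth$area_per_lipid, tolerance = 1e-12)
  expect_equal(attr(ap, "mean"), 0.62, tolerance = 1e-9)
})

test_that("degenerate inputs raise explicit errors", {
  sim <- small_bilayer(n_lipids_per_leaflet = 4, n_frames = 2,
                       water_number_density = 0, seed = 28)
  b <- region_boundaries(1.0)
  # every interacting lipid inside the buffer: no LR lipids anywhere
  fake <- tibble::tibble(epoch = 1, epoch_start = 0, epoch_end = 10,
                         molecule_id = unique(sim$trajectory$topology$molecule_id[
                           sim$trajectory$topology$molecule_type == "AOPC"]),
                         region = "SR")
  expect_error(area_per_lipid_lr(sim$trajectory, fake, b, window = NULL),
               "no LR lipids")
})
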