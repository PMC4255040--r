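test_that("GRO files round-trip coordinates to format precision and preserve ordering", {
  sim <- small_bilayer(seed = 9, n_lipids_per_leaflet = 4)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(sim$trajectory, path)
  back <- read_gro(path)
  expect_equal(back$coords, round(sim$trajectory$coords, 3), tolerance = 1e-12)
  expect_identical(back$topology$site_name, sim$trajectory$topology$site_name)
  expect_identical(back$topology$molecule_id, sim$trajectory$topology$molecule_id)
  expect_equal(back$times, sim$trajectory$times)
  expect_equal(back$boxes, round(sim$trajectory$boxes, 5), ignore_attr = TRUE)
})

test_that("a minimal hand-written GRO parses and malformed files are rejected", {
  path <- withr::local_tempfile(fileext = ".gro")
  atom <- function(i, x, y, z) {
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", i, "SOL", "OW", i, x, y, z)
  }
  writeLines(c(
    "three atoms t= 0.0",
    "    3",
    atom(1, 0.1, 0.2, 0.3), atom(2, 0.4, 0.5, 0.6), atom(3, 0.7, 0.8, 0.9),
    "   1.00000   1.00000   1.00000"), path)
  tr <- read_gro(path)
  expect_equal(n_frames(tr), 1)
  expect_equal(n_sites(tr), 3)
  expect_equal(frame_coords(tr, 1)[2, ], c(0.4, 0.5, 0.6))
  expect_equal(frame_box(tr, 1), c(1, 1, 1))

  # header promises 5 atoms, only 4 present: the box line is consumed as an
  # atom line and the frame is truncated
  bad <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "bad", "    5",
    atom(1, 0.1, 0.2, 0.3), atom(2, 0.4, 0.5, 0.6),
    atom(3, 0.7, 0.8, 0.9), atom(4, 0.7, 0.8, 0.9),
    "   1.00000   1.00000   1.00000"), bad)
  expect_error(read_gro(bad), "line")

  nobox <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("nobox", "    1", atom(1, 0.1, 0.2, 0.3)), nobox)
  expect_error(read_gro(nobox), "box")

  tric <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "triclinic", "    1", atom(1, 0.1, 0.2, 0.3),
    "   1.0 1.0 1.0 0.0 0.0 0.5 0.0 0.0 0.0"), tric)
  expect_error(read_gro(tric), "triclinic")

  expect_error(read_trajectory("foo.xtc"), "not supported")
})

test_that("minimum-image displacement wraps into [-L/2, L/2)", {
  box <- c(1, 1, 1)
  expect_equal(minimum_image_vector(c(0, 0, 0), c(0.9, 0, 0), box),
               c(-0.1, 0, 0))
  expect_equal(minimum_image_vector(c(0.3, 0.3, 0.3), c(0.3, 0.3, 0.3), box),
               c(0, 0, 0))
  expect_equal(minimum_image_vector(c(0, 0, 0), c(0.4, 0.4, 0.4), box),
               c(0.4, 0.4, 0.4))
  # property: norm never exceeds half the box diagonal
  set.seed(1)
  for (i in 1:50) {
    bx <- runif(3, 0.5, 5)
    a <- runif(3, -10, 10); b <- runif(3, -10, 10)
    d <- minimum_image_vector(a, b, bx)
    expect_true(all(abs(d) <= bx / 2 + 1e-12))
  }
})

test_that("center of mass handles straddling molecules by periodic re-wrap", {
  top <- md_topology(c(1, 1), c("TRC", "TRC"), c("T1", "T2"), c(1, 1))
  tr <- md_trajectory(top, rbind(c(0, 0, 0), c(1, 0, 0)), 0, c(100, 100, 100))
  expect_equal(center_of_mass(tr, 1:2), c(0.5, 0, 0))
  expect_equal(center_of_mass(tr, 1), c(0, 0, 0))
  # two sites straddling the boundary of a 1 nm box: CoM at the boundary,
  # not in the middle of the box
  tr2 <- md_trajectory(top, rbind(c(0.05, 0, 0), c(0.95, 0, 0)), 0, c(1, 1, 1))
  expect_equal(center_of_mass(tr2, 1:2), c(0, 0, 0), tolerance = 1e-12)
  expect_error(center_of_mass(tr, integer(0)), "empty")
})

test_that("leaflet assignment partitions lipids and finds the interacting side", {
  box <- c(5, 5, 10)
  n_xy <- cbind(runif(4, 0, 5), runif(4, 0, 5))
  frame <- stub_lipid_frame(n_xy, c(6, 6, 4, 4), box)
  top <- stub_lipid_topology(4)
  tr <- md_trajectory(top, frame, 0, box)
  lf <- assign_leaflets(tr, np_com = c(2.5, 2.5, 7))
  expect_setequal(lf$molecule_id, 1:4)
  expect_equal(lf$leaflet, c("upper", "upper", "lower", "lower"))
  expect_equal(attr(lf, "interacting_leaflet"), "upper")
  expect_true(all(table(lf$molecule_id) == 1))  # partition: one label each

  # NP exactly at the midplane: tie broken to upper
  lf_tie <- assign_leaflets(tr, np_com = c(2.5, 2.5, 5))
  expect_equal(attr(lf_tie, "interacting_leaflet"), "upper")

  mono <- md_trajectory(top, stub_lipid_frame(n_xy, c(6, 6, 6, 6), box), 0, box)
  expect_error(assign_leaflets(mono, np_com = c(0, 0, 7)), "monolayer")
})

test_that("leaflet assignment matches generator ground truth", {
  sim <- small_bilayer(seed = 21)
  lf <- assign_leaflets(sim$trajectory)
  truth <- sim$truth$lipids
  expect_equal(lf$leaflet[match(truth$molecule_id, lf$molecule_id)],
               truth$leaflet)
  expect_equal(attr(lf, "interacting_leaflet"), sim$truth$interacting_leaflet)
})

test_that("topology manifests round-trip through JSON", {
  top <- bilayer_topology(2, n_gold = 3, n_waters = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_topology(top, path)
  back <- read_topology(path)
  expect_equal(back$site_name, top$site_name)
  expect_equal(back$mass, top$mass)
  expect_equal(attr(back, "chains")$sn1, attr(top, "chains")$sn1)
})

test_that("AOPC topology has 56 united atoms with the documented chains", {
  sites <- aopc_sites()
  expect_equal(nrow(sites), 56)
  ch <- aopc_chains()
  expect_length(ch$sn1, 20)
  expect_length(ch$sn2, 18)
  expect_equal(ch$unsaturated, c("C37", "C38"))
  expect_true(all(c(ch$sn1, ch$sn2) %in% sites$site_name))
  # Table 1 arithmetic relies on 56 sites/lipid
  expect_equal(128 * nrow(sites), 7168)
})
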