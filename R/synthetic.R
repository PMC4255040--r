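# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Closed-form -S_CD of a rigid all-trans chain at a given tilt
#'
#' For an azimuthally symmetric rigid all-trans chain whose axis makes angle
#' theta with the bilayer normal, the deuterium order parameter is
#' `-S_CD = (3 <cos^2 theta> - 1) / 4`: 0.5 for a chain along the normal,
#' 0 for isotropic orientations (`<cos^2> = 1/3`). Used as the analytic anchor
#' for parameter-recovery tests of [order_parameter_scd()].
#'
#' @param mean_cos2_tilt `<cos^2 theta>` of the chain axis, in `[1/3, 1]`.
#' @return The expected `-S_CD`.
#' @export
expected_scd <- function(mean_cos2_tilt) {
  if (any(!is.finite(mean_cos2_tilt)) ||
      any(mean_cos2_tilt < 1 / 3 - 1e-12) || any(mean_cos2_tilt > 1 + 1e-12)) {
    abort("mean_cos2_tilt must lie in [1/3, 1]")
  }
  (3 * mean_cos2_tilt - 1) / 4
}

#' Configuration for the synthetic bilayer generator
#'
#' The generator is kinematic, not a physics engine: every observable (tilt
#' order, gauche fraction, leaflet separation, area per lipid, lateral
#' diffusion) is imposed by construction, which is what makes parameter
#' recovery a valid oracle for the analysis code. Region-dependent parameters
#' are named vectors over `SR`, `BUFFER`, `LR`; non-interacting-leaflet lipids
#' use the `LR` values.
#'
#' Defaults emulate a fluid AOPC bilayer with a 2 nm gold nanoparticle resting
#' on the upper leaflet: 64 lipids per leaflet, area per lipid 0.62 nm^2,
#' N-to-N leaflet separation 4 nm, lateral diffusion 0.0098 (SR) to
#' 0.0142 (LR) nm^2/ns (the measured order of magnitude for SR/LR lipids),
#' SPC-like water number density 33.4 nm^-3.
#'
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param area_per_lipid target area per lipid (nm^2); with `lx`/`ly` `NULL`
#'   the box is sized so the realized area per lipid equals it exactly.
#' @param lx,ly box edges (nm); default `sqrt(n * area_per_lipid)`.
#' @param leaflet_separation N-to-N distance h between leaflets (nm).
#' @param lz box height (nm); default `h + 2 * water_slab`.
#' @param water_slab water slab thickness on each side of the bilayer (nm).
#' @param tilt_mean_cos2 named vector, `<cos^2 theta>` of the chain axis per
#'   region, each in `[1/3, 1]`.
#' @param gauche_probability named vector, probability a tail dihedral is
#'   gauche (+/-60 deg) instead of trans, per region.
#' @param D_lateral named vector, lateral diffusion constant per region
#'   (nm^2/ns).
#' @param z_fluctuation_sigma stationary standard deviation of the per-lipid
#'   vertical Ornstein-Uhlenbeck fluctuation (nm).
#' @param z_relaxation_ns OU relaxation time (ns).
#' @param np_radius nanoparticle radius (nm); 0 disables the nanoparticle.
#' @param np_lattice_constant fcc lattice constant (nm).
#' @param np_z_start,np_z_end nanoparticle center z at the first and last
#'   frame (linear path); defaults rest the particle on the upper leaflet and
#'   sink it half a radius.
#' @param water_number_density bulk water number density (nm^-3); single-site
#'   waters (OW, mass 18.0154 u) since all water observables use the oxygen.
#' @param cluster_waters_near_np waters placed within 0.5 nm of the
#'   nanoparticle surface inside the bilayer slab (they ride with the
#'   particle), emulating the penetrating cluster.
#' @param dt frame spacing (ns).
#' @param n_frames number of frames.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_lipids_per_leaflet = 64,
                             area_per_lipid = 0.62,
                             lx = NULL, ly = NULL,
                             leaflet_separation = 4.0,
                             lz = NULL, water_slab = 2.0,
                             tilt_mean_cos2 = c(SR = 0.45, BUFFER = 0.55, LR = 0.62),
                             gauche_probability = c(SR = 0.25, BUFFER = 0.20, LR = 0.15),
                             D_lateral = c(SR = 0.0098, BUFFER = 0.012, LR = 0.0142),
                             z_fluctuation_sigma = 0.05,
                             z_relaxation_ns = 1.0,
                             np_radius = 1.0,
                             np_lattice_constant = 0.4078,
                             np_z_start = NULL, np_z_end = NULL,
                             water_number_density = 33.4,
                             cluster_waters_near_np = 30,
                             dt = 0.1, n_frames = 101, seed = 1) {
  if (is.null(lx)) lx <- sqrt(n_lipids_per_leaflet * area_per_lipid)
  if (is.null(ly)) ly <- sqrt(n_lipids_per_leaflet * area_per_lipid)
  if (is.null(lz)) lz <- leaflet_separation + 2 * water_slab
  reg <- c("SR", "BUFFER", "LR")
  fill_regions <- function(x) {
    if (length(x) == 1) x <- setNames(rep(x, 3), reg)
    if (is.null(names(x))) names(x) <- reg
    x[reg]
  }
  tilt_mean_cos2 <- fill_regions(tilt_mean_cos2)
  gauche_probability <- fill_regions(gauche_probability)
  D_lateral <- fill_regions(D_lateral)
  if (any(tilt_mean_cos2 < 1 / 3 - 1e-12 | tilt_mean_cos2 > 1 + 1e-12)) {
    abort("tilt_mean_cos2 entries must lie in [1/3, 1]")
  }
  if (any(c(gauche_probability, D_lateral, z_fluctuation_sigma, np_radius,
            water_number_density, cluster_waters_near_np) < 0)) {
    abort("rates and sizes must be >= 0")
  }
  if (n_lipids_per_leaflet * area_per_lipid > lx * ly + 1e-9) {
    abort("area_per_lipid * n_lipids_per_leaflet exceeds the box area")
  }
  if (np_radius > 0) {
    if (is.null(np_z_start)) np_z_start <- lz / 2 + leaflet_separation / 2 + np_radius / 2
    if (is.null(np_z_end)) np_z_end <- lz / 2 + leaflet_separation / 2 - np_radius / 2
  }
  structure(list(
    n_lipids_per_leaflet = n_lipids_per_leaflet, area_per_lipid = area_per_lipid,
    lx = lx, ly = ly, lz = lz, leaflet_separation = leaflet_separation,
    water_slab = water_slab, tilt_mean_cos2 = tilt_mean_cos2,
    gauche_probability = gauche_probability, D_lateral = D_lateral,
    z_fluctuation_sigma = z_fluctuation_sigma, z_relaxation_ns = z_relaxation_ns,
    np_radius = np_radius, np_lattice_constant = np_lattice_constant,
    np_z_start = np_z_start, np_z_end = np_z_end,
    water_number_density = water_number_density,
    cluster_waters_near_np = cluster_waters_near_np,
    dt = dt, n_frames = n_frames, seed = seed
  ), class = "generator_config")
}

# --- internal geometry -------------------------------------------------------

# Place atom D given A-B-C with bond |CD|, angle B-C-D (deg) and dihedral
# A-B-C-D (deg, IUPAC: cis = 0). Standard NeRF construction.
place_next <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) abort("collinear reference atoms in internal-coordinate build")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), -bond * sin(ang) * sin(dih))
  C + d[1] * bc + d[2] * m + d[3] * n
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C_ <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(
    c_ + x * x * C_, x * y * C_ - z * s_, x * z * C_ + y * s_,
    y * x * C_ + z * s_, c_ + y * y * C_, y * z * C_ - x * s_,
    z * x * C_ - y * s_, z * y * C_ + x * s_, c_ + z * z * C_
  ), 3, 3, byrow = TRUE)
}

# Grow an n-carbon chain from three seed atoms: bond 0.153 nm, angle 111 deg,
# dihedrals trans with probability 1 - gauche_p, else +/-60 deg.
grow_chain <- function(n_carbons, gauche_p, seed_atoms) {
  pts <- matrix(0, n_carbons, 3)
  prev <- seed_atoms
  for (i in seq_len(n_carbons)) {
    dih <- if (i <= 2) 180 else {
      if (stats::runif(1) < gauche_p) sample(c(-60, 60), 1) else 180
    }
    p <- place_next(prev[1, ], prev[2, ], prev[3, ], 0.153, 111, dih)
    pts[i, ] <- p
    prev <- rbind(prev[2, ], prev[3, ], p)
  }
  pts
}

#' Generate one lipid conformation
#'
#' Builds the 56 united-atom sites of one AOPC lipid in a local frame with the
#' head-group N at the origin and the tails pointing toward negative z (upper
#' leaflet convention). The head group uses a fixed internal geometry (bonds
#' 0.143-0.161 nm, all backbone angles 111 deg, backbone dihedrals trans), so
#' head-group angle and dihedral distributions on generated data are delta
#' functions at known values. Each tail is grown with bond 0.153 nm, angle
#' 111 deg and trans/gauche dihedrals, then rigidly rotated so its axis makes
#' angle `theta = acos(sqrt(tilt_mean_cos2[region]))` with the normal, with
#' uniform azimuth and uniform roll about the chain axis. The fixed tilt makes
#' the population `<cos^2 theta>` equal the configured value exactly; the
#' random roll supplies the azimuthal averaging the closed form
#' [expected_scd()] assumes.
#'
#' @param config a [generator_config()].
#' @param region `"SR"`, `"BUFFER"` or `"LR"`; selects tilt and gauche values.
#' @return A 56 x 3 matrix (nm) of site positions in [aopc_sites()] order.
#' @export
generate_lipid_conformation <- function(config, region = "LR") {
  tilt_c2 <- config$tilt_mean_cos2[[region]]
  gauche_p <- config$gauche_probability[[region]]
  pos <- list()
  # backbone down the -z axis, zigzag in the xz plane
  pos$N <- c(0, 0, 0)
  # virtual previous atom to seed the chain above N
  virt <- c(0.1, 0, 0.1)
  chain_names <- c("C25", "C24", "O6", "P", "O3", "C23", "C22", "C21")
  bonds <- c(0.147, 0.153, 0.143, 0.161, 0.161, 0.143, 0.153, 0.153)
  # first placement: straight down from N
  p1 <- pos$N + c(0, 0, -bonds[1])
  pos[[chain_names[1]]] <- p1
  prev <- rbind(virt, pos$N, p1)
  for (i in 2:length(chain_names)) {
    p <- place_next(prev[1, ], prev[2, ], prev[3, ], bonds[i], 111, 180)
    pos[[chain_names[i]]] <- p
    prev <- rbind(prev[2, ], prev[3, ], p)
  }
  # N-methyls: three tetrahedral directions with +z component
  for (k in 1:3) {
    phi <- 2 * pi * (k - 1) / 3
    dirv <- c(sin(1.2) * cos(phi), sin(1.2) * sin(phi), cos(1.2))
    pos[[paste0("CN", k)]] <- pos$N + 0.147 * dirv
  }
  # phosphate non-ester oxygens, off the backbone plane at P
  pos$O4 <- place_next(pos$C24, pos$O6, pos$P, 0.148, 109.5, 60)
  pos$O5 <- place_next(pos$C24, pos$O6, pos$P, 0.148, 109.5, -60)
  # sn2 ester on C22, sn1 ester on C21
  pos$O7 <- place_next(pos$O3, pos$C23, pos$C22, 0.143, 109.5, -90)
  pos$O1 <- place_next(pos$C23, pos$C22, pos$C21, 0.143, 111, 180)
  tails <- list()
  for (tail in c("sn1", "sn2")) {
    n_c <- if (tail == "sn1") 20 else 18
    est <- if (tail == "sn1") pos$O1 else pos$O7
    # grow in a canonical frame; the chain is re-oriented afterwards, so the
    # seed stub only needs to be non-collinear
    carbons <- grow_chain(n_c, gauche_p,
                          rbind(c(0.5, 0, 0.3), c(0.15, 0, 0.1), c(0, 0, 0)))
    # align the chain axis with -z; the axis is the local repeat vector
    # C3 - C1 (for an all-trans chain this equals every C(i+1) - C(i-1), so
    # the scored segment vectors are exactly along the normal at zero tilt)
    axis <- carbons[3, ] - carbons[1, ]
    axis <- axis / sqrt(sum(axis^2))
    target <- c(0, 0, -1)
    v <- c(axis[2] * target[3] - axis[3] * target[2],
           axis[3] * target[1] - axis[1] * target[3],
           axis[1] * target[2] - axis[2] * target[1])
    s <- sqrt(sum(v^2)); cthe <- sum(axis * target)
    R0 <- if (s < 1e-12) diag(3) * sign(cthe) else rotation_matrix(v, atan2(s, cthe))
    local <- sweep(carbons, 2, carbons[1, ])
    local <- local %*% t(R0)
    # roll about the chain axis, then tilt by theta at uniform azimuth
    roll <- rotation_matrix(c(0, 0, 1), stats::runif(1, 0, 2 * pi))
    theta <- acos(sqrt(tilt_c2))
    phi <- stats::runif(1, 0, 2 * pi)
    tiltR <- rotation_matrix(c(cos(phi), sin(phi), 0), theta)
    local <- local %*% t(roll) %*% t(tiltR)
    tails[[tail]] <- sweep(local, 2, est + c(0, 0, -0.05), "+")
  }
  sn1_names <- paste0("C", 1:20)
  sn2_names <- paste0("C", 29:46)
  for (i in seq_along(sn1_names)) pos[[sn1_names[i]]] <- tails$sn1[i, ]
  for (i in seq_along(sn2_names)) pos[[sn2_names[i]]] <- tails$sn2[i, ]
  # carbonyl oxygens off the first tail carbons
  pos$O2 <- pos$C1 + c(0.09, 0.09, 0.03)
  pos$O8 <- pos$C29 + c(-0.09, 0.09, 0.03)
  nm <- aopc_sites()$site_name
  out <- do.call(rbind, pos[nm])
  rownames(out) <- NULL
  out
}

# region of a point at 3D distance d from the NP center, given boundaries
.region_of <- function(d, b) {
  ifelse(d <= b$d_sr, "SR", ifelse(d < b$d_buf, "BUFFER", "LR"))
}

#' Generate a synthetic bilayer + nanoparticle + water trajectory
#'
#' Lipids are placed on a jittered rectangular grid filling the box (realized
#' area per lipid `lx*ly / n_lipids_per_leaflet`), two leaflets with head-group
#' N planes separated by `leaflet_separation`, bilayer midplane at `lz/2`.
#' Regions are imposed geometrically at t = 0 from the 3D N-to-nanoparticle
#' distance using the SR/buffer/LR boundaries; each lipid then performs a rigid
#' lateral random walk with per-axis step variance `2 D(region) dt` and a
#' vertical Ornstein-Uhlenbeck fluctuation. The nanoparticle is a rigid fcc
#' sphere following a linear z path at the box center in xy. Waters are single
#' OW sites, uniform outside the bilayer slab, plus a cluster riding within
#' 0.5 nm of the nanoparticle surface inside the slab. All imposed observables
#' are recorded in the returned ground truth.
#'
#' @param config a [generator_config()].
#' @return A list with elements `trajectory` ([md_trajectory()]) and `truth`
#'   (class `ground_truth`: per-region `-S_CD` from [expected_scd()], true
#'   `D_lateral`, thickness, area per lipid, per-lipid leaflet and initial
#'   region, nanoparticle path, config echo).
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_lipids_per_leaflet
    lx <- config$lx; ly <- config$ly; lz <- config$lz
    h <- config$leaflet_separation
    # lipid anchors on a jittered grid
    nx <- max(1L, round(sqrt(n * lx / ly)))
    ny <- ceiling(n / nx)
    gx <- (rep(seq_len(nx), times = ny)[seq_len(n)] - 0.5) * (lx / nx)
    gy <- (rep(seq_len(ny), each = nx)[seq_len(n)] - 0.5) * (ly / ny)
    jit <- 0.04 * min(lx / nx, ly / ny)
    anchors <- cbind(
      x = c(gx, gx) + stats::runif(2 * n, -jit, jit),
      y = c(gy, gy) + stats::runif(2 * n, -jit, jit)
    )
    leaflet <- rep(c("upper", "lower"), each = n)
    nz <- ifelse(leaflet == "upper", lz / 2 + h / 2, lz / 2 - h / 2)
    has_np <- config$np_radius > 0
    np <- if (has_np) build_fcc_sphere(config$np_radius, config$np_lattice_constant)
    np_center0 <- if (has_np) c(lx / 2, ly / 2, config$np_z_start)
    b <- if (has_np) region_boundaries(config$np_radius)
    region <- rep("LR", 2 * n)
    if (has_np) {
      dN <- sqrt((anchors[, 1] - np_center0[1])^2 +
                   (anchors[, 2] - np_center0[2])^2 +
                   (nz - np_center0[3])^2)
      region[leaflet == "upper"] <- .region_of(dN[leaflet == "upper"], b)
    }
    # conformations: region parameters for the interacting (upper) leaflet,
    # LR parameters elsewhere
    conf_region <- ifelse(leaflet == "upper", region, "LR")
    lipids <- lapply(seq_len(2 * n), function(i) {
      loc <- generate_lipid_conformation(config, conf_region[i])
      if (leaflet[i] == "lower") loc[, 3] <- -loc[, 3]
      sweep(loc, 2, c(anchors[i, 1], anchors[i, 2], nz[i]), "+")
    })
    k <- nrow(lipids[[1]])
    base_lipids <- do.call(rbind, lipids)
    # waters outside the slab, avoiding the nanoparticle start position
    slab_lo <- lz / 2 - h / 2
    slab_hi <- lz / 2 + h / 2
    vol_w <- lx * ly * (lz - (slab_hi - slab_lo))
    n_w <- round(config$water_number_density * vol_w)
    waters <- NULL
    if (n_w > 0) {
      zs <- stats::runif(n_w, 0, lz - (slab_hi - slab_lo))
      wz <- ifelse(zs < slab_lo, zs, zs + (slab_hi - slab_lo))
      waters <- cbind(stats::runif(n_w, 0, lx), stats::runif(n_w, 0, ly), wz)
      if (has_np) {
        dd <- sqrt(rowSums(sweep(waters, 2, np_center0)^2))
        clash <- dd < config$np_radius + 0.15
        while (any(clash)) {
          m <- sum(clash)
          zs <- stats::runif(m, 0, lz - (slab_hi - slab_lo))
          wz <- ifelse(zs < slab_lo, zs, zs + (slab_hi - slab_lo))
          waters[clash, ] <- cbind(stats::runif(m, 0, lx),
                                   stats::runif(m, 0, ly), wz)
          dd <- sqrt(rowSums(sweep(waters, 2, np_center0)^2))
          clash <- dd < config$np_radius + 0.15
        }
      }
    }
    # cluster waters: fixed offsets from the NP center, inside the slab
    n_cl <- if (has_np) config$cluster_waters_near_np else 0
    cluster_off <- NULL
    if (n_cl > 0) {
      cluster_off <- matrix(0, n_cl, 3)
      for (i in seq_len(n_cl)) {
        repeat {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          if (u[3] > 0) u[3] <- -u[3]  # bias toward the bilayer side
          off <- u * (config$np_radius + stats::runif(1, 0.05, 0.5))
          zc <- np_center0[3] + off[3]
          if (zc > slab_lo && zc < slab_hi) break
        }
        cluster_off[i, ] <- off
      }
    }
    n_gold <- if (has_np) nrow(np$coords) else 0
    topology <- bilayer_topology(2 * n, n_gold, n_w + n_cl)
    nf <- config$n_frames
    dt <- config$dt
    times <- (seq_len(nf) - 1) * dt
    # lateral random walk per lipid (cumulative), OU vertical fluctuation
    Dlip <- config$D_lateral[conf_region]
    Dlip[leaflet == "lower"] <- config$D_lateral[["LR"]]
    step_sd <- sqrt(2 * Dlip * dt)
    dx <- matrix(0, 2 * n, nf); dy <- matrix(0, 2 * n, nf); dz <- matrix(0, 2 * n, nf)
    sig <- config$z_fluctuation_sigma
    if (sig > 0) dz[, 1] <- stats::rnorm(2 * n, 0, sig)
    rho <- exp(-dt / config$z_relaxation_ns)
    ou_sd <- sig * sqrt(1 - rho^2)
    for (f in 2:max(2, nf)) {
      if (f > nf) break
      dx[, f] <- dx[, f - 1] + stats::rnorm(2 * n, 0, step_sd)
      dy[, f] <- dy[, f - 1] + stats::rnorm(2 * n, 0, step_sd)
      dz[, f] <- dz[, f - 1] * rho + if (sig > 0) stats::rnorm(2 * n, 0, ou_sd) else 0
    }
    np_z <- if (has_np) {
      if (nf == 1) config$np_z_start else
        config$np_z_start + (config$np_z_end - config$np_z_start) *
        (times - times[1]) / (times[nf] - times[1])
    }
    n_sites_tot <- nrow(topology)
    coords <- array(0, dim = c(n_sites_tot, 3, nf))
    lip_rows <- seq_len(2 * n * k)
    row_lip <- rep(seq_len(2 * n), each = k)
    for (f in seq_len(nf)) {
      fr <- matrix(0, n_sites_tot, 3)
      fr[lip_rows, ] <- base_lipids +
        cbind(dx[row_lip, f], dy[row_lip, f], dz[row_lip, f])
      at <- 2 * n * k
      if (has_np) {
        npc <- c(lx / 2, ly / 2, np_z[f])
        fr[at + seq_len(n_gold), ] <- sweep(np$coords, 2, npc, "+")
        at <- at + n_gold
      }
      if (n_w > 0) {
        fr[at + seq_len(n_w), ] <- waters
        at <- at + n_w
      }
      if (n_cl > 0) {
        fr[at + seq_len(n_cl), ] <- sweep(cluster_off, 2,
                                          c(lx / 2, ly / 2, np_z[f]), "+")
      }
      coords[, , f] <- wrap_coords(fr, c(lx, ly, lz))
    }
    traj <- md_trajectory(topology, coords, times, c(lx, ly, lz))
    truth <- structure(list(
      scd = expected_scd(config$tilt_mean_cos2),
      D_lateral = config$D_lateral,
      thickness = h,
      area_per_lipid = lx * ly / n,
      lipids = tibble(molecule_id = seq_len(2 * n), leaflet = leaflet,
                      region = ifelse(leaflet == "upper", region,
                                      "OTHER_LEAFLET")),
      interacting_leaflet = if (has_np) "upper" else NA_character_,
      np_radius = config$np_radius,
      np_path = if (has_np) c(start = config$np_z_start, end = config$np_z_end),
      cluster_waters = n_cl,
      config = unclass(config)
    ), class = "ground_truth")
    list(trajectory = traj, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat("  -S_CD:", paste(sprintf("%s=%.4f", names(x$scd), x$scd), collapse = ", "), "\n")
  cat("  D_lateral (nm^2/ns):",
      paste(sprintf("%s=%.4g", names(x$D_lateral), x$D_lateral), collapse = ", "), "\n")
  cat(sprintf("  thickness %.3f nm, area per lipid %.4f nm^2\n",
              x$thickness, x$area_per_lipid))
  invisible(x)
}

#' Serialize ground truth as JSON
#' @param truth a `ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- unclass(truth)
  obj$lipids <- as.data.frame(obj$lipids)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate independent Brownian point tracers
#'
#' Pure Gaussian random walks with per-axis step variance `2 D dt`, the
#' validation fixture for the Einstein-relation pipeline ([msd()] +
#' [diffusion_coefficient()]). In `"lateral"` mode the walk is two-dimensional
#' (z fixed); `"full"` walks all three axes.
#'
#' @param D diffusion constant (nm^2/ns), `>= 0`.
#' @param n_tracers number of tracers.
#' @param dt frame spacing (ns).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param mode `"lateral"` (2D walk) or `"full"` (3D).
#' @param box optional length-3 box (nm); when supplied, coordinates are
#'   wrapped into it (exercising [unwrap_positions()]); otherwise a box large
#'   enough that no wrapping occurs is used.
#' @return An [md_trajectory()] of single-site `TRC` molecules.
#' @export
generate_brownian_tracers <- function(D, n_tracers, dt, n_frames, seed = 1,
                                      mode = c("lateral", "full"), box = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(D) || D < 0) abort("D must be >= 0")
  with_seed(seed, {
    sd_step <- sqrt(2 * D * dt)
    dims <- if (mode == "lateral") 1:2 else 1:3
    coords <- array(0, dim = c(n_tracers, 3, n_frames))
    start <- matrix(stats::runif(n_tracers * 3, 0, 1), n_tracers, 3)
    coords[, , 1] <- start
    if (n_frames > 1) {
      for (f in 2:n_frames) {
        step <- matrix(0, n_tracers, 3)
        step[, dims] <- stats::rnorm(n_tracers * length(dims), 0, sd_step)
        coords[, , f] <- coords[, , f - 1] + step
      }
    }
    if (is.null(box)) {
      span <- max(abs(coords)) + 1
      box <- c(span * 2, span * 2, span * 2)
      offset <- span
      coords <- coords + offset
    } else {
      for (f in seq_len(n_frames)) coords[, , f] <- wrap_coords(coords[, , f], box)
    }
    top <- md_topology(seq_len(n_tracers), rep("TRC", n_tracers),
                       rep("T", n_tracers), rep(1, n_tracers))
    md_trajectory(top, coords, (seq_len(n_frames) - 1) * dt, box)
  })
}
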