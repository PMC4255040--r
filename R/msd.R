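#' Mean square displacement of tagged lipid subsets
#'
#' The analysis window (default the last 20 ns) is cut into consecutive
#' non-overlapping intervals of `interval` ns (default 2 ns). Within each
#' interval, displacements are measured from the interval's first frame;
#' MSD(lag) is averaged over intervals and over the molecules whose region tag
#' is constant across the interval. Positions are molecule centers of mass
#' from unwrapped coordinates (`position = "N"` uses the head-group N site
#' instead); `"lateral"` uses (x, y), `"normal"` z, `"full"` all three.
#' Leaflet center-of-mass motion is not removed by default;
#' `remove_drift = TRUE` subtracts the subset's per-frame mean displacement.
#'
#' @param traj an [md_trajectory()].
#' @param tags optional `epoch_tags` from [tag_trajectory()]; required for
#'   region subsets.
#' @param subset `"all"`, `"SR"`, `"BUFFER"` or `"LR"`.
#' @param mode `"lateral"`, `"normal"` or `"full"`.
#' @param window analysis window (ns or `c(t0, t1)`).
#' @param interval time-origin interval length (ns).
#' @param position `"com"` or `"N"`.
#' @param remove_drift subtract subset mean displacement per frame.
#' @return A tibble of class `msd_curve`: `lag` (ns), `msd` (nm^2);
#'   attributes `mode`, `subset`, `n_molecules`, `n_origins`.
#' @export
msd <- function(traj, tags = NULL, subset = "all",
                mode = c("lateral", "normal", "full"), window = 20,
                interval = 2, position = c("com", "N"),
                remove_drift = FALSE) {
  mode <- match.arg(mode)
  position <- match.arg(position)
  frames <- window_frames(traj, window)
  if (length(frames) < 2) abort("window must contain at least 2 frames")
  times <- traj$times[frames]
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-9) abort("window frames must be evenly spaced")
  dt <- dt[1]
  if (interval < dt) abort("interval shorter than the frame spacing")
  if (times[length(times)] - times[1] < interval - 1e-9) {
    abort("window shorter than one interval")
  }
  top <- traj$topology
  mobile <- top$molecule_type %in% c("AOPC", "TRC")
  mol_ids <- unique(top$molecule_id[mobile])
  if (position == "N" && any(top$molecule_type == "AOPC")) {
    sel <- select_sites(top, molecule_type = c("AOPC", "TRC"),
                        site_name = c("N", "T"))
  } else {
    sel <- which(mobile)
  }
  sub <- subset_frames(traj, frames)
  un <- unwrap_positions(sub, sel)
  mol_of <- top$molecule_id[sel]
  mass <- top$mass[sel]
  fac <- factor(mol_of, levels = mol_ids)
  msum <- as.numeric(rowsum(mass, fac))
  nfw <- length(frames)
  com <- array(0, dim = c(length(mol_ids), 3, nfw))
  for (f in seq_len(nfw)) {
    m <- un[, , f, drop = TRUE]
    if (length(sel) == 1) m <- matrix(m, 1, 3)
    com[, , f] <- rowsum(m * mass, fac) / msum
  }
  if (remove_drift) {
    drift <- apply(com, c(2, 3), mean)
    drift <- sweep(drift, 1, drift[, 1])
    for (f in seq_len(nfw)) com[, , f] <- com[, , f] - rep(drift[, f], each = length(mol_ids))
  }
  dims <- switch(mode, lateral = 1:2, normal = 3, full = 1:3)
  k <- round(interval / dt)
  origins <- seq(1, nfw - k, by = k)
  if (length(origins) == 0) abort("no complete interval fits the window")
  acc <- rep(0, k + 1)
  wt <- rep(0, k + 1)
  used_mols <- integer(0)
  dropped <- 0L
  for (o in origins) {
    t_start <- times[o]
    t_end <- times[o + k]
    keep <- rep(TRUE, length(mol_ids))
    if (subset != "all") {
      if (is.null(tags)) abort("tags required for region subsets")
      lab_start <- .tags_at_time(tags, t_start)
      lab_end <- .tags_at_time(tags, t_end - 1e-9)
      r1 <- lab_start$region[match(mol_ids, lab_start$molecule_id)]
      r2 <- lab_end$region[match(mol_ids, lab_end$molecule_id)]
      keep <- !is.na(r1) & r1 == subset & !is.na(r2) & r2 == subset
      dropped <- dropped + sum(!is.na(r1) & r1 == subset & (is.na(r2) | r2 != subset))
    }
    if (!any(keep)) next
    used_mols <- union(used_mols, mol_ids[keep])
    ref <- com[keep, dims, o, drop = FALSE]
    for (j in 0:k) {
      d <- com[keep, dims, o + j, drop = FALSE] - ref
      acc[j + 1] <- acc[j + 1] + sum(d^2)
      wt[j + 1] <- wt[j + 1] + sum(keep)
    }
  }
  if (all(wt == 0)) {
    abort(sprintf("subset '%s' empty after tag-constancy filter (%d molecules dropped)",
                  subset, dropped))
  }
  out <- tibble(lag = (0:k) * dt, msd = acc / wt)
  attr(out, "mode") <- mode
  attr(out, "subset") <- subset
  attr(out, "n_molecules") <- length(used_mols)
  attr(out, "n_origins") <- length(origins)
  attr(out, "dimensionality") <- length(dims)
  class(out) <- c("msd_curve", class(out))
  out
}

#' @export
glance.msd_curve <- function(x, ...) {
  tibble(mode = attr(x, "mode"), subset = attr(x, "subset"),
         n_molecules = attr(x, "n_molecules"),
         n_origins = attr(x, "n_origins"),
         max_lag = max(x$lag), msd_max = x$msd[which.max(x$lag)])
}

#' Diffusion coefficient from an MSD curve by the Einstein relation
#'
#' Least-squares slope m of MSD versus lag over the central fraction of the
#' lag range (default 10-90%); `D = m / (2 d)` with dimensionality d = 2 for
#' lateral, 1 for normal, 3 for full MSD. The uncertainty is the two-segment
#' convention: half the absolute difference between the D values fitted on
#' the first and second halves of the fit range. Units: nm^2/ns internally;
#' `1 nm^2/ns = 1e-5 cm^2/s`, so a lateral D of 0.015 nm^2/ns is
#' 1.5e-7 cm^2/s. A negative fitted slope is clamped to D = 0 with
#' `clamped = TRUE`.
#'
#' @param curve an [msd()] result.
#' @param fit_fraction lower/upper bounds of the fit range as fractions of
#'   the maximum lag.
#' @param dimensionality override for d (defaults to the curve's mode).
#' @return A list of class `diffusion_estimate`: `D` (cm^2/s), `D_nm2_ns`,
#'   `uncertainty` (cm^2/s), `fit_range` (ns), `dimensionality`, `clamped`.
#' @export
diffusion_coefficient <- function(curve, fit_fraction = c(0.1, 0.9),
                                  dimensionality = NULL) {
  d <- dimensionality %||% attr(curve, "dimensionality") %||% 2
  lo <- fit_fraction[1] * max(curve$lag)
  hi <- fit_fraction[2] * max(curve$lag)
  pts <- curve[curve$lag >= lo - 1e-12 & curve$lag <= hi + 1e-12 & curve$lag > 0, ]
  if (nrow(pts) < 10) abort("need at least 10 lag points in the fit range")
  slope_D <- function(p) {
    unname(coef(lm(msd ~ lag, data = p))[2]) / (2 * d)
  }
  D <- slope_D(pts)
  mid <- (lo + hi) / 2
  D1 <- slope_D(pts[pts$lag <= mid, ])
  D2 <- slope_D(pts[pts$lag > mid, ])
  unc <- abs(D1 - D2) / 2
  clamped <- FALSE
  if (D < 0) {
    warn("negative fitted slope; D clamped to 0")
    D <- 0
    clamped <- TRUE
  }
  structure(list(
    D = D * .D_NM2NS_TO_CM2S, D_nm2_ns = D,
    uncertainty = unc * .D_NM2NS_TO_CM2S, uncertainty_nm2_ns = unc,
    fit_range = c(lo, hi), dimensionality = d,
    subset = attr(curve, "subset"), mode = attr(curve, "mode"),
    clamped = clamped
  ), class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.3g +/- %.2g x10^7 cm^2/s (%s, %s%s)\n",
              x$D * 1e7, x$uncertainty * 1e7, x$mode %||% "?",
              x$subset %||% "all", if (x$clamped) ", clamped" else ""))
  invisible(x)
}

#' @export
tidy.diffusion_estimate <- function(x, ...) {
  tibble(term = "D", estimate = x$D, std.error = x$uncertainty,
         estimate_x1e7 = x$D * 1e7, estimate_nm2_ns = x$D_nm2_ns,
         subset = x$subset %||% NA_character_, mode = x$mode %||% NA_character_)
}

#' @export
glance.diffusion_estimate <- function(x, ...) {
  tibble(D_cm2_s = x$D, D_x1e7 = x$D * 1e7, uncertainty_x1e7 = x$uncertainty * 1e7,
         dimensionality = x$dimensionality,
         fit_lo = x$fit_range[1], fit_hi = x$fit_range[2], clamped = x$clamped)
}
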