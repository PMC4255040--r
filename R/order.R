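#' Deuterium order parameter -S_CD for united-atom acyl chains
#'
#' For each scored carbon i of a chain, a molecular frame is built from its
#' chain neighbours: the molecular z-axis is the unit vector from C(i-1) to
#' C(i+1), the molecular x-axis is the unit normal of the C(i-1), C(i), C(i+1)
#' plane, and y completes a right-handed frame. The order tensor elements
#' `S_aa = <(3 cos^2 theta_a - 1)/2>`, with `theta_a` the angle between
#' molecular axis a and the lab bilayer normal (z), are averaged over the
#' molecules of the requested region and over frames; the deuterium order
#' parameter is then reconstructed as `S_CD = (2/3) S_xx + (1/3) S_yy` and
#' reported as `-S_CD`. This is the standard reconstruction for united-atom
#' chains, where no explicit hydrogens exist. Values lie in `[-1, 0.5]`: 0.5
#' for an all-trans chain along the normal, 0 for isotropic chains.
#'
#' @param traj an [md_trajectory()].
#' @param chain `"sn1"` or `"sn2"` (chain definitions from the topology).
#' @param carbons carbon names to score; default all interior carbons of the
#'   chain (each needs both neighbours).
#' @param tags optional `epoch_tags`/`region_tags`; one profile per region in
#'   `regions` (-S_CD is computed for SR, buffer and LR alike).
#' @param regions regions scored when `tags` is given.
#' @param window analysis window (default last 20 ns).
#' @return A tibble of class `order_profile`: `region`, `chain`, `carbon`
#'   (ordered factor), `minus_scd`, `n_samples`.
#' @export
order_parameter_scd <- function(traj, chain = "sn1", carbons = NULL,
                                tags = NULL, regions = c("SR", "BUFFER", "LR"),
                                window = 20) {
  top <- traj$topology
  chains <- attr(top, "chains")
  if (is.null(chains) || is.null(chains[[chain]])) {
    abort(sprintf("topology has no chain definition '%s'", chain))
  }
  chain_carbons <- chains[[chain]]
  if (length(chain_carbons) < 3) abort("chain needs at least 3 carbons")
  if (is.null(carbons)) {
    carbons <- chain_carbons[2:(length(chain_carbons) - 1)]
  }
  bad <- setdiff(carbons, chain_carbons[2:(length(chain_carbons) - 1)])
  if (length(bad) > 0) {
    abort(sprintf("carbon %s lacks chain neighbours", bad[1]))
  }
  frames <- window_frames(traj, window)
  sets <- .region_sets(traj, tags, regions)
  out <- purrr::map(names(sets), function(rg) {
    ids <- sets[[rg]]
    sxx <- setNames(rep(0, length(carbons)), carbons)
    syy <- sxx
    nsm <- sxx
    for (f in frames) {
      box <- frame_box(traj, f)
      co <- rewrap_molecules(frame_coords(traj, f), top, box)
      pos <- lapply(chain_carbons, function(s) .site_positions(co, top, s, ids))
      names(pos) <- chain_carbons
      for (cb in carbons) {
        i <- match(cb, chain_carbons)
        Pm <- pos[[i - 1]]; P0 <- pos[[i]]; Pp <- pos[[i + 1]]
        zm <- Pp - Pm
        zm <- zm / sqrt(rowSums(zm^2))
        v1 <- P0 - Pm; v2 <- Pp - P0
        xm <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
                    v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
                    v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
        xm <- xm / sqrt(rowSums(xm^2))
        ym <- cbind(zm[, 2] * xm[, 3] - zm[, 3] * xm[, 2],
                    zm[, 3] * xm[, 1] - zm[, 1] * xm[, 3],
                    zm[, 1] * xm[, 2] - zm[, 2] * xm[, 1])
        sxx[cb] <- sxx[cb] + sum((3 * xm[, 3]^2 - 1) / 2)
        syy[cb] <- syy[cb] + sum((3 * ym[, 3]^2 - 1) / 2)
        nsm[cb] <- nsm[cb] + nrow(P0)
      }
    }
    scd <- (2 / 3) * (sxx / nsm) + (1 / 3) * (syy / nsm)
    tibble(region = rg, chain = chain,
           carbon = factor(carbons, levels = chain_carbons),
           minus_scd = unname(-scd), n_samples = as.integer(unname(nsm)))
  })
  out <- bind_rows(out)
  class(out) <- c("order_profile", class(out))
  out
}
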