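#' United-atom site table for one AOPC lipid
#'
#' AOPC (1-arachidoyl-2-oleoyl-sn-glycero-3-phosphocholine) is represented with
#' 56 united-atom sites: a choline group (N plus three N-methyl carbons CN1-CN3
#' and the two linker carbons C25, C24), a phosphate (P with bridging esters O6
#' toward choline and O3 toward glycerol, and the non-ester oxygens O4, O5), a
#' glycerol backbone (C21-C23) with two ester linkages (O1/O2 for sn1, O7/O8 for
#' sn2), a saturated 20-carbon sn1 chain (carbonyl C1 then C2..C20) and a
#' monounsaturated 18-carbon sn2 chain (carbonyl C29 then C30..C46) whose
#' C37-C38 bond is the cis double bond. The numbering is self-consistent with
#' the head-group names used in the source force field (N, C25, C24, O6, P,
#' O3-O6) and places the oleoyl delta-9 unsaturation on C37-C38.
#'
#' @return A tibble with one row per site: `site_name`, `mass` (u) and `role`
#'   (one of `"head"`, `"glycerol"`, `"sn1"`, `"sn2"`).
#' @export
#' @examples
#' nrow(aopc_sites())  # 56 united atoms per lipid
aopc_sites <- function() {
  head_sites <- tibble(
    site_name = c("N", "CN1", "CN2", "CN3", "C25", "C24",
                  "O6", "P", "O4", "O5", "O3"),
    mass = c(14.0067, 15.035, 15.035, 15.035, 14.027, 14.027,
             15.9994, 30.9738, 15.9994, 15.9994, 15.9994),
    role = "head"
  )
  glycerol <- tibble(
    site_name = c("C23", "C22", "C21", "O1", "O2", "O7", "O8"),
    mass = c(14.027, 13.019, 14.027, 15.9994, 15.9994, 15.9994, 15.9994),
    role = "glycerol"
  )
  sn1_names <- paste0("C", 1:20)
  sn1 <- tibble(
    site_name = sn1_names,
    mass = c(12.011, rep(14.027, 18), 15.035),
    role = "sn1"
  )
  sn2_names <- paste0("C", 29:46)
  sn2_mass <- rep(14.027, 18)
  sn2_mass[1] <- 12.011                       # carbonyl carbon
  sn2_mass[sn2_names %in% c("C37", "C38")] <- 13.019  # CH at the double bond
  sn2_mass[18] <- 15.035                      # terminal methyl
  sn2 <- tibble(site_name = sn2_names, mass = sn2_mass, role = "sn2")
  bind_rows(head_sites, glycerol, sn1, sn2)
}

#' Acyl-chain definitions for AOPC
#'
#' @return Named list with the ordered carbon names of each chain and the
#'   unsaturated pair.
#' @export
aopc_chains <- function() {
  list(
    sn1 = paste0("C", 1:20),
    sn2 = paste0("C", 29:46),
    unsaturated = c("C37", "C38")
  )
}

# Site names counted as lipid head-group sites (vicinity tests, Fig-3-style
# distance distributions).
aopc_head_site_names <- function() {
  c("N", "CN1", "CN2", "CN3", "C25", "C24", "O6", "P", "O4", "O5", "O3")
}

.site_mass_lookup <- function(site_name, molecule_type) {
  tab <- aopc_sites()
  m <- tab$mass[match(site_name, tab$site_name)]
  m[site_name == "OW"] <- 18.0154   # single-site water
  m[site_name == "HW1" | site_name == "HW2"] <- 1.008
  m[molecule_type == "AU"] <- 196.9666
  miss <- is.na(m)
  if (any(miss)) {
    # fall back on the element implied by the first letter; unknowns get 1 u
    el <- substr(site_name[miss], 1, 1)
    m[miss] <- c(C = 12.011, N = 14.0067, O = 15.9994, P = 30.9738,
                 H = 1.008, S = 32.06, T = 1.0)[el]
    m[is.na(m)] <- 1.0
  }
  m
}

#' Build a topology table
#'
#' A topology maps every coordinate row of a trajectory to a molecule and a
#' named site, and carries per-lipid chain definitions. Invariants: site names
#' are unique within a molecule, every lipid has an identical site layout, and
#' all masses are positive.
#'
#' @param molecule_id integer vector, one entry per site.
#' @param molecule_type character vector: `"AOPC"`, `"AU"`, `"SOL"` or a custom
#'   type such as `"TRC"` for point tracers.
#' @param site_name character vector of site names.
#' @param mass optional numeric masses (u); looked up from the AOPC/SPC/gold
#'   tables when omitted.
#' @param chains list of ordered carbon-name vectors (defaults to
#'   [aopc_chains()] when any AOPC molecules are present).
#' @return A tibble of class `md_topology` with columns `site_id`,
#'   `molecule_id`, `molecule_type`, `site_name`, `mass`.
#' @export
md_topology <- function(molecule_id, molecule_type, site_name, mass = NULL,
                        chains = NULL) {
  n <- length(molecule_id)
  stopifnot(length(molecule_type) == n, length(site_name) == n)
  if (is.null(mass)) mass <- .site_mass_lookup(site_name, molecule_type)
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    abort("all site masses must be positive and finite")
  }
  top <- tibble(
    site_id = seq_len(n),
    molecule_id = as.integer(molecule_id),
    molecule_type = as.character(molecule_type),
    site_name = as.character(site_name),
    mass = as.numeric(mass)
  )
  dup <- top |>
    dplyr::count(.data$molecule_id, .data$site_name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate site name '", dup$site_name[1],
                 "' in molecule ", dup$molecule_id[1]))
  }
  if (is.null(chains) && any(top$molecule_type == "AOPC")) chains <- aopc_chains()
  if (!is.null(chains)) {
    for (ch in c("sn1", "sn2")) {
      if (!is.null(chains[[ch]]) && length(chains[[ch]]) < 3) {
        abort(sprintf("chain %s needs at least 3 carbons", ch))
      }
    }
  }
  attr(top, "chains") <- chains
  class(top) <- c("md_topology", class(top))
  top
}

#' @export
print.md_topology <- function(x, ...) {
  cat(sprintf("<md_topology> %d sites, %d molecules (%s)\n",
              nrow(x), length(unique(x$molecule_id)),
              paste(unique(x$molecule_type), collapse = ", ")))
  NextMethod()
}

#' Topology for a stack of identical AOPC lipids plus optional gold and water
#'
#' @param n_lipids number of AOPC molecules.
#' @param n_gold number of gold atoms (one rigid nanoparticle, one site each).
#' @param n_waters number of single-site waters (site `OW`).
#' @return An `md_topology`.
#' @export
bilayer_topology <- function(n_lipids, n_gold = 0, n_waters = 0) {
  sites <- aopc_sites()
  k <- nrow(sites)
  mol_id <- rep(seq_len(n_lipids), each = k)
  top <- tibble(
    molecule_id = mol_id,
    molecule_type = "AOPC",
    site_name = rep(sites$site_name, n_lipids),
    mass = rep(sites$mass, n_lipids)
  )
  next_id <- n_lipids
  if (n_gold > 0) {
    top <- bind_rows(top, tibble(
      molecule_id = next_id + 1L, molecule_type = "AU",
      site_name = paste0("A", seq_len(n_gold)), mass = 196.9666
    ))
    next_id <- next_id + 1L
  }
  if (n_waters > 0) {
    top <- bind_rows(top, tibble(
      molecule_id = next_id + seq_len(n_waters), molecule_type = "SOL",
      site_name = "OW", mass = 18.0154
    ))
  }
  md_topology(top$molecule_id, top$molecule_type, top$site_name, top$mass,
              chains = aopc_chains())
}

#' Select site indices by molecule type, site name or molecule id
#'
#' @param topology an `md_topology`.
#' @param molecule_type,site_name,molecule_id optional filters; `NULL` keeps
#'   everything.
#' @return Integer vector of site ids (row indices into the coordinate array).
#' @export
select_sites <- function(topology, molecule_type = NULL, site_name = NULL,
                         molecule_id = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(molecule_type)) keep <- keep & topology$molecule_type %in% molecule_type
  if (!is.null(site_name)) keep <- keep & topology$site_name %in% site_name
  if (!is.null(molecule_id)) keep <- keep & topology$molecule_id %in% molecule_id
  which(keep)
}

#' Read / write a topology manifest (JSON)
#'
#' The manifest is a plain JSON table of `molecule_id`, `molecule_type`,
#' `site_name`, `mass`, plus the chain definitions.
#'
#' @param path file path.
#' @return `read_topology()` returns an `md_topology`; `write_topology()`
#'   returns `path` invisibly.
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  chains <- obj$chains
  if (!is.null(chains)) chains <- lapply(chains, as.character)
  md_topology(obj$sites$molecule_id, obj$sites$molecule_type,
              obj$sites$site_name, obj$sites$mass, chains = chains)
}

#' @rdname read_topology
#' @param topology an `md_topology` to serialize.
#' @export
write_topology <- function(topology, path) {
  obj <- list(
    sites = as.data.frame(topology[, c("molecule_id", "molecule_type",
                                       "site_name", "mass")]),
    chains = attr(topology, "chains")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
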