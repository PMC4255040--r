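#' Run configuration for the end-to-end pipeline
#'
#' Exactly one of `trajectory`/`topology` (input paths) or `generator`
#' (a [generator_config()] or a list of its arguments) must be supplied.
#'
#' @param trajectory path to a (multi-frame) GRO trajectory, or `NULL`.
#' @param topology optional path to a JSON topology manifest.
#' @param generator a [generator_config()] or argument list, or `NULL`.
#' @param np_radius nanoparticle radius (nm); `NULL` means no nanoparticle
#'   (taken from the generator when generating).
#' @param epoch_length_ns re-tagging epoch (ns).
#' @param analyses character vector of analyses to run, from
#'   `c("density", "map2d", "dist", "rdf", "angles", "dihedrals", "scd",
#'   "thickness", "apl", "msd")`.
#' @param windows named list of analysis windows (ns); defaults:
#'   distributions and the 2D map use the last 10 ns, order parameters,
#'   thickness, area per lipid and MSD the last 20 ns (clipped to the
#'   trajectory span).
#' @param output_dir output directory (created if missing).
#' @param seed RNG seed for generation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(trajectory = NULL, topology = NULL, generator = NULL,
                       np_radius = NULL, epoch_length_ns = 10,
                       analyses = c("density", "scd", "thickness", "apl", "msd"),
                       windows = list(), output_dir = "npbilayer-out",
                       seed = 1) {
  if (is.null(trajectory) == is.null(generator)) {
    abort("exactly one of `trajectory` or `generator` must be given")
  }
  known <- c("density", "map2d", "dist", "rdf", "angles", "dihedrals", "scd",
             "thickness", "apl", "msd")
  bad <- setdiff(analyses, known)
  if (length(bad) > 0) abort(sprintf("unknown analysis '%s'", bad[1]))
  if (!is.null(generator) && !inherits(generator, "generator_config")) {
    generator <- do.call(generator_config, generator)
  }
  structure(list(trajectory = trajectory, topology = topology,
                 generator = generator, np_radius = np_radius,
                 epoch_length_ns = epoch_length_ns, analyses = analyses,
                 windows = windows, output_dir = output_dir, seed = seed),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file; keys mirror [run_config()] arguments, with
#'   `generator:` a mapping of [generator_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.stage <- function(name, quiet, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
  if (!quiet) {
    message(sprintf("[npbilayer] %-10s %6.2f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  res
}

.write_result_csv <- function(x, path, meta = character()) {
  hdr <- c(sprintf("# npbilayer %s", as.character(utils::packageVersion("npbilayer"))),
           paste0("# ", meta))
  writeLines(hdr, path)
  readr::write_csv(as_tibble(as.data.frame(x)), path, append = TRUE,
                   col_names = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Sequences the standard workflow: obtain the trajectory (read or generate),
#' assign leaflets, tag SR/buffer/LR epochs, run the enabled analyses, and
#' write every result as CSV plus a JSON summary into the output directory.
#' Deterministic for a fixed config and seed. Each output CSV carries a
#' comment header echoing the parameters that produced it.
#'
#' @param config a [run_config()] (or a YAML path for one).
#' @param quiet suppress per-stage timing messages.
#' @return A list of class `run_report`: `files` (tibble registry of outputs),
#'   `region_counts`, `summary` (named list of headline numbers), `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(config$generator)) {
    gen <- config$generator
    gen$seed <- config$seed
    sim <- .stage("generate", quiet, generate_trajectory(gen))
    traj <- sim$trajectory
    truth <- sim$truth
    np_radius <- if (gen$np_radius > 0) gen$np_radius else NULL
  } else {
    top <- if (!is.null(config$topology)) read_topology(config$topology)
    traj <- .stage("read", quiet, read_gro(config$trajectory, topology = top))
    np_radius <- config$np_radius
  }
  has_np <- !is.null(np_radius) &&
    length(select_sites(traj$topology, molecule_type = "AU")) > 0
  boundaries <- if (has_np) region_boundaries(np_radius)
  tags <- .stage("partition", quiet,
                 tag_trajectory(traj, boundaries, config$epoch_length_ns))
  counts <- region_counts(tags)
  span <- traj$times[n_frames(traj)] - traj$times[1]
  win <- function(name, default) {
    w <- config$windows[[name]] %||% default
    min(w, span)
  }
  files <- list()
  summary <- list()
  reg <- function(analysis, path) {
    files[[length(files) + 1]] <<- tibble(analysis = analysis, path = path)
  }
  outd <- config$output_dir
  meta <- sprintf("epoch=%g ns, np_radius=%s, seed=%d", config$epoch_length_ns,
                  if (has_np) np_radius else "none", config$seed)
  an <- config$analyses
  if ("density" %in% an) {
    .stage("density", quiet, {
      w <- win("density", 10)
      for (lab in c("water", "AOPC")) {
        sel <- if (lab == "water") {
          select_sites(traj$topology, molecule_type = "SOL")
        } else select_sites(traj$topology, molecule_type = "AOPC")
        if (length(sel) == 0) next
        p <- partial_density_profile(traj, sel, window = w, label = lab)
        reg("density", .write_result_csv(p, file.path(outd, paste0("density_", lab, ".csv")),
                                         c(meta, sprintf("window=%g ns, mode=mass", w))))
      }
      sr_ids <- unique(tags$molecule_id[tags$region == "SR"])
      lr_ids <- unique(tags$molecule_id[tags$region == "LR"])
      for (lab in c("N_SR", "N_LR")) {
        ids <- if (lab == "N_SR") sr_ids else lr_ids
        if (length(ids) == 0) next
        sel <- select_sites(traj$topology, molecule_type = "AOPC",
                            site_name = "N", molecule_id = ids)
        p <- partial_density_profile(traj, sel, window = w, label = lab)
        reg("density", .write_result_csv(p, file.path(outd, paste0("density_", lab, ".csv")),
                                         c(meta, sprintf("window=%g ns", w))))
      }
    })
  }
  if ("map2d" %in% an) {
    .stage("map2d", quiet, {
      m <- density_map_2d(traj, window = win("map2d", 10))
      reg("map2d", .write_result_csv(m, file.path(outd, "water_map_xz.csv"), meta))
    })
  }
  if ("dist" %in% an && has_np) {
    .stage("dist", quiet, {
      for (grp in list(N = "N", NMe = c("CN1", "CN2", "CN3"),
                       O_nonester = c("O4", "O5"))) {
        lab <- paste(grp, collapse = "+")
        h <- distance_distribution(traj, grp, window = win("dist", 10))
        reg("dist", .write_result_csv(h, file.path(outd, paste0("golddist_", lab, ".csv")),
                                      c(meta, sprintf("sites=%s", lab))))
      }
    })
  }
  if ("rdf" %in% an && has_np) {
    .stage("rdf", quiet, {
      au <- select_sites(traj$topology, molecule_type = "AU")
      ow <- select_sites(traj$topology, molecule_type = "SOL", site_name = "OW")
      if (length(ow) > 0) {
        g <- rdf(traj, au, ow, window = win("rdf", 10))
        reg("rdf", .write_result_csv(g, file.path(outd, "rdf_au_ow.csv"), meta))
      }
    })
  }
  if ("angles" %in% an) {
    .stage("angles", quiet, {
      for (tr in list(c("N", "C25", "C24"), c("C25", "C24", "O6"),
                      c("C24", "O6", "P"))) {
        a <- angle_distribution(traj, tr, tags = if (has_np) tags,
                                window = win("angles", 10))
        reg("angles", .write_result_csv(a, file.path(outd, paste0("angle_", paste(tr, collapse = "-"), ".csv")), meta))
      }
    })
  }
  if ("dihedrals" %in% an) {
    .stage("dihedrals", quiet, {
      for (qd in list(c("N", "C25", "C24", "O6"), c("C25", "C24", "O6", "P"))) {
        dh <- dihedral_distribution(traj, qd, tags = if (has_np) tags,
                                    window = win("dihedrals", 10))
        reg("dihedrals", .write_result_csv(dh, file.path(outd, paste0("dihedral_", paste(qd, collapse = "-"), ".csv")), meta))
      }
    })
  }
  if ("scd" %in% an) {
    .stage("scd", quiet, {
      for (ch in c("sn1", "sn2")) {
        op <- order_parameter_scd(traj, ch, tags = if (has_np) tags,
                                  window = win("scd", 20))
        reg("scd", .write_result_csv(op, file.path(outd, paste0("scd_", ch, ".csv")), meta))
        if (ch == "sn1") {
          summary$minus_scd_sn1 <- setNames(
            as.list(tapply(op$minus_scd, op$region, mean)),
            paste0("mean_", names(tapply(op$minus_scd, op$region, mean))))
        }
      }
    })
  }
  if ("thickness" %in% an) {
    .stage("thickness", quiet, {
      tf <- grid_thickness(traj, boundaries = boundaries,
                           window = win("thickness", 20))
      reg("thickness", .write_result_csv(tidy(tf), file.path(outd, "thickness_cells.csv"), meta))
      reg("thickness", .write_result_csv(tf$distribution, file.path(outd, "thickness_distribution.csv"), meta))
      summary$mean_thickness_nm <- tf$mean
    })
  }
  if ("apl" %in% an) {
    .stage("apl", quiet, {
      ap <- area_per_lipid_lr(traj, tags = tags, boundaries = boundaries,
                              window = win("apl", 20))
      reg("apl", .write_result_csv(ap, file.path(outd, "area_per_lipid_lr.csv"), meta))
      summary$mean_area_per_lipid_nm2 <- attr(ap, "mean")
    })
  }
  if ("msd" %in% an) {
    .stage("msd", quiet, {
      subsets <- if (has_np) c("SR", "LR") else "all"
      for (sb in subsets) {
        for (md in c("lateral", "normal")) {
          cv <- tryCatch(
            msd(traj, tags = tags, subset = sb, mode = md,
                window = win("msd", 20),
                interval = min(2, win("msd", 20) / 2)),
            error = function(e) NULL)
          if (is.null(cv)) next
          reg("msd", .write_result_csv(cv, file.path(outd, sprintf("msd_%s_%s.csv", sb, md)), meta))
          de <- tryCatch(diffusion_coefficient(cv), error = function(e) NULL)
          if (!is.null(de)) {
            summary[[sprintf("D_%s_%s_x1e7_cm2_s", sb, md)]] <- de$D * 1e7
          }
        }
      }
    })
  }
  files <- bind_rows(files)
  summary_path <- file.path(outd, "summary.json")
  jsonlite::write_json(
    list(summary = summary,
         region_counts = as.data.frame(counts),
         parameters = list(epoch_length_ns = config$epoch_length_ns,
                           np_radius = np_radius, seed = config$seed,
                           analyses = an),
         version = as.character(utils::packageVersion("npbilayer"))),
    summary_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    write_ground_truth(truth, file.path(outd, "ground_truth.json"))
  }
  structure(list(files = files, region_counts = counts, summary = summary,
                 config = config, truth = truth),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d output files in %s\n", nrow(x$files),
              x$config$output_dir))
  print(x$region_counts)
  for (nm in names(x$summary)) {
    v <- x$summary[[nm]]
    if (is.numeric(v) && length(v) == 1) cat(sprintf("  %s = %.4g\n", nm, v))
  }
  invisible(x)
}
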