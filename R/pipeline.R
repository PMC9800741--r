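#' Assemble a pipeline run configuration
#'
#' Every parameter that affects a number in any report is collected here and
#' echoed into the run's provenance block.
#'
#' @param rng_seed integer seed for the whole run.
#' @param out_dir output directory (created if missing).
#' @param segmentation named list of \code{\link{segment_vessels}} arguments.
#' @param skeleton named list of \code{\link{skeletonize_graph}} arguments.
#' @param perfusion a \code{\link{perfusion_params}}.
#' @param vessel_type named list: \code{tolerance_um}, \code{coverage_tau}.
#' @param diameters named list: \code{bin_width_um}, \code{sampling_step_um},
#'   \code{upstream_distance_um}.
#' @param coloc named list: \code{matching_radius_um} plus
#'   \code{\link{detect_neutrophils}} arguments.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(rng_seed = 1L, out_dir = "noreflow_out",
                       segmentation = list(),
                       skeleton = list(),
                       perfusion = perfusion_params(),
                       vessel_type = list(tolerance_um = 5, coverage_tau = 0.5),
                       diameters = list(bin_width_um = 0.5, sampling_step_um = 4,
                                        upstream_distance_um = 20),
                       coloc = list(matching_radius_um = 10)) {
  structure(list(rng_seed = as.integer(rng_seed), out_dir = out_dir,
                 segmentation = segmentation, skeleton = skeleton,
                 perfusion = perfusion, vessel_type = vessel_type,
                 diameters = diameters, coloc = coloc,
                 software_version = as.character(utils::packageVersion("noreflow"))),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are errors (this protects against silent typos). Nested
#' sections mirror the arguments of \code{\link{run_config}}.
#'
#' @param path YAML file path.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("rng_seed", "out_dir", "segmentation", "skeleton", "perfusion",
             "vessel_type", "diameters", "coloc")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")))
  args <- y
  if (!is.null(y$perfusion)) args$perfusion <- do.call(perfusion_params, y$perfusion)
  do.call(run_config, args)
}

#' Run the full recognition-and-analysis pipeline
#'
#' Executes segmentation, occlusion recognition, blockage analysis and
#' neutrophil co-localization in order on co-registered channel volumes,
#' skipping stages whose channels are absent, and writes all reports plus a
#' run manifest (every output file with an MD5 content hash and the full
#' provenance block). Two runs with identical configuration and inputs
#' produce identical reports.
#'
#' @param config a \code{\link{run_config}}.
#' @param volumes named list of \code{\link{image_volume}}s; names from
#'   \code{existing}, \code{functional}, \code{asma}, \code{neutrophil},
#'   \code{nucleus}. \code{existing} and \code{functional} are required.
#' @param region_mask optional \code{\link{vessel_mask}} region restriction.
#' @return (invisibly) a list with the labeled graph, occlusion report,
#'   blockage points, coloc report, diameter histogram and the manifest.
#' @export
run_pipeline <- function(config, volumes, region_mask = NULL) {
  stopifnot(inherits(config, "run_config"))
  for (ch in c("existing", "functional"))
    if (is.null(volumes[[ch]]))
      stop(sprintf("required channel '%s' is missing", ch))
  d0 <- dim(volumes$existing$data)
  for (ch in names(volumes))
    if (!identical(dim(volumes[[ch]]$data), d0))
      stop(sprintf("channel '%s' shape differs from 'existing'", ch))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  stages <- character(0)
  outputs <- character(0)
  save_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }

  with_seed(config$rng_seed, {
    # --- segmentation ------------------------------------------------------
    logf("stage segmentation")
    seg <- function(ch) do.call(segment_vessels, c(list(volumes[[ch]]), config$segmentation))
    existing_mask <- seg("existing")
    functional_mask <- seg("functional")
    asma_mask <- if (!is.null(volumes$asma)) seg("asma") else NULL
    graph <- do.call(skeletonize_graph, c(list(existing_mask), config$skeleton))
    stages <- c(stages, "segmentation")

    # --- occlusion recognition --------------------------------------------
    logf("stage recognition")
    graph <- classify_edges(graph, functional_mask, config$perfusion)
    occ <- quantify_occlusion(graph, region_mask = region_mask)
    save_csv(as.data.frame(occ), "occlusion_report.csv")
    write_vessel_graph(graph, file.path(config$out_dir, "vessel_graph.json"))
    write_swc(graph, file.path(config$out_dir, "vessel_graph.swc"))
    outputs <- c(outputs, file.path(config$out_dir, c("vessel_graph.json", "vessel_graph.swc")))
    stages <- c(stages, "recognition")

    # --- blockage analysis -------------------------------------------------
    logf("stage blockage")
    points <- detect_blockage_points(graph)
    if (nrow(points) > 0) {
      points <- measure_blockage_diameters(points, volumes$existing, graph,
        upstream_distance_um = config$diameters$upstream_distance_um)
      if (is.null(asma_mask)) {
        logf("  no asma channel: vessel_type = unknown everywhere")
      } else {
        points <- classify_vessel_type(points, graph, asma_mask,
                                       tolerance_um = config$vessel_type$tolerance_um,
                                       coverage_tau = config$vessel_type$coverage_tau)
      }
    }
    hist_d <- diameter_distribution(volumes$existing, graph, region_mask = region_mask,
                                    bin_width_um = config$diameters$bin_width_um,
                                    sampling_step_um = config$diameters$sampling_step_um)
    save_csv(data.frame(bin_left_um = utils::head(hist_d$breaks_um, -1),
                        bin_right_um = hist_d$breaks_um[-1],
                        rel_freq = hist_d$rel_freq),
             "diameter_histogram.csv")
    stages <- c(stages, "blockage")

    # --- colocalization ----------------------------------------------------
    coloc_rep <- NULL
    if (!is.null(volumes$neutrophil)) {
      logf("stage coloc")
      cargs <- config$coloc
      matching <- cargs$matching_radius_um %||% 10
      cargs$matching_radius_um <- NULL
      cells <- do.call(detect_neutrophils,
                       c(list(volumes$neutrophil, volumes$nucleus, existing_mask), cargs))
      coloc_rep <- colocalize_blockages(points, cells, matching_radius_um = matching,
                                        existing_length_um = total_length(graph))
      points <- coloc_rep$points
      save_csv(as.data.frame(cells), "cells.csv")
      save_csv(as.data.frame(coloc_rep), "coloc_report.csv")
      stages <- c(stages, "coloc")
    } else {
      logf("stage coloc skipped: no neutrophil channel")
    }
    save_csv(as.data.frame(points), "blockage_points.csv")

    # --- manifest -----------------------------------------------------------
    manifest <- list(schema_version = SCHEMA_VERSION,
                     software_version = config$software_version,
                     rng_seed = config$rng_seed,
                     stages = stages,
                     provenance = provenance_block(config),
                     outputs = lapply(sort(unique(outputs)), function(p)
                       list(file = basename(p), md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("done: %d stages", length(stages))
    invisible(list(graph = graph, occlusion = occ, blockage_points = points,
                   coloc = coloc_rep, diameter_histogram = hist_d,
                   manifest = manifest,
                   masks = list(existing = existing_mask, functional = functional_mask,
                                asma = asma_mask)))
  })
}

provenance_block <- function(config) {
  list(rng_seed = config$rng_seed,
       segmentation = config$segmentation,
       skeleton = config$skeleton,
       perfusion = unclass(config$perfusion),
       vessel_type = config$vessel_type,
       diameters = config$diameters,
       coloc = config$coloc,
       software_version = config$software_version)
}
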