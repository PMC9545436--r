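#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_stage()] /
#' [run_pipeline()]. Every defaulted value is materialized (and therefore
#' logged in stage manifests); one master seed deterministically derives all
#' stage seeds.
#'
#' @param out_dir Output directory for artifacts and manifests.
#' @param seed Master seed.
#' @param simulation Named list of overrides for [simulation_config()] (used
#'   by the `simulate` stage). The simulation inherits the master seed unless
#'   it sets its own.
#' @param genotypes,climate_table,climate_grid Optional input paths; when set
#'   they replace the simulated artifacts for downstream stages.
#' @param reference_zones Optional reference zone-map path (`.asc`) for the
#'   `compare` stage.
#' @param maf_threshold MAF filter cutoff (strict `>`; default 0.05).
#' @param n_trees,mtry,min_node Forest settings (defaults 200, 6, 5).
#' @param n_bins,density_floor Importance-binning settings (101, 0.01).
#' @param pca_components Score components to attach (default 3).
#' @param k_range,theta,n_restarts,max_points Zonation settings (defaults
#'   2:16, 0.5, 5, 20000).
#' @param denominator Overlap-rate denominator convention.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("gfzone_run_"), seed = 1,
                            simulation = list(), genotypes = NULL,
                            climate_table = NULL, climate_grid = NULL,
                            reference_zones = NULL, maf_threshold = 0.05,
                            n_trees = 200, mtry = 6, min_node = 5,
                            n_bins = 101, density_floor = 0.01,
                            pca_components = 3, k_range = 2:16, theta = 0.5,
                            n_restarts = 5, max_points = 20000,
                            denominator = "reference") {
  if (!is.numeric(seed) || length(seed) != 1) stop("seed must be one integer",
                                                   call. = FALSE)
  sim_args <- utils::modifyList(list(seed = derive_seed(seed, "simulate")),
                                simulation)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         simulation = do.call(simulation_config, sim_args),
         genotypes = genotypes, climate_table = climate_table,
         climate_grid = climate_grid, reference_zones = reference_zones,
         maf_threshold = maf_threshold, n_trees = n_trees, mtry = mtry,
         min_node = min_node, n_bins = n_bins, density_floor = density_floor,
         pca_components = pca_components, k_range = as.integer(k_range),
         theta = theta, n_restarts = n_restarts, max_points = max_points,
         denominator = denominator),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; the `simulation` block
#' maps onto [simulation_config()]. Unset keys take the package defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

stage_order <- c("simulate", "fit", "transform", "map", "zone", "compare")

stage_outputs <- function(cfg, stage) {
  d <- cfg$out_dir
  switch(stage,
    simulate = c(genotypes = file.path(d, "genotypes.tsv"),
                 climate = file.path(d, "climate.csv"),
                 truth = file.path(d, "truth.csv"),
                 locations = file.path(d, "locations.csv"),
                 grid = file.path(d, "grid")),
    fit = c(model = file.path(d, "model.json")),
    transform = c(scores = file.path(d, "scores.csv"),
                  variance = file.path(d, "pca_variance.csv"),
                  loadings = file.path(d, "pca_loadings.csv")),
    map = c(rgb = file.path(d, "rgb_map.csv")),
    zone = c(scan = file.path(d, "cluster_scan.csv"),
             selection = file.path(d, "k_selection.json"),
             zones = file.path(d, "zones.asc")),
    compare = c(report = file.path(d, "overlap_report.csv"),
                summary = file.path(d, "overlap_summary.json")))
}

require_upstream <- function(cfg, stage, needed_stage, files) {
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop(sprintf("stage '%s' needs artifacts from stage '%s' (missing: %s); run it first",
                 stage, needed_stage,
                 paste(basename(missing), collapse = ", ")), call. = FALSE)
  }
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  existing <- inputs[file.exists(inputs)]
  manifest <- list(
    stage = stage, seed = cfg$seed,
    stage_seed = derive_seed(cfg$seed, stage),
    package_version = as.character(utils::packageVersion("gfzone")),
    config = config_snapshot(cfg),
    input_hashes = as.list(tools::md5sum(existing)),
    outputs = as.list(outputs))
  path <- file.path(cfg$out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

config_snapshot <- function(cfg) {
  snap <- unclass(cfg)
  snap$simulation <- unclass(snap$simulation)
  snap
}

#' Run one pipeline stage (or the whole chain)
#'
#' Stages: `simulate` (synthetic landscape), `fit` (gradient forest),
#' `transform` (grid transformation + PCA), `map` (RGB map), `zone`
#' (cluster scan, k selection, zone map), `compare` (overlap against a
#' configured reference zone map), or `all`. Each stage writes its artifacts
#' plus a JSON manifest (config snapshot, stage seed, input hashes); reruns
#' with identical configuration and inputs are bit-identical.
#'
#' @param stage One of `"simulate"`, `"fit"`, `"transform"`, `"map"`,
#'   `"zone"`, `"compare"`, `"all"`.
#' @param cfg A [pipeline_config()].
#' @return Named vector of output paths (for `"all"`, the union), invisibly.
#' @export
run_stage <- function(stage = c("all", stage_order), cfg = pipeline_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    stages <- stage_order
    if (is.null(cfg$reference_zones)) stages <- setdiff(stages, "compare")
    out <- unlist(lapply(stages, run_stage, cfg = cfg))
    return(invisible(out))
  }
  out <- stage_outputs(cfg, stage)
  inputs <- character(0)

  if (stage == "simulate") {
    land <- simulate_landscape(cfg$simulation)
    write_genotypes(land$genotypes, out["genotypes"])
    write_climate_table(land$climate, out["climate"])
    utils::write.csv(land$truth, out["truth"], row.names = FALSE)
    utils::write.csv(land$locations, out["locations"], row.names = FALSE)
    write_climate_grid(land$grid, out["grid"])
  } else if (stage == "fit") {
    gpath <- cfg$genotypes %||% stage_outputs(cfg, "simulate")["genotypes"]
    cpath <- cfg$climate_table %||% stage_outputs(cfg, "simulate")["climate"]
    require_upstream(cfg, "fit", "simulate", c(gpath, cpath))
    inputs <- c(gpath, cpath)
    g <- read_genotypes(gpath)
    g <- filter_maf(g, cfg$maf_threshold)
    climate <- read_climate_table(cpath)
    model <- fit_gradient_forest(
      g, climate, n_trees = cfg$n_trees, mtry = cfg$mtry,
      min_node = cfg$min_node, seed = derive_seed(cfg$seed, "fit"),
      n_bins = cfg$n_bins, density_floor = cfg$density_floor)
    write_gf_model(model, out["model"])
  } else if (stage == "transform") {
    mpath <- stage_outputs(cfg, "fit")["model"]
    gdir <- cfg$climate_grid %||% stage_outputs(cfg, "simulate")["grid"]
    require_upstream(cfg, "transform", "fit", mpath)
    require_upstream(cfg, "transform", "simulate", gdir)
    inputs <- c(mpath, file.path(gdir, "grid.json"))
    model <- read_gf_model(mpath)
    grid <- read_climate_grid(gdir)
    gg <- pca_scores(transform_grid(model, grid),
                     n_components = cfg$pca_components)
    utils::write.csv(gg, out["scores"], row.names = FALSE)
    utils::write.csv(
      data.frame(component = seq_along(pca_variance_fractions(gg)),
                 variance_fraction = pca_variance_fractions(gg)),
      out["variance"], row.names = FALSE)
    utils::write.csv(
      data.frame(predictor = rownames(pca_loadings(gg)), pca_loadings(gg)),
      out["loadings"], row.names = FALSE)
  } else if (stage == "map") {
    spath <- stage_outputs(cfg, "transform")["scores"]
    require_upstream(cfg, "map", "transform", spath)
    inputs <- spath
    gg <- tibble::as_tibble(utils::read.csv(spath))
    utils::write.csv(rgb_map(gg), out["rgb"], row.names = FALSE)
  } else if (stage == "zone") {
    spath <- stage_outputs(cfg, "transform")["scores"]
    require_upstream(cfg, "zone", "transform", spath)
    inputs <- spath
    gg <- tibble::as_tibble(utils::read.csv(spath))
    pcs <- grep("^PC[0-9]+$", names(gg), value = TRUE)
    scan <- cluster_scan(gg[pcs], k_range = cfg$k_range,
                         seed = derive_seed(cfg$seed, "zone"),
                         n_restarts = cfg$n_restarts,
                         max_points = cfg$max_points)
    sel <- select_k(scan, theta = cfg$theta)
    utils::write.csv(scan$scan, out["scan"], row.names = FALSE)
    jsonlite::write_json(list(k = sel$k, no_elbow = sel$no_elbow,
                              theta = sel$theta, trace = sel$trace),
                         out["selection"], auto_unbox = TRUE, digits = NA)
    zm <- make_zone_map(scan,
                        climate_grid(gg[c("x", "y")],
                                     cellsize = cfg$simulation$cellsize),
                        sel$k)
    write_zone_map(zm, out["zones"])
  } else if (stage == "compare") {
    zpath <- stage_outputs(cfg, "zone")["zones"]
    require_upstream(cfg, "compare", "zone", zpath)
    if (is.null(cfg$reference_zones)) {
      stop("compare stage needs cfg$reference_zones", call. = FALSE)
    }
    inputs <- c(zpath, cfg$reference_zones)
    rep <- overlap_report(read_zone_map(zpath),
                          read_zone_map(cfg$reference_zones),
                          denominator = cfg$denominator)
    utils::write.csv(rep, out["report"], row.names = FALSE)
    jsonlite::write_json(list(average_rate = average_overlap_rate(rep),
                              denominator = attr(rep, "denominator")),
                         out["summary"], auto_unbox = TRUE, digits = NA)
  }
  manifest <- write_manifest(cfg, stage, inputs, out)
  gf_log("stage '%s' complete (%s)", stage, basename(manifest))
  invisible(out)
}

#' @rdname run_stage
#' @export
run_pipeline <- function(cfg = pipeline_config()) run_stage("all", cfg)
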