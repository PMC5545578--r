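#' Pipeline configuration
#'
#' One configuration object drives the end-to-end run. Analysis thresholds
#' default to the standard printed values of the method: 512 ROIs per
#' hemisphere, FA stop 0.2, angle stop 45 degrees, alpha = q = 0.05,
#' Bonferroni multiplicity 3. The demo simulation blocks are sized so a
#' full run completes in minutes on one CPU.
#'
#' @param outdir output directory for all stages.
#' @param seed master seed; stage seeds derive from it.
#' @param n_rois ROIs per hemisphere.
#' @param fa_stop,angle_stop,step,max_len tractography parameters.
#' @param edge_min_fibers minimum fiber count per network edge.
#' @param distance_rule weight-to-length conversion for efficiencies.
#' @param alpha,q,bonferroni_m statistical thresholds.
#' @param phantom optional list of [phantom_spec()] arguments for the
#'   simulate stage.
#' @param cohort optional list of [cohort_spec()] arguments.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "hemiconn_out", seed = 1L,
                            n_rois = 512L, fa_stop = 0.2, angle_stop = 45,
                            step = NULL, max_len = 300,
                            edge_min_fibers = 1L,
                            distance_rule = "inverse",
                            alpha = 0.05, q = 0.05, bonferroni_m = 3L,
                            phantom = NULL, cohort = NULL) {
  # canonicalize the simulation blocks through their constructors so that a
  # YAML round trip reproduces the config exactly
  if (!is.null(phantom)) phantom <- do.call(phantom_spec, as.list(phantom))
  if (!is.null(cohort)) cohort <- do.call(cohort_spec, as.list(cohort))
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              n_rois = as.integer(n_rois),
              fa_stop = as.numeric(fa_stop),
              angle_stop = as.numeric(angle_stop),
              step = if (is.null(step)) NULL else as.numeric(step),
              max_len = as.numeric(max_len),
              edge_min_fibers = as.integer(edge_min_fibers),
              distance_rule = distance_rule, alpha = as.numeric(alpha),
              q = as.numeric(q), bonferroni_m = as.integer(bonferroni_m),
              phantom = phantom, cohort = cohort)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (cfg$fa_stop <= 0 || cfg$fa_stop >= 1)
    stop("config invalid: fa_stop must lie in (0, 1)")
  if (cfg$angle_stop <= 0 || cfg$angle_stop > 90)
    stop("config invalid: angle_stop must lie in (0, 90]")
  if (!is.null(cfg$step) && cfg$step <= 0)
    stop("config invalid: step must be positive")
  if (cfg$max_len <= 0) stop("config invalid: max_len must be positive")
  if (cfg$n_rois < 1) stop("config invalid: n_rois must be >= 1")
  if (cfg$edge_min_fibers < 1)
    stop("config invalid: edge_min_fibers must be >= 1")
  if (!cfg$distance_rule %in% c("inverse", "neglog"))
    stop("config invalid: distance_rule must be 'inverse' or 'neglog'")
  if (cfg$alpha <= 0 || cfg$alpha >= 1 || cfg$q <= 0 || cfg$q >= 1)
    stop("config invalid: alpha and q must lie in (0, 1)")
  invisible(cfg)
}

#' Save / load a pipeline configuration as YAML
#'
#' Round-trips exactly: `load_config(save_config(cfg, f))` equals `cfg`.
#'
#' @param cfg a `pipeline_config`.
#' @param file YAML path.
#' @export
save_config <- function(cfg, file) {
  # yaml drops the names of named atomic vectors; write them as maps
  namedify <- function(x) {
    if (is.list(x)) lapply(x, namedify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(namedify(unclass(cfg)), file)
  invisible(file)
}

#' @rdname save_config
#' @export
load_config <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  save_config(cfg, f)
  unname(tools::md5sum(f))
}

#' Run the hemispheric-asymmetry pipeline
#'
#' Executes the stages `simulate` -> `parcellate` -> `track` -> `build_net`
#' -> `metrics` -> `stats` on the configured inputs, writing every
#' intermediate to `outdir` so any suffix of stages can be rerun from saved
#' intermediates with identical results. The simulate stage realizes the
#' configured phantom (tensor volume for the tractography stages) and the
#' simulated cohort (paired hemispheric networks for the statistics stages).
#' A provenance manifest records the config hash, seeds, package version,
#' and per-stage record counts; it contains no timestamps, so reruns with an
#' identical config produce identical manifests.
#'
#' @param config a [pipeline_config()] or path to its YAML file.
#' @param stages subset of stages to run (defaults to all, in order).
#' @return list with the stage outputs that were produced plus `manifest`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "parcellate", "track",
                                    "build_net", "metrics", "stats")) {
  cfg <- if (is.character(config)) load_config(config) else config
  validate_config(cfg)
  stages <- match.arg(stages, several.ok = TRUE)
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  result <- list()

  if ("simulate" %in% stages) {
    if (!is.null(cfg$phantom)) {
      ph <- make_tensor_phantom(do.call(phantom_spec, cfg$phantom))
      write_phantom(ph, file.path(out, "phantom"))
      write_mask_nifti(binary_mask(ph$fa$data >= cfg$fa_stop, ph$fa$affine),
                       file.path(out, "phantom", "parcel_mask.nii.gz"))
      result$phantom <- ph
      counts$phantom_bundle_voxels <- sum(ph$truth > 0)
    }
    if (!is.null(cfg$cohort)) {
      sim <- simulate_cohort(do.call(cohort_spec, cfg$cohort))
      write_cohort(sim, file.path(out, "cohort"))
      result$cohort <- sim
      counts$cohort_subjects <- nrow(sim$cohort)
    }
  }

  if ("parcellate" %in% stages) {
    ph <- result$phantom
    mask <- if (!is.null(ph))
      binary_mask(ph$fa$data >= cfg$fa_stop, ph$fa$affine)
    else read_mask_nifti(file.path(out, "phantom", "parcel_mask.nii.gz"))
    labels <- build_parcellation(mask, n_rois = cfg$n_rois, seed = cfg$seed)
    write_labels_nifti(labels, file.path(out, "template.nii.gz"))
    write_homologs(labels, file.path(out, "homologs.tsv"))
    result$labels <- labels
    counts$template_rois <- labels$n_rois
  }

  if ("track" %in% stages) {
    tensors <- if (!is.null(result$phantom)) result$phantom$tensors
    else read_tensor_nifti(file.path(out, "phantom", "tensors.nii.gz"),
                           file.path(out, "phantom", "mask.nii.gz"))
    sl <- fact_track(tensors, fa_stop = cfg$fa_stop,
                     angle_stop = cfg$angle_stop, step = cfg$step,
                     max_len = cfg$max_len)
    write_streamlines_jsonl(sl, file.path(out, "streamlines.jsonl"))
    result$streamlines <- sl
    counts$streamlines <- length(sl)
  }

  if ("build_net" %in% stages) {
    sl <- result$streamlines %||%
      read_streamlines_jsonl(file.path(out, "streamlines.jsonl"))
    labels <- result$labels %||%
      read_labels_nifti(file.path(out, "template.nii.gz"), cfg$n_rois,
                        "bilateral",
                        read_homologs(file.path(out, "homologs.tsv")))
    fa <- if (!is.null(result$phantom)) result$phantom$fa
    else read_fa_nifti(file.path(out, "phantom", "fa.nii.gz"))
    nets <- list(
      right = build_network(sl, labels, fa, "right", cfg$edge_min_fibers),
      left = build_network(sl, labels, fa, "left", cfg$edge_min_fibers))
    write_network(nets$right, file.path(out, "phantom_right.txt"))
    write_network(nets$left, file.path(out, "phantom_left.txt"))
    result$phantom_networks <- nets
    counts$phantom_edges_right <- sum(nets$right$weights > 0) / 2
  }

  if ("metrics" %in% stages) {
    # always consume the serialized cohort so that running the stages
    # separately is byte-identical to a one-shot run
    networks <- read_cohort(file.path(out, "cohort"))$networks
    metrics <- cohort_metrics(networks, cfg$distance_rule)
    mout <- metrics
    mout$value <- format(mout$value, digits = 17, trim = TRUE)
    utils::write.table(mout, file.path(out, "metrics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    aitab <- ai_table(metrics)
    aout <- aitab
    for (cl in c("m_right", "m_left", "ai"))
      aout[[cl]] <- format(aout[[cl]], digits = 17, trim = TRUE)
    utils::write.table(aout, file.path(out, "ai.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    result$metrics <- metrics
    result$ai <- aitab
    counts$metric_rows <- nrow(metrics)
  }

  if ("stats" %in% stages) {
    metrics <- utils::read.table(file.path(out, "metrics.tsv"), header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
    cohort_df <- utils::read.table(file.path(out, "cohort", "cohort.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
    battery <- run_full_battery(metrics, cohort_df,
                                battery_config(cfg$alpha, cfg$q,
                                               cfg$bonferroni_m))
    write_battery(battery, file.path(out, "stats"))
    result$battery <- battery
    counts$battery_group_tests <-
      if (is.null(battery$group_effects)) 0L else nrow(battery$group_effects)
  }

  manifest <- list(config_md5 = config_hash(cfg), seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("hemiconn")),
                   stages = stages, counts = counts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Demo pipeline configuration
#'
#' A small end-to-end configuration: a bilaterally asymmetric two-bundle
#' phantom for the imaging stages and a simulated cohort with a planted
#' AD-only rightward global asymmetry for the statistics stages.
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @export
demo_config <- function(outdir = tempfile("hemiconn_demo"), seed = 1L) {
  pipeline_config(
    outdir = outdir, seed = seed, n_rois = 6L,
    phantom = list(
      grid_shape = c(24L, 24L, 12L), voxel_size = c(1, 1, 1),
      bundles = list(
        bundle(c(6.5, -8, 0), c(6.5, 8, 0), radius = 1.6, fa = 0.7),
        bundle(c(-6.5, -8, 0), c(-6.5, 8, 0), radius = 1.6, fa = 0.7)),
      background_fa = 0.05, noise_sd = 0, seed = seed),
    cohort = list(
      n_per_group = c(NC = 20L, MCI = 20L, AD = 20L), n_nodes = 32L,
      density = 0.3,
      global_asym_delta = c(NC = 0, MCI = 0.01, AD = 0.03),
      subject_asym_sd = 0.012, seed = seed))
}
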