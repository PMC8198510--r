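# End-to-end pipeline: (simulate) -> segment -> measure -> identify ->
# spatial, with validated configuration, artifact writing and a run manifest.

#' Pipeline configuration
#'
#' Collects every stage's parameters, validates referenced paths up front,
#' and fixes the seed that makes the whole run deterministic. Voxel spacing
#' resolution order is: this config, then the stack's JSON sidecar; a
#' mismatch between an explicit config spacing and a sidecar is an error.
#'
#' @param out_dir Output directory for all artifacts.
#' @param stack_path Input TIFF stack; `NULL` simulates a phantom instead.
#' @param voxel_nm Spacing override (x, y, z) nm.
#' @param seed Integer seed governing simulation.
#' @param phantom Named list of [phantom_config()] overrides (used when
#'   simulating).
#' @param band Segmentation band preset name or [segmentation_band()].
#' @param denoise Apply bilateral in-plane denoising before thresholding.
#' @param denoise_radius,range_sd Denoiser parameters.
#' @param connectivity,min_voxels Component labeling parameters.
#' @param split_merged Apply [split_touching()] when fewer than
#'   `expected_objects` objects are found.
#' @param expected_objects Expected karyotype size (46).
#' @param strict Fail (after writing partial outputs) when the segmented
#'   object count differs from `expected_objects`.
#' @param sex Karyotype template, `"XY"` or `"XX"`.
#' @param weights Assignment cost weights, see [assign_karyotype()].
#' @param cutoff_nm Neighbor cutoff in nm.
#' @param reference_path Optional custom reference karyotype CSV.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            stack_path = NULL,
                            voxel_nm = NULL,
                            seed = 42L,
                            phantom = list(),
                            band = "medium",
                            denoise = FALSE,
                            denoise_radius = 2,
                            range_sd = 300,
                            connectivity = 26,
                            min_voxels = NULL,
                            split_merged = FALSE,
                            expected_objects = 46L,
                            strict = TRUE,
                            sex = c("XY", "XX"),
                            weights = c(volume = 1, length = 1, ci = 0.5),
                            cutoff_nm = 250,
                            reference_path = NULL) {
  sex <- match.arg(sex)
  if (!is.null(stack_path) && !file.exists(stack_path)) {
    stop("stack_path does not exist: ", stack_path)
  }
  if (!is.null(reference_path) && !file.exists(reference_path)) {
    stop("reference_path does not exist: ", reference_path)
  }
  if (!is.null(voxel_nm)) voxel_nm <- check_spacing(voxel_nm)
  cfg <- list(out_dir = out_dir, stack_path = stack_path,
              voxel_nm = voxel_nm, seed = as.integer(seed),
              phantom = phantom, band = band, denoise = denoise,
              denoise_radius = denoise_radius, range_sd = range_sd,
              connectivity = connectivity, min_voxels = min_voxels,
              split_merged = split_merged,
              expected_objects = as.integer(expected_objects),
              strict = strict, sex = sex, weights = weights,
              cutoff_nm = cutoff_nm, reference_path = reference_path)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when no input stack is given), segment, measure,
#' identify and spatial stages, writing every artifact (TIFF stacks, CSV
#' tables, JSON reports) plus a run manifest with the effective config, seed,
#' package version and stage timings into `config$out_dir`. Any stage error
#' aborts the run after the manifest is written; artifacts of completed
#' stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(config$out_dir,
                                          "pipeline_config.yaml"))
  manifest <- list(
    package = "karyo3d",
    version = as.character(utils::packageVersion("karyo3d")),
    seed = config$seed,
    config = serializable_config(config),
    stages = list()
  )
  t_all <- proc.time()[["elapsed"]]
  bundle <- list()
  write_manifest <- function() {
    manifest$elapsed_s <- round(proc.time()[["elapsed"]] - t_all, 3)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(
        status = "error", message = conditionMessage(e),
        elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  reference <- load_reference(config$reference_path)

  if (is.null(config$stack_path)) {
    bundle$phantom <- run_stage("simulate", function() {
      ph_args <- config$phantom
      ph_args$seed <- config$seed
      if (!is.null(config$voxel_nm)) ph_args$voxel_nm <- config$voxel_nm
      ph_args$karyotype <- config$sex
      ph <- generate_phantom(do.call(phantom_config, ph_args), reference)
      write_phantom(ph, config$out_dir)
      ph
    })
    stack <- bundle$phantom$stack
  } else {
    stack <- run_stage("read", function() {
      st <- read_stack(config$stack_path, config$voxel_nm)
      if (!is.null(config$voxel_nm) &&
          !isTRUE(all.equal(unname(st$voxel_nm), unname(config$voxel_nm)))) {
        stop("voxel spacing mismatch between config and sidecar metadata")
      }
      st
    })
  }

  bundle$labels <- run_stage("segment", function() {
    lab <- segment_stack(stack, band = config$band,
                         denoise = config$denoise,
                         connectivity = config$connectivity,
                         min_voxels = config$min_voxels,
                         expected_objects = NA,
                         spatial_radius = config$denoise_radius,
                         range_sd = config$range_sd)
    if (config$split_merged &&
        attr(lab, "n_objects") < config$expected_objects) {
      lab <- split_touching(lab)
    }
    write_labels(lab, file.path(config$out_dir, "segmented_labels.tif"))
    k <- attr(lab, "n_objects")
    if (config$strict && k != config$expected_objects) {
      stop("segmentation produced ", k, " objects, expected ",
           config$expected_objects, " (strict mode)")
    }
    lab
  })

  bundle$morphometry <- run_stage("measure", function() {
    morph <- measure_chromosomes(bundle$labels)
    utils::write.csv(as.data.frame(morph),
                     file.path(config$out_dir, "morphometry.csv"),
                     row.names = FALSE)
    morph
  })

  bundle$assignment <- run_stage("identify", function() {
    asg <- assign_karyotype(bundle$morphometry, reference,
                            weights = config$weights, sex = config$sex)
    utils::write.csv(as.data.frame(asg),
                     file.path(config$out_dir, "assignment.csv"),
                     row.names = FALSE)
    val <- validate_assignment(asg, bundle$morphometry, reference)
    jsonlite::write_json(
      list(slope = val$slope, intercept = val$intercept,
           r_squared = val$r_squared,
           outliers = val$outliers),
      file.path(config$out_dir, "validation.json"),
      auto_unbox = TRUE, digits = NA)
    attr(asg, "validation") <- val
    asg
  })

  bundle$spatial <- run_stage("spatial", function() {
    rep <- spatial_report(bundle$labels, bundle$morphometry,
                          bundle$assignment, reference,
                          cutoff_nm = config$cutoff_nm)
    utils::write.csv(rep$chromosomes,
                     file.path(config$out_dir, "spatial.csv"),
                     row.names = FALSE)
    nm <- rep$neighbor_map$matrix * 1L
    utils::write.csv(data.frame(name = rownames(nm), nm, check.names = FALSE),
                     file.path(config$out_dir, "neighbor_matrix.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(rep$regressions, list(cutoff_nm = rep$cutoff_nm)),
      file.path(config$out_dir, "regressions.json"),
      auto_unbox = TRUE, digits = NA)
    rep
  })

  write_manifest()
  invisible(bundle)
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$voxel_nm <- if (is.null(cfg$voxel_nm)) NULL else unname(cfg$voxel_nm)
  cfg$weights <- as.list(cfg$weights)
  if (inherits(cfg$band, "segmentation_band")) cfg$band <- unclass(cfg$band)
  cfg
}

#' Read / write a pipeline configuration file
#'
#' Configurations serialise to YAML or JSON (chosen by file extension), so a
#' run can be reproduced from the `pipeline_config.yaml` it echoes.
#'
#' @param config A [pipeline_config()].
#' @param path File ending in `.yaml`, `.yml` or `.json`.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a validated [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- serializable_config(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    stop("unsupported config extension: .", ext)
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: .", ext)
  }
  if (!is.null(cfg$weights)) cfg$weights <- unlist(cfg$weights)
  if (is.list(cfg$band)) {
    cfg$band <- segmentation_band(cfg$band$name, cfg$band$min_intensity,
                                  cfg$band$max_intensity)
  }
  do.call(pipeline_config, cfg)
}
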