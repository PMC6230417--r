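#' Default stage parameters of the measurement pipeline
#'
#' One place holding every documented default: the liver-segmentation
#' spread multiplier and closing radius, the texture window and
#' quantization, the classifier architecture and training schedule, the
#' decision threshold and clean-up radii, and the lesion connectivity.
#'
#' @return Nested list of defaults; see the vignette for the rationale of
#'   each value.
#' @export
pipeline_defaults <- function() {
  list(
    liver = list(k = 2.5, closing_radius_vox = 2L, connectivity = 26L),
    features = list(window = 11L, levels = 32L, hu_window = c(-100, 300)),
    classifier = list(hidden = c(16L, 8L), learning_rate = 0.5,
                      epochs = 1500L, threshold = 0.5),
    tumor_morphology = list(closing_radius_vox = 1L, opening_radius_vox = 1L),
    measure = list(connectivity = 26L, max_targets = 2L,
                   min_diameter_cm = 1.0)
  )
}

.merge_defaults <- function(user, defaults) {
  if (is.null(user)) return(defaults)
  for (nm in names(defaults)) {
    if (is.list(defaults[[nm]])) {
      user[[nm]] <- .merge_defaults(user[[nm]], defaults[[nm]])
    } else if (is.null(user[[nm]])) {
      user[[nm]] <- defaults[[nm]]
    }
  }
  user
}

#' Run the full response-assessment pipeline
#'
#' Chains liver segmentation, tumor segmentation and response measurement
#' for a pre/post pair and writes every stage product into `out_dir`:
#' liver and tumor masks (NIfTI), the lesion inventories (CSV), the
#' response record (`record.json`) and a parameter log (`log.json`)
#' recording every default in effect. Stages whose output files already
#' exist are resumed (loaded, not recomputed); the run is deterministic
#' given the config seed, so a rerun in a fresh directory is
#' byte-identical.
#'
#' The config is a nested list (or path to a YAML file) with either a
#' `phantom:` block (inputs are generated; the classifier is trained on an
#' independent training phantom) or an `inputs:` block with paths
#' `pre_volume`, `post_volume`, `seed_slice`, `seed_mask` (NIfTI of the
#' seeded slice region) and `model` (classifier JSON). Stage parameter
#' blocks (`liver`, `features`, `classifier`, `tumor_morphology`,
#' `measure`) override [pipeline_defaults()].
#'
#' @param config nested list or YAML file path.
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return The [measure_response()] record, invisibly, with attribute
#'   `paths` naming the stage outputs.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop_ctb("run_pipeline: config file not found: ", config,
               class = "ctb_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) {
    stop_ctb("run_pipeline: no output directory given",
             class = "ctb_validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  par <- .merge_defaults(config, pipeline_defaults())
  seed <- par$seed %||% 1L
  pth <- function(f) file.path(out_dir, f)
  log <- list(seed = seed, parameters = par[c("liver", "features",
                                              "classifier",
                                              "tumor_morphology",
                                              "measure")])

  stage <- function(name, files, producer, loader) {
    if (all(file.exists(vapply(files, pth, character(1))))) {
      loader()
    } else {
      producer()
    }
  }

  # --- inputs ---
  if (!is.null(par$phantom)) {
    ph_args <- par$phantom
    ph_args$seed <- ph_args$seed %||% seed
    ph <- make_phantom(do.call(phantom_config, ph_args))
    tr_args <- ph_args
    tr_args$seed <- seed + 1000L
    training_ph <- make_phantom(do.call(phantom_config, tr_args))
    pre_vol <- ph$pre; post_vol <- ph$post
    sd2 <- phantom_seed_slice(ph)
    seed_slice <- sd2$slice; seed_mask_2d <- sd2$mask
    model_file <- pth("model.json")
    model <- stage("model", "model.json", function() {
      m <- train_phantom_classifier(
        training_ph, window = par$features$window,
        levels = par$features$levels, hu_window = par$features$hu_window,
        seed = seed, hidden = par$classifier$hidden,
        learning_rate = par$classifier$learning_rate,
        epochs = par$classifier$epochs)
      save_classifier(m, model_file)
      m
    }, function() load_classifier(model_file))
    if (!file.exists(pth("pre.nii.gz"))) {
      write_volume(pre_vol, pth("pre.nii.gz"))
      write_volume(post_vol, pth("post.nii.gz"))
      write_mask(ph$truth$tumor_mask_pre, pth("truth_tumor_pre.nii.gz"))
      write_mask(ph$truth$tumor_mask_post, pth("truth_tumor_post.nii.gz"))
    }
    log$phantom <- list(config = unclass(ph$config),
                        truth = ph$truth[c("v_pre_cm3", "v_post_cm3",
                                           "d_pre_hu", "d_post_hu",
                                           "delta_v_pct", "delta_d_pct")])
  } else if (!is.null(par$inputs)) {
    inp <- par$inputs
    for (f in c("pre_volume", "post_volume", "seed_mask", "model")) {
      if (is.null(inp[[f]]) || !file.exists(inp[[f]])) {
        stop_ctb("run_pipeline: stage `segment-tumors` inputs incomplete: ",
                 "missing ", f, class = "ctb_io_error")
      }
    }
    pre_vol <- read_volume(inp$pre_volume)
    post_vol <- read_volume(inp$post_volume)
    seed_slice <- inp$seed_slice
    seed_mask_2d <- read_mask(inp$seed_mask)$data[seed_slice, , ]
    model <- load_classifier(inp$model)
  } else {
    stop_ctb("run_pipeline: config needs a `phantom` or `inputs` block",
             class = "ctb_validation_error")
  }

  # --- liver segmentation ---
  liver_of <- function(vol, file) {
    stage(file, file, function() {
      m <- segment_liver(vol, seed_slice, seed_mask_2d, k = par$liver$k,
                         closing_radius_vox = par$liver$closing_radius_vox,
                         connectivity = par$liver$connectivity)
      write_mask(m, pth(file))
      m
    }, function() read_mask(pth(file), reference = vol))
  }
  liver_pre <- liver_of(pre_vol, "liver_pre.nii.gz")
  liver_post <- liver_of(post_vol, "liver_post.nii.gz")
  g <- attr(liver_pre, "gmm")
  if (!is.null(g)) {
    log$liver_gmm_pre <- list(weights = g$weights, means = g$means,
                              variances = g$variances,
                              range = unclass(attr(liver_pre, "range")))
  }

  # --- tumor segmentation ---
  tumor_of <- function(vol, liver_mask, file) {
    stage(file, file, function() {
      m <- segment_tumors(
        vol, liver_mask, model, window = par$features$window,
        levels = par$features$levels, hu_window = par$features$hu_window,
        threshold = par$classifier$threshold,
        closing_radius_vox = par$tumor_morphology$closing_radius_vox,
        opening_radius_vox = par$tumor_morphology$opening_radius_vox)
      write_mask(m, pth(file))
      m
    }, function() read_mask(pth(file), reference = vol))
  }
  tumor_pre <- tumor_of(pre_vol, liver_pre, "tumor_pre.nii.gz")
  tumor_post <- tumor_of(post_vol, liver_post, "tumor_post.nii.gz")

  # --- measurement ---
  rec <- measure_response(tumor_pre, tumor_post, pre_vol, post_vol,
                          connectivity = par$measure$connectivity,
                          max_targets = par$measure$max_targets,
                          min_diameter_cm = par$measure$min_diameter_cm)
  write.csv(rec$pre$lesions, pth("lesions_pre.csv"), row.names = FALSE)
  write.csv(rec$post$lesions, pth("lesions_post.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(delta_volume_pct = rec$delta_volume_pct,
         delta_density_pct = rec$delta_density_pct,
         delta_size_pct = rec$delta_size_pct,
         combined_pct = rec$combined_pct,
         recist_category = rec$recist_category,
         progression_group = rec$progression_group,
         values = rec$values),
    pth("record.json"), digits = NA, auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(log, pth("log.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  attr(rec, "paths") <- list(
    record = pth("record.json"), log = pth("log.json"),
    liver = c(pth("liver_pre.nii.gz"), pth("liver_post.nii.gz")),
    tumor = c(pth("tumor_pre.nii.gz"), pth("tumor_post.nii.gz")))
  invisible(rec)
}
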