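#' Pipeline configuration
#'
#' Assembles and validates every stage's parameters with documented defaults.
#' `read_pipeline_config()` loads the same structure from a YAML file; any
#' field not present keeps its default.
#'
#' @param seed master seed; the study seed and the split seed derive from it.
#' @param class_counts,image_shape,background see [study_config()].
#' @param sigma,low_frac,high_frac preprocessing parameters, see
#'   [preprocess_image()].
#' @param roi_size ROI side length (default 40).
#' @param methods feature methods to run, subset of
#'   `c("glcm", "glrlm", "wavelet")`.
#' @param glcm_d,glcm_angles,G co-occurrence parameters (G is shared with the
#'   run-length extractor).
#' @param wavelet_levels decomposition depth (default 3).
#' @param train_fraction,kernel,C,gamma classifier parameters.
#' @param positive_classes labels forming the positive class of the binary
#'   task (default: the three lesion classes, i.e. lesion-vs-normal).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            class_counts = c(abscess = 73, cyst = 52,
                                             tumor = 27, normal = 40),
                            image_shape = c(400, 800),
                            background = background_defaults(),
                            sigma = 1, low_frac = 0.01, high_frac = 0.01,
                            roi_size = 40L,
                            methods = c("glcm", "glrlm", "wavelet"),
                            glcm_d = 1L, glcm_angles = c(0, 45, 90, 135),
                            G = 8L, wavelet_levels = 3L,
                            train_fraction = 2 / 3,
                            kernel = "rbf", C = 1, gamma = NULL,
                            positive_classes = c("cyst", "tumor", "abscess")) {
  bad <- setdiff(methods, c("glcm", "glrlm", "wavelet"))
  if (length(bad)) stop("unknown feature method(s): ", paste(bad, collapse = ", "))
  if (!kernel %in% c("rbf", "linear")) stop("unknown kernel: ", kernel)
  if (roi_size < 2L) stop("roi_size must be >= 2")
  cfg <- list(seed = as.integer(seed), class_counts = class_counts,
              image_shape = image_shape, background = background,
              sigma = sigma, low_frac = low_frac, high_frac = high_frac,
              roi_size = as.integer(roi_size), methods = methods,
              glcm_d = glcm_d, glcm_angles = glcm_angles, G = as.integer(G),
              wavelet_levels = wavelet_levels,
              train_fraction = train_fraction, kernel = kernel, C = C,
              gamma = gamma, positive_classes = positive_classes)
  # a study_config() call validates the simulation block
  study_config(class_counts, image_shape, background, seed)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file; top-level keys match the arguments above.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$class_counts)) y$class_counts <- unlist(y$class_counts)
  if (!is.null(y$image_shape)) y$image_shape <- as.integer(unlist(y$image_shape))
  if (!is.null(y$background)) y$background <- utils::modifyList(background_defaults(), y$background)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Feature extraction over a set of ROI patches
#'
#' @param patches named list of square integer patches.
#' @param labels character vector parallel to `patches`.
#' @param method `"glcm"`, `"glrlm"` or `"wavelet"`.
#' @param config a [pipeline_config()] supplying the method parameters.
#' @return a [feature_table()].
#' @export
extract_features <- function(patches, labels, method, config = pipeline_config()) {
  fv <- switch(method,
    glcm = function(p) glcm_feature_vector(p, d = config$glcm_d,
                                           angles = config$glcm_angles,
                                           G = config$G),
    glrlm = function(p) glrlm_feature_vector(p, G = config$G),
    wavelet = function(p) wavelet_feature_vector(p, levels = config$wavelet_levels),
    stop("unknown feature method: ", method))
  mat <- t(vapply(patches, fv, fv(patches[[1]])))
  feature_table(cbind(data.frame(image_id = names(patches), label = labels,
                                 stringsAsFactors = FALSE),
                      as.data.frame(mat)),
                method = method)
}

#' Run the full pipeline: simulate, preprocess, extract, classify, evaluate
#'
#' Executes every stage on the synthetic study described by `config` and
#' (optionally) writes each intermediate artifact to `out_dir` so every
#' stage is independently inspectable: simulated PNGs + annotation CSV,
#' preprocessed PNGs, ROI PNGs, one feature CSV per method, the fitted model
#' JSONs, per-method ROC CSVs, and a combined `report.json` with the
#' method-comparison table. Deterministic under `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional artifact directory.
#' @param quiet suppress per-stage messages.
#' @return list with `evaluations` (per method), `comparison` (data frame),
#'   `features` (per-method tables) and `annotations`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  art <- function(sub) {
    if (is.null(out_dir)) return(NULL)
    d <- file.path(out_dir, sub)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }

  say("[simulate] seed=%d, %d images", config$seed, sum(config$class_counts))
  study <- generate_study(study_config(config$class_counts, config$image_shape,
                                       config$background, config$seed),
                          out_dir = art("images"))
  ann <- study$annotations

  say("[preprocess] sigma=%g, stretch tails %g/%g", config$sigma,
      config$low_frac, config$high_frac)
  pre <- lapply(study$images, preprocess_image, sigma = config$sigma,
                low_frac = config$low_frac, high_frac = config$high_frac)
  if (!is.null(out_dir)) {
    d <- art("preprocessed")
    for (id in names(pre)) write_gray_png(pre[[id]], file.path(d, paste0(id, ".png")))
  }

  say("[extract-roi] size=%d", config$roi_size)
  patches <- lapply(seq_len(nrow(ann)), function(i) {
    extract_roi(pre[[ann$image_id[i]]],
                c(ann$center_row[i], ann$center_col[i]), config$roi_size)
  })
  names(patches) <- ann$image_id
  if (!is.null(out_dir)) {
    d <- art("rois")
    for (id in names(patches)) {
      write_gray_png(patches[[id]], file.path(d, paste0(id, "_roi.png")))
    }
  }

  features <- list()
  evaluations <- list()
  for (m in config$methods) {
    say("[features] method=%s", m)
    ft <- extract_features(patches, ann$label, m, config)
    features[[m]] <- ft
    if (!is.null(out_dir)) {
      utils::write.csv(ft, file.path(out_dir, sprintf("features_%s.csv", m)),
                       row.names = FALSE, quote = FALSE)
    }
    say("[train/evaluate] method=%s, split=%g, kernel=%s", m,
        config$train_fraction, config$kernel)
    ev <- evaluate_method(ft, train_fraction = config$train_fraction,
                          seed = config$seed, kernel = config$kernel,
                          C = config$C, gamma = config$gamma,
                          positive_classes = config$positive_classes)
    evaluations[[m]] <- ev
    if (!is.null(out_dir)) {
      save_model(ev$model, file.path(out_dir, sprintf("model_%s.json", m)))
      utils::write.csv(ev$roc$points, file.path(out_dir, sprintf("roc_%s.csv", m)),
                       row.names = FALSE, quote = FALSE)
    }
  }

  comparison <- compare_methods(evaluations)
  if (!is.null(out_dir)) {
    rep <- lapply(evaluations, function(ev) {
      c(ev$report[c("AC", "MCC", "SN", "SP", "PPV")],
        list(full = ev$report$full, AUC = ev$roc$auc,
             confusion = unclass(ev$report$confusion)))
    })
    jsonlite::write_json(list(seed = config$seed, report = rep),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  say("[done] methods: %s", paste(config$methods, collapse = ", "))
  list(evaluations = evaluations, comparison = comparison,
       features = features, annotations = ann)
}
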