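# End-to-end orchestration: spectra ingestion/simulation -> wavelength
# crop -> denoise -> PCA -> train/test split -> three classifiers ->
# evaluation report, driven by one config with explicit seeds.

#' Pipeline configuration
#'
#' Bundles every stage's settings. Exactly one input source must be
#' given: a [synthetic_config()] (`synthetic`), a directory of ENVI cube
#' triples (`cube_dir`: per sample `<name>.hdr`, `<name>_white.hdr`,
#' `<name>_dark.hdr`, class parsed from a leading `c<k>_` in the name), or
#' a delimited spectra file (`spectra_file`). All seeds are explicit; no
#' wall-clock seeding anywhere.
#'
#' @param synthetic a [synthetic_config()], or a list of its arguments.
#' @param cube_dir directory of calibrated-ready ENVI cubes.
#' @param spectra_file delimited spectra table (see [read_spectra()]).
#' @param window wavelength crop window in nm (`NULL` to skip).
#' @param band_nm segmentation wavelength for cube input.
#' @param denoise list `(family, level)` for [denoise_spectra()], or
#'   `NULL` to skip.
#' @param split_ratio,split_seed stratified split settings.
#' @param pca_k components for the exploratory PCA (`NULL` skips PCA).
#' @param models character subset of `c("plsda", "svm", "cnn")`; empty
#'   stops the pipeline after PCA.
#' @param cnn_epochs training epochs for the CNN stage (default: the
#'   architecture's 800).
#' @param model_seed seed for model training (CNN init/shuffle, SVM inner
#'   CV).
#' @param outdir output directory (created if missing).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, cube_dir = NULL,
                            spectra_file = NULL, window = c(875, 1546),
                            band_nm = 1019, denoise = list(family = "db6",
                                                           level = 3L),
                            split_ratio = c(4, 1), split_seed = 1L,
                            pca_k = 10L,
                            models = c("plsda", "svm", "cnn"),
                            cnn_epochs = NULL, model_seed = 1L,
                            outdir = tempfile("herbspec_run_")) {
  sources <- !vapply(list(synthetic, cube_dir, spectra_file), is.null, TRUE)
  if (sum(sources) != 1L)
    stopf("exactly one input source (synthetic, cube_dir, spectra_file) required")
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config"))
    synthetic <- do.call(synthetic_config, synthetic)
  if (length(models)) models <- match.arg(models, several.ok = TRUE)
  structure(list(synthetic = synthetic, cube_dir = cube_dir,
                 spectra_file = spectra_file, window = window,
                 band_nm = band_nm, denoise = denoise,
                 split_ratio = split_ratio,
                 split_seed = as.integer(split_seed), pca_k = pca_k,
                 models = models, cnn_epochs = cnn_epochs,
                 model_seed = as.integer(model_seed), outdir = outdir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file with [pipeline_config()] fields; a `synthetic`
#'   object is interpreted as [synthetic_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$synthetic)) cfg$synthetic <- as.list(cfg$synthetic)
  if (!is.null(cfg$denoise)) cfg$denoise <- as.list(cfg$denoise)
  do.call(pipeline_config, cfg)
}

ingest_cube_dir <- function(dir, band_nm) {
  headers <- list.files(dir, pattern = "\\.hdr$", full.names = TRUE)
  headers <- headers[!grepl("_(white|dark)\\.hdr$", headers)]
  if (!length(headers)) stopf("no sample cubes found in '%s'", dir)
  rows <- list()
  labels <- integer(0)
  wl <- NULL
  for (h in sort(headers)) {
    stem <- sub("\\.hdr$", "", h)
    name <- basename(stem)
    lab <- suppressWarnings(as.integer(sub("^c(\\d+)_.*$", "\\1", name)))
    raw <- read_envi(h, kind = "raw_counts")
    white <- read_envi(paste0(stem, "_white.hdr"), kind = "raw_counts")
    dark <- read_envi(paste0(stem, "_dark.hdr"), kind = "raw_counts")
    refl <- calibrate(raw, white$values, dark$values)
    mask <- threshold_mask(select_band(refl, band_nm))
    px <- extract_pixel_spectra(refl, mask)
    rows[[length(rows) + 1L]] <- mean_spectrum(px)
    labels <- c(labels, lab)
    wl <- refl$wavelengths
  }
  spectra_table(do.call(rbind, rows), wl,
                labels = if (anyNA(labels)) NULL else labels)
}

#' Run the full discrimination pipeline
#'
#' Executes ingest/simulate, wavelength cropping, wavelet denoising, PCA,
#' the stratified split, training of the requested classifiers, and the
#' evaluation report, writing every artefact plus a JSON manifest to the
#' config's output directory. Re-running with the same config reproduces
#' the outputs (all randomness is seeded).
#'
#' @param config a [pipeline_config()].
#' @return the manifest (named list), invisibly with class
#'   `pipeline_manifest`; written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("herbspec")),
                   r_version = R.version.string,
                   seeds = list(split = config$split_seed,
                                model = config$model_seed),
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$error <<- list(stage = name, message = conditionMessage(e))
      write_manifest(manifest, config$outdir)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    res
  }

  table <- stage("ingest", {
    if (!is.null(config$synthetic)) simulate_spectra_table(config$synthetic)
    else if (!is.null(config$cube_dir))
      ingest_cube_dir(config$cube_dir, config$band_nm)
    else read_spectra(config$spectra_file)
  })
  manifest$stages$ingest <- list(n_samples = nrow(table$X),
                                 n_bands = ncol(table$X))

  if (!is.null(config$window)) {
    table <- stage("crop", crop_wavelengths(table, config$window[1],
                                            config$window[2]))
    manifest$stages$crop <- list(window = config$window,
                                 n_bands = ncol(table$X))
  }
  if (!is.null(config$denoise)) {
    table <- stage("denoise",
                   denoise_spectra(table, family = config$denoise$family,
                                   level = config$denoise$level))
    manifest$stages$denoise <- config$denoise
  }
  write_spectra(table, file.path(config$outdir, "spectra.csv"))

  if (!is.null(config$pca_k)) {
    pca <- stage("pca", spectra_pca(table, k = min(config$pca_k,
                                                   nrow(table$X) - 1L,
                                                   ncol(table$X))))
    utils::write.csv(pca$scores, file.path(config$outdir, "pca_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(pca$loadings,
                     file.path(config$outdir, "pca_loadings.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(component = seq_along(pca$explained_pct),
                                explained_pct = pca$explained_pct),
                     file.path(config$outdir, "pca_explained.csv"),
                     row.names = FALSE)
    manifest$stages$pca <- list(k = pca$k,
                                explained_pct = round(pca$explained_pct, 4))
  }

  if (!length(config$models)) {
    manifest$stages$stopped_after <- "pca"
    manifest$note <- "no model specs given; pipeline stopped after PCA"
    write_manifest(manifest, config$outdir)
    return(invisible(structure(manifest, class = "pipeline_manifest")))
  }

  split <- stage("split", stratified_split(table$labels,
                                           ratio = config$split_ratio,
                                           seed = config$split_seed))
  jsonlite::write_json(list(train_rows = split$train_rows,
                            test_rows = split$test_rows,
                            seed = split$seed),
                       file.path(config$outdir, "split.json"))
  manifest$stages$split <- list(n_train = length(split$train_rows),
                                n_test = length(split$test_rows),
                                ratio = config$split_ratio)

  Xtr <- table$X[split$train_rows, , drop = FALSE]
  ytr <- table$labels[split$train_rows]
  models <- list()
  for (m in config$models) {
    models[[m]] <- stage(paste0("train_", m), switch(m,
      plsda = fit_plsda(Xtr, ytr),
      svm = fit_svm_rbf(Xtr, ytr, seed = config$model_seed),
      cnn = fit_cnn(Xtr, ytr,
                    spec = cnn_spec(n_classes = max(table$labels) + 1L,
                                    seed = config$model_seed),
                    epochs = config$cnn_epochs)))
    saveRDS(models[[m]], file.path(config$outdir,
                                   sprintf("model_%s.rds", m)))
  }
  manifest$stages$train <- lapply(models, function(mo) switch(mo$kind,
    plsda = list(ncomp = mo$ncomp),
    svm_rbf = list(c = mo$c, g = mo$g, cv_accuracy = mo$cv_accuracy),
    cnn = list(epochs = length(mo$history$loss),
               best_epoch = mo$history$best_epoch)))

  report <- stage("evaluate", model_report(models, split, table))
  utils::write.csv(as.data.frame(report),
                   file.path(config$outdir, "report.csv"),
                   row.names = FALSE)
  writeLines(utils::capture.output(print(report)),
             file.path(config$outdir, "report.txt"))
  manifest$stages$evaluate <- list(rows = nrow(report))
  write_manifest(manifest, config$outdir)
  invisible(structure(manifest, class = "pipeline_manifest"))
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
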