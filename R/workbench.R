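# Experiment orchestration: configs, manifests, and a reproducible
# end-to-end pipeline over the package's stages.

#' Experiment configuration
#'
#' A fully serializable description of a pipeline run; re-running an
#' archived config reproduces the outputs of all deterministic stages.
#'
#' @param seed master seed for every stochastic stage.
#' @param n_characters number of corpus glyphs (<= 26 uses the letter
#'   corpus; more adds random glyphs).
#' @param repetitions repetitions per character.
#' @param misalign timeline-resampling misalignment on/off.
#' @param noise_sd observation-noise scale.
#' @param n_channels simulated channels.
#' @param loss `"mse"` or `"dilate"`.
#' @param decoder `"linear"`, `"lstm"`, or `"kalman"`.
#' @param epochs,lr training schedule.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, n_characters = 26L, repetitions = 3L,
                              misalign = TRUE, noise_sd = 1,
                              n_channels = 96L, loss = "dilate",
                              decoder = "linear", epochs = 150L, lr = 0.005) {
  structure(list(seed = as.integer(seed),
                 n_characters = as.integer(n_characters),
                 repetitions = as.integer(repetitions),
                 misalign = isTRUE(misalign), noise_sd = noise_sd,
                 n_channels = as.integer(n_channels), loss = loss,
                 decoder = decoder, epochs = as.integer(epochs), lr = lr),
            class = "experiment_config")
}

#' Write / read an experiment config as JSON
#'
#' @param config an [experiment_config()].
#' @param file path.
#' @return `read_config` returns the config; `write_config` the path,
#'   invisibly.
#' @export
write_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(experiment_config, raw)
}

config_hash <- function(config) {
  key <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1L)),
    sep = "=", collapse = ";")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(path, config, metrics, started) {
  manifest <- list(config = unclass(config),
                   config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("handbci")),
                   seed = config$seed,
                   metrics = metrics,
                   started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)  # atomic publish
  invisible(path)
}

#' Run the simulate-train-decode-recognize pipeline
#'
#' Builds the corpus, simulates a feature session, runs
#' leave-one-character-out cross-validation with the configured decoder and
#' loss, recognizes every decoded trajectory against the corpus library,
#' and (when `out_dir` is given) writes the per-trial metrics as CSV plus
#' an atomically-written JSON run manifest recording the config, its hash,
#' seeds, and summary metrics.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list of class `pipeline_run`: `config`, `cv` (the [crossval_loco()]
#'   result), `recognition_rate`, `metrics`, `manifest_path` (or `NA`).
#' @export
run_pipeline <- function(config = experiment_config(), out_dir = NULL) {
  started <- Sys.time()
  base <- letter_corpus()$templates
  templates <- if (config$n_characters <= 26L)
    base[seq_len(config$n_characters)]
  else c(base, lapply(seq_len(config$n_characters - 26L), function(k)
    random_glyph(derive_seed(config$seed, "pipeglyph", k),
                 n_strokes = 1L + (k %% 4L))))
  session <- simulate_session(templates,
                              encoder = make_linear_encoder(config$n_channels,
                                                            seed = config$seed),
                              repetitions = config$repetitions,
                              misalign = config$misalign,
                              noise_sd = config$noise_sd, seed = config$seed)
  cv <- crossval_loco(session,
                      loss = loss_spec(config$loss, zscore = FALSE),
                      cfg = train_config(epochs = config$epochs, lr = config$lr,
                                         seed = config$seed),
                      decoder = config$decoder)
  library <- build_library(templates)
  ids <- vapply(session$trials, `[[`, character(1L), "id")
  correct <- vapply(seq_along(session$trials), function(k)
    recognize(cv$decoded[[k]], library, truth = ids[k])$top1_correct,
    logical(1L))
  metrics <- list(mean_cc = mean(cv$metrics$cc),
                  mean_ndtw = mean(cv$metrics$ndtw),
                  recognition_rate = mean(correct))
  manifest_path <- NA_character_
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cv$metrics, file.path(out_dir, "trial_metrics.csv"),
                     row.names = FALSE)
    manifest_path <- write_manifest(file.path(out_dir, "manifest.json"),
                                    config, metrics, started)
  }
  structure(list(config = config, cv = cv,
                 recognition_rate = metrics$recognition_rate,
                 metrics = metrics, manifest_path = manifest_path),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    "Pipeline run (%s/%s, %s): mean CC %.3f, recognition rate %.1f%%\n",
    x$config$decoder, x$config$loss,
    if (x$config$misalign) "misaligned" else "aligned",
    x$metrics$mean_cc, 100 * x$metrics$recognition_rate))
  invisible(x)
}
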