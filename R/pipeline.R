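# MD5 of an R object's serialized form; provenance stamp for outputs.
obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Session manifest
#'
#' Describes one recording session: its condition, channel files, stimulus
#' protocol and analysis-config overrides. Channels reference CSV time
#' series (columns `time_s,value`) relative to the manifest directory.
#'
#' @param session_id Identifier string.
#' @param condition `"acute"`, `"chronic"` or `"sham"`.
#' @param channels Tibble with `path`, `modality` (one of `emg`,
#'   `root_ventral`, `root_dorsal`, `intracellular`, `calcium`), `rate_hz`,
#'   `units`.
#' @param stim A [stimulus_protocol()].
#' @param config Named list of analysis-config overrides.
#' @return A list of class `session_manifest`.
#' @export
session_manifest <- function(session_id, condition, channels, stim,
                             config = list()) {
  condition <- match.arg(condition, c("acute", "chronic", "sham"))
  mods <- c("emg", "root_ventral", "root_dorsal", "intracellular", "calcium")
  if (!all(channels$modality %in% mods)) {
    abort(sprintf("Channel modalities must be among: %s.",
                  paste(mods, collapse = ", ")), class = "spasm_error_config")
  }
  structure(
    list(session_id = session_id, condition = condition,
         channels = channels, stim = stim, config = config),
    class = "session_manifest"
  )
}

#' Write a synthetic session to disk
#'
#' One CSV per channel (`time_s,value`), a JSON manifest and a JSON
#' ground-truth file, the on-disk layout consumed by [run_pipeline()].
#'
#' @param session Output of [gen_spasm_session()].
#' @param dir Output directory (created if needed).
#' @param session_id,condition Manifest fields.
#' @param calcium Optional output of [gen_calcium_population()]; written as a
#'   wide per-cell trace CSV plus a JSON ROI table.
#' @return The manifest path, invisibly.
#' @export
write_spasm_session <- function(session, dir, session_id = "synthetic",
                                condition = "chronic", calcium = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_timeseries(session$emg, file.path(dir, "emg.csv"))
  write_timeseries(session$root, file.path(dir, "root.csv"))
  channels <- tibble::tibble(
    path = c("emg.csv", "root.csv"),
    modality = c("emg", "root_ventral"),
    rate_hz = c(ts_rate(session$emg), ts_rate(session$root)),
    units = c(ts_units(session$emg), ts_units(session$root))
  )
  if (!is.null(calcium)) {
    wide <- tidyr::pivot_wider(calcium$traces, id_cols = "time_s",
                               names_from = "cell_id", values_from = "raw_f")
    utils::write.csv(wide, file.path(dir, "calcium.csv"), row.names = FALSE)
    jsonlite::write_json(calcium$cells, file.path(dir, "rois.json"),
                         digits = NA)
    channels <- dplyr::bind_rows(channels, tibble::tibble(
      path = "calcium.csv", modality = "calcium",
      rate_hz = 1 / median(diff(wide$time_s)), units = "au"
    ))
  }
  gt <- session$ground_truth
  stim <- gt$stim
  manifest <- list(
    session_id = session_id, condition = condition,
    channels = channels,
    stim = list(pulse_times = stim$pulse_times,
                pulse_width_us = stim$pulse_width_us,
                frequency_hz = stim$frequency_hz,
                strength_t = stim$strength_t),
    config = list()
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(spikes = gt$spikes, units = gt$units,
         segmentation = as.list(gt$segmentation)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(file.path(dir, "manifest.json"))
}

#' Read a session manifest
#'
#' @param path Path to `manifest.json`.
#' @return A `session_manifest` with an attached base directory.
#' @export
read_session_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  stim <- stimulus_protocol(
    pulse_times = m$stim$pulse_times,
    pulse_width_us = m$stim$pulse_width_us,
    frequency_hz = m$stim$frequency_hz,
    strength_t = m$stim$strength_t
  )
  out <- session_manifest(m$session_id, m$condition,
                          tibble::as_tibble(m$channels), stim,
                          config = m$config %||% list())
  attr(out, "dir") <- dirname(path)
  out
}

#' Run the full analysis pipeline on a session
#'
#' Stages run in dependency order: the root channel is segmented first, then
#' motor units are detected and phenotyped on the EMG channel and calcium
#' peaks are normalized against the segmentation and fitted per cell class.
#' Each stage is isolated: a failure is logged and reported while the other
#' stages still run. Deterministic stages are bit-identical across re-runs;
#' the dip-test bootstrap and mixture fits take stage seeds derived from
#' `seed` by a fixed increment so every stage is independently reproducible.
#'
#' @param manifest A `session_manifest` (from [read_session_manifest()]) or a
#'   path to a session directory or manifest file.
#' @param seed Integer master seed.
#' @param min_duration Minimum recording span for phenotyping (s); the
#'   default accepts any span so short synthetic sessions classify.
#' @return A list of class `spasm_results`: `segmentation`, `units`,
#'   `spikes`, `peaks`, `fits`, `log` (tibble: stage, status, message) and
#'   `provenance` (seed, config hash, package version).
#' @export
run_pipeline <- function(manifest, seed = 1, min_duration = 0) {
  if (is.character(manifest)) {
    path <- if (dir.exists(manifest)) file.path(manifest, "manifest.json") else manifest
    manifest <- read_session_manifest(path)
  }
  dir <- attr(manifest, "dir") %||% "."
  log <- list()
  note <- function(stage, status, message = "") {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage, status = status,
                                              message = message)
  }
  res <- list(segmentation = NULL, units = NULL, spikes = NULL,
              peaks = NULL, fits = NULL)
  ch <- manifest$channels
  get_path <- function(modality) {
    p <- ch$path[ch$modality == modality]
    if (length(p)) file.path(dir, p[1]) else NULL
  }

  root_path <- get_path("root_ventral") %||% get_path("emg")
  seg <- NULL
  tryCatch({
    root <- read_timeseries(root_path)
    seg <- segment_epochs(root, manifest$stim)
    res$segmentation <- seg
    note("segment", "ok")
  }, error = function(e) note("segment", "error", conditionMessage(e)))

  emg_path <- get_path("emg")
  if (is.null(emg_path)) {
    note("emg", "skipped", "no emg channel")
  } else {
    tryCatch({
      emg <- read_timeseries(emg_path)
      gt_path <- file.path(dir, "ground_truth.json")
      templates <- if (file.exists(gt_path)) {
        u <- jsonlite::read_json(gt_path, simplifyVector = TRUE)$units
        tibble::tibble(unit_id = u$unit_id, amplitude = u$amplitude)
      } else {
        sp0 <- detect_spikes(emg)
        tibble::tibble(unit_id = "u01", amplitude = median(sp0$amplitude))
      }
      with_seed(seed + 1L, {
        mu <- analyze_motor_units(emg, templates, min_duration = min_duration)
        res$units <- mu$units
        res$spikes <- mu$spikes
      })
      note("emg", "ok")
    }, error = function(e) note("emg", "error", conditionMessage(e)))
  }

  ca_path <- get_path("calcium")
  if (is.null(ca_path)) {
    note("calcium", "skipped", "no calcium channel")
  } else if (is.null(seg) || !seg$spasm_detected) {
    note("calcium", "skipped", "no segmentation available")
  } else {
    tryCatch({
      wide <- utils::read.csv(ca_path, check.names = FALSE)
      traces <- tidyr::pivot_longer(wide, -"time_s", names_to = "cell_id",
                                    values_to = "raw_f")
      rois_path <- file.path(dir, "rois.json")
      cells <- if (file.exists(rois_path)) {
        tibble::as_tibble(jsonlite::read_json(rois_path, simplifyVector = TRUE))
      } else {
        tibble::tibble(cell_id = unique(traces$cell_id), cell_class = "eIN")
      }
      peaks <- recover_peak_times(traces, seg)
      peaks <- dplyr::left_join(peaks, cells, by = "cell_id")
      res$peaks <- peaks
      with_seed(seed + 2L, {
        res$fits <- purrr::map(
          split(peaks, peaks$cell_class),
          function(p) {
            g <- if (manifest$condition == "chronic") 2 else 1
            fit_peak_distribution(p, n_components = g,
                                  cell_class = p$cell_class[1],
                                  condition = manifest$condition)
          }
        )
      })
      note("calcium", "ok")
    }, error = function(e) note("calcium", "error", conditionMessage(e)))
  }

  res$log <- dplyr::bind_rows(log)
  res$provenance <- list(
    seed = seed,
    config_hash = obj_hash(manifest),
    package_version = as.character(utils::packageVersion("spasmpipe"))
  )
  res$ok <- !any(res$log$status == "error")
  class(res) <- "spasm_results"
  res
}

#' @export
print.spasm_results <- function(x, ...) {
  cat("spasmpipe pipeline results\n")
  print(x$log)
  invisible(x)
}
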