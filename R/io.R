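## Plain-text I/O for recordings, datasets and model checkpoints.
## CSV dialect: comma-separated, header row, '.' decimal.  EMG files
## carry channel columns ch1..ch32; angle files carry WFWE, PS, HGHO
## (degrees).  Checkpoints round-trip bit-exactly through RDS; a JSON
## export is provided for cross-tool interchange.

#' Read a recording from CSV
#'
#' @param path File path.
#' @param kind `"emg"` (expects 32 channel columns) or `"angles"`
#'   (expects 3 joint columns).
#' @param fs Sampling rate to attach (Hz); defaults to 500 for EMG and
#'   120 for angles.
#' @return An `emg_recording` or `angle_recording`.
#' @export
read_recording <- function(path, kind = c("emg", "angles"), fs = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_data("file not found: ", path)
  x <- as.matrix(utils::read.csv(path, check.names = FALSE))
  expected <- if (kind == "emg") 32L else 3L
  if (ncol(x) != expected)
    stop_data(path, ": expected ", expected, " ", kind, " columns, found ",
              ncol(x))
  if (!all(is.finite(x))) stop_data(path, ": non-finite values")
  if (kind == "emg") {
    emg_recording(x, fs = fs %||% 500, channel_ids = seq_len(32))
  } else {
    angle_recording(x, fs = fs %||% 120)
  }
}

#' Write a recording to CSV
#'
#' @param rec An `emg_recording` or `angle_recording`.
#' @param path Output path (refuses to overwrite unless `force`).
#' @param force Overwrite an existing file.
#' @return The path, invisibly.
#' @export
write_recording <- function(rec, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop_data(path, " exists; use force = TRUE to overwrite")
  if (inherits(rec, "emg_recording")) {
    m <- rec$samples
    colnames(m) <- paste0("ch", rec$channel_ids)
  } else if (inherits(rec, "angle_recording")) {
    m <- rec$angles
  } else stop_data("rec must be an emg_recording or angle_recording")
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Export a session's trials to per-trial CSV files
#'
#' Writes `emg_trialXX.csv` (time x 32, header ch1-ch32) and
#' `angles_trialXX.csv` (time x 3, header WFWE, PS, HGHO) per trial.
#'
#' @param session An `emg_session`.
#' @param dir Output directory (created if missing).
#' @param force Overwrite existing files.
#' @return Character vector of written paths, invisibly.
#' @export
write_session <- function(session, dir, force = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(session$trials)) {
    pe <- file.path(dir, sprintf("emg_trial%02d.csv", i))
    pa <- file.path(dir, sprintf("angles_trial%02d.csv", i))
    write_recording(session$trials[[i]]$emg, pe, force = force)
    write_recording(session$trials[[i]]$angles, pa, force = force)
    paths <- c(paths, pe, pa)
  }
  invisible(paths)
}

#' Save / load a model checkpoint
#'
#' `.rds` checkpoints round-trip bit-exactly (asserted in the test
#' suite); `.json` exports the parameter arrays and hyperparameters as
#' readable text for interchange with other tools.
#'
#' @param model A fitted `fpcnn`.
#' @param path Destination; format chosen by extension.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "fpcnn")) stop_config("model must be a fitted fpcnn")
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(model, path)
  } else if (ext == "json") {
    p <- model$params
    jsonlite::write_json(list(
      hyperparameters = list(n_filters = p$n_filters, win_len = p$win_len,
                             n_channels = p$n_channels, n_out = p$n_out,
                             use_conv_bias = p$use_conv_bias,
                             config = model$config),
      conv_filters = p$conv_filters, conv_bias = p$conv_bias,
      W = p$W, b = p$b), path, digits = NA, auto_unbox = TRUE)
  } else stop_config("unsupported checkpoint extension '", ext, "'")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    m <- readRDS(path)
    if (!inherits(m, "fpcnn")) stop_data(path, " is not an fpcnn checkpoint")
    m
  } else if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    p <- structure(list(
      conv_filters = as.matrix(j$conv_filters),
      conv_bias = if (isTRUE(j$hyperparameters$use_conv_bias))
        as.numeric(j$conv_bias) else NULL,
      W = as.matrix(j$W), b = as.numeric(j$b),
      n_filters = j$hyperparameters$n_filters,
      win_len = j$hyperparameters$win_len,
      n_channels = j$hyperparameters$n_channels,
      n_out = j$hyperparameters$n_out,
      use_conv_bias = isTRUE(j$hyperparameters$use_conv_bias)),
      class = "fpcnn_params")
    structure(list(params = p, loss_history = numeric(0),
                   config = j$hyperparameters$config, n_train = NA,
                   call = NULL), class = "fpcnn")
  } else stop_config("unsupported checkpoint extension '", ext, "'")
}
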