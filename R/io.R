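pad_str <- function(s, n) {
  s <- substr(s, 1, n)
  sprintf(paste0("%-", n, "s"), s)
}

#' Write a recording to EDF or CSV
#'
#' EDF output is single-channel (physical dimension uV) with 1-s data
#' records and 16-bit samples; a trailing partial record is padded with the
#' final sample value and the true sample count is stored in the reserved
#' header field so [read_ecog()] can trim it. CSV output has columns
#' `time_s`, `uv`.
#'
#' @param recording An [ecog_recording()].
#' @param path Output path; format inferred from the `.edf` / `.csv`
#'   extension unless `format` is given.
#' @param format `"EDF"` or `"CSV"`.
#' @return `path`, invisibly.
#' @export
write_ecog <- function(recording, path,
                       format = toupper(tools::file_ext(path))) {
  stopifnot(inherits(recording, "ecog_recording"))
  format <- match.arg(format, c("EDF", "CSV"))
  if (format == "CSV") {
    n <- length(recording$samples)
    readr::write_csv(
      tibble(time_s = (seq_len(n) - 1) / recording$sampling_rate,
             uv = recording$samples),
      path
    )
    return(invisible(path))
  }
  x <- recording$samples
  fs <- recording$sampling_rate
  spr <- round(fs)                    # samples per 1-s record
  n <- length(x)
  nrec <- ceiling(n / spr)
  if (nrec * spr > n) x <- c(x, rep(x[n], nrec * spr - n))
  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * 65535) - 32768)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_str("0", 8),
    pad_str(paste0("animal ", recording$animal_id), 80),
    pad_str("synthetic ECoG", 80),
    pad_str("01.01.26", 8), pad_str("00.00.00", 8),
    pad_str("512", 8),                       # header bytes: 256 * (1 + 1)
    pad_str(paste0("nsamples=", n), 44),
    pad_str(as.character(nrec), 8),
    pad_str("1", 8),
    pad_str("1", 4)
  )
  sig <- paste0(
    pad_str("ECoG", 16), pad_str("synthetic", 80), pad_str("uV", 8),
    pad_str(formatC(pmin_, digits = 6, format = "g"), 8),
    pad_str(formatC(pmax_, digits = 6, format = "g"), 8),
    pad_str("-32768", 8), pad_str("32767", 8),
    pad_str("none", 80), pad_str(as.character(spr), 8), pad_str("", 32)
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a single-channel recording from EDF or CSV
#'
#' EDF files must contain exactly one signal. CSV files need columns
#' `time_s` and `uv` with uniform timestamps (the sampling rate is
#' inferred); nonuniform timestamps are rejected.
#'
#' @param path Input path.
#' @param format `"EDF"` or `"CSV"` (inferred from the extension).
#' @param animal_id Optional identifier to attach.
#' @return An [ecog_recording()].
#' @export
read_ecog <- function(path, format = toupper(tools::file_ext(path)),
                      animal_id = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  format <- match.arg(format, c("EDF", "CSV"))
  if (format == "CSV") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("time_s", "uv") %in% names(df))) {
      abort("CSV must have columns time_s, uv.")
    }
    dt <- diff(df$time_s)
    if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-6)) {
      abort("Nonuniform timestamps: cannot infer a sampling rate.")
    }
    return(ecog_recording(df$uv, sampling_rate = 1 / dt[1],
                          animal_id = animal_id %||% "csv"))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  patient <- fld(hdr, 9, 80)
  reserved <- fld(hdr, 185, 44)
  nrec <- as.integer(fld(hdr, 237, 8))
  recdur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns != 1) {
    abort(sprintf("Expected a single-channel EDF; found %s signals.",
                  ifelse(is.na(ns), "unreadable", ns)))
  }
  sig <- readChar(con, 256, useBytes = TRUE)
  pmin_ <- as.numeric(fld(sig, 105, 8))
  pmax_ <- as.numeric(fld(sig, 113, 8))
  dmin <- as.numeric(fld(sig, 121, 8))
  dmax <- as.numeric(fld(sig, 129, 8))
  spr <- as.integer(fld(sig, 217, 8))
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr, nrec, recdur))) {
    abort("Corrupt EDF header.")
  }
  dig <- readBin(con, "integer", n = nrec * spr, size = 2, signed = TRUE,
                 endian = "little")
  if (length(dig) < nrec * spr) abort("Truncated EDF data section.")
  x <- pmin_ + (dig - dmin) / (dmax - dmin) * (pmax_ - pmin_)
  if (grepl("^nsamples=", reserved)) {
    n_true <- as.integer(sub("^nsamples=", "", reserved))
    if (!is.na(n_true) && n_true <= length(x)) x <- x[seq_len(n_true)]
  }
  aid <- animal_id %||% sub("^animal ", "", patient)
  ecog_recording(x, sampling_rate = spr / recdur, animal_id = aid)
}

#' Write / read the tabular artifacts
#'
#' Thin CSV wrappers for the pipeline's tables: stimulation logs, event
#' tables, feature matrices and trial pairs.
#'
#' @param x The tibble to write.
#' @param path CSV path.
#' @return The tibble (readers) or `path` invisibly (writers).
#' @export
write_stim_log <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_stim_log
#' @export
read_stim_log <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    delay_class = readr::col_character(),
                    condition = readr::col_character(),
                    triggered = readr::col_logical()
                  ))
}

#' @rdname write_stim_log
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_stim_log
#' @export
read_table_csv <- function(path) readr::read_csv(path, show_col_types = FALSE)

#' Ground-truth sidecar
#'
#' Writes the generator's ground truth as a flat CSV with columns
#' `kind` (`state` / `seizure` / `stim`), `start_s`, `end_s`, `label`,
#' `extra`.
#'
#' @param recording A generated [ecog_recording()].
#' @param path CSV path.
#' @export
write_ground_truth <- function(recording, path) {
  iv <- state_intervals(recording)
  ev <- seizure_events(recording)
  st <- stim_events(recording)
  out <- bind_rows(
    tibble(kind = "state", start_s = iv$start_s, end_s = iv$end_s,
           label = iv$state, extra = NA_character_),
    tibble(kind = "seizure", start_s = ev$onset_s, end_s = ev$offset_s,
           label = ev$role,
           extra = ifelse(is.na(ev$counterfactual_s), NA_character_,
                          sprintf("counterfactual=%.4f", ev$counterfactual_s))),
    tibble(kind = "stim", start_s = st$detection_time_s,
           end_s = st$light_on_s + st$light_duration_s,
           label = st$delay_class,
           extra = sprintf("triggered=%s", st$triggered))
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Save / load a classifier artifact
#'
#' The artifact embeds a format version, the class order and the feature
#' names; [load_state_classifier()] refuses artifacts whose feature names
#' do not match the package's feature set.
#'
#' @param model A `state_classifier`.
#' @param path Artifact path (`.rds`).
#' @export
save_state_classifier <- function(model, path) {
  stopifnot(inherits(model, "state_classifier"))
  saveRDS(list(format = "ictalloop/state_classifier/1", model = model), path)
  invisible(path)
}

#' @rdname save_state_classifier
#' @export
load_state_classifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ictalloop/state_classifier/1")) {
    abort("Not an ictalloop state_classifier artifact.")
  }
  if (!identical(obj$model$feature_names, feature_names())) {
    abort("Feature names in the artifact do not match this package version.")
  }
  obj$model
}
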