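# Trial IO. Two on-disk forms are supported:
#  * headered CSV (one column per channel, samples as rows, full-precision
#    "%.17g" values) with a JSON sidecar carrying fs and metadata -- this
#    round-trips bit-exactly;
#  * EDF (European Data Format), the conventional exchange format for EEG
#    recordings, with 16-bit quantisation -- this round-trips to within the
#    physical/digital scaling resolution.

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write an EEG trial to disk
#'
#' @param trial An [eeg_trial()].
#' @param path Output path; `.csv` writes the CSV + JSON-sidecar dialect,
#'   `.edf` writes a single-record EDF file.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(write_edf(trial, path))
  if (!grepl("\\.csv$", path)) stop("unsupported trial format: ", path)
  mat <- t(trial$data)  # samples x channels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(trial$channel_labels, collapse = ","), con)
  body <- apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(body, con)
  meta <- list(fs = trial$fs, channel_labels = as.list(trial$channel_labels),
               onset = trial$onset, true_target = trial$true_target,
               subject = trial$subject, session = trial$session,
               run = trial$run, units = "uV")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read an EEG trial from disk
#'
#' @param path Path to a `.csv` trial (its JSON sidecar must sit next to
#'   it) or an `.edf` file.
#' @param format `"auto"` (by extension), `"csv"`, or `"edf"`.
#' @return An [eeg_trial()].
#' @export
read_trial <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("trial file not found: ", path)
  if (format == "edf") return(read_edf(path))
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar '", sc,
         "': the CSV dialect stores fs and metadata there")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$fs))
    stop("sidecar '", sc, "' lacks the required field 'fs'")
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- t(as.matrix(df))
  labels <- colnames(df)
  if (!is.null(meta$channel_labels) &&
      !identical(unlist(meta$channel_labels), labels))
    stop("channel labels in sidecar disagree with the CSV header")
  nn <- function(x, d) if (is.null(x) || (length(x) == 1 && is.na(x))) d else x
  eeg_trial(mat, meta$fs, labels, onset = nn(meta$onset, 0),
            true_target = nn(meta$true_target, NA_integer_),
            subject = nn(meta$subject, NA), session = nn(meta$session, NA),
            run = nn(meta$run, NA))
}

# --- minimal EDF ----------------------------------------------------------

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = -width)
}

write_edf <- function(trial, path) {
  data <- trial$data
  nch <- nrow(data)
  m <- ncol(data)
  pmin_ <- floor(min(data, -1))
  pmax_ <- ceiling(max(data, 1))
  dmin <- -32768; dmax <- 32767
  dig <- round((data - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field("X X X X", 80),
    edf_field("Startdate X X X X", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 + 256 * nch, 8), edf_field("", 44),
    edf_field(1, 8), edf_field(format(m / trial$fs), 8), edf_field(nch, 4))
  sig <- paste0(
    paste(vapply(trial$channel_labels, edf_field, "", width = 16),
          collapse = ""),
    strrep(edf_field("", 80), nch),
    strrep(edf_field("uV", 8), nch),
    strrep(edf_field(pmin_, 8), nch), strrep(edf_field(pmax_, 8), nch),
    strrep(edf_field(dmin, 8), nch), strrep(edf_field(dmax, 8), nch),
    strrep(edf_field("", 80), nch),
    strrep(edf_field(m, 8), nch),
    strrep(edf_field("", 32), nch))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (ch in seq_len(nch))
    writeBin(as.integer(dig[ch, ]), con, size = 2L, endian = "little")
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header: version field is '",
                           version, "', expected '0'")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1) stop("malformed EDF header: signal count field")
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)  # transducer
  for (i in seq_len(nch)) rd(8)   # dimension
  pmin_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)  # prefilter
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)
  if (any(is.na(pmin_)) || any(is.na(spr)))
    stop("malformed EDF header: physical range or samples-per-record field")
  data <- matrix(0, nch, spr[1] * n_rec)
  for (r in seq_len(n_rec)) for (ch in seq_len(nch)) {
    dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                   endian = "little")
    data[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <-
      (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) * (pmax_[ch] - pmin_[ch]) +
      pmin_[ch]
  }
  fs <- spr[1] / dur
  eeg_trial(data, fs, labels)
}

# --- dataset manifests ----------------------------------------------------

#' Write a simulated dataset to a directory
#'
#' Writes every trial in the CSV + sidecar dialect plus a
#' `manifest.json` recording the plan and per-trial metadata, the layout
#' [read_manifest()] and the CLI consume.
#'
#' @param dataset A `ssmvep_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ssmvep_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  paths <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    paths[i] <- sprintf("trial_%04d.csv", man$trial[i])
    write_trial(dataset$trials[[i]], file.path(dir, paths[i]))
  }
  man$path <- paths
  obj <- list(format_version = 1L,
              plan = list(base = dataset$plan$base,
                          midpoints = dataset$plan$midpoints,
                          margin = dataset$plan$margin,
                          pairs = dataset$plan$pairs),
              fs = dataset$config$fs,
              trials = man)
  out <- file.path(dir, "manifest.json")
  jsonlite::write_json(obj, out, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(out)
}

#' Read a dataset manifest (and its trials)
#'
#' Validates that every referenced trial file exists and that target
#' indices fall inside the plan before loading anything.
#'
#' @param path Path to a `manifest.json` written by [write_dataset()].
#' @param load_trials Read the trial files as well (default TRUE).
#' @return A `ssmvep_dataset` (with `trials = NULL` when
#'   `load_trials = FALSE`).
#' @export
read_manifest <- function(path, load_trials = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("plan", "trials"))
    if (is.null(obj[[f]])) stop("manifest lacks required field '", f, "'")
  man <- as.data.frame(obj$trials)
  plan <- structure(list(base = obj$plan$base, midpoints = obj$plan$midpoints,
                         margin = obj$plan$margin,
                         pairs = as.data.frame(obj$plan$pairs)),
                    class = "frequency_plan")
  n_targets <- nrow(plan$pairs)
  bad <- !(man$target %in% seq_len(n_targets))
  if (any(bad))
    stop("manifest trial(s) ", paste(man$trial[bad], collapse = ", "),
         " reference target indices outside the ", n_targets, "-target plan")
  dir <- dirname(path)
  missing <- !file.exists(file.path(dir, man$path))
  if (any(missing))
    stop("manifest references missing trial file(s): ",
         paste(man$path[missing], collapse = ", "))
  trials <- NULL
  if (load_trials)
    trials <- lapply(seq_len(nrow(man)), function(i) {
      tr <- read_trial(file.path(dir, man$path[i]))
      tr$true_target <- man$target[i]
      tr$subject <- man$subject[i]
      tr$session <- man$session[i]
      tr$run <- man$run[i]
      tr
    })
  structure(list(trials = trials, manifest = man, plan = plan,
                 config = NULL),
            class = "ssmvep_dataset")
}

#' Write a frequency plan as JSON
#' @param plan A `frequency_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(list(base = plan$base, midpoints = plan$midpoints,
                            margin = plan$margin, pairs = plan$pairs),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a frequency plan from JSON
#' @param path Path written by [write_plan()].
#' @return A `frequency_plan`.
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(base = obj$base, midpoints = obj$midpoints,
                 margin = obj$margin, pairs = as.data.frame(obj$pairs)),
            class = "frequency_plan")
}
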