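#' The twelve analysis channels and their scalp regions
#'
#' Effective connectivity is computed on a fixed set of 12 channels grouped
#' into four anterior-to-posterior regions: frontal (Fz, F3, F4), central
#' (Cz, C3, C4), parietal (Pz, P3, P4) and occipital (POz, O1, O2). The
#' midline channels Fz, Cz, Pz and POz act as sources of information flow;
#' regions act as sinks. Region and source indices run 1-4 from anterior to
#' posterior, which is also the unit-step coding used by the distance
#' predictors in the statistics stage.
#'
#' @return a list with components `channels` (the 12 analysis channels in
#'   fixed order), `regions` (named index 1-4), `members` (channels per
#'   region), `sources` (named index 1-4 of the midline source channels) and
#'   `channel_region` (region letter per analysis channel).
#' @export
#' @examples
#' region_scheme()$sources
region_scheme <- function() {
  members <- list(F = c("Fz", "F3", "F4"),
                  C = c("Cz", "C3", "C4"),
                  P = c("Pz", "P3", "P4"),
                  O = c("POz", "O1", "O2"))
  channels <- c("F3", "Fz", "F4", "C3", "Cz", "C4",
                "P3", "Pz", "P4", "O1", "POz", "O2")
  channel_region <- vapply(channels, function(ch)
    names(members)[vapply(members, function(m) ch %in% m, logical(1))],
    character(1))
  list(channels = channels,
       regions = c(F = 1L, C = 2L, P = 3L, O = 4L),
       members = members,
       sources = c(Fz = 1L, Cz = 2L, Pz = 3L, POz = 4L),
       channel_region = channel_region)
}

#' Default 22-channel montage labels
#'
#' International 10-20 labels for a 22-channel EEG montage containing the 12
#' analysis channels.
#' @return character vector of length 22.
#' @export
default_channel_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8",
    "P7", "P3", "Pz", "P4", "P8",
    "POz", "O1", "O2", "FCz", "CPz")
}

.stage_vocab <- c("W", "N1", "N2", "SWS", "REM")

#' Construct a multichannel sleep EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels channel labels (10-20 names); matched case-insensitively
#'   against the analysis set.
#' @param stages character vector of sleep-stage labels, one per 30-s epoch
#'   (vocabulary W, N1, N2, SWS, REM). Must cover the full duration.
#' @return an object of class `so_recording`.
#' @export
recording <- function(data, fs, labels, stages) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (length(labels) != nrow(data)) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  bad <- setdiff(unique(stages), .stage_vocab)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  n_epochs <- floor(ncol(data) / (30 * fs))
  if (length(stages) < n_epochs)
    stop("hypnogram too short: ", length(stages), " epochs for a recording of ",
         n_epochs, " full 30-s epochs")
  scheme <- region_scheme()
  idx <- match(tolower(scheme$channels), tolower(labels))
  if (anyNA(idx))
    stop("missing analysis channel(s): ",
         paste(scheme$channels[is.na(idx)], collapse = ", "))
  structure(list(data = data, fs = fs, labels = labels,
                 stages = as.character(stages),
                 analysis_index = stats::setNames(idx, scheme$channels),
                 region_map = scheme$channel_region),
            class = "so_recording")
}

#' @export
print.so_recording <- function(x, ...) {
  cat("Sleep EEG recording:", nrow(x$data), "channels x",
      ncol(x$data), "samples @", x$fs, "Hz (",
      round(ncol(x$data) / x$fs / 60, 1), "min )\n")
  st <- table(factor(x$stages, levels = .stage_vocab))
  cat("Hypnogram (30-s epochs):",
      paste(names(st), st, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Extract the analysis-channel submatrix in fixed order
#' @param recording an `so_recording`.
#' @return 12 x samples matrix with rows in `region_scheme()$channels` order.
#' @export
analysis_matrix <- function(recording) {
  stopifnot(inherits(recording, "so_recording"))
  m <- recording$data[recording$analysis_index, , drop = FALSE]
  rownames(m) <- names(recording$analysis_index)
  m
}

#' Sample-level mask of the sleep stages of interest
#'
#' @param recording an `so_recording`.
#' @param stages_of_interest character vector of stage labels to keep.
#' @return logical vector, one element per sample; `TRUE` inside a 30-s epoch
#'   whose label is in `stages_of_interest`.
#' @export
stage_mask <- function(recording, stages_of_interest = c("N2", "SWS")) {
  stopifnot(inherits(recording, "so_recording"))
  bad <- setdiff(stages_of_interest, .stage_vocab)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  epoch_len <- as.integer(round(30 * recording$fs))
  n <- ncol(recording$data)
  mask <- rep(FALSE, n)
  for (e in seq_along(recording$stages)) {
    if (recording$stages[e] %in% stages_of_interest) {
      i0 <- (e - 1L) * epoch_len + 1L
      i1 <- min(e * epoch_len, n)
      if (i0 <= n) mask[i0:i1] <- TRUE
    }
  }
  mask
}

#' Write a recording to plain-text files
#'
#' Stores the sample matrix as TSV (channels in columns), a JSON sidecar
#' with the sampling rate and channel labels, and the hypnogram as one stage
#' label per line.
#'
#' @param recording an `so_recording`.
#' @param path base path; writes `<path>.tsv`, `<path>.json`,
#'   `<path>.hypno.txt`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "so_recording"))
  m <- t(recording$data)
  colnames(m) <- recording$labels
  utils::write.table(format(m, digits = 8, trim = TRUE, scientific = FALSE),
                     paste0(path, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(fs = recording$fs, labels = recording$labels,
                            n_samples = ncol(recording$data)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  writeLines(recording$stages, paste0(path, ".hypno.txt"))
  invisible(path)
}

#' Read a recording written by [write_recording]
#'
#' @param path base path (as passed to [write_recording]).
#' @param hypnogram_path optional explicit hypnogram file; defaults to
#'   `<path>.hypno.txt`.
#' @return an `so_recording`.
#' @export
read_recording <- function(path, hypnogram_path = paste0(path, ".hypno.txt")) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(path, ".tsv"), header = TRUE,
                                   sep = "\t", check.names = FALSE))
  if (ncol(m) != length(meta$labels))
    stop("channel count mismatch between data and sidecar metadata")
  stages <- readLines(hypnogram_path)
  n_epochs <- floor(nrow(m) / (30 * meta$fs))
  if (length(stages) < n_epochs)
    stop("hypnogram too short for the recording duration")
  recording(t(m), fs = meta$fs, labels = meta$labels, stages = stages)
}
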