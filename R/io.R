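# Full-precision number formatting for text round trips (<= 1e-9 mm).
fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[!is.finite(x)] <- "NaN"
  out
}

#' Read marker trajectories from CSV or TRC
#'
#' CSV dialect: header `frame,<marker>_x,<marker>_y,<marker>_z,...`, one row
#' per frame (0-based frame index), `NaN` or an empty cell meaning missing.
#' TRC dialect: the standard Motion Analysis / OpenSim tab-separated header
#' (`DataRate`, `NumFrames`, `NumMarkers`, `Units`) followed by
#' `Frame# Time X1 Y1 Z1 ...` columns. In both dialects a marker-frame with
#' any missing coordinate is treated as fully missing.
#'
#' @param path File to read.
#' @param dialect `"csv"` or `"trc"`.
#' @param frame_rate Frame rate (Hz) for the CSV dialect, which does not
#'   carry one (default 240). Ignored for TRC, whose header stores it.
#' @return List with `trajectories` (a [trajectory_matrix()]) and `mask`
#'   (an [observation_mask()]).
#' @export
read_trajectories <- function(path, dialect = c("csv", "trc"),
                              frame_rate = 240) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tm <- switch(dialect,
    csv = read_csv_dialect(path, frame_rate),
    trc = read_trc_dialect(path)
  )
  mask <- mask_from_values(tm)
  # atomicity may demote partially-missing marker-frames; reflect it in values
  tm$values[!mask$observed] <- NA_real_
  list(trajectories = tm, mask = mask)
}

read_csv_dialect <- function(path, frame_rate) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1], "frame")) {
    stop(sprintf("%s: first CSV column must be 'frame'", path), call. = FALSE)
  }
  ch_names <- names(df)[-1]
  if (length(ch_names) %% 3L != 0L) {
    stop(sprintf("%s: channel count %d is not a multiple of 3", path,
                 length(ch_names)), call. = FALSE)
  }
  markers <- unique(sub("_[xyz]$", "", ch_names))
  expected <- channel_labels(markers)
  if (!identical(ch_names, expected)) {
    stop(sprintf("%s: channel headers must be <marker>_x,_y,_z triples", path),
         call. = FALSE)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  trajectory_matrix(values, frame_rate, markers)
}

read_trc_dialect <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L) stop(sprintf("%s: truncated TRC file", path), call. = FALSE)
  keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  hdr <- stats::setNames(as.list(vals), keys)
  rate <- as.numeric(hdr[["DataRate"]])
  n_markers <- as.integer(hdr[["NumMarkers"]])
  if (!is.finite(rate) || is.na(n_markers)) {
    stop(sprintf("%s: TRC header lacks DataRate/NumMarkers", path), call. = FALSE)
  }
  marker_line <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  markers <- marker_line[seq(3L, by = 3L, length.out = n_markers)]
  markers <- markers[markers != ""]
  if (length(markers) != n_markers) {
    stop(sprintf("%s: marker name row inconsistent with NumMarkers", path),
         call. = FALSE)
  }
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rows <- lapply(seq_along(data_lines), function(i) {
    parts <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L + 3L * n_markers) {
      stop(sprintf("%s: line %d has %d fields, expected %d", path, i + 5L,
                   length(parts), 2L + 3L * n_markers), call. = FALSE)
    }
    suppressWarnings(as.numeric(parts[-(1:2)]))
  })
  values <- do.call(rbind, rows)
  trajectory_matrix(values, rate, markers)
}

#' Write marker trajectories to CSV or TRC
#'
#' Missing entries (positions where `mask` is `FALSE`, plus any `NA` already
#' in the values) are serialized as `NaN`. Numbers are printed with 17
#' significant digits so a write/read round trip preserves values to better
#' than 1e-9 mm.
#'
#' @param tm A [trajectory_matrix()].
#' @param path Output file.
#' @param dialect `"csv"` or `"trc"`.
#' @param mask Optional [observation_mask()]; entries marked unobserved are
#'   written as `NaN`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(tm, path, dialect = c("csv", "trc"),
                               mask = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(tm, "trajectory_matrix"))
  values <- tm$values
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "observation_mask"))
    values[!mask$observed] <- NA_real_
  }
  if (any(colSums(is.finite(values)) == 0L)) {
    warning("writing a channel with no observed entries", call. = FALSE)
  }
  n <- nrow(values)
  if (dialect == "csv") {
    header <- paste(c("frame", channel_labels(tm$marker_names)), collapse = ",")
    body <- vapply(seq_len(n), function(i) {
      paste(c(i - 1L, fmt_num(values[i, ])), collapse = ",")
    }, character(1))
    writeLines(c(header, body), path)
  } else {
    m <- length(tm$marker_names)
    l1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
    l2 <- paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                  "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"),
                collapse = "\t")
    l3 <- paste(c(fmt_num(tm$frame_rate), fmt_num(tm$frame_rate), n, m, "mm",
                  fmt_num(tm$frame_rate), 1L, n), collapse = "\t")
    l4 <- paste(c("Frame#", "Time",
                  as.vector(rbind(tm$marker_names, "", ""))), collapse = "\t")
    l5 <- paste(c("", "", paste0(rep(c("X", "Y", "Z"), m),
                                 rep(seq_len(m), each = 3L))), collapse = "\t")
    body <- vapply(seq_len(n), function(i) {
      paste(c(i, fmt_num((i - 1L) / tm$frame_rate), fmt_num(values[i, ])),
            collapse = "\t")
    }, character(1))
    writeLines(c(l1, l2, l3, l4, l5, body), path)
  }
  invisible(path)
}

#' Write a gap manifest
#'
#' @param gaps Data frame `(marker, start_frame, end_frame)` as produced by
#'   [simulate_gaps()] (half-open, 0-based frame intervals).
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_gap_manifest <- function(gaps, path) {
  utils::write.csv(gaps, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
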