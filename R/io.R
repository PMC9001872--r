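# Frame-sequence container, PNG-directory ingestion, snippet extraction,
# ratings CSV parsing, and report serialization. Video is consumed as
# directories of numbered still frames (lossless PNG) plus a manifest CSV;
# the synthetic generator writes the same layout, so generated and ingested
# clips are interchangeable.

#' Construct a frame sequence
#'
#' @param frames Non-empty list of frame matrices.
#' @param fps Frames per second (> 0); used to derive timestamps when none
#'   are supplied.
#' @param timestamps Optional non-decreasing numeric vector of seconds, one
#'   per frame; defaults to `(0 .. n-1) / fps`.
#' @param clip_id Identifier.
#' @param ground_truth_bands Optional integer vector of known bands (from
#'   the synthetic generator).
#' @return A `frame_sequence` list.
#' @export
frame_sequence <- function(frames, fps = 25, timestamps = NULL,
                           clip_id = "clip", ground_truth_bands = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of frames", call. = FALSE)
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (is.null(timestamps)) timestamps <- (seq_along(frames) - 1) / fps
  if (length(timestamps) != length(frames))
    stop("one timestamp per frame required", call. = FALSE)
  if (is.unsorted(timestamps)) stop("timestamps must be non-decreasing", call. = FALSE)
  structure(list(frames = frames, timestamps = timestamps, fps = fps,
                 clip_id = clip_id, ground_truth_bands = ground_truth_bands),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %s: %d frames @ %g fps (%.2f s), %d x %d px\n",
              x$clip_id, length(x$frames), x$fps,
              length(x$frames) / x$fps,
              nrow(x$frames[[1]]), ncol(x$frames[[1]])))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Write a frame sequence as a PNG directory with manifest
#'
#' Writes numbered PNGs (`frame_00000.png`, ...) and a `manifest.csv` with
#' columns `clip_id`, `frame_index`, `timestamp`, `ground_truth_band` (NA
#' when unknown), `fps`.
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(seq, dir) {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(seq$frames)
  files <- sprintf("frame_%05d.png", seq_len(n) - 1L)
  for (i in seq_len(n))
    png::writePNG(seq$frames[[i]], target = file.path(dir, files[i]))
  gtb <- if (is.null(seq$ground_truth_bands)) rep(NA_integer_, n)
         else seq$ground_truth_bands
  utils::write.csv(
    data.frame(clip_id = seq$clip_id, frame_index = seq_len(n) - 1L,
               file = files, timestamp = seq$timestamps,
               ground_truth_band = gtb, fps = seq$fps),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a frame sequence from a PNG/TIFF directory
#'
#' If a `manifest.csv` is present its `file`, `timestamp` and `fps` columns
#' drive ordering and timing; otherwise image files are taken in lexical
#' order and timestamps derived from `fps`. Frames are converted to
#' grayscale on ingestion.
#'
#' @param path Directory of still frames.
#' @param stride Keep every `stride`-th frame starting from the first
#'   (default 1 = all frames).
#' @param fps Fallback frames per second when no manifest is present.
#' @return A `frame_sequence`.
#' @export
read_frames <- function(path, stride = 1L, fps = 25) {
  if (!dir.exists(path))
    stop(sprintf("frame directory not found: %s", path), call. = FALSE)
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("`stride` must be >= 1", call. = FALSE)
  manifest_path <- file.path(path, "manifest.csv")
  gtb <- NULL
  clip_id <- basename(path)
  if (file.exists(manifest_path)) {
    man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
    files <- file.path(path, man$file)
    ts <- man$timestamp
    if (!is.null(man$fps)) fps <- man$fps[1L]
    if (!is.null(man$ground_truth_band)) gtb <- as.integer(man$ground_truth_band)
    if (!is.null(man$clip_id)) clip_id <- as.character(man$clip_id[1L])
  } else {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    ts <- (seq_along(files) - 1) / fps
  }
  if (length(files) == 0L)
    stop(sprintf("no image frames found in %s", path), call. = FALSE)
  keep <- seq(1L, length(files), by = stride)
  frames <- lapply(files[keep], read_frame)
  frame_sequence(frames, fps = fps, timestamps = ts[keep], clip_id = clip_id,
                 ground_truth_bands = if (!is.null(gtb)) gtb[keep])
}

#' Extract random snippets from a longer sequence
#'
#' Draws `n` snippets whose durations are uniform in `duration_bounds`
#' seconds and whose start offsets are uniform over the feasible range.
#' Snippets may overlap. Deterministic under `seed`.
#'
#' @param seq A [frame_sequence()] longer than `max(duration_bounds)`.
#' @param duration_bounds Two-element numeric vector of seconds,
#'   default `c(20, 25)`.
#' @param n Number of snippets (>= 1).
#' @param seed Integer seed.
#' @return List of `frame_sequence` snippets with ids
#'   `"<clip_id>_snip<k>"`.
#' @export
extract_snippets <- function(seq, duration_bounds = c(20, 25), n, seed = 1L) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (missing(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (length(duration_bounds) != 2L || duration_bounds[1] <= 0 ||
      duration_bounds[2] < duration_bounds[1])
    stop("`duration_bounds` must be increasing positive seconds", call. = FALSE)
  total <- length(seq$frames) / seq$fps
  if (total <= duration_bounds[2])
    stop(sprintf("source (%.1f s) must be longer than the maximum snippet duration (%.1f s)",
                 total, duration_bounds[2]), call. = FALSE)
  with_seed(seed, {
    out <- vector("list", n)
    for (k in seq_len(n)) {
      dur <- stats::runif(1, duration_bounds[1], duration_bounds[2])
      start <- stats::runif(1, 0, total - dur)
      sel <- which(seq$timestamps >= start & seq$timestamps < start + dur)
      out[[k]] <- frame_sequence(
        seq$frames[sel], fps = seq$fps, timestamps = seq$timestamps[sel],
        clip_id = sprintf("%s_snip%02d", seq$clip_id, k),
        ground_truth_bands = if (!is.null(seq$ground_truth_bands))
          seq$ground_truth_bands[sel])
    }
    out
  })
}

#' Read a ratings CSV
#'
#' Accepts either long format (`clip_id`, `rater`, `band`) with exactly two
#' raters, or wide format (`clip_id`, `rating_c1`, `rating_c2`), and
#' returns the wide rating-pair data frame used by the agreement
#' statistics.
#'
#' @param path CSV file path.
#' @return Data frame with `clip_id`, `rating_c1`, `rating_c2`.
#' @export
read_ratings_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("ratings file not found: %s", path),
                               call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("rating_c1", "rating_c2") %in% names(x)))
    return(x[, c("clip_id", "rating_c1", "rating_c2")])
  if (!all(c("clip_id", "rater", "band") %in% names(x)))
    stop("ratings CSV needs columns (clip_id, rater, band) or (clip_id, rating_c1, rating_c2)",
         call. = FALSE)
  raters <- sort(unique(x$rater))
  if (length(raters) != 2L)
    stop("long-format ratings must contain exactly two raters", call. = FALSE)
  a <- x[x$rater == raters[1L], c("clip_id", "band")]
  b <- x[x$rater == raters[2L], c("clip_id", "band")]
  m <- merge(a, b, by = "clip_id", suffixes = c("_c1", "_c2"))
  data.frame(clip_id = m$clip_id, rating_c1 = as.integer(m$band_c1),
             rating_c2 = as.integer(m$band_c2))
}

# Recursively strip S3 classes and drop function/NULL members so reports
# serialize to stable plain JSON.
report_to_list <- function(x) {
  if (inherits(x, "crosstab")) {
    return(list(counts = unclass(unname(x))[seq_len(4), seq_len(4)],
                n = attr(x, "n")))
  }
  if (is.list(x)) return(lapply(unclass(x), report_to_list))
  if (is.matrix(x)) return(unclass(x))
  x
}

#' Serialize a result to JSON or CSV
#'
#' JSON handles any report object (agreement reports, clip estimates,
#' models); CSV applies to tabular results such as a clip score series.
#'
#' @param x Object to write.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(x))
      stop("CSV output requires a data frame (e.g. a clip score series)",
           call. = FALSE)
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(report_to_list(x), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path JSON file written by [write_report()].
#' @return Parsed list.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
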