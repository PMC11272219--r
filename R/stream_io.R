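STREAM_BEGIN <- "----- Begin chunk -----"
STREAM_END <- "----- End chunk -----"
REFL_BEGIN <- "Reflections measured after indexing"
REFL_END <- "End of reflections"

#' Write a frame set to the minimal stream-chunk dialect
#'
#' One chunk per frame, delimited by the public stream chunk markers, with the
#' reflection block listing `h k l I sigma(I)` rows. Ordering is deterministic:
#' frames by frame_id, rows by (h, k, l). Numeric output uses `%.6g`.
#'
#' @param frames A [frame_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(frames, path) {
  stopifnot(inherits(frames, "frame_set"))
  obs <- frames$obs[order(frames$obs$frame, frames$obs$h, frames$obs$k, frames$obs$l), ]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  split_obs <- split(obs, obs$frame)
  for (id in seq_len(frames$n_frames) - 1L) {
    o <- split_obs[[as.character(id)]]
    writeLines(c(STREAM_BEGIN, sprintf("Image serial number: %d", id),
                 REFL_BEGIN,
                 "   h    k    l          I   sigma(I)"), con)
    if (!is.null(o) && nrow(o) > 0)
      writeLines(sprintf("%4d %4d %4d %10s %10s", o$h, o$k, o$l,
                         formatC(o$I, format = "g", digits = 6),
                         formatC(o$sigma, format = "g", digits = 6)), con)
    writeLines(c(REFL_END, STREAM_END), con)
  }
  invisible(path)
}

#' Read a frame set from the minimal stream-chunk dialect
#'
#' Parses the chunk dialect written by [write_stream()], which is a subset of
#' the public CrystFEL stream reflection block: real chunks parse too, with
#' columns beyond the first five (peak, background, fs/px, ss/px, panel)
#' ignored. Unknown header lines inside a chunk are skipped and counted.
#'
#' @param path Path to a stream file.
#' @param cell Optional [unit_cell()] to attach to the frame set.
#' @return A [frame_set()]; attribute `counts` holds the numbers of parsed
#'   chunks and ignored header lines.
#' @export
read_stream <- function(path, cell = NULL) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  i <- 1L
  frames <- list()
  serials <- integer()
  ignored <- 0L
  frame_counter <- 0L
  while (i <= n) {
    if (trimws(lines[i]) != STREAM_BEGIN) { i <- i + 1L; next }
    chunk_start <- i
    i <- i + 1L
    frame_id <- NA_integer_
    rows <- NULL
    in_refl <- FALSE
    terminated <- FALSE
    while (i <= n) {
      ln <- lines[i]
      tln <- trimws(ln)
      if (tln == STREAM_END) { terminated <- TRUE; i <- i + 1L; break }
      if (tln == REFL_BEGIN) {
        in_refl <- TRUE
        refl_rows <- character()
        row_lines <- integer()
        i <- i + 1L
        # optional column-header line
        if (i <= n && grepl("^\\s*h\\s+k\\s+l", lines[i])) i <- i + 1L
        while (i <= n && trimws(lines[i]) != REFL_END) {
          if (trimws(lines[i]) == STREAM_END)
            stop(sprintf("unterminated reflection block at line %d", i))
          refl_rows <- c(refl_rows, lines[i])
          row_lines <- c(row_lines, i)
          i <- i + 1L
        }
        if (i > n) stop(sprintf("unterminated reflection block starting near line %d", chunk_start))
        i <- i + 1L  # consume REFL_END
        if (length(refl_rows) > 0) {
          parts <- strsplit(trimws(refl_rows), "\\s+")
          nf <- vapply(parts, length, 0L)
          bad <- which(nf < 5)
          if (length(bad) > 0)
            stop(sprintf("malformed reflection row at line %d", row_lines[bad[1]]))
          m <- t(vapply(parts, function(p) suppressWarnings(as.numeric(p[1:5])),
                        numeric(5)))
          if (anyNA(m)) {
            bad <- which(apply(m, 1, anyNA))[1]
            stop(sprintf("non-numeric reflection row at line %d", row_lines[bad]))
          }
          rows <- data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                             l = as.integer(m[, 3]), I = m[, 4], sigma = m[, 5])
        } else {
          rows <- data.frame(h = integer(), k = integer(), l = integer(),
                             I = numeric(), sigma = numeric())
        }
        next
      }
      if (grepl("^Image serial number:", tln)) {
        frame_id <- as.integer(sub("^Image serial number:\\s*", "", tln))
      } else {
        ignored <- ignored + 1L
      }
      i <- i + 1L
    }
    if (!terminated) stop(sprintf("unterminated chunk starting at line %d", chunk_start))
    if (is.na(frame_id)) frame_id <- frame_counter
    if (is.null(rows))
      rows <- data.frame(h = integer(), k = integer(), l = integer(),
                         I = numeric(), sigma = numeric())
    # frames are renumbered densely from 0 in order of appearance; the
    # original serial numbers are kept in params$serials
    if (nrow(rows) > 0) rows$frame <- frame_counter
    frames[[length(frames) + 1L]] <- rows
    serials <- c(serials, frame_id)
    frame_counter <- frame_counter + 1L
  }
  obs <- do.call(rbind, Filter(function(d) nrow(d) > 0, frames))
  if (is.null(obs)) obs <- data.frame(frame = integer(), h = integer(),
                                      k = integer(), l = integer(),
                                      I = numeric(), sigma = numeric())
  obs <- obs[, c("frame", "h", "k", "l", "I", "sigma")]
  sb_log("read_stream: %d chunks parsed, %d header lines ignored",
         frame_counter, ignored)
  fs <- frame_set(obs, n_frames = frame_counter, cell = cell,
                  params = list(source = path, serials = serials))
  attr(fs, "counts") <- list(chunks = frame_counter, ignored_lines = ignored)
  fs
}
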