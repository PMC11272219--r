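#' Write a reflection set to a columnar text table
#'
#' Whitespace-separated text with header `h k l F phase sigF`; phases are
#' written in degrees (internal storage is radians). Missing phases or sigmas
#' are written as `NA`. This plain-text table plays the role an MTZ file plays
#' in a full crystallographic stack; an MTZ adapter would slot in behind the
#' same reader/writer pair.
#'
#' @param refls A [reflection_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(refls, path) {
  df <- data.frame(h = refls$h, k = refls$k, l = refls$l,
                   F = fmt_num(refls$F),
                   phase = ifelse(is.na(refls$phase), "NA",
                                  fmt_num(wrap_deg(refls$phase * 180 / pi))),
                   sigF = ifelse(is.na(refls$sigF), "NA", fmt_num(refls$sigF)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("h k l F phase sigF", con)
  writeLines(do.call(paste, df), con)
  invisible(path)
}

#' Read a reflection set from a columnar text table
#'
#' Inverse of [write_reflections()]. A table lacking the `sigF` column is
#' accepted; the returned sigmas are then `NA` and attribute `sigmas_absent`
#' is set. Duplicate Miller indices are an error.
#'
#' @param path Path to a reflection table.
#' @param cell Optional [unit_cell()] used to attach d-spacings.
#' @param d_min Resolution cutoff to record (not enforced on read).
#' @param role Role tag for the returned set.
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path, cell = NULL, d_min = NA_real_,
                             role = "calculated") {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("h", "k", "l", "F") %in% names(df)))
    stop("reflection table must have header columns h k l F")
  sig_absent <- !("sigF" %in% names(df))
  phase <- if ("phase" %in% names(df)) as.numeric(df$phase) * pi / 180 else NA_real_
  sig <- if (sig_absent) NA_real_ else as.numeric(df$sigF)
  rs <- reflection_set(as.matrix(df[, c("h", "k", "l")]), amplitude = df$F,
                       phase = phase, sigma = sig, cell = cell, d_min = d_min,
                       role = role)
  attr(rs, "sigmas_absent") <- sig_absent
  rs
}
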