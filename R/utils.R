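#' Derive a child seed from a master seed
#'
#' Counter-based splitting rule used everywhere the package fans one master
#' seed out into per-frame, per-replicate or per-stage seeds. Deterministic and
#' independent of iteration order, so any subset of frames or replicates can be
#' regenerated in isolation. Child seeds stay below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param counter Integer counter (stage index, frame id, replicate id, ...).
#' @return An integer seed.
#' @export
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), is.numeric(counter))
  m <- 2147483647  # 2^31 - 1, prime
  x <- ((as.numeric(master) %% m) * 48271) %% m
  x <- (x + (as.numeric(counter) %% m) * 69621) %% m
  as.integer(x)
}

sb_log <- function(..., verbose = getOption("serialboot.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[serialboot] ", sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x) formatC(x, format = "g", digits = 10)
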