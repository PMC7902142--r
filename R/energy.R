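# Gait energy images. A GEI is the pixel-wise mean of one subject's N
# binary silhouette frames; the F-GEI (full GEI) is the pixel-wise mean
# of all involved subjects' GEIs, maintained either in one batch or by
# an exact incremental update as each subject passes. All arithmetic is
# double precision: repeated incremental averaging quantized to 8 bits
# would drift, so the F-GEI is only rounded on export.

#' Compute a subject's gait energy image (GEI)
#'
#' Pixel-wise arithmetic mean of the `N` binary frames:
#' `G(x, y) = (1/N) * sum_t B_t(x, y)`. A bright pixel marks a position
#' where the walker's body dwells for much of the sequence.
#'
#' @param frames list of `N >= 1` binary matrices of identical dimensions,
#'   or a [gait_sequence()].
#' @param subject_id identifier stored on the result (taken from the
#'   sequence when one is supplied).
#' @return Object of class `gei`: list with `pixels` (matrix in
#'   `[0, 255]`), `subject_id`, `n_frames`.
#' @export
compute_gei <- function(frames, subject_id = "subject") {
  if (inherits(frames, "gait_sequence")) {
    subject_id <- frames$subject_id
    frames <- frames$frames
  }
  if (length(frames) == 0L) stop("no frames", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("shape mismatch: frames differ in dimensions", call. = FALSE)
  acc <- Reduce(`+`, lapply(frames, function(f) {
    stopifnot_binary(f)
    f * 1.0
  }))
  structure(list(pixels = acc / length(frames), subject_id = subject_id,
                 n_frames = length(frames)),
            class = "gei")
}

#' Compute the full gait energy image (F-GEI) in one batch
#'
#' Pixel-wise mean of `M` subjects' GEIs. The F-GEI represents the gait
#' energy distribution of all subjects involved so far: its bright region
#' is where walkers most frequently appear.
#'
#' @param geis list of `M >= 1` `gei` objects of identical dimensions.
#' @return Object of class `fgei`: list with `pixels` and `m_count = M`.
#' @export
compute_fgei_batch <- function(geis) {
  if (length(geis) == 0L) stop("no GEIs", call. = FALSE)
  stopifnot(all(vapply(geis, inherits, logical(1), "gei")))
  dims <- vapply(geis, function(g) dim(g$pixels), integer(2))
  if (any(dims != dims[, 1]))
    stop("shape mismatch: GEIs differ in dimensions", call. = FALSE)
  acc <- Reduce(`+`, lapply(geis, `[[`, "pixels"))
  structure(list(pixels = acc / length(geis), m_count = length(geis)),
            class = "fgei")
}

#' Incrementally fold one more GEI into the F-GEI
#'
#' Exact online update `F_M = (1/M) * (G_M + (M - 1) * F_{M-1})` with
#' `M = fgei$m_count + 1`, so any sequence of updates reproduces the
#' batch mean of the same GEIs (up to floating rounding).
#'
#' @param fgei current `fgei` state.
#' @param new_gei the newly involved subject's `gei`.
#' @return Updated `fgei` with `m_count` incremented.
#' @export
update_fgei <- function(fgei, new_gei) {
  stopifnot(inherits(fgei, "fgei"), inherits(new_gei, "gei"))
  if (!identical(dim(fgei$pixels), dim(new_gei$pixels)))
    stop("shape mismatch", call. = FALSE)
  m <- fgei$m_count + 1L
  structure(list(pixels = (new_gei$pixels + (m - 1) * fgei$pixels) / m,
                 m_count = m),
            class = "fgei")
}

#' @export
print.gei <- function(x, ...) {
  cat(sprintf("<gei> subject '%s', %d frames, %dx%d\n", x$subject_id,
              x$n_frames, nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' @export
print.fgei <- function(x, ...) {
  cat(sprintf("<fgei> M = %d subjects, %dx%d\n", x$m_count,
              nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Export an energy image as an 8-bit PNG for inspection
#'
#' @param x a `gei` or `fgei` object.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_energy_png <- function(x, path) {
  stopifnot(inherits(x, "gei") || inherits(x, "fgei"))
  png::writePNG(round(x$pixels) / 255, path)
  invisible(path)
}

#' Save / load F-GEI state losslessly as CSV
#'
#' The floating-point grid is written unrounded; `m_count` is recorded on
#' a header comment line so a detection run can resume exactly.
#'
#' @param fgei an `fgei` object.
#' @param path CSV path.
#' @return `path` (write) or the restored `fgei` (read).
#' @export
write_fgei_csv <- function(fgei, path) {
  stopifnot(inherits(fgei, "fgei"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# m_count=%d", fgei$m_count), con)
  utils::write.table(fgei$pixels, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_fgei_csv
#' @export
read_fgei_csv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- as.integer(sub("# m_count=", "", header, fixed = TRUE))
  px <- as.matrix(utils::read.table(path, sep = ",", skip = 1L))
  dimnames(px) <- NULL
  structure(list(pixels = px, m_count = m), class = "fgei")
}
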