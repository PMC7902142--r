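# Internal helpers shared across modules.

# Evaluate `expr` with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_binary <- function(m, what = "frame") {
  if (!is.matrix(m)) stop(sprintf("%s must be a matrix", what), call. = FALSE)
  if (!all(m %in% c(0, 255)))
    stop(sprintf("%s must be binary with values in {0, 255}", what), call. = FALSE)
  invisible(m)
}

# Horizontal (column) centroid of foreground pixels, 1-based fractional.
centroid_x <- function(frame) {
  fg <- which(frame > 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("blank frame: no foreground pixels", call. = FALSE)
  mean(fg[, 2L])
}

# Bounding box of foreground: list(rows = c(min,max), cols = c(min,max)).
fg_bbox <- function(frame) {
  fg <- which(frame > 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) stop("blank frame: no foreground pixels", call. = FALSE)
  list(rows = range(fg[, 1L]), cols = range(fg[, 2L]))
}

#' Construct a gait sequence
#'
#' Bundles one subject's ordered binary silhouette frames with an identifier
#' and an optional ground-truth label.
#'
#' @param subject_id character scalar identifier.
#' @param frames list of binary matrices (values in `{0, 255}`), all of
#'   identical dimensions, ordered along the walk.
#' @param label optional `"normal"` or `"abnormal"`; `NA` when unknown.
#' @return An object of class `gait_sequence`.
#' @export
gait_sequence <- function(subject_id, frames, label = NA_character_) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.list(frames), length(frames) >= 1L)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape mismatch: all frames must share dimensions", call. = FALSE)
  if (!is.na(label) && !label %in% c("normal", "abnormal"))
    stop("label must be 'normal', 'abnormal' or NA", call. = FALSE)
  structure(list(subject_id = subject_id, frames = frames, label = label),
            class = "gait_sequence")
}

#' @export
print.gait_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<gait_sequence> subject '%s': %d frames of %dx%d, label: %s\n",
              x$subject_id, length(x$frames), d[1], d[2],
              ifelse(is.na(x$label), "unknown", x$label)))
  invisible(x)
}
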