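# Frame and cohort ingest. Frames arrive as 8-bit grayscale PNG or PGM;
# any nonzero pixel is treated as foreground (255) on ingest. Directory
# convention: one subdirectory per subject, frames ordered
# lexicographically.

#' Read a silhouette frame from PNG or PGM
#'
#' @param path image path (`.png`, `.pgm`).
#' @return Binary matrix with values in `{0, 255}`.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              png = {
                a <- png::readPNG(path)
                if (length(dim(a)) == 3L) a <- a[, , 1L]  # first channel
                a * 255
              },
              pgm = read_pgm(path),
              stop("unsupported frame format: .", ext, call. = FALSE))
  nonbin <- m != 0 & m != 255
  if (any(nonbin))
    message(sprintf("%s: %d nonzero non-255 pixels treated as foreground",
                    basename(path), sum(nonbin)))
  out <- matrix(0L, nrow(m), ncol(m))
  out[m != 0] <- 255L
  out
}

# Minimal PGM reader (P2 ASCII and P5 binary, maxval <= 255).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM", call. = FALSE)
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
                                if (c2 == "\n") break } ; next }
      if (!grepl("^[ \t\r\n]$", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("^[ \t\r\n]$", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file", call. = FALSE)
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  if (maxv > 255) stop("16-bit PGM unsupported", call. = FALSE)
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Read one subject's frames from a directory
#'
#' @param dir directory holding the subject's frames (PNG/PGM),
#'   lexicographically ordered.
#' @param label optional ground-truth label.
#' @return A [gait_sequence()] of raw frames.
#' @export
read_sequence_dir <- function(dir, label = NA_character_) {
  files <- sort(list.files(dir, pattern = "\\.(png|pgm)$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no frames in ", dir, call. = FALSE)
  gait_sequence(basename(dir), lapply(files, read_frame), label)
}

#' Read a cohort directory (one subdirectory per subject)
#'
#' Labels come from `labels` (a data frame or CSV with columns
#' `subject_id`, `label`), from a `manifest.csv` in `dir`, or stay `NA`.
#' Stream order follows the manifest's `order_index` when present, else
#' lexicographic subject order.
#'
#' @param dir cohort root directory.
#' @param labels optional labels CSV path or data frame.
#' @return List with `sequences` and `manifest` (may have `NA` labels).
#' @export
read_cohort_dir <- function(dir, labels = NULL) {
  subs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(subs) == 0L) stop("no subject directories in ", dir, call. = FALSE)
  man_path <- file.path(dir, "manifest.csv")
  if (is.null(labels) && file.exists(man_path)) labels <- man_path
  lab_df <- NULL
  if (!is.null(labels)) {
    lab_df <- if (is.character(labels)) utils::read.csv(labels,
                                                        stringsAsFactors = FALSE)
              else labels
  }
  ids <- basename(subs)
  get_label <- function(id) {
    if (is.null(lab_df)) return(NA_character_)
    hit <- lab_df$label[match(id, lab_df$subject_id)]
    if (length(hit) == 0L) NA_character_ else hit
  }
  sequences <- lapply(subs, function(d) read_sequence_dir(d, get_label(basename(d))))
  names(sequences) <- ids
  if (!is.null(lab_df) && "order_index" %in% names(lab_df)) {
    ord_ids <- lab_df$subject_id[order(lab_df$order_index)]
    sequences <- sequences[ord_ids[ord_ids %in% ids]]
  }
  manifest <- data.frame(subject_id = names(sequences),
                         label = vapply(sequences, `[[`, character(1), "label"),
                         order_index = seq_along(sequences),
                         row.names = NULL, stringsAsFactors = FALSE)
  list(sequences = unname(sequences), manifest = manifest)
}
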