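# Silhouette preprocessing: frame selection at key location points,
# morphological denoising, body extraction, size normalization and
# centroid alignment. Frames are H x W integer matrices with values
# in {0, 255}; coordinates are (x, y) = (column, row), origin top-left.

#' Select frames at key location points
#'
#' Evenly spaced virtual key points along the walking path define which of
#' the captured frames are kept: for each key point, in order, the
#' remaining frame whose horizontal foreground centroid lies closest to
#' that key point's x-position is selected. A frame is never selected
#' twice; equidistant candidates resolve to the earlier frame index.
#'
#' @param raw_frames ordered list of binary matrices, each with at least
#'   one foreground pixel.
#' @param keypoints strictly increasing numeric vector of key point
#'   x-positions (same units as pixel columns).
#' @return List of `length(keypoints)` frames in key-point order.
#' @export
select_frames <- function(raw_frames, keypoints) {
  stopifnot(is.list(raw_frames), is.numeric(keypoints), length(keypoints) >= 1L)
  if (any(diff(keypoints) <= 0))
    stop("keypoints must be strictly increasing", call. = FALSE)
  if (length(raw_frames) < length(keypoints))
    stop("insufficient frames: fewer raw frames than key points", call. = FALSE)
  cx <- vapply(raw_frames, centroid_x, numeric(1))  # errors on blank frames
  taken <- logical(length(raw_frames))
  out <- vector("list", length(keypoints))
  for (k in seq_along(keypoints)) {
    d <- abs(cx - keypoints[k])
    d[taken] <- Inf
    pick <- which.min(d)  # ties -> earliest index
    taken[pick] <- TRUE
    out[[k]] <- raw_frames[[pick]]
  }
  out
}

#' Morphological denoising of a binary silhouette
#'
#' One dilation followed by one erosion (a morphological closing) with a
#' square structuring element, removing pepper noise and filling small
#' interior holes while leaving closed shapes untouched.
#'
#' @param frame binary matrix (values in `{0, 255}`).
#' @param kernel_size odd positive integer, side of the square element.
#' @return Denoised binary matrix.
#' @export
denoise <- function(frame, kernel_size = 3L) {
  stopifnot_binary(frame)
  if (length(kernel_size) != 1L || kernel_size < 1 || kernel_size %% 2 != 1)
    stop("invalid kernel: kernel_size must be a positive odd integer", call. = FALSE)
  if (kernel_size == 1L) return(frame)
  # Compute the closing of the foreground point set proper: zero-pad so
  # the structuring element can reach past the frame edge, close, crop.
  # (Closing directly on the bounded frame would depend on the library's
  # border convention.)
  k <- as.integer(kernel_size)
  pad <- k - 1L
  padded <- matrix(0L, nrow(frame) + 2L * pad, ncol(frame) + 2L * pad)
  padded[pad + seq_len(nrow(frame)), pad + seq_len(ncol(frame))] <- frame
  brush <- EBImage::makeBrush(k, shape = "box")
  closed <- EBImage::closing(padded > 0, brush)
  core <- closed[pad + seq_len(nrow(frame)), pad + seq_len(ncol(frame))]
  matrix(as.integer(core > 0) * 255L, nrow(frame), ncol(frame))
}

# 8-connected component labeling by BFS flood fill. Returns an integer
# matrix of labels (0 = background). EBImage::bwlabel is 4-connected,
# which would split silhouettes touching only diagonally.
label_components8 <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  lab <- matrix(0L, h, w)
  fg <- frame > 0
  cur <- 0L
  idx <- which(fg)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    lab[start] <- cur
    while (length(frontier) > 0L) {
      r <- (frontier - 1L) %% h + 1L
      c <- (frontier - 1L) %/% h + 1L
      nbr <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
        if (any(ok)) nbr <- c(nbr, (cc[ok] - 1L) * h + rr[ok])
      }
      nbr <- unique(nbr)
      nbr <- nbr[fg[nbr] & lab[nbr] == 0L]
      lab[nbr] <- cur
      frontier <- nbr
    }
  }
  lab
}

#' Extract the body silhouette
#'
#' Keeps only the largest 8-connected foreground component (the body) and
#' zeroes the bottom fraction of that component's bounding-box height to
#' cut away floor background attached to the feet.
#'
#' @param frame binary matrix with at least one foreground pixel.
#' @param bottom_cut_fraction fraction in `[0, 1)` of the component's
#'   bounding-box height to remove from the bottom.
#' @return Binary matrix containing only the trimmed main component.
#' @export
extract_body <- function(frame, bottom_cut_fraction = 0.05) {
  stopifnot_binary(frame)
  if (bottom_cut_fraction < 0 || bottom_cut_fraction >= 1)
    stop("bottom_cut_fraction must be in [0, 1)", call. = FALSE)
  if (!any(frame > 0)) stop("blank frame: no foreground pixels", call. = FALSE)
  lab <- label_components8(frame)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  out <- matrix(0L, nrow(frame), ncol(frame))
  out[lab == keep] <- 255L
  bb <- fg_bbox(out)
  height <- bb$rows[2] - bb$rows[1] + 1L
  ncut <- floor(bottom_cut_fraction * height + 1e-9)
  if (ncut > 0) out[(bb$rows[2] - ncut + 1L):bb$rows[2], ] <- 0L
  out
}

#' Normalize size and align silhouettes by centroid
#'
#' Each silhouette is cropped to its foreground bounding box, scaled
#' (aspect ratio preserved, bilinear) so the box height equals `target_h`,
#' re-binarized at 50%, and placed on a `target_h` x `target_w` canvas
#' with its foreground centroid at the horizontal center. All outputs
#' share identical dimensions, the canonical template on which energy
#' images are accumulated.
#'
#' @param frames list of binary matrices, each with foreground.
#' @param target_w,target_h canvas width and height in pixels.
#' @return List of binary `target_h` x `target_w` matrices.
#' @export
normalize_align <- function(frames, target_w = 88L, target_h = 128L) {
  stopifnot(is.list(frames), target_w >= 1, target_h >= 1)
  lapply(frames, function(f) {
    stopifnot_binary(f)
    bb <- fg_bbox(f)
    crop <- f[bb$rows[1]:bb$rows[2], bb$cols[1]:bb$cols[2], drop = FALSE]
    s <- target_h / nrow(crop)
    new_w <- max(1L, as.integer(round(ncol(crop) * s)))
    # EBImage images are (x, y) = (width, height); transpose in and out.
    scaled <- EBImage::resize(EBImage::Image(t(crop) / 255), w = new_w,
                              h = as.integer(target_h))
    sm <- t(EBImage::imageData(scaled)) > 0.5  # re-binarize at 127.5/255
    if (!any(sm)) stop("blank frame after scaling", call. = FALSE)
    if (ncol(sm) > target_w) {
      warning("canvas overflow: silhouette wider than target_w, clipping",
              call. = FALSE)
    }
    canvas <- matrix(0L, target_h, target_w)
    cx <- mean(which(sm, arr.ind = TRUE)[, 2L])
    shift <- round((target_w + 1) / 2 - cx)
    src_cols <- seq_len(ncol(sm))
    dst_cols <- src_cols + shift
    ok <- dst_cols >= 1L & dst_cols <= target_w
    rows_avail <- min(nrow(sm), target_h)
    canvas[seq_len(rows_avail), dst_cols[ok]] <-
      as.integer(sm[seq_len(rows_avail), src_cols[ok], drop = FALSE]) * 255L
    canvas
  })
}

#' Preprocess one subject's raw frames into a clean gait sequence
#'
#' Chains frame selection (when `keypoints` is given), denoising, body
#' extraction and size/centroid normalization into the fixed-length,
#' fixed-size binary sequence the energy stage consumes.
#'
#' @param raw_frames ordered list of binary matrices.
#' @param subject_id identifier carried through to the result.
#' @param keypoints optional key point x-positions; when `NULL`,
#'   `raw_frames` is taken as already selected.
#' @param kernel_size square closing element side (odd), see [denoise()].
#' @param bottom_cut_fraction see [extract_body()].
#' @param target_w,target_h see [normalize_align()].
#' @param label optional ground-truth label.
#' @return A [gait_sequence()].
#' @export
preprocess_sequence <- function(raw_frames, subject_id = "subject",
                                keypoints = NULL, kernel_size = 3L,
                                bottom_cut_fraction = 0.05,
                                target_w = 88L, target_h = 128L,
                                label = NA_character_) {
  sel <- if (is.null(keypoints)) raw_frames else select_frames(raw_frames, keypoints)
  cleaned <- lapply(sel, function(f)
    extract_body(denoise(f, kernel_size), bottom_cut_fraction))
  gait_sequence(subject_id, normalize_align(cleaned, target_w, target_h), label)
}
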