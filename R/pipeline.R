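# The online detection flow. An initiation stage accumulates the first L
# subjects (labeled by visual inspection; detection disabled), seeding
# the F-GEI and the labeled feature sets. Every later subject is then
# classified as it passes: GEI -> incremental F-GEI update -> energy mask
# recomputed -> overlap features -> BC-COP-K-means.

#' Build a run configuration
#'
#' @param L initiation-stage subject count (labeled subjects).
#' @param N frames per subject.
#' @param target_w,target_h canonical silhouette canvas (pixels).
#' @param kernel_size closing element side for denoising (odd).
#' @param bottom_cut_fraction bottom fraction of the body bounding box
#'   removed to detach the floor.
#' @param threshold_method `"otsu"` or `"fixed"` (see
#'   [select_threshold()]).
#' @param threshold_value fixed threshold when `threshold_method =
#'   "fixed"`.
#' @param frozen_features if `TRUE`, a subject's feature vector is
#'   computed once, at its own detection step, against the mask current
#'   at that moment; the default (`FALSE`) recomputes every involved
#'   subject's features from the current mask before each clustering run
#'   so all vectors are commensurate.
#' @param seed base integer seed; per-step clustering seeds derive from
#'   it deterministically.
#' @return List of class `run_config`.
#' @export
run_config <- function(L = 4L, N = 16L, target_w = 88L, target_h = 128L,
                       kernel_size = 3L, bottom_cut_fraction = 0.05,
                       threshold_method = "otsu", threshold_value = NULL,
                       frozen_features = FALSE, seed = 1L) {
  stopifnot(L >= 1L, N >= 1L)
  structure(list(L = as.integer(L), N = as.integer(N),
                 target_w = as.integer(target_w),
                 target_h = as.integer(target_h),
                 kernel_size = as.integer(kernel_size),
                 bottom_cut_fraction = bottom_cut_fraction,
                 threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 frozen_features = isTRUE(frozen_features),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `L`, `n_frames`, `target_w`, `target_h`,
#' `kernel_size`, `bottom_cut_fraction`, `keypoints`,
#' `threshold_method`, `threshold_value`, `frozen_features`, `seed`.
#'
#' @param path YAML file path.
#' @return A `run_config`; the `keypoints` entry (if any) is attached as
#'   attribute `keypoints`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config(
    L = y$L %||% 4L, N = y$n_frames %||% 16L,
    target_w = y$target_w %||% 88L, target_h = y$target_h %||% 128L,
    kernel_size = y$kernel_size %||% 3L,
    bottom_cut_fraction = y$bottom_cut_fraction %||% 0.05,
    threshold_method = y$threshold_method %||% "otsu",
    threshold_value = y$threshold_value,
    frozen_features = y$frozen_features %||% FALSE,
    seed = y$seed %||% 1L)
  attr(cfg, "keypoints") <- y$keypoints
  cfg
}

# Flatten a sequence's frames into an n_pixels x N logical matrix.
flatten_frames <- function(sequence) {
  vapply(sequence$frames, function(f) as.vector(f == 255L),
         logical(length(sequence$frames[[1]])))
}

#' Initiation stage over the first L labeled subjects
#'
#' Computes each subject's GEI and folds all of them into the F-GEI
#' (`m_count = L`); builds the labeled sets (one or two classes depending
#' on which labels occur). No predictions are emitted — detection is
#' disabled during initiation.
#'
#' @param sequences list of `L` [gait_sequence()] objects, each carrying
#'   a `"normal"` or `"abnormal"` label.
#' @param config a [run_config()].
#' @return Pipeline state (class `agd_state`) to pass to [detect_next()].
#' @export
run_initiation <- function(sequences, config = run_config()) {
  if (length(sequences) == 0L) stop("empty initiation", call. = FALSE)
  labels <- vapply(sequences, `[[`, character(1), "label")
  if (any(is.na(labels)))
    stop("initiation sequences must all carry labels", call. = FALSE)
  if (any(vapply(sequences, function(s) length(s$frames), integer(1)) != config$N))
    stop("shape mismatch: initiation sequences must have N frames", call. = FALSE)
  geis <- lapply(sequences, compute_gei)
  fgei <- compute_fgei_batch(geis)
  bmat <- do.call(cbind, lapply(sequences, flatten_frames))
  labeled <- split(seq_along(sequences), labels)
  # keep "normal" first for readability
  labeled <- labeled[order(names(labeled) != "normal")]
  counters <- new.env(parent = emptyenv())
  counters$clustering_calls <- 0L
  state <- list(
    config = config,
    fgei = fgei,
    bmat = bmat,
    dim = dim(sequences[[1]]$frames[[1]]),
    subject_ids = vapply(sequences, `[[`, character(1), "subject_id"),
    true_labels = labels,
    predicted = labels,        # initiation labels are ground truth, not scored
    clamped = rep(NA, length(sequences)),
    labeled = labeled,
    frozen = if (config$frozen_features)
      matrix(numeric(0), 0, 2) else NULL,
    records = data.frame(),
    counters = counters)
  if (config$frozen_features) {
    thr <- select_threshold(fgei, config$threshold_method,
                            config$threshold_value)
    mask <- segment_energy_mask(fgei, thr)
    state$frozen <- overlap_features_matrix(bmat, mask, config$N)
  }
  class(state) <- "agd_state"
  state
}

#' Detect one more passing subject
#'
#' Runs the online per-subject chain: GEI, incremental F-GEI update,
#' energy-mask recomputation, overlap features for all involved subjects
#' (or only the new one under `frozen_features`), then BC-COP-K-means.
#'
#' @param state pipeline state from [run_initiation()] (or a previous
#'   `detect_next` call).
#' @param sequence the passing subject's [gait_sequence()] (N frames on
#'   the canonical canvas).
#' @return Updated state; the new detection record is the last row of
#'   `state$records` (columns `subject_id`, `index`, `predicted`,
#'   `clamped`, `m_at_detection`, `true_label`).
#' @export
detect_next <- function(state, sequence) {
  stopifnot(inherits(state, "agd_state"), inherits(sequence, "gait_sequence"))
  cfg <- state$config
  if (length(sequence$frames) != cfg$N)
    stop(sprintf("subject '%s': expected %d frames, got %d",
                 sequence$subject_id, cfg$N, length(sequence$frames)),
         call. = FALSE)
  if (!all(dim(sequence$frames[[1]]) == state$dim))
    stop(sprintf("subject '%s': frame dimensions differ from pipeline canvas",
                 sequence$subject_id), call. = FALSE)
  gei <- compute_gei(sequence)
  state$fgei <- update_fgei(state$fgei, gei)
  state$bmat <- cbind(state$bmat, flatten_frames(sequence))
  m <- state$fgei$m_count
  thr <- select_threshold(state$fgei, cfg$threshold_method, cfg$threshold_value)
  mask <- segment_energy_mask(state$fgei, thr)
  if (cfg$frozen_features) {
    new_cols <- state$bmat[, (ncol(state$bmat) - cfg$N + 1L):ncol(state$bmat),
                           drop = FALSE]
    state$frozen <- rbind(state$frozen,
                          overlap_features_matrix(new_cols, mask, cfg$N))
    points <- state$frozen
  } else {
    points <- overlap_features_matrix(state$bmat, mask, cfg$N)
  }
  res <- bc_cop_kmeans(points, state$labeled, new_index = m,
                       seed = cfg$seed + 131L * m,
                       counters = state$counters)
  state$subject_ids <- c(state$subject_ids, sequence$subject_id)
  state$true_labels <- c(state$true_labels, sequence$label)
  state$predicted <- c(state$predicted, res$label)
  state$clamped <- c(state$clamped, res$clamped)
  rec <- data.frame(subject_id = sequence$subject_id, index = m,
                    predicted = res$label, clamped = res$clamped,
                    m_at_detection = m,
                    true_label = sequence$label,
                    stringsAsFactors = FALSE)
  state$records <- rbind(state$records, rec)
  state
}

#' Correct classification rate (CCR)
#'
#' Fraction of post-initiation subjects (indices `L+1 .. S`) whose
#' predicted label matches the known label.
#'
#' @param records detection records (data frame with `index`,
#'   `predicted`, `true_label`).
#' @param L initiation count; records must cover `L+1 .. S`.
#' @param S total subject count.
#' @return CCR in `[0, 1]`.
#' @export
ccr <- function(records, L, S) {
  want <- seq.int(L + 1L, S)
  sub <- records[match(want, records$index), , drop = FALSE]
  if (any(is.na(sub$index)))
    stop("records must cover subjects L+1..S", call. = FALSE)
  if (any(is.na(sub$true_label)))
    stop("unlabeled ground truth", call. = FALSE)
  mean(sub$predicted == sub$true_label)
}

#' Anomaly correct classification rate (ACCR)
#'
#' Fraction of the abnormal subjects that were detected as abnormal.
#'
#' @param records detection records.
#' @param abnormal_index indices of the abnormal subjects to score; by
#'   default every record whose true label is `"abnormal"`.
#' @return ACCR in `[0, 1]`.
#' @export
accr <- function(records, abnormal_index = NULL) {
  if (is.null(abnormal_index))
    abnormal_index <- records$index[!is.na(records$true_label) &
                                      records$true_label == "abnormal"]
  if (length(abnormal_index) == 0L)
    stop("no abnormal subjects: ACCR undefined", call. = FALSE)
  sub <- records[match(abnormal_index, records$index), , drop = FALSE]
  if (any(is.na(sub$index)) || any(is.na(sub$true_label)) ||
      any(sub$true_label != "abnormal"))
    stop("every scored subject needs a record with a true abnormal label",
         call. = FALSE)
  mean(sub$predicted == "abnormal")
}

#' Run the full online flow over an ordered subject stream
#'
#' Initiation over the first `L` sequences (their ground-truth labels are
#' the visual-inspection labels), then one detection step per remaining
#' subject, then evaluation when ground truth is available.
#'
#' @param sequences ordered list of [gait_sequence()] objects (the
#'   subject stream); the first `config$L` must be labeled.
#' @param config a [run_config()].
#' @return List of class `agd_report`: `records`, `ccr`, `accr` (`NA`
#'   when ground truth or abnormal subjects are missing), `state`,
#'   `clamp_rate`.
#' @export
run_stream <- function(sequences, config = run_config()) {
  stopifnot(length(sequences) > config$L)
  state <- run_initiation(sequences[seq_len(config$L)], config)
  for (s in sequences[(config$L + 1L):length(sequences)])
    state <- detect_next(state, s)
  S <- length(sequences)
  truth_known <- !any(is.na(state$records$true_label))
  rep_ccr <- if (truth_known) ccr(state$records, config$L, S) else NA_real_
  rep_accr <- if (truth_known &&
                  any(state$records$true_label == "abnormal"))
    accr(state$records) else NA_real_
  structure(list(records = state$records, ccr = rep_ccr, accr = rep_accr,
                 clamp_rate = mean(state$records$clamped),
                 clustering_calls = state$counters$clustering_calls,
                 state = state),
            class = "agd_report")
}

#' @export
print.agd_report <- function(x, ...) {
  cat(sprintf("<agd_report> %d detections | CCR %s | ACCR %s | clamp rate %.2f\n",
              nrow(x$records),
              ifelse(is.na(x$ccr), "NA", sprintf("%.4f", x$ccr)),
              ifelse(is.na(x$accr), "NA", sprintf("%.4f", x$accr)),
              x$clamp_rate))
  invisible(x)
}

#' Write a detection report as JSON
#'
#' @param report an `agd_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  cfg <- report$state$config
  out <- list(config = unclass(cfg),
              records = report$records,
              ccr = report$ccr, accr = report$accr,
              clamp_rate = report$clamp_rate)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
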