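# Parametric synthetic silhouette walker. A side-view binary body —
# rectangular torso, disc head, two legs whose horizontal spread swings
# sinusoidally across frames — with controllable abnormal variants:
# postural lean (shear), asymmetric leg swing, or reduced oscillation.
# Salt-and-pepper noise and interior holes emulate segmentation defects.
# Rasterization is integer-only so frames reproduce bit-for-bit.

#' Walker body parameters
#'
#' All geometry in pixels on the rendering canvas. Defaults draw a
#' roughly 113-pixel-tall adult silhouette.
#'
#' @param torso_width,torso_height torso rectangle size.
#' @param head_radius head disc radius.
#' @param leg_length hip-to-ankle distance.
#' @param leg_width thickness of each leg.
#' @param stride_amplitude peak horizontal ankle offset from the hip
#'   (half the peak ankle-to-ankle spread).
#' @param phase_offset starting gait phase in `[0, 2*pi)`.
#' @param lean torso shear in pixels per row (positive leans the head
#'   forward); 0 for an upright walker.
#' @param asymmetry left/right stride ratio in `(0, 1]`; 1 is symmetric.
#' @param noise_rate per-pixel salt-and-pepper flip probability, at most
#'   0.2.
#' @param hole_rate per-frame probability of an interior erasure, at most
#'   0.2.
#' @return List of class `walker_params`.
#' @export
walker_params <- function(torso_width = 24, torso_height = 50,
                          head_radius = 9, leg_length = 45, leg_width = 7,
                          stride_amplitude = 14, phase_offset = 0,
                          lean = 0, asymmetry = 1,
                          noise_rate = 0, hole_rate = 0) {
  stopifnot(torso_width > 0, torso_height > 0, head_radius > 0,
            leg_length > 0, leg_width > 0, stride_amplitude >= 0,
            asymmetry > 0, asymmetry <= 1,
            noise_rate >= 0, noise_rate <= 0.2,
            hole_rate >= 0, hole_rate <= 0.2)
  structure(as.list(environment()), class = "walker_params")
}

# Rasterize one walker pose. Returns an h x w binary matrix.
draw_walker <- function(params, phase, canvas_w, canvas_h) {
  p <- params
  total_h <- 2 * p$head_radius + p$torso_height + p$leg_length
  if (total_h + 4 > canvas_h || p$torso_width + 2 * p$stride_amplitude +
      p$leg_width + 4 > canvas_w)
    stop("canvas overflow: body model exceeds canvas", call. = FALSE)
  m <- matrix(0L, canvas_h, canvas_w)
  cx <- as.integer(round(canvas_w / 2))
  y_ground <- canvas_h - 2L
  y_hip <- y_ground - as.integer(round(p$leg_length))
  y_shoulder <- y_hip - as.integer(round(p$torso_height))
  y_head <- y_shoulder - as.integer(round(p$head_radius))
  # torso
  half_w <- as.integer(round(p$torso_width / 2))
  m[y_shoulder:y_hip, (cx - half_w):(cx + half_w)] <- 255L
  # head disc
  r <- p$head_radius
  for (dy in -ceiling(r):ceiling(r)) {
    half <- floor(sqrt(max(r^2 - dy^2, 0)))
    yy <- y_head + dy
    if (yy >= 1 && yy <= canvas_h)
      m[yy, max(1, cx - half):min(canvas_w, cx + half)] <- 255L
  }
  # legs: linear interpolation hip -> ankle, thick columns
  hip_off <- as.integer(round(p$torso_width / 4))
  lw <- as.integer(round(p$leg_width / 2))
  swing <- c(p$stride_amplitude * sin(phase),
             -p$stride_amplitude * p$asymmetry * sin(phase))
  hips <- c(cx - hip_off, cx + hip_off)
  for (leg in 1:2) {
    ankle_x <- hips[leg] + swing[leg]
    for (yy in y_hip:y_ground) {
      f <- (yy - y_hip) / (y_ground - y_hip)
      xc <- as.integer(round(hips[leg] + f * (ankle_x - hips[leg])))
      lo <- max(1L, xc - lw); hi <- min(canvas_w, xc + lw)
      m[yy, lo:hi] <- 255L
    }
  }
  # postural lean as integer row-wise shear about the ground line
  if (p$lean != 0) {
    out <- matrix(0L, canvas_h, canvas_w)
    for (yy in seq_len(canvas_h)) {
      shift <- as.integer(round(p$lean * (y_ground - yy)))
      cols <- which(m[yy, ] == 255L)
      cols <- cols + shift
      cols <- cols[cols >= 1 & cols <= canvas_w]
      out[yy, cols] <- 255L
    }
    m <- out
  }
  m
}

#' Render one subject's synthetic gait sequence
#'
#' `n_frames` binary frames of the walker; the leg spread follows one
#' full sinusoidal gait cycle across the sequence starting at
#' `phase_offset`. Noise (salt-and-pepper flips) and interior holes are
#' applied after rasterization. Deterministic given `seed`.
#'
#' @param params a [walker_params()].
#' @param n_frames number of frames `N`.
#' @param canvas_w,canvas_h rendering canvas size in pixels.
#' @param seed integer seed for noise and holes.
#' @param subject_id identifier for the resulting sequence.
#' @param label optional ground-truth label to attach.
#' @return A [gait_sequence()] of raw (unpreprocessed) frames.
#' @export
render_sequence <- function(params, n_frames = 16L, canvas_w = 96L,
                            canvas_h = 132L, seed = 1L,
                            subject_id = "synthetic", label = NA_character_) {
  stopifnot(inherits(params, "walker_params"), n_frames >= 1L)
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(t) {
      phase <- params$phase_offset + 2 * pi * (t - 1) / n_frames
      m <- draw_walker(params, phase, canvas_w, canvas_h)
      if (params$noise_rate > 0) {
        flip <- runif(length(m)) < params$noise_rate
        m[flip] <- 255L - m[flip]
      }
      if (params$hole_rate > 0 && runif(1) < params$hole_rate) {
        fg <- which(m == 255L, arr.ind = TRUE)
        if (nrow(fg) > 0) {
          ctr <- fg[sample.int(nrow(fg), 1L), ]
          rr <- sample(2:4, 1L)
          rows <- pmax(1, ctr[1] - rr):pmin(canvas_h, ctr[1] + rr)
          cols <- pmax(1, ctr[2] - rr):pmin(canvas_w, ctr[2] + rr)
          m[rows, cols] <- 0L
        }
      }
      m
    })
  })
  gait_sequence(subject_id, frames, label)
}

#' Cohort specification for the synthetic study
#'
#' Defaults mirror a small gait-anomaly study: 62 subjects of which 12
#' walk abnormally, 16 frames each, abnormality expressed as a postural
#' lean. `effect_size` scales the perturbed parameter away from its
#' normal value; at `effect_size = 1` the abnormal subjects are drawn
#' from the normal distribution (null cohort).
#'
#' @param n_normal,n_abnormal subject counts.
#' @param abnormal_mode `"lean"`, `"asymmetry"` or `"reduced_stride"`.
#' @param effect_size positive multiplier on the perturbed parameter
#'   (1 = no perturbation).
#' @param frames_per_subject frames `N` per subject.
#' @param canvas_w,canvas_h rendering canvas.
#' @param noise_rate,hole_rate defect rates applied to every subject.
#' @param seed cohort seed (jitter, phases, noise, stream order).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_normal = 50L, n_abnormal = 12L,
                        abnormal_mode = c("lean", "asymmetry",
                                          "reduced_stride"),
                        effect_size = 5, frames_per_subject = 16L,
                        canvas_w = 96L, canvas_h = 132L,
                        noise_rate = 0, hole_rate = 0, seed = 1L) {
  abnormal_mode <- match.arg(abnormal_mode)
  stopifnot(n_normal >= 0L, n_abnormal >= 0L, effect_size > 0)
  if (n_normal + n_abnormal == 0L)
    stop("empty cohort: subject counts are both zero", call. = FALSE)
  structure(list(n_normal = as.integer(n_normal),
                 n_abnormal = as.integer(n_abnormal),
                 abnormal_mode = abnormal_mode, effect_size = effect_size,
                 frames_per_subject = as.integer(frames_per_subject),
                 canvas_w = as.integer(canvas_w),
                 canvas_h = as.integer(canvas_h),
                 noise_rate = noise_rate, hole_rate = hole_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Per-subject walker parameters: base geometry with mild jitter, plus
# the abnormal perturbation scaled by (effect_size - 1)-style factors so
# effect_size = 1 reproduces the normal distribution exactly.
subject_params <- function(spec, abnormal) {
  es <- spec$effect_size
  lean <- 0
  asym <- 1
  stride <- max(4, rnorm(1, 14, 1.5))
  if (abnormal) {
    lean <- switch(spec$abnormal_mode, lean = 0.08 * (es - 1), 0)
    asym <- if (spec$abnormal_mode == "asymmetry") max(0.1, 1 / es) else 1
    if (spec$abnormal_mode == "reduced_stride") stride <- stride / es
  }
  walker_params(
    torso_width = max(14, rnorm(1, 24, 1.5)),
    torso_height = max(30, rnorm(1, 50, 2)),
    head_radius = max(6, rnorm(1, 9, 0.7)),
    leg_length = max(30, rnorm(1, 45, 2)),
    leg_width = max(5, rnorm(1, 7, 0.6)),
    stride_amplitude = stride,
    phase_offset = runif(1, 0, 2 * pi),
    lean = lean, asymmetry = asym,
    noise_rate = spec$noise_rate, hole_rate = spec$hole_rate)
}

#' Generate a labeled synthetic cohort
#'
#' Normal subjects draw jittered parameters around a common base;
#' abnormal subjects additionally carry the perturbation selected by
#' `abnormal_mode`, scaled by `effect_size`. The subject stream order is
#' shuffled by the cohort seed, emulating walkers passing the detection
#' point in random order.
#'
#' @param spec a [cohort_spec()].
#' @return List with `sequences` (ordered list of raw
#'   [gait_sequence()]s) and `manifest` (data frame: `subject_id`,
#'   `label`, `order_index`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_normal + spec$n_abnormal
  if (n == 0L) stop("empty cohort", call. = FALSE)
  labels <- c(rep("normal", spec$n_normal), rep("abnormal", spec$n_abnormal))
  ids <- sprintf("%s%02d", ifelse(labels == "normal", "B", "A"),
                 c(seq_len(spec$n_normal), seq_len(spec$n_abnormal)))
  cohort <- with_seed(spec$seed, {
    params <- lapply(seq_len(n), function(i)
      subject_params(spec, labels[i] == "abnormal"))
    seeds <- sample.int(.Machine$integer.max %/% 2L, n)
    order_idx <- sample.int(n)
    list(params = params, seeds = seeds, order = order_idx)
  })
  sequences <- lapply(seq_len(n), function(i)
    render_sequence(cohort$params[[i]], spec$frames_per_subject,
                    spec$canvas_w, spec$canvas_h, seed = cohort$seeds[i],
                    subject_id = ids[i], label = labels[i]))
  ord <- cohort$order
  list(sequences = sequences[ord],
       manifest = data.frame(subject_id = ids[ord], label = labels[ord],
                             order_index = seq_len(n),
                             stringsAsFactors = FALSE))
}

#' Write a cohort to a PNG directory tree
#'
#' One subdirectory per subject with frames as lexicographically ordered
#' PNGs — the same layout [read_cohort_dir()] ingests — plus
#' `manifest.csv` and the spec echoed as `cohort.yaml`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param spec optional [cohort_spec()] echoed to YAML.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sequences) {
    sub <- file.path(dir, s$subject_id)
    dir.create(sub, showWarnings = FALSE)
    for (j in seq_along(s$frames))
      png::writePNG(s$frames[[j]] / 255, file.path(sub, sprintf("frame_%03d.png", j)))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(spec))
    yaml::write_yaml(unclass(spec), file.path(dir, "cohort.yaml"))
  invisible(dir)
}
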