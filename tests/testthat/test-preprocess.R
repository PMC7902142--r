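# Frame selection, denoising, body extraction, normalization.

frame_with_centroid <- function(cx, h = 10, w = 20) {
  # a 2-pixel-wide column puts the centroid exactly at cx + 0.5
  m <- matrix(0L, h, w)
  m[4:6, cx:(cx + 1)] <- 255L
  m
}

test_that("select_frames picks nearest-centroid frames in key-point order", {
  frames <- lapply(c(1, 5, 9), function(cx) {
    m <- matrix(0L, 5, 12); m[2, cx] <- 255L; m
  })
  sel <- select_frames(frames, keypoints = c(1, 9))
  expect_identical(sel, frames[c(1, 3)])

  # nearest assignment without reuse, against the independent oracle
  frames2 <- lapply(c(1, 3, 5, 7, 9), function(cx) {
    m <- matrix(0L, 5, 12); m[2, cx] <- 255L; m
  })
  cx <- c(1, 3, 5, 7, 9)
  picks <- oracle_select(cx, c(4, 8))
  sel2 <- select_frames(frames2, keypoints = c(4, 8))
  expect_identical(sel2, frames2[picks])
})

test_that("select_frames resolves ties to the earlier frame and never reuses", {
  mk <- function(cx) { m <- matrix(0L, 3, 10); m[2, cx] <- 255L; m }
  frames <- lapply(c(2, 4, 6), mk)
  # key point 3 is equidistant from centroids 2 and 4 -> earlier frame
  sel <- select_frames(frames, keypoints = c(3, 4))
  expect_identical(sel[[1]], frames[[1]])
  expect_identical(sel[[2]], frames[[2]])  # frame 1 already taken
})

test_that("select_frames validates inputs", {
  f <- matrix(0L, 3, 3); f[2, 2] <- 255L
  expect_error(select_frames(list(f), keypoints = c(1, 2)),
               "insufficient frames")
  expect_error(select_frames(list(matrix(0L, 3, 3), f), keypoints = 2),
               "blank frame")
  expect_error(select_frames(list(f, f), keypoints = c(3, 1)),
               "strictly increasing")
})

test_that("denoise is a closing: fills holes, preserves closed shapes", {
  z <- matrix(0L, 8, 8)
  expect_identical(denoise(z, 3), z)

  holed <- rect_frame(14, 14, 3:12, 3:12)
  holed[7, 7] <- 0L
  expect_identical(denoise(holed, 3), oracle_closing(holed, 3))
  expect_equal(denoise(holed, 3)[7, 7], 255L)

  solid <- rect_frame(12, 12, 4:9, 4:9)
  expect_identical(denoise(solid, 3), solid)
})

test_that("denoise matches the direct dilate-then-erode oracle on random grids", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(sample(c(0L, 255L), 12 * 15, replace = TRUE, prob = c(0.6, 0.4)),
                12, 15)
    expect_identical(denoise(m, 3), oracle_closing(m, 3))
  }
})

test_that("closing is idempotent on random binary grids", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(sample(c(0L, 255L), 20 * 20, replace = TRUE), 20, 20)
    once <- denoise(m, 3)
    expect_identical(denoise(once, 3), once)
  }
})

test_that("denoise rejects invalid kernels", {
  m <- rect_frame(5, 5, 2:4, 2:4)
  expect_error(denoise(m, 2), "invalid kernel")
  expect_error(denoise(m, 0), "invalid kernel")
})

test_that("extract_body keeps the largest 8-connected component", {
  m <- matrix(0L, 20, 20)
  m[2:11, 2:6] <- 255L          # 50 px
  m[15:16, 15:19] <- 255L       # 10 px
  out <- extract_body(m, 0)
  expect_equal(sum(out == 255L), 50)
  expect_true(all(out[15:16, 15:19] == 0L))

  # diagonal-only touching pixels are one component under 8-connectivity
  d <- matrix(0L, 6, 6)
  d[2, 2] <- d[3, 3] <- d[4, 4] <- 255L
  d[6, 6] <- 255L  # separate single pixel
  out2 <- extract_body(d, 0)
  expect_equal(sum(out2 == 255L), 3)
})

test_that("extract_body cuts the bottom fraction of the bounding box", {
  m <- rect_frame(20, 10, 5:14, 3:7)  # 10 rows tall
  out <- extract_body(m, 0.1)
  expect_true(all(out[14, ] == 0L))        # bottom 1 row removed
  expect_true(all(out[5:13, 3:7] == 255L))
  expect_identical(extract_body(m, 0), m)  # identity at cut = 0
  expect_error(extract_body(matrix(0L, 4, 4), 0), "blank frame")
})

test_that("normalize_align produces the canonical canvas with centered centroid", {
  tw <- 20L; th <- 30L
  # already at target height and centered: unchanged
  base <- matrix(0L, th, tw)
  base[1:th, 9:12] <- 255L
  out <- normalize_align(list(base), tw, th)[[1]]
  expect_identical(out, base)

  # 2x-oversized silhouette scales to target height
  big <- matrix(0L, 60, 40)
  big[1:60, 17:24] <- 255L
  out2 <- normalize_align(list(big), tw, th)[[1]]
  bb <- range(which(rowSums(out2) > 0))
  expect_lte(abs((bb[2] - bb[1] + 1) - th), 1)

  # different raw sizes -> identical output dimensions
  small <- matrix(0L, 15, 9); small[2:14, 3:6] <- 255L
  outs <- normalize_align(list(big, small), tw, th)
  expect_true(all(vapply(outs, function(o) all(dim(o) == c(th, tw)), logical(1))))
})

test_that("normalize_align centers the centroid and preserves binarity", {
  set.seed(11)
  for (rep in 1:5) {
    h <- sample(30:50, 1); w <- sample(10:30, 1)
    m <- matrix(0L, h, w)
    # keep the silhouette taller than wide so the scaled width fits
    rspan <- sample(20:(h - 1), 1)
    cspan <- sample(seq_len(max(2, rspan %/% 3)), 1)
    r0 <- sample(seq_len(h - rspan), 1); c0 <- sample(seq_len(w - cspan), 1)
    m[r0:(r0 + rspan), c0:(c0 + cspan)] <- 255L
    out <- normalize_align(list(m), 40L, 64L)[[1]]
    expect_true(all(out %in% c(0L, 255L)))
    fg <- which(out > 0, arr.ind = TRUE)
    expect_lte(abs(mean(fg[, 2]) - (40 + 1) / 2), 1)
    hh <- diff(range(fg[, 1])) + 1
    expect_lte(abs(hh - 64), 1)
  }
})

test_that("preprocess_sequence chains into a fixed-size labeled sequence", {
  p <- walker_params()
  raw <- render_sequence(p, n_frames = 4, seed = 3, label = "normal")
  seq <- preprocess_sequence(raw$frames, "s1", target_w = 44L, target_h = 64L,
                             label = "normal")
  expect_s3_class(seq, "gait_sequence")
  expect_length(seq$frames, 4)
  expect_true(all(dim(seq$frames[[1]]) == c(64, 44)))
  expect_identical(seq$label, "normal")
})
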