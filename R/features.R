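# Deviation features. The F-GEI is thresholded into a binary high-energy
# mask E; a subject's per-frame overlap with E gives an N-element overlap
# vector, summarized by its mean and population standard deviation. The
# summary deliberately discards frame order: subjects are captured at
# arbitrary gait phases, so per-frame values are phase-sensitive but
# their distribution is not.

#' Select the F-GEI segmentation threshold
#'
#' Either a fixed gray level or Otsu's criterion (maximal between-class
#' variance) computed over the strictly positive pixels only — the zero
#' background outside the walking envelope would otherwise dominate the
#' histogram and pull the threshold down.
#'
#' @param fgei an `fgei` object.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_value gray level in `(0, 255]`, required for
#'   `method = "fixed"`.
#' @return Threshold `T` as a single numeric value.
#' @export
select_threshold <- function(fgei, method = c("otsu", "fixed"),
                             fixed_value = NULL) {
  stopifnot(inherits(fgei, "fgei"))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("fixed_value required", call. = FALSE)
    stopifnot(fixed_value > 0, fixed_value <= 255)
    return(as.numeric(fixed_value))
  }
  v <- fgei$pixels[fgei$pixels > 0]
  u <- sort(unique(v))
  if (length(u) < 2L)
    stop("degenerate image: no class separation among positive pixels",
         call. = FALSE)
  # Candidate thresholds: each observed level except the lowest (a
  # threshold at the minimum leaves the lower class empty). Any T between
  # two adjacent levels induces the same split, so observed levels are
  # exhaustive. Between-class variance via cumulative counts and sums.
  vs <- sort(v)
  n <- length(vs)
  cs <- cumsum(vs)
  k <- match(u[-1L], vs) - 1L       # elements strictly below each candidate
  w0 <- k / n
  w1 <- 1 - w0
  mu0 <- cs[k] / k
  mu1 <- (cs[n] - cs[k]) / (n - k)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  u[-1L][which.max(bcv)]
}

#' Segment the F-GEI into the high-energy mask
#'
#' `E(x, y) = 255` where `F(x, y) >= T`, else 0. The on-region is where
#' the involved subjects' bodies most frequently appear and serves as the
#' common reference for overlap features.
#'
#' @param fgei an `fgei` object.
#' @param threshold positive gray level `T`.
#' @return Binary matrix (class `energy_mask`) with attribute
#'   `threshold_used`.
#' @export
segment_energy_mask <- function(fgei, threshold) {
  stopifnot(inherits(fgei, "fgei"), threshold > 0)
  m <- matrix(0L, nrow(fgei$pixels), ncol(fgei$pixels))
  m[fgei$pixels >= threshold] <- 255L
  structure(m, threshold_used = as.numeric(threshold), class = c("energy_mask", class(m)))
}

#' Per-frame overlap of a subject's silhouettes with the energy mask
#'
#' For frame `j`, the fraction of mask on-pixels the silhouette covers:
#' `o_j = |B_j = 255 and E = 255| / |E = 255|`.
#'
#' @param sequence a [gait_sequence()] (frames must match the mask's
#'   dimensions).
#' @param mask binary energy mask with at least one on-pixel.
#' @return Numeric vector of length `N`, each element in `[0, 1]`.
#' @export
overlap_vector <- function(sequence, mask) {
  stopifnot(inherits(sequence, "gait_sequence"))
  on <- which(mask == 255L)
  if (length(on) == 0L) stop("empty energy mask", call. = FALSE)
  if (!all(dim(sequence$frames[[1]]) == dim(mask)))
    stop("shape mismatch: frames and mask differ in dimensions", call. = FALSE)
  vapply(sequence$frames, function(f) sum(f[on] == 255L) / length(on),
         numeric(1))
}

#' Summarize an overlap vector into the 2-D feature
#'
#' Mean and standard deviation of the overlap vector. The standard
#' deviation uses the population convention (divisor `N`): the vector is
#' a fixed N-element description of one subject, not a sample from a
#' larger population. Set `convention = "sample"` for the `N - 1`
#' divisor in sensitivity checks.
#'
#' @param o numeric overlap vector (length `N >= 1`).
#' @param convention `"population"` (default) or `"sample"`.
#' @return Numeric vector `c(mean, std)`.
#' @export
feature_vector <- function(o, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  if (length(o) == 0L) stop("no elements", call. = FALSE)
  m <- mean(o)
  s <- if (convention == "population") sqrt(mean((o - m)^2))
       else stats::sd(o)
  c(mean = m, std = unname(s))
}

# Vectorized overlap features for many subjects at once. `bmat` is an
# n_pixels x (N * n_subjects) logical matrix of flattened frames in
# subject-major order; returns an n_subjects x 2 matrix (mean, std).
overlap_features_matrix <- function(bmat, mask, n_frames) {
  on <- which(mask == 255L)
  if (length(on) == 0L) stop("empty energy mask", call. = FALSE)
  o <- colSums(bmat[on, , drop = FALSE]) / length(on)
  om <- matrix(o, nrow = n_frames)
  mu <- colMeans(om)
  s <- sqrt(pmax(colMeans(om^2) - mu^2, 0))
  cbind(mean = mu, std = s)
}

#' Write subject features (and overlap vectors) to CSV
#'
#' @param features data frame with columns `subject_id`, `mean`, `std`,
#'   and optionally the per-frame overlap columns `o1..oN`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
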