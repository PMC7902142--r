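# Semisupervised binary classification. Labeled subjects induce pairwise
# constraints (must-link within a class, cannot-link across classes);
# COP-K-means only permits constraint-respecting assignments; boundary
# clamping short-circuits clustering entirely when a new subject's
# feature lies inside exactly one labeled class's bounding box.

#' Generate pairwise constraints from labeled subject sets
#'
#' Every pair within one labeled class becomes a must-link; every pair
#' across classes becomes a cannot-link.
#'
#' @param labeled named list of disjoint integer index vectors, one per
#'   class (names are the class labels, e.g. `"normal"`, `"abnormal"`);
#'   one or two classes.
#' @return List with `must` and `cannot`, each a two-column integer
#'   matrix of unordered index pairs (zero rows when none).
#' @export
generate_constraints <- function(labeled) {
  stopifnot(is.list(labeled), length(labeled) >= 1L, length(labeled) <= 2L)
  idx <- unlist(labeled, use.names = FALSE)
  if (anyDuplicated(idx))
    stop("inconsistent labels: labeled subsets overlap", call. = FALSE)
  pairs_within <- function(v) {
    if (length(v) < 2L) return(matrix(integer(0), 0, 2))
    t(utils::combn(sort(v), 2L))
  }
  must <- do.call(rbind, lapply(labeled, pairs_within))
  cannot <- if (length(labeled) == 2L) {
    as.matrix(expand.grid(labeled[[1]], labeled[[2]], KEEP.OUT.ATTRS = FALSE))
  } else matrix(integer(0), 0, 2)
  dimnames(must) <- dimnames(cannot) <- NULL
  list(must = must, cannot = cannot)
}

# Resolve constraints to must-link components: points joined by a chain
# of must-links form one component; cannot-links lift to component pairs.
# Working at the component level makes constraint checking independent of
# the order in which points are visited (a raw pairwise check would let
# two ends of a must-link chain drift into different clusters before the
# middle point is reached) and surfaces inconsistencies up front.
resolve_constraints <- function(n, constraints) {
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  ml <- constraints$must
  if (nrow(ml) > 0) for (q in seq_len(nrow(ml))) {
    a <- find(ml[q, 1]); b <- find(ml[q, 2])
    if (a != b) comp[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp <- match(comp, unique(comp))
  cl <- constraints$cannot
  cannot <- if (nrow(cl) > 0) {
    pairs <- cbind(comp[cl[, 1]], comp[cl[, 2]])
    if (any(pairs[, 1] == pairs[, 2]))
      stop("inconsistent constraints: a cannot-link joins must-linked points",
           call. = FALSE)
    unique(t(apply(pairs, 1, sort)))
  } else matrix(integer(0), 0, 2)
  list(comp = comp, cannot = cannot)
}

# Would assigning point i to cluster k violate a constraint, given the
# partial assignment `asg` (NA = not yet assigned this iteration)?
violates_constraints <- function(i, k, asg, resolved) {
  ci <- resolved$comp[i]
  same <- which(resolved$comp == ci)
  pk <- asg[same]
  if (any(!is.na(pk) & pk != k)) return(TRUE)
  cl <- resolved$cannot
  if (nrow(cl) > 0) {
    other <- c(cl[cl[, 1] == ci, 2], cl[cl[, 2] == ci, 1])
    if (length(other) > 0) {
      pk <- asg[resolved$comp %in% other]
      if (any(!is.na(pk) & pk == k)) return(TRUE)
    }
  }
  FALSE
}

#' Constrained K-means (COP-K-means)
#'
#' Standard K-means iteration in which each point is assigned to the
#' nearest (Euclidean) center whose choice violates no must-link or
#' cannot-link constraint against points already assigned in the current
#' pass. If some point has no feasible cluster the attempt fails; up to
#' `restarts` fresh seeded initializations are tried before raising an
#' error, the original algorithm's failure mode.
#'
#' Centers initialize to `k` distinct data points drawn uniformly without
#' replacement. A cluster emptied during iteration is reseeded to the
#' point farthest from its assigned center. Points are clustered on the
#' raw feature scale (both dimensions are overlap proportions).
#'
#' @param points numeric matrix, one row per subject (any dimension).
#' @param k number of clusters (`k <= nrow(points)`).
#' @param constraints list with `must` / `cannot` pair matrices, as from
#'   [generate_constraints()]; `NULL` for unconstrained K-means.
#' @param seed integer seed controlling initialization (and restarts).
#' @param max_iter iteration cap per attempt.
#' @param restarts attempts with different initializations before failing.
#' @return List of class `cluster_assignment`: `labels` (cluster index
#'   per point), `centers` (k x d), `converged`, `n_iterations`,
#'   `attempts`.
#' @export
cop_kmeans <- function(points, k = 2L, constraints = NULL, seed = 1L,
                       max_iter = 100L, restarts = 10L) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(k >= 1L, k <= n)
  if (is.null(constraints))
    constraints <- list(must = matrix(integer(0), 0, 2),
                        cannot = matrix(integer(0), 0, 2))
  resolved <- resolve_constraints(n, constraints)
  for (attempt in seq_len(restarts)) {
    init <- with_seed(seed + attempt - 1L, {
      list(centers = points[sample.int(n, k), , drop = FALSE],
           # later attempts also reshuffle the assignment order: the
           # greedy pass can strand a point between cannot-linked
           # neighbors, and a different visiting order escapes that
           order = if (attempt == 1L) seq_len(n) else sample.int(n))
    })
    centers <- init$centers
    asg <- rep(NA_integer_, n)
    converged <- FALSE
    iter <- 0L
    feasible <- TRUE
    while (iter < max_iter) {
      iter <- iter + 1L
      new_asg <- rep(NA_integer_, n)
      for (i in init$order) {
        d2 <- colSums((t(centers) - points[i, ])^2)
        assigned <- FALSE
        for (kk in order(d2)) {
          if (!violates_constraints(i, kk, new_asg, resolved)) {
            new_asg[i] <- kk
            assigned <- TRUE
            break
          }
        }
        if (!assigned) { feasible <- FALSE; break }
      }
      if (!feasible) break
      for (kk in seq_len(k)) {
        members <- which(new_asg == kk)
        if (length(members) == 0L) {
          # reseed an emptied center to the worst-fit point
          d2own <- rowSums((points - centers[new_asg, , drop = FALSE])^2)
          centers[kk, ] <- points[which.max(d2own), ]
        } else {
          centers[kk, ] <- colMeans(points[members, , drop = FALSE])
        }
      }
      if (identical(new_asg, asg)) { converged <- TRUE; break }
      asg <- new_asg
    }
    if (feasible) {
      return(structure(list(labels = asg, centers = centers,
                            converged = converged, n_iterations = iter,
                            attempts = attempt),
                       class = "cluster_assignment"))
    }
  }
  stop("constraint violation failure: no feasible assignment in ",
       restarts, " attempts", call. = FALSE)
}

#' Per-class feature bounds from labeled subjects only
#'
#' For each labeled class, the per-dimension minimum and maximum over
#' that class's labeled members. Only subjects labeled in advance enter
#' the boxes — predictions never widen them.
#'
#' @param points numeric feature matrix, one row per subject.
#' @param labeled named list of class index vectors.
#' @return Named list of `d x 2` matrices (columns `min`, `max`).
#' @export
compute_bounds <- function(points, labeled) {
  points <- as.matrix(points)
  lapply(labeled, function(idx) {
    if (any(idx < 1L | idx > nrow(points)))
      stop("unknown subject: labeled index has no feature vector", call. = FALSE)
    sub <- points[idx, , drop = FALSE]
    cbind(min = apply(sub, 2, min), max = apply(sub, 2, max))
  })
}

#' Boundary clamping
#'
#' Assigns a feature vector directly to a labeled class when it falls
#' inside that class's per-dimension box (inclusive bounds) and inside no
#' other class's box. Inside zero or several boxes the result is `NULL`
#' and the decision falls through to clustering.
#'
#' @param v numeric feature vector.
#' @param bounds named list of class boxes from [compute_bounds()].
#' @return Class label (name in `bounds`) or `NULL`.
#' @export
boundary_clamp <- function(v, bounds) {
  stopifnot(length(bounds) >= 1L)
  inside <- vapply(bounds, function(b)
    all(v >= b[, "min"] & v <= b[, "max"]), logical(1))
  if (sum(inside) == 1L) names(bounds)[inside] else NULL
}

#' Map clusters to normal / abnormal labels
#'
#' The cluster holding the majority of labeled-normal subjects is
#' "normal". With two labeled classes the cannot-links already force the
#' labeled classes into distinct clusters; with one labeled class the
#' remaining cluster is "abnormal".
#'
#' @param assignment a `cluster_assignment` (two clusters).
#' @param labeled named list of class index vectors; must contain
#'   `"normal"`.
#' @return Character vector of per-subject labels
#'   (`"normal"`/`"abnormal"`).
#' @export
map_clusters <- function(assignment, labeled) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  normals <- labeled[["normal"]]
  if (is.null(normals) || length(normals) == 0L)
    stop("labeled sets must contain a 'normal' class", call. = FALSE)
  tab <- tabulate(assignment$labels[normals], nbins = 2L)
  if (tab[1] == tab[2])
    stop("ambiguous mapping: labeled normals split evenly", call. = FALSE)
  normal_cluster <- which.max(tab)
  ifelse(assignment$labels == normal_cluster, "normal", "abnormal")
}

#' Boundary-clamping constrained K-means (BC-COP-K-means)
#'
#' Classifies the newest subject: first boundary clamping against the
#' labeled classes' boxes; only when clamping is inconclusive does
#' COP-K-means run over all involved subjects with constraints generated
#' from the labeled sets, its two clusters mapped to normal/abnormal by
#' the labeled members. On a clamp, no clustering (and no distance
#' computation over the point set) happens at all — the mechanism's
#' efficiency advantage.
#'
#' @param points numeric feature matrix over all involved subjects.
#' @param labeled named list of labeled class index vectors.
#' @param new_index row of `points` for the newest subject.
#' @param seed integer seed passed to [cop_kmeans()].
#' @param counters optional environment; `counters$clustering_calls` is
#'   incremented whenever clustering actually runs (instrumentation).
#' @return List: `label` (the new subject's class), `clamped` (logical),
#'   `labels` (per-subject labels from the clustering run, or `NULL` on
#'   a clamp), `assignment` (the `cluster_assignment`, or `NULL`).
#' @export
bc_cop_kmeans <- function(points, labeled, new_index, seed = 1L,
                          counters = NULL) {
  points <- as.matrix(points)
  stopifnot(new_index >= 1L, new_index <= nrow(points))
  bounds <- compute_bounds(points, labeled)
  clamp <- boundary_clamp(points[new_index, ], bounds)
  if (!is.null(clamp)) {
    return(list(label = clamp, clamped = TRUE, labels = NULL,
                assignment = NULL))
  }
  if (!is.null(counters))
    counters$clustering_calls <- (counters$clustering_calls %||% 0L) + 1L
  constraints <- generate_constraints(labeled)
  assignment <- cop_kmeans(points, k = 2L, constraints = constraints,
                           seed = seed)
  labels <- map_clusters(assignment, labeled)
  list(label = labels[new_index], clamped = FALSE, labels = labels,
       assignment = assignment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
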