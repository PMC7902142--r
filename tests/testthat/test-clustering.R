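# Constraint generation, COP-K-means, boundary clamping, cluster mapping.

test_that("generate_constraints enumerates within/cross pairs", {
  cs <- generate_constraints(list(normal = c(1L, 2L), abnormal = 3L))
  expect_equal(cs$must, matrix(c(1L, 2L), 1, 2))
  expect_equal(nrow(cs$cannot), 2)
  expect_setequal(paste(cs$cannot[, 1], cs$cannot[, 2]), c("1 3", "2 3"))

  single <- generate_constraints(list(normal = 5L))
  expect_equal(nrow(single$must), 0)
  expect_equal(nrow(single$cannot), 0)

  # |Q1| = 3, |Q2| = 2 -> C(3,2)+C(2,2) = 4 must, 3*2 = 6 cannot,
  # cross-checked by exhaustive pair enumeration
  big <- generate_constraints(list(normal = 1:3, abnormal = 4:5))
  expect_equal(nrow(big$must), 4)
  expect_equal(nrow(big$cannot), 6)
  all_pairs <- t(combn(5, 2))
  same <- function(p) (p[1] <= 3) == (p[2] <= 3)
  expect_equal(nrow(big$must), sum(apply(all_pairs, 1, same)))
  expect_equal(nrow(big$cannot), sum(!apply(all_pairs, 1, same)))

  expect_error(generate_constraints(list(normal = 1:2, abnormal = 2:3)),
               "inconsistent labels")
})

test_that("cop_kmeans recovers the optimal unconstrained bipartition", {
  pts <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  res <- cop_kmeans(pts, 2, NULL, seed = 1)
  expect_true(res$converged)
  expect_equal(res$labels[1], res$labels[2])
  expect_equal(res$labels[3], res$labels[4])
  expect_false(res$labels[1] == res$labels[3])
  oracle <- oracle_best_bipartition(pts, list(must = matrix(integer(0), 0, 2),
                                              cannot = matrix(integer(0), 0, 2)))
  expect_equal(wcss_of(pts, res$labels), oracle$wcss, tolerance = 1e-9)
})

test_that("cannot-link separates identical points", {
  pts <- matrix(c(1, 1, 1, 1), 2, 2)
  cs <- list(must = matrix(integer(0), 0, 2),
             cannot = matrix(c(1L, 2L), 1, 2))
  res <- cop_kmeans(pts, 2, cs, seed = 4)
  expect_false(res$labels[1] == res$labels[2])
})

test_that("a must-link pulls a borderline point to its partner's cluster", {
  # dense cluster near 0, dense cluster near 1, borderline point slightly
  # nearer the far cluster
  pts <- rbind(matrix(c(0, 0.02, 0.05, 0.04, 0, 0.03), 3, 2),
               matrix(c(1, 0.98, 1.02, 0.01, 0.05, 0.02), 3, 2),
               c(0.60, 0.02))
  free <- cop_kmeans(pts, 2, NULL, seed = 2)
  expect_equal(free$labels[7], free$labels[4])  # drawn to the nearer cluster
  linked <- cop_kmeans(pts, 2, list(must = matrix(c(1L, 7L), 1, 2),
                                    cannot = matrix(integer(0), 0, 2)),
                       seed = 2)
  expect_equal(linked$labels[7], linked$labels[1])
})

test_that("cop_kmeans is deterministic for a fixed seed", {
  set.seed(88)
  pts <- matrix(rnorm(40), 20, 2)
  a <- cop_kmeans(pts, 2, NULL, seed = 9)
  b <- cop_kmeans(pts, 2, NULL, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centers, b$centers)
})

test_that("converged assignments always satisfy the constraints", {
  set.seed(500)
  ok <- 0L
  for (rep in 1:40) {
    inst <- random_instance(sample(5:30, 1), sample(0:10, 1))
    res <- tryCatch(cop_kmeans(inst$points, 2, inst$constraints, seed = rep),
                    error = function(e) e)
    if (inherits(res, "error")) {
      # the documented failure mode: assignment declared infeasible
      expect_match(conditionMessage(res), "constraint violation failure")
    } else {
      ok <- ok + 1L
      expect_true(constraints_ok(res$labels, inst$constraints))
    }
  }
  expect_gte(ok, 38L)  # failures must stay rare
})

test_that("compute_bounds boxes labeled members componentwise", {
  pts <- rbind(c(0.2, 0.1), c(0.4, 0.05), c(0.9, 0.3))
  b <- compute_bounds(pts, list(normal = 1:2, abnormal = 3L))
  expect_equal(b$normal[, "min"], c(0.2, 0.05))
  expect_equal(b$normal[, "max"], c(0.4, 0.1))
  expect_equal(b$abnormal[, "min"], b$abnormal[, "max"])
  # a labeled member is always inside its own box
  expect_equal(boundary_clamp(pts[3, ], b), "abnormal")
  expect_error(compute_bounds(pts, list(normal = c(1L, 9L))),
               "unknown subject")
})

test_that("boundary_clamp assigns inside exactly one box, else defers", {
  b <- list(normal = cbind(min = c(0, 0), max = c(1, 1)),
            abnormal = cbind(min = c(2, 2), max = c(3, 3)))
  expect_equal(boundary_clamp(c(0.5, 0.5), b), "normal")
  expect_null(boundary_clamp(c(1.5, 1.5), b))
  # inclusive boundaries
  expect_equal(boundary_clamp(c(1, 1), b), "normal")
  # overlapping boxes: ambiguity defers to clustering
  bo <- list(normal = cbind(min = c(0, 0), max = c(2, 2)),
             abnormal = cbind(min = c(1, 1), max = c(3, 3)))
  expect_null(boundary_clamp(c(1.5, 1.5), bo))
})

test_that("labeled subjects never clamp to the other class when boxes are disjoint", {
  set.seed(61)
  for (rep in 1:10) {
    pts_n <- matrix(runif(10, 0, 0.4), 5, 2)
    pts_a <- matrix(runif(6, 0.6, 1), 3, 2)
    pts <- rbind(pts_n, pts_a)
    labeled <- list(normal = 1:5, abnormal = 6:8)
    b <- compute_bounds(pts, labeled)
    for (i in 1:5) {
      cl <- boundary_clamp(pts[i, ], b)
      expect_true(is.null(cl) || cl == "normal")
    }
    for (i in 6:8) {
      cl <- boundary_clamp(pts[i, ], b)
      expect_true(is.null(cl) || cl == "abnormal")
    }
  }
})

test_that("map_clusters follows the labeled majority", {
  asg <- structure(list(labels = c(2L, 2L, 1L, 1L, 2L), centers = NULL,
                        converged = TRUE, n_iterations = 1L),
                   class = "cluster_assignment")
  lab <- map_clusters(asg, list(normal = c(1L, 2L)))
  expect_equal(lab, c("normal", "normal", "abnormal", "abnormal", "normal"))

  # even split among labeled normals is ambiguous
  asg2 <- structure(list(labels = c(1L, 2L, 1L, 2L), centers = NULL,
                         converged = TRUE, n_iterations = 1L),
                    class = "cluster_assignment")
  expect_error(map_clusters(asg2, list(normal = c(1L, 2L))),
               "ambiguous mapping")
})

test_that("bc_cop_kmeans clamps without invoking clustering", {
  pts <- rbind(c(0.1, 0.1), c(0.3, 0.3), c(0.9, 0.9), c(0.2, 0.2))
  labeled <- list(normal = 1:2, abnormal = 3L)
  counters <- new.env()
  counters$clustering_calls <- 0L
  res <- bc_cop_kmeans(pts, labeled, new_index = 4L, seed = 1,
                       counters = counters)
  expect_true(res$clamped)
  expect_equal(res$label, "normal")
  expect_equal(counters$clustering_calls, 0L)
  expect_null(res$assignment)
})

test_that("bc_cop_kmeans clusters when clamping is inconclusive", {
  set.seed(3)
  pts_n <- matrix(runif(12, 0.0, 0.2), 6, 2)
  pts_a <- matrix(runif(8, 0.8, 1.0), 4, 2)
  newpt <- c(0.45, 0.45)  # outside both boxes, nearer the normal block
  pts <- rbind(pts_n, pts_a, newpt)
  labeled <- list(normal = 1:3, abnormal = 7:8)
  counters <- new.env(); counters$clustering_calls <- 0L
  res <- bc_cop_kmeans(pts, labeled, new_index = 11L, seed = 5,
                       counters = counters)
  expect_false(res$clamped)
  expect_equal(counters$clustering_calls, 1L)
  # clustering must match the constrained exhaustive optimum's side
  oracle <- oracle_best_bipartition(pts, generate_constraints(labeled))
  same_side <- oracle$groups[11] == oracle$groups[1]
  expect_equal(res$label == "normal", same_side)
})

test_that("lambda = 1: a new subject inside the single labeled box is normal", {
  pts <- rbind(matrix(runif(12, 0.4, 0.6), 6, 2), c(0.5, 0.5))
  labeled <- list(normal = 1:6)
  res <- bc_cop_kmeans(pts, labeled, new_index = 7L, seed = 1)
  expect_true(res$clamped)
  expect_equal(res$label, "normal")
})
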