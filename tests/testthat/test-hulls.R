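unit_tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

test_that("hull construction validates its inputs", {
  h <- build_hulls(unit_tet, rep("A", 4))[[1]]
  expect_equal(nrow(h$N), 4)                      # a tetrahedron has 4 facets
  expect_equal(distance_to_hull(colMeans(unit_tet), h), 0)
  expect_error(build_hulls(unit_tet[1:3, ], rep("A", 3)), "at least 4")
  coplanar <- cbind(matrix(runif(8), 4), 0)
  expect_error(build_hulls(coplanar, rep("A", 4)), "coplanar")
  ## merged groups pool points under a combined label
  pts <- rbind(unit_tet, sweep(unit_tet, 2, c(5, 0, 0), "+"))
  hulls <- build_hulls(pts, c(rep("bwambae", 4), rep("fontenillei", 4)),
                       merge_groups = list(c("bwambae", "fontenillei")))
  expect_length(hulls, 1)
  expect_equal(hulls[[1]]$label, "bwambae+fontenillei")
  expect_equal(nrow(hulls[[1]]$points), 8)
})

test_that("point-to-hull distance: boundary, inside and exact face cases", {
  h <- build_hulls(unit_tet, rep("A", 4))[[1]]
  expect_equal(distance_to_hull(c(0, 0, 0), h), 0)      # vertex is inside
  expect_equal(distance_to_hull(c(0.2, 0.2, 0.2), h), 0)
  expect_equal(distance_to_hull(c(2, 0, 0), h), 1)      # beyond a vertex
  cube <- box_hull(c(0, 1))
  expect_equal(distance_to_hull(c(0.5, 0.5, 3), cube), 2)  # above a face
  expect_equal(distance_to_hull(c(3, 3, 0.5), cube),
               sqrt(8))                                   # beyond an edge
})

test_that("point-to-hull distance matches the surface-sampling oracle", {
  set.seed(81)
  for (i in 1:3) {
    verts <- matrix(rnorm(12), 4)
    h <- build_hulls(verts, rep("A", 4))[[1]]
    for (j in 1:2) {
      p <- rnorm(3, sd = 3)
      if (distance_to_hull(p, h) < 0.5) p <- p * 4
      d <- distance_to_hull(p, h)
      d_oracle <- oracle_surface_distance(p, verts)
      expect_equal(d, d_oracle, tolerance = 1e-6)
    }
  }
})

test_that("overlap means a shared interior point, not boundary contact", {
  hA <- build_hulls(unit_tet, rep("A", 4))[[1]]
  hFar <- build_hulls(sweep(unit_tet, 2, c(10, 0, 0), "+"), rep("B", 4))[[1]]
  expect_false(hulls_overlap(hA, hFar))
  hIn <- build_hulls(sweep(unit_tet, 2, c(0.1, 0.1, 0.1), "+"),
                     rep("C", 4))[[1]]
  expect_true(hulls_overlap(hA, hIn))
  ## sharing exactly one vertex (the origin): the plane x+y+z = 0 separates
  hMirror <- build_hulls(-unit_tet, rep("D", 4))[[1]]
  expect_true(all(rowSums(unit_tet) >= 0) && all(rowSums(-unit_tet) <= 0))
  expect_false(hulls_overlap(hA, hMirror))
})

test_that("trimming removes intruding points until hulls are disjoint", {
  set.seed(83)
  ## each cluster contains one point sitting at the other cluster's centre
  A <- rbind(matrix(rnorm(30, sd = 0.3), 10), c(3, 0, 0))
  B <- rbind(sweep(matrix(rnorm(30, sd = 0.3), 10), 2, c(3, 0, 0), "+"),
             c(0, 0, 0))
  hulls <- build_hulls(rbind(A, B), c(rep("a", 11), rep("b", 11)))
  expect_true(hulls_overlap(hulls[[1]], hulls[[2]]))
  tr <- trim_overlaps(hulls)
  expect_false(hulls_overlap(tr$hulls[[1]], tr$hulls[[2]]))
  expect_lte(nrow(tr$removed), 2)
  expect_setequal(unique(tr$removed$label), c("a", "b"))
  expect_true(all(tr$removed$depth > 0))
  ## every retained defining point classifies as its own label
  for (h in tr$hulls) {
    for (r in seq_len(nrow(h$points))) {
      cl <- classify_latent(h$points[r, ], tr$hulls, special_pair = NULL)
      expect_equal(cl$outcome, h$label)
    }
  }
  ## disjoint hulls are untouched
  far <- build_hulls(rbind(unit_tet, sweep(unit_tet, 2, c(9, 0, 0), "+")),
                     c(rep("x", 4), rep("y", 4)))
  tr2 <- trim_overlaps(far)
  expect_equal(nrow(tr2$removed), 0)
  expect_equal(tr2$hulls$x$points, far[[1]]$points)
})

test_that("classification applies the inside, ratio, radius and special rules", {
  ## axis-aligned boxes give exact distances along x
  hA <- box_hull(c(-1, 0), label = "A")
  hB <- box_hull(c(9, 10), label = "B")
  hC <- box_hull(c(20, 21), label = "C")
  p_inside <- c(-0.5, 0.5, 0.5)
  expect_equal(classify_latent(p_inside, list(hA, hB),
                               special_pair = NULL)$outcome, "A")
  ## distances {A: 1, B: 8}: 8 >= 7 x 1, classified A
  p1 <- c(1, 0.5, 0.5)
  cl1 <- classify_latent(p1, list(hA, hB), special_pair = NULL)
  expect_equal(unname(cl1$distances), c(1, 8))
  expect_equal(cl1$outcome, "A")
  ## distances {A: 1, B: 5, C: 19}: C is outside the radius, B inside
  hB5 <- box_hull(c(6, 7), label = "B")
  cl2 <- classify_latent(p1, list(hA, hB5, hC), special_pair = NULL)
  expect_equal(unname(cl2$distances), c(1, 5, 19))
  expect_equal(cl2$outcome, "uncertain_A_B")
  ## the gambiae/coluzzii exception: both hulls close by
  hG <- box_hull(c(-21, -11), label = "gambiae")
  hCo <- box_hull(c(12, 22), label = "coluzzii")
  p2 <- c(0, 0.5, 0.5)     # gambiae at 11, coluzzii at 12, both < 14
  cl3 <- classify_latent(p2, list(hG, hCo))
  expect_equal(unname(cl3$distances), c(11, 12))
  expect_equal(cl3$outcome, "uncertain_gambiae_coluzzii")
  cl4 <- classify_latent(c(1.5, 0.5, 0.5), list(hG, hCo))
  expect_equal(cl4$outcome, "uncertain_coluzzii_gambiae")
  ## far from both: the special rule does not fire and the ratio rule runs
  cl5 <- classify_latent(c(-25, 0.5, 0.5), list(hG, hCo))
  expect_equal(cl5$outcome, "gambiae")
})

test_that("classification outcomes are scale-covariant", {
  set.seed(87)
  hA <- box_hull(c(-1, 0), label = "A")
  hB <- box_hull(c(3, 4), label = "B")
  scale_hull <- function(h, c) build_hulls(h$points * c, rep(h$label, nrow(h$points)))[[1]]
  for (i in 1:20) {
    p <- rnorm(3, sd = 3)
    c0 <- runif(1, 0.5, 20)
    base <- classify_latent(p, list(hA, hB), special_pair = c("A", "B"),
                            special_dist = 2)
    scaled <- classify_latent(p * c0,
                              list(scale_hull(hA, c0), scale_hull(hB, c0)),
                              special_pair = c("A", "B"),
                              special_dist = 2 * c0)
    expect_equal(scaled$outcome, base$outcome)
    expect_equal(unname(scaled$distances), unname(c0 * base$distances),
                 tolerance = 1e-7)
  }
})

test_that("hull bundles round-trip through the text store", {
  set.seed(89)
  pts <- rbind(matrix(rnorm(24), 8), sweep(matrix(rnorm(24), 8), 2,
                                           c(8, 0, 0), "+"))
  tr <- trim_overlaps(build_hulls(pts, rep(c("left", "right"), each = 8)))
  dir <- withr::local_tempdir()
  save_hulls(tr, dir)
  back <- load_hulls(dir)
  expect_setequal(names(back), c("left", "right"))
  expect_equal(back$left$points, tr$hulls$left$points, ignore_attr = TRUE)
  p <- c(4, 0, 0)
  expect_equal(classify_latent(p, back, special_pair = NULL)$outcome,
               classify_latent(p, tr$hulls, special_pair = NULL)$outcome)
})
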