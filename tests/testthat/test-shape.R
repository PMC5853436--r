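test_that("resample_curve spaces points equally in arc length", {
  seg <- rbind(c(0, 0), c(0, 10))
  out <- resample_curve(seg, 5L)
  expect_equal(out[, 2], c(0, 2.5, 5, 7.5, 10))
  expect_equal(out[, 1], rep(0, 5))
  # L-shaped polyline: total length 7, midpoint at arc length 3.5
  L <- rbind(c(0, 0), c(0, 4), c(3, 4))
  out3 <- resample_curve(L, 3L)
  expect_equal(unname(out3[2, ]), c(0, 3.5))
  expect_equal(unname(out3[c(1, 3), ]), rbind(c(0, 0), c(3, 4)))
  # chord property: resampled arc length <= original, converging as m grows
  set.seed(5)
  wig <- cbind(cumsum(runif(40)), cumsum(rnorm(40)))
  l0 <- arc_length(wig)
  l10 <- arc_length(resample_curve(wig, 10L))
  l500 <- arc_length(resample_curve(wig, 500L))
  expect_lte(l10, l0 + 1e-12)
  expect_lte(l500, l0 + 1e-12)
  expect_lt(l0 - l500, l0 - l10 + 1e-12)
  expect_lt(l0 - l500, 0.02 * l0)
  expect_error(resample_curve(seg, 1L), "at least 2")
})

test_that("system distance is zero on identity and matches a loop oracle", {
  v <- vertical_system(10)
  expect_equal(system_distance(v, v), 0)
  co <- small_cohort()
  expect_equal(system_distance(co[[5]], co[[5]]), 0, tolerance = 1e-9)
  # vertical line vs 45-degree line, single curves: direct pointwise oracle
  m <- 50L
  a <- vertical_system(10)
  b <- root_system("b", c(0, 0), list(straight_seminal(45, 10)), toy_meta())
  pa <- resample_curve(a$curves[[1]]$points, m)
  pb <- resample_curve(b$curves[[1]]$points, m)
  oracle <- sqrt(mean(vapply(seq_len(m), function(i)
    sum((pa[i, ] - pb[i, ])^2), numeric(1))))
  expect_equal(system_distance(a, b, m = m), oracle, tolerance = 1e-12)
})

test_that("unmatched seminal pays its RMS distance to the origin", {
  m <- 50L
  a <- root_system("a", c(0, 0),
                   list(straight_seminal(0, 10), straight_seminal(45, 10)),
                   toy_meta())
  b <- vertical_system(10)
  pb <- resample_curve(a$curves[[2]]$points, m)
  penalty <- sqrt(mean(rowSums(pb^2)))
  # vertical roots match at zero cost; the 45-degree root is unmatched
  expect_equal(system_distance(a, b, m = m), penalty, tolerance = 1e-12)
})

test_that("system distance is symmetric and translation-invariant", {
  co <- small_cohort()
  set.seed(6)
  for (k in 1:5) {
    ij <- sample(length(co), 2)
    a <- co[[ij[1]]]; b <- co[[ij[2]]]
    expect_equal(system_distance(a, b), system_distance(b, a),
                 tolerance = 1e-9)
    shift <- rnorm(2, sd = 40)
    b2 <- b
    b2$seed_point <- b$seed_point + shift
    b2$curves <- lapply(b$curves, function(cv) {
      cv$points <- sweep(cv$points, 2L, shift, `+`); cv
    })
    expect_equal(system_distance(a, b2), system_distance(a, b),
                 tolerance = 1e-9)
  }
})

test_that("distance_matrix is symmetric with zero diagonal, permutation-consistent", {
  co <- small_cohort()[c(1, 20, 40)]
  class(co) <- "root_cohort"
  D <- distance_matrix(co, m = 20L)
  expect_equal(diag(unclass(D)), setNames(rep(0, 3), rownames(D)))
  expect_equal(unclass(D), t(unclass(D)))
  expect_length(unique(D[upper.tri(D)]), 3L)
  perm <- c(3, 1, 2)
  co2 <- co[perm]
  class(co2) <- "root_cohort"
  D2 <- distance_matrix(co2, m = 20L)
  expect_equal(unclass(D2), unclass(D)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
  # a cohort of clones has an all-zero matrix
  clones <- lapply(1:3, function(i) {
    s <- vertical_system(50, plant_id = paste0("c", i)); s
  })
  class(clones) <- "root_cohort"
  expect_equal(max(abs(distance_matrix(clones, m = 10L))), 0)
})

test_that("classical MDS embeds two points at +/- d/2", {
  D <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  emb <- classical_mds(D, k = 1L)
  expect_equal(sort(emb$coordinates[, 1]), c(-2, 2), ignore_attr = TRUE)
})

test_that("classical MDS recovers a planted Euclidean configuration exactly", {
  set.seed(7)
  config <- matrix(rnorm(30 * 5), 30, 5)
  D <- as.matrix(dist(config))
  emb <- classical_mds(D, k = 5L)
  expect_lt(procrustes_rms(config, emb$coordinates), 1e-8)
  # embedding distances reproduce D when k equals the affine dimension
  expect_lt(max(abs(as.matrix(dist(emb$coordinates)) - D)), 1e-8)
  # eigenvalues descending, retained ones positive
  expect_equal(emb$eigenvalues, sort(emb$eigenvalues, decreasing = TRUE))
  expect_true(all(emb$eigenvalues[1:5] > 0))
  expect_equal(emb$positive_mass_captured, 1, tolerance = 1e-8)
  # cross-check against the standard Torgerson implementation
  ref <- cmdscale(D, k = 5)
  for (j in 1:5) {
    expect_equal(abs(emb$coordinates[, j]), abs(ref[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_error(classical_mds(D, k = 10L), "positive eigenvalues")
})

test_that("first shape coordinate tracks overall size on a synthetic cohort", {
  co <- small_cohort()
  D <- distance_matrix(co, m = 20L)
  emb <- classical_mds(D, k = 5L)
  tot <- trait_record_matrix(co)[, "TotalLength"]
  expect_gt(abs(cor(emb$coordinates[, "Geom1"], tot)), 0.3)
})
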