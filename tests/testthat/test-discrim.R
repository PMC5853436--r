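test_that("scatter matrices satisfy hand-computed and algebraic identities", {
  # p = 1, groups {0,0} and {1,1}: means 0 and 1, grand 0.5 -> H = 1, E = 0
  X <- matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(NULL, "x"))
  sc <- scatter_matrices(X, c("a", "a", "b", "b"))
  expect_equal(unname(sc$H[1, 1]), 1)
  expect_equal(unname(sc$E[1, 1]), 0)
  # equal group means give H = 0
  X2 <- matrix(c(-1, 1, -1, 1), 4, 1)
  sc2 <- scatter_matrices(X2, c("a", "a", "b", "b"))
  expect_equal(unname(sc2$H[1, 1]), 0)
  # T equals the directly computed total scatter, and T = H + E
  set.seed(51)
  X3 <- matrix(rnorm(60), 20, 3)
  lab <- rep(1:4, each = 5)
  sc3 <- scatter_matrices(X3, lab)
  Xc <- sweep(X3, 2, colMeans(X3))
  expect_equal(unname(sc3$T), unname(crossprod(Xc)), tolerance = 1e-12)
  expect_lt(max(abs(sc3$T - sc3$H - sc3$E)), 1e-8 * max(abs(sc3$T)))
  expect_error(scatter_matrices(X3, rep(1, 20)), "2 groups")
  expect_error(scatter_matrices(X3, c(1, rep(2, 19))), "singleton")
})

test_that("two-group one-variable LDA reduces to the t statistic", {
  set.seed(52)
  x <- c(rnorm(12, 0), rnorm(18, 1.5))
  lab <- rep(c("a", "b"), c(12, 18))
  fit <- fit_lda(matrix(x, ncol = 1, dimnames = list(NULL, "x")), lab)
  gap <- diff(fit$group_means[, 1])
  tt <- t.test(x ~ lab, var.equal = TRUE)$statistic
  expect_equal(unname(abs(gap)), unname(abs(tt)) * sqrt(1 / 12 + 1 / 18),
               tolerance = 1e-10)
})

test_that("LDA satisfies its score and eigen conventions", {
  inst <- random_lda_instance(p = 5, g = 4, n_per = 15, seed = 53)
  fit <- fit_lda(inst$X, inst$labels)
  r <- ncol(fit$loadings)
  expect_equal(r, 3L)
  # pooled within-class covariance of scores is the identity
  N <- nrow(inst$X); G <- 4L
  sc <- scatter_matrices(fit$scores, inst$labels)
  expect_lt(max(abs(sc$E / (N - G) - diag(r))), 1e-6)
  # eigenvalues sorted, equal the between/within ratio of each score
  expect_equal(fit$eigenvalues, sort(fit$eigenvalues, decreasing = TRUE))
  for (j in seq_len(r))
    expect_equal(sc$H[j, j] / sc$E[j, j], fit$eigenvalues[j],
                 tolerance = 1e-8)
  # scores are centred
  expect_lt(max(abs(colMeans(fit$scores))), 1e-10)
})

test_that("LD1 maximizes the Rayleigh quotient (brute-force oracle)", {
  inst <- random_lda_instance(p = 3, g = 2, n_per = 10, seed = 54)
  fit <- fit_lda(inst$X, inst$labels)
  sc <- fit$scatter
  set.seed(55)
  bf <- brute_rayleigh_max(sc$H, sc$E, n_random = 1e5)
  a <- fit$loadings[, 1] / sqrt(sum(fit$loadings[, 1]^2))
  expect_gt(abs(sum(a * bf$direction)), 0.999)
  expect_equal(fit$eigenvalues[1], bf$value, tolerance = 1e-6)
})

test_that("two-group LD1 is collinear with the Fisher direction", {
  inst <- random_lda_instance(p = 6, g = 2, n_per = 25, seed = 56)
  fit <- fit_lda(inst$X, inst$labels)
  sc <- fit$scatter
  Sw <- sc$E / (nrow(inst$X) - 2L)
  fisher <- solve(Sw, sc$group_means[1, ] - sc$group_means[2, ])
  cs <- sum(fisher * fit$loadings[, 1]) /
    sqrt(sum(fisher^2) * sum(fit$loadings[, 1]^2))
  expect_gt(abs(cs), 1 - 1e-8)
})

test_that("LDA agrees with the reference implementation up to sign", {
  inst <- random_lda_instance(p = 4, g = 3, n_per = 20, seed = 57)
  fit <- fit_lda(inst$X, inst$labels)
  ref <- MASS::lda(inst$X, grouping = inst$labels)
  for (j in seq_len(ncol(fit$loadings))) {
    a <- fit$loadings[, j]; b <- ref$scaling[, j]
    expect_gt(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1 - 1e-6)
  }
})

test_that("orientation reference puts the low group on the negative side", {
  inst <- random_lda_instance(p = 4, g = 2, n_per = 20, seed = 58)
  ref <- c("low", "high")[inst$labels]
  fit <- fit_lda(inst$X, inst$labels, orientation_ref = ref)
  expect_lt(mean(fit$scores[ref == "low", 1]), 0)
  expect_gt(mean(fit$scores[ref == "high", 1]), 0)
})

test_that("singular within-scatter is reported with advice", {
  X <- cbind(x = rnorm(10), y = 0)
  expect_error(fit_lda(X, rep(1:2, 5)), "singular")
})

test_that("PCA conventions: correlation eigenstructure and diagonal score covariance", {
  set.seed(59)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  res <- pca(X, k = 3)
  expect_lt(max(abs(res$eigenvalues - 1)), 0.35)        # isotropic data
  covz <- cov(res$scores)
  expect_lt(max(abs(covz - diag(diag(covz)))), 1e-10)   # orthogonal scores
  # rank-1 structure concentrates the spectrum
  y <- rnorm(100)
  X1 <- cbind(a = y, b = 2 * y + rnorm(100, sd = 1e-4),
              c = -y + rnorm(100, sd = 1e-4))
  ev <- pca(X1, k = 1)$eigenvalues
  expect_gt(ev[1], 2.99)
  expect_lt(ev[2], 0.01)
  expect_error(pca(X, k = 5), "exceed")
})

test_that("Mahalanobis distance matches closed forms and the inverse oracle", {
  A <- matrix(c(-1, 1, -1, 1), 4, 1)
  expect_equal(mahalanobis_group_distance(A, A + 0), 0)
  # 1-D: pooled variance 1, means 0 and 1 -> distance 1
  a <- matrix(c(-1, 0, 1), 3, 1) / sd(c(-1, 0, 1))
  expect_equal(mahalanobis_group_distance(a, a + 1), 1, tolerance = 1e-12)
  # 2-D correlated toy vs explicit inverse
  set.seed(61)
  S <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  L <- chol(S)
  A2 <- matrix(rnorm(400), 200, 2) %*% L
  B2 <- sweep(matrix(rnorm(400), 200, 2) %*% L, 2, c(1, 0), `+`)
  d <- colMeans(A2) - colMeans(B2)
  Sp <- (199 * cov(A2) + 199 * cov(B2)) / 398
  oracle <- sqrt(drop(t(d) %*% solve(Sp) %*% d))
  expect_equal(mahalanobis_group_distance(A2, B2), oracle, tolerance = 1e-12)
})

test_that("Mahalanobis distance is invariant under joint affine maps", {
  set.seed(62)
  A <- matrix(rnorm(60), 20, 3)
  B <- sweep(matrix(rnorm(60), 20, 3), 2, c(1, -1, 2), `+`)
  d0 <- mahalanobis_group_distance(A, B)
  for (k in 1:5) {
    M <- matrix(rnorm(9), 3, 3)
    while (abs(det(M)) < 0.1) M <- matrix(rnorm(9), 3, 3)
    shift <- rnorm(3)
    f <- function(X) sweep(X %*% M, 2, shift, `+`)
    expect_equal(mahalanobis_group_distance(f(A), f(B)), d0,
                 tolerance = 1e-8)
  }
})

test_that("group distance maps: orderings, outlier line, degenerate cohort", {
  set.seed(63)
  lines <- c("L1", "L2", "L3", "L4")
  nupe <- c("low", "low", "high", "high")
  rows <- list()
  for (i in seq_along(lines)) {
    for (nit in c("low", "high")) {
      n <- 8
      mu <- if (lines[i] == "L2") 6 else 0   # planted aberrant line
      X <- matrix(rnorm(n * 3, mean = mu), n, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = sprintf("%s_%s_%d", lines[i], nit, 1:n),
        line = lines[i], nupe_class = nupe[i], nitrate = nit,
        group_code = group_code_for(nupe[i], nit),
        TotalLength = X[, 1], AvgSeminalTipAngle = X[, 2],
        AvgSeminalEmergAngle = X[, 3])
    }
  }
  df <- do.call(rbind, rows)
  for (v in setdiff(trait_vars(),
                    c("TotalLength", "AvgSeminalTipAngle",
                      "AvgSeminalEmergAngle")))
    df[[v]] <- rnorm(nrow(df))
  tab <- structure(df, class = c("trait_table", "data.frame"),
                   standardized = FALSE)
  mapA <- group_distance_map(tab, "line-pairs")
  mapB <- group_distance_map(tab, "nitrate-blocks")
  # same multiset of distances under both orderings
  expect_equal(sort(mapA$distances[upper.tri(mapA$distances)]),
               sort(mapB$distances[upper.tri(mapB$distances)]),
               tolerance = 1e-10)
  # line-pairs ordering alternates nitrate within each line
  expect_equal(mapA$cells$line[1:2], rep(mapA$cells$line[1], 2))
  expect_equal(mapA$cells$nitrate[1:2], c("low", "high"))
  # nitrate-blocks ordering puts all low-N cells of a NUpE block first
  lowblock <- mapB$cells[mapB$cells$nupe_class == "low", ]
  expect_equal(lowblock$nitrate, rep(c("low", "high"), each = 2))
  # the aberrant line is farthest from everything else
  rowmean <- rowMeans(mapA$distances)
  worst <- mapA$cells$line[order(rowmean, decreasing = TRUE)][1:2]
  expect_equal(unique(worst), "L2")
  expect_equal(diag(mapA$distances), setNames(rep(0, 8),
                                              rownames(mapA$distances)))
})

test_that("confidence regions follow the chi-square radius and 1/n scaling", {
  set.seed(64)
  Z <- matrix(rnorm(400), 200, 2)
  # whiten so the empirical covariance is exactly the identity
  Z <- sweep(Z, 2, colMeans(Z))
  Z <- Z %*% solve(chol(cov(Z)))
  half <- rep(c("g1", "g2"), each = 100)
  model <- list(scores = cbind(LD1 = Z[, 1], LD2 = Z[, 2]),
                labels = factor(half))
  class(model) <- "discriminant_model"
  reg <- mean_confidence_regions(model, level = 0.99, dims = c(1, 2))
  # each group has ~100 points with covariance ~I: radius ~ sqrt(9.21/100)
  r1 <- sqrt(rowSums(sweep(reg$g1$boundary, 2, reg$g1$centre)^2))
  expect_equal(mean(r1), sqrt(qchisq(0.99, 2) / 100), tolerance = 0.12)
  # level 0 collapses to the centre
  reg0 <- mean_confidence_regions(model, level = 0, dims = c(1, 2))
  expect_lt(max(abs(sweep(reg0$g1$boundary, 2, reg0$g1$centre))), 1e-12)
  # doubling n halves the ellipse area (shape = S/n)
  a1 <- det(reg$g1$shape)
  model2 <- list(scores = model$scores[c(1:100, 1:100, 101:200), ],
                 labels = factor(rep(c("g1", "g2"), c(200, 100))))
  class(model2) <- "discriminant_model"
  reg2 <- mean_confidence_regions(model2, level = 0.99, dims = c(1, 2))
  expect_equal(sqrt(det(reg2$g1$shape) / a1), 0.5, tolerance = 0.02)
})

test_that("percentile exemplars pick nearest plants with id tie-breaking", {
  scores <- setNames(as.numeric(1:10), as.character(1:10))
  ex <- percentile_exemplars(scores, k = 1L, step = 0.5)
  expect_equal(ex$plant_id[ex$percentile == 0], "1")
  expect_equal(ex$value[ex$percentile == 0.5], 5.5)
  # 5 and 6 tie at |score - 5.5|; the smaller id wins
  expect_equal(ex$plant_id[ex$percentile == 0.5], "5")
  # k = N returns every plant at every percentile
  exN <- percentile_exemplars(scores, k = 10L, step = 0.5)
  expect_setequal(exN$plant_id[exN$percentile == 1], as.character(1:10))
  # percentile 0 includes the minimum-score plant among its k
  ex5 <- percentile_exemplars(scores, k = 5L, step = 0.1)
  expect_true("1" %in% ex5$plant_id[ex5$percentile == 0])
  expect_error(percentile_exemplars(c(a = 1, b = NA_real_), k = 1),
               "finite")
})
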