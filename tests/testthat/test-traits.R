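test_that("single vertical seminal gives the expected trait vector", {
  tr <- compute_traits(vertical_system(100))
  expect_equal(unname(tr["TotalLength"]), 100)
  expect_equal(unname(tr["MaxDepth"]), 100)
  expect_equal(unname(tr["MaxWidth"]), 0)
  expect_equal(unname(tr["WidthDepthRatio"]), 0)
  expect_equal(unname(tr["ConvexHullArea"]), 0)
  expect_equal(unname(tr["AvgSeminalEmergAngle"]), 0)
  expect_equal(unname(tr["AvgSeminalTipAngle"]), 0)
  expect_equal(unname(tr["SeminalCount"]), 1)
  expect_equal(unname(tr["LateralCount"]), 0)
  expect_equal(unname(tr["AvgLateralLength"]), 0)
})

test_that("two straight seminals at +/-45 degrees match hand geometry", {
  sys <- root_system("fan", c(0, 0),
                     list(straight_seminal(45, sqrt(2) * 50),
                          straight_seminal(-45, sqrt(2) * 50)),
                     toy_meta())
  tr <- compute_traits(sys)
  expect_equal(unname(tr["MaxWidth"]), 100, tolerance = 1e-9)
  expect_equal(unname(tr["MaxDepth"]), 50, tolerance = 1e-9)
  expect_equal(unname(tr["WidthDepthRatio"]), 2, tolerance = 1e-9)
  # hull is the triangle (0,0), (-50,50), (50,50): area 2500
  expect_equal(unname(tr["ConvexHullArea"]), 2500, tolerance = 1e-9)
  expect_equal(unname(tr["AvgSeminalEmergAngle"]), 45, tolerance = 1e-9)
  expect_equal(unname(tr["AvgSeminalTipAngle"]), 45, tolerance = 1e-9)
  expect_equal(unname(tr["TotalLength"]), 2 * sqrt(2) * 50, tolerance = 1e-9)
})

test_that("lateral bookkeeping: one seminal with three laterals", {
  sem <- straight_seminal(0, 30)
  lats <- lapply(c(5, 10, 15), function(s)
    root_curve(rbind(c(0, s), c(3, s + 1)), "lateral", parent_index = 1L,
               attachment_arclength = s))
  sys <- root_system("lat3", c(0, 0), c(list(sem), lats), toy_meta())
  tr <- compute_traits(sys)
  expect_equal(unname(tr["LateralCount"]), 3)
  expect_equal(unname(tr["SeminalCount"]), 1)
  expect_equal(unname(tr["AvgLateralLength"]), sqrt(10), tolerance = 1e-12)
})

test_that("traits are translation-invariant and scale as s and s^2", {
  rs <- generate_root_system(default_group_params()[["1"]], seed = 21)
  tr <- compute_traits(rs)
  shift <- c(13.5, -4.2)
  moved <- rs
  moved$seed_point <- rs$seed_point + shift
  moved$curves <- lapply(rs$curves, function(cv) {
    cv$points <- sweep(cv$points, 2L, shift, `+`); cv
  })
  expect_equal(compute_traits(moved), tr, tolerance = 1e-9)
  s <- 2.5
  scaled <- rs
  scaled$curves <- lapply(rs$curves, function(cv) {
    cv$points <- cv$points * s
    if (cv$order == "lateral")
      cv$attachment_arclength <- cv$attachment_arclength * s
    cv
  })
  tr_s <- compute_traits(scaled)
  len_traits <- c("TotalLength", "AvgSeminalLength", "AvgLateralLength",
                  "MaxWidth", "MaxDepth")
  expect_equal(tr_s[len_traits], tr[len_traits] * s, tolerance = 1e-9)
  expect_equal(unname(tr_s["ConvexHullArea"]),
               unname(tr["ConvexHullArea"]) * s^2, tolerance = 1e-9)
  ang <- c("AvgSeminalTipAngle", "AvgSeminalEmergAngle", "WidthDepthRatio")
  expect_equal(tr_s[ang], tr[ang], tolerance = 1e-9)
  expect_equal(unname(tr_s["WidthDepthRatio"] * tr_s["MaxDepth"]),
               unname(tr_s["MaxWidth"]), tolerance = 1e-9)
})

test_that("standardize yields exact zero means and unit sample variances", {
  expect_equal(unname(standardize(matrix(c(1, 2, 3), 3, 1))[, 1]),
               c(-1, 0, 1))
  set.seed(31)
  X <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  Z <- standardize(X)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_equal(unname(apply(Z, 2, var)), rep(1, 3), tolerance = 1e-8)
  expect_equal(unname(standardize(Z)), unname(Z), tolerance = 1e-12)
  X[, 2] <- 7
  expect_error(standardize(X), "zero-variance.*b")
})

test_that("build_trait_table joins traits, shape coordinates and metadata", {
  co <- small_cohort()[1:5]
  class(co) <- "root_cohort"
  geom <- matrix(rnorm(25), 5, 5, dimnames = list(NULL, geom_vars()))
  tab <- build_trait_table(co, geom)
  expect_s3_class(tab, "trait_table")
  expect_equal(dim(as.data.frame(tab)), c(5L, 21L))
  expect_equal(names(tab)[1:5],
               c("plant_id", "line", "nupe_class", "nitrate", "group_code"))
  expect_false(attr(tab, "standardized"))
  # missing Geom columns rejected by name
  expect_error(build_trait_table(co, geom[, 1:4]), "Geom5")
  # row mismatch rejected
  expect_error(build_trait_table(co, geom[1:4, ]), "match")
})

test_that("trait CSV round-trips values to 1e-12", {
  co <- small_cohort()[1:6]
  class(co) <- "root_cohort"
  geom <- matrix(rnorm(30), 6, 5, dimnames = list(NULL, geom_vars()))
  tab <- build_trait_table(co, geom)
  path <- tempfile(fileext = ".csv")
  write_trait_csv(tab, path)
  back <- read_trait_csv(path)
  expect_equal(trait_matrix(back), trait_matrix(tab), tolerance = 1e-12)
  expect_identical(back$plant_id, tab$plant_id)
})

test_that("correlated_subset keeps exactly the strongly correlated variables", {
  set.seed(41)
  n <- 2000
  x <- rnorm(n)
  X <- cbind(a = x, b = x + rnorm(n, sd = 0.1), c = rnorm(n), d = rnorm(n))
  res <- correlated_subset(X, 0.5)
  expect_setequal(res$vars, c("a", "b"))
  expect_equal(dim(res$cor), c(4L, 4L))
  expect_equal(res$cor_display, round(res$cor, 2))
  # duplicated column is retained at any threshold below 1
  X2 <- cbind(u = x, v = x)
  expect_setequal(correlated_subset(X2, 1)$vars, c("u", "v"))
  # independent draws: no variable passes 0.5 at large n
  expect_length(correlated_subset(X[, c("c", "d")], 0.5)$vars, 0L)
  # threshold 0 keeps everything
  expect_length(correlated_subset(X, 0)$vars, 4L)
  expect_error(correlated_subset(X, 1.2), "threshold")
})
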