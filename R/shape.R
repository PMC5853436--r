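# Pairwise distance between root systems and classical (Torgerson) MDS.
#
# The distance contract: both systems are re-anchored so the seed sits at
# the origin; every curve is resampled to m points equally spaced in arc
# length; the cost between two curves is the root-mean-square of the
# pointwise Euclidean gaps of the m aligned points; seminal roots of the
# two plants are matched by a minimum-total-cost assignment, and so are the
# lateral sets; a curve left unmatched by a count difference pays its RMS
# distance to the degenerate curve at the origin; the distance is the
# seminal cost plus lateral_weight times the lateral cost. Symmetric and
# translation-invariant by construction; the triangle inequality is NOT
# guaranteed (assignment plus penalty terms can violate it). Size is
# deliberately retained: no normalisation by root count or length.

#' Resample a curve to equal arc-length spacing
#'
#' @param curve a [root_curve()] or two-column coordinate matrix.
#' @param m number of points (>= 2); endpoints are preserved.
#' @return same type as the input, with `m` points.
#' @export
resample_curve <- function(curve, m) {
  if (m < 2L) stop("'m' must be at least 2")
  pts <- if (inherits(curve, "root_curve")) curve$points else as.matrix(curve)
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  L <- cum[length(cum)]
  if (L <= 0) stop("cannot resample a zero-length curve")
  s <- seq(0, L, length.out = m)
  out <- cbind(approx(cum, pts[, 1], xout = s)$y,
               approx(cum, pts[, 2], xout = s)$y)
  colnames(out) <- colnames(pts)
  if (inherits(curve, "root_curve")) {
    curve$points <- out
    curve
  } else out
}

# flatten each curve of a system (seed at origin) into a 2m-vector row
prepare_system <- function(system, m) {
  shift <- system$seed_point
  orders <- vapply(system$curves, function(cv) cv$order, character(1))
  flat <- function(idx) {
    if (!length(idx)) return(matrix(numeric(0), 0L, 2L * m))
    t(vapply(system$curves[idx], function(cv) {
      p <- resample_curve(sweep(cv$points, 2L, shift), m)
      c(p[, 1], p[, 2])
    }, numeric(2L * m)))
  }
  list(sem = flat(which(orders == "seminal")),
       lat = flat(which(orders == "lateral")), m = m)
}

# minimum-cost matching between two curve sets, with origin penalties for
# the count difference; A, B are n x 2m flattened matrices
curve_set_cost <- function(A, B, m) {
  curve_set_cost_cpp(A, B, as.integer(m))
}

#' Distance between two root systems
#'
#' See the module header above for the construction. All knobs (resample
#' count `m`, `lateral_weight`) are exposed.
#'
#' @param a,b [root_system()] objects.
#' @param m resample count per curve.
#' @param lateral_weight weight of the lateral-set cost term.
#' @return nonnegative scalar; 0 when the systems have identical geometry
#'   relative to their seeds.
#' @export
system_distance <- function(a, b, m = 50L, lateral_weight = 1) {
  pa <- prepare_system(a, m)
  pb <- prepare_system(b, m)
  curve_set_cost(pa$sem, pb$sem, m) +
    lateral_weight * curve_set_cost(pa$lat, pb$lat, m)
}

#' All pairwise root-system distances of a cohort
#'
#' @param cohort a `root_cohort` (>= 2 plants).
#' @param m,lateral_weight passed to the distance; see [system_distance()].
#' @return object of class `distance_matrix`: a symmetric matrix with zero
#'   diagonal and plant ids as dimnames; attributes record `m` and
#'   `lateral_weight`.
#' @export
distance_matrix <- function(cohort, m = 50L, lateral_weight = 1) {
  n <- length(cohort)
  if (n < 2L) stop("need at least 2 plants")
  ids <- vapply(cohort, function(s) s$plant_id, character(1))
  preps <- lapply(cohort, prepare_system, m = m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- tryCatch(
        curve_set_cost(preps[[i]]$sem, preps[[j]]$sem, m) +
          lateral_weight * curve_set_cost(preps[[i]]$lat, preps[[j]]$lat, m),
        error = function(e) stop(sprintf("distance(%s, %s) failed: %s",
                                         ids[i], ids[j], conditionMessage(e))))
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(D, class = c("distance_matrix", "matrix"), m = m,
            lateral_weight = lateral_weight)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Doubly centres the squared distances, eigendecomposes the resulting
#' Gram matrix and returns the top-k coordinates scaled by the square roots
#' of the eigenvalues. Columns are named Geom1..Geomk and each is flipped
#' so its entry of largest magnitude is positive (a deterministic sign
#' convention). Negative eigenvalues (non-Euclidean input) are dropped and
#' their mass recorded.
#'
#' @param D a `distance_matrix` or symmetric nonnegative matrix.
#' @param k embedding dimension (default 5).
#' @return object of class `embedding_result` with `coordinates` (n x k),
#'   `eigenvalues` (all n, descending), `positive_mass_captured` (fraction
#'   of the positive eigenvalue mass held by the k retained axes) and
#'   `negative_mass` (absolute sum of negative eigenvalues).
#' @export
classical_mds <- function(D, k = 5L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-9)
    stop("'D' must be a symmetric distance matrix")
  d2 <- D^2
  rm <- rowMeans(d2); gm <- mean(d2)
  B <- -0.5 * (d2 - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + gm)
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  npos <- sum(e$values > tol)
  if (npos < k)
    stop(sprintf(paste0("only %d positive eigenvalues; choose k <= %d"),
                 npos, npos))
  lam <- e$values[seq_len(k)]
  X <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  for (j in seq_len(k)) {
    if (X[which.max(abs(X[, j])), j] < 0) X[, j] <- -X[, j]
  }
  dimnames(X) <- list(rownames(D), paste0("Geom", seq_len(k)))
  structure(list(coordinates = X, eigenvalues = e$values,
                 positive_mass_captured =
                   sum(lam) / sum(e$values[e$values > 0]),
                 negative_mass = sum(abs(e$values[e$values < 0]))),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result: %d plants x %d axes; %.1f%% of positive eigenvalue mass>\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$positive_mass_captured))
  invisible(x)
}
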