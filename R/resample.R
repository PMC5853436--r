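# Bootstrap inference on discriminant loadings and block-permutation
# significance tests.

#' Bootstrap the loadings of a fitted discriminant analysis
#'
#' Resamples plants (rows) with replacement B times, refits the LDA on the
#' chosen variable subset for each replicate, orders the discriminants by
#' eigenvalue, and flips each replicate discriminant's sign when its dot
#' product with the corresponding reference loading is negative (sign
#' alignment: without it, the arbitrary eigenvector sign would wash out
#' the loading means). Replicates that lose an entire group are redrawn
#' and counted.
#'
#' Two standard-error scales are reported: `sd` is the bootstrap standard
#' deviation of each loading, and `se = sd / sqrt(B)` the Monte-Carlo
#' standard error of the bootstrap mean. The per-loading p-value for a
#' zero loading is the normal approximation 2 Phi(-|mean| / se).
#'
#' @param X numeric matrix (plants x variables) with column names.
#' @param labels group label per row.
#' @param subset variables to refit on (default: all columns).
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param orientation_ref passed to [fit_lda()] for the reference fit.
#' @return object of class `bootstrap_result`: `B`, `replicates`
#'   (B x (p*r) matrix of sign-aligned loadings), `mean`, `sd`, `se`,
#'   `p_value` (p x r matrices), `covariance` and `correlation` of the
#'   flattened loadings, `reference` (the full-data model), `redraws`.
#' @export
bootstrap_loadings <- function(X, labels, subset = NULL, B = 1000L,
                               seed = NULL, orientation_ref = NULL) {
  if (B < 2L) stop("'B' must be at least 2")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.null(subset)) subset <- colnames(X)
  if (is.numeric(subset)) subset <- colnames(X)[subset]
  Xs <- X[, subset, drop = FALSE]
  g <- factor(labels)
  ref <- fit_lda(Xs, g, orientation_ref = orientation_ref)
  p <- ncol(Xs); r <- ncol(ref$loadings)
  if (!is.null(seed)) set.seed(as.integer(seed))
  N <- nrow(Xs)
  reps <- matrix(NA_real_, B, p * r)
  colnames(reps) <- as.vector(outer(subset, colnames(ref$loadings),
                                    paste, sep = ":"))
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(N, N, replace = TRUE)
      # a refit needs every group present with at least two members
      if (min(table(g[idx])) >= 2L) break
      redraws <- redraws + 1L
    }
    fit <- fit_lda(Xs[idx, , drop = FALSE], g[idx])
    A <- fit$loadings
    for (j in seq_len(r))
      if (sum(A[, j] * ref$loadings[, j]) < 0) A[, j] <- -A[, j]
    reps[b, ] <- as.vector(A)
  }
  mean_m <- matrix(colMeans(reps), p, r,
                   dimnames = dimnames(ref$loadings))
  sd_m <- matrix(apply(reps, 2L, sd), p, r,
                 dimnames = dimnames(ref$loadings))
  se_m <- sd_m / sqrt(B)
  pv <- 2 * pnorm(-abs(mean_m) / se_m)
  pv[se_m == 0 & mean_m == 0] <- 1
  pv[se_m == 0 & mean_m != 0] <- 0
  structure(list(B = B, replicates = reps, mean = mean_m, sd = sd_m,
                 se = se_m, p_value = pv, covariance = cov(reps),
                 correlation = suppressWarnings(cor(reps)),
                 reference = ref, redraws = redraws, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, digits = 2L, ...) {
  cat(sprintf("Bootstrapped loading means (SE), B = %d:\n", x$B))
  fmt <- matrix(sprintf(paste0("%.", digits, "f (%.3f)"), x$mean, x$se),
                nrow(x$mean), ncol(x$mean), dimnames = dimnames(x$mean))
  print(fmt, quote = FALSE)
  invisible(x)
}

#' Normal-approximation p-value for a bootstrapped loading
#'
#' `2 * pnorm(-abs(mean) / se)`: the two-sided tail probability of a zero
#' loading under a normal model for the bootstrap mean.
#' @param mean loading mean.
#' @param se its standard error.
#' @return p-value in [0, 1].
#' @export
loading_p_value <- function(mean, se) 2 * pnorm(-abs(mean) / se)

# ---------------------------------------------------------------------------
# block-permutation tests

#' Named block-permutation schemes over the four group codes
#'
#' Returns the label blocks that are shuffled for each named scheme:
#' `"all"` permutes all four codes; `"within-nupe"` permutes within (0,1)
#' and within (2,3); `"within-nitrate"` within (0,2) and (1,3);
#' `"crossed"` within (0,3) and (1,2); `"low-nupe"` permutes (0,1) holding
#' (2,3) fixed; `"high-nupe"` permutes (2,3) holding (0,1) fixed.
#' @return named list of lists of integer vectors.
#' @export
permutation_schemes <- function() {
  list("all" = list(0:3),
       "within-nupe" = list(c(0L, 1L), c(2L, 3L)),
       "within-nitrate" = list(c(0L, 2L), c(1L, 3L)),
       "crossed" = list(c(0L, 3L), c(1L, 2L)),
       "low-nupe" = list(c(0L, 1L)),
       "high-nupe" = list(c(2L, 3L)))
}

#' Block-permutation test of the zeta-squared criterion
#'
#' Shuffles group labels uniformly within each block of the scheme
#' (preserving group sizes and leaving labels outside every block fixed)
#' and recomputes the zeta-squared criterion of the full grouping on a
#' fixed variable subset. The p-value uses the add-one estimator
#' p = (1 + #\{null >= observed\}) / (1 + n_perm), which never returns 0.
#'
#' By default the statistic subset is fixed at the subset selected once on
#' the observed labels (or all variables when `statistic_subset` is NULL
#' and `reselect_size` is NA); fixing the subset is slightly
#' anti-conservative relative to re-selecting per permutation, which is
#' available via `reselect = TRUE` at substantial cost.
#'
#' @param X numeric matrix (plants x variables).
#' @param labels group codes per row (any labels; named schemes assume the
#'   codes 0--3).
#' @param scheme a name from [permutation_schemes()] or a list of label
#'   blocks.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param statistic_subset variable names for the statistic; default all.
#' @param reselect if TRUE, re-run [best_subsets()] of size
#'   `reselect_size` inside every permutation.
#' @param reselect_size subset size used when `reselect = TRUE`.
#' @return object of class `permutation_result`: `scheme`, `observed`,
#'   `null` (length n_perm), `p_value`, `n_perm`, `seed`, `subset`.
#' @export
permutation_test <- function(X, labels, scheme = "all", n_perm = 10000L,
                             seed = NULL, statistic_subset = NULL,
                             reselect = FALSE, reselect_size = 9L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (n_perm < 1L) stop("'n_perm' must be positive")
  scheme_name <- if (is.character(scheme)) scheme else "custom"
  if (is.character(scheme)) {
    schemes <- permutation_schemes()
    if (!scheme %in% names(schemes))
      stop("unknown scheme '", scheme, "'; see permutation_schemes()")
    blocks <- schemes[[scheme]]
  } else blocks <- scheme
  lab <- as.vector(labels)
  if (scheme_name == "all") blocks <- list(unique(lab))
  block_idx <- lapply(blocks, function(b) which(lab %in% b))
  for (bi in seq_along(blocks)) {
    found <- unique(lab[block_idx[[bi]]])
    if (length(found) < 2L)
      stop(sprintf("block %d holds fewer than 2 distinct labels", bi))
  }
  if (is.null(statistic_subset)) statistic_subset <- colnames(X)
  if (is.numeric(statistic_subset))
    statistic_subset <- colnames(X)[statistic_subset]
  Xs <- X[, statistic_subset, drop = FALSE]
  gcodes <- as.integer(factor(lab))      # 1..G for the fast path
  Tm <- crossprod(Xs - matrix(colMeans(Xs), nrow(Xs), ncol(Xs),
                              byrow = TRUE))
  stat <- function(gvec) {
    if (reselect) {
      bb <- best_subsets(X, gvec, sizes = reselect_size)
      bb$best[[1L]]$zeta2
    } else zeta2_stat(Xs, gvec, Tm = Tm)
  }
  observed <- stat(gcodes)
  if (!is.null(seed)) set.seed(as.integer(seed))
  null <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    gp <- gcodes
    for (idx in block_idx) gp[idx] <- gp[idx][sample.int(length(idx))]
    null[k] <- stat(gp)
  }
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(scheme = scheme_name, blocks = blocks,
                 observed = observed, null = null, p_value = p,
                 n_perm = n_perm, seed = seed, subset = statistic_subset),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test [%s]: observed zeta2 = %.4f, p = %.4g (n_perm = %d)\n",
              x$scheme, x$observed, x$p_value, x$n_perm))
  invisible(x)
}
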