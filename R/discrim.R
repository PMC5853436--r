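# Scatter decomposition, multi-group LDA, PCA, Mahalanobis group
# distances, confidence regions and percentile exemplars.

#' Between-, within- and total-scatter decomposition
#'
#' H = sum_g n_g (xbar_g - xbar)(xbar_g - xbar)', E = pooled within-group
#' scatter, T = H + E.
#'
#' @param X numeric matrix (plants x variables).
#' @param labels group label per row (factor or vector); every group needs
#'   at least 2 members and there must be at least 2 groups.
#' @return list of class `scatter_decomposition` with `H`, `E`, `T`,
#'   `group_sizes`, `grand_mean`, `group_means`.
#' @export
scatter_matrices <- function(X, labels) {
  X <- as.matrix(X)
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  ns <- table(g)
  if (any(ns < 2L))
    stop("singleton group(s): ", paste(names(ns)[ns < 2L], collapse = ", "))
  if (nrow(X) <= ncol(X))
    warning("fewer plants than variables + 1; scatter matrices may be singular")
  grand <- colMeans(X)
  gm <- rowsum(X, g) / as.vector(ns)
  dif <- gm - matrix(grand, nrow(gm), ncol(X), byrow = TRUE)
  H <- crossprod(dif * sqrt(as.vector(ns)))
  Xc <- X - matrix(grand, nrow(X), ncol(X), byrow = TRUE)
  Tm <- crossprod(Xc)
  E <- Tm - H
  dimnames(H) <- dimnames(E) <- dimnames(Tm) <-
    list(colnames(X), colnames(X))
  structure(list(H = H, E = E, T = Tm, group_sizes = as.vector(ns),
                 grand_mean = grand, group_means = gm,
                 groups = levels(g)),
            class = "scatter_decomposition")
}

#' Multi-group linear discriminant analysis
#'
#' Solves the generalized eigenproblem of the between-group scatter H
#' against the within-group scatter E by whitening through the Cholesky
#' factor of E, keeping r = min(p, g - 1) discriminants ordered by
#' decreasing eigenvalue. Each loading vector a is scaled so that
#' a' S_w a = 1 with S_w = E / (N - g): scores have identity pooled
#' within-class covariance, the convention under which printed loading
#' magnitudes are comparable across variables. Scores are centred at the
#' grand mean.
#'
#' Sign convention: when `orientation_ref` is supplied (a two-level
#' low/high factor aligned with the rows), LD1 is flipped so that the mean
#' score of the "low" level is negative; all other discriminants (and all
#' discriminants when no reference is supplied) are flipped so the loading
#' of largest magnitude is positive.
#'
#' @param X numeric matrix (plants x variables) with column names.
#' @param labels group label per row.
#' @param orientation_ref optional two-level reference contrast for LD1
#'   orientation; if its levels are "low"/"high" the "low" level is the
#'   negative side, otherwise the factor's first level is.
#' @return object of class `discriminant_model`: `loadings` (p x r),
#'   `eigenvalues`, `scores` (N x r), `group_means` (score space),
#'   `scatter` (the [scatter_matrices()] result), `grand_mean`,
#'   `variable_names`, `labels`.
#' @export
fit_lda <- function(X, labels, orientation_ref = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  g <- factor(labels)
  sc <- scatter_matrices(X, g)
  N <- nrow(X); G <- nlevels(g); p <- ncol(X)
  r <- min(p, G - 1L)
  R <- tryCatch(chol(sc$E), error = function(e)
    stop("within-group scatter is singular; drop or select variables, or regularize"))
  M <- backsolve(R, t(backsolve(R, t(sc$H), transpose = TRUE)),
                 transpose = TRUE)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  A <- backsolve(R, e$vectors[, seq_len(r), drop = FALSE]) * sqrt(N - G)
  rownames(A) <- colnames(X)
  colnames(A) <- paste0("LD", seq_len(r))
  scores <- (X - matrix(sc$grand_mean, N, p, byrow = TRUE)) %*% A
  # orientation
  flip_largest <- function(v) if (v[which.max(abs(v))] < 0) -1 else 1
  signs <- vapply(seq_len(r), function(j) flip_largest(A[, j]), numeric(1))
  if (!is.null(orientation_ref)) {
    ref <- factor(orientation_ref)
    if (nlevels(ref) != 2L)
      stop("'orientation_ref' must have exactly two levels")
    low <- if (all(levels(ref) %in% c("low", "high"))) "low" else
      levels(ref)[1L]
    signs[1L] <- if (mean(scores[ref == low, 1L]) > 0) -1 else 1
  }
  A <- sweep(A, 2L, signs, `*`)
  scores <- sweep(scores, 2L, signs, `*`)
  rownames(scores) <- rownames(X)
  gmeans <- rowsum(scores, g) / as.vector(table(g))
  structure(list(loadings = A, eigenvalues = e$values[seq_len(r)],
                 scores = scores, group_means = gmeans, scatter = sc,
                 grand_mean = sc$grand_mean, variable_names = colnames(X),
                 labels = g),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model: %d variables, %d groups, %d discriminants>\n",
              length(x$variable_names), nlevels(x$labels),
              ncol(x$loadings)))
  cat("eigenvalues:", signif(x$eigenvalues, 4L), "\n")
  print(round(x$loadings, 2L))
  invisible(x)
}

#' Principal component analysis of a standardized trait matrix
#'
#' Eigendecomposition of the correlation matrix, with the same
#' deterministic sign rule as the MDS embedding (largest-magnitude loading
#' entry positive).
#'
#' @param X numeric matrix.
#' @param k number of components.
#' @return list with `loadings` (p x k), `scores` (N x k), `eigenvalues`
#'   (all p).
#' @export
pca <- function(X, k = 3L) {
  X <- as.matrix(X)
  if (k > ncol(X)) stop("'k' cannot exceed the number of variables")
  e <- eigen(cor(X), symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PC", seq_len(k))
  Z <- scale(X) %*% V
  list(loadings = V, scores = Z, eigenvalues = e$values)
}

#' Mahalanobis distance between two samples
#'
#' D_M = sqrt((xbar_A - xbar_B)' S^-1 (xbar_A - xbar_B)), with S either the
#' pooled covariance of the two samples (`pooling = "pair"`) or a
#' caller-supplied pooled within-group covariance `S` (e.g. pooled over all
#' cells of an experiment, the stabler choice when p is large relative to
#' the per-cell sample sizes).
#'
#' @param A,B sample matrices (rows = plants).
#' @param pooling `"pair"` or `"supplied"`.
#' @param S pooled covariance matrix when `pooling = "supplied"`.
#' @return nonnegative scalar.
#' @export
mahalanobis_group_distance <- function(A, B,
                                       pooling = c("pair", "supplied"),
                                       S = NULL) {
  pooling <- match.arg(pooling)
  A <- as.matrix(A); B <- as.matrix(B)
  if (pooling == "pair") {
    if (nrow(A) < 2L || nrow(B) < 2L)
      stop("pair pooling needs at least 2 rows per sample")
    S <- ((nrow(A) - 1L) * cov(A) + (nrow(B) - 1L) * cov(B)) /
      (nrow(A) + nrow(B) - 2L)
  } else if (is.null(S)) {
    stop("supply 'S' when pooling = \"supplied\"")
  }
  d <- colMeans(A) - colMeans(B)
  if (all(d == 0)) return(0)
  v <- tryCatch(solve(S, d), error = function(e)
    stop("pooled covariance is singular; use all-groups pooling or fewer variables"))
  sqrt(max(sum(d * v), 0))
}

#' Mahalanobis distance map over line x nitrate cells
#'
#' Computes all pairwise Mahalanobis distances between the cell mean
#' vectors, pooling the within-cell covariance over all cells (N - G
#' degrees of freedom) by default. Two row/column orderings are offered:
#' `"line-pairs"` places the low- and high-nitrate samples of the same line
#' next to each other (low-NUpE lines first); `"nitrate-blocks"` groups
#' cells by nitrate level within each NUpE block.
#'
#' @param table a `trait_table` (standardized or raw).
#' @param mode ordering mode.
#' @param vars variables to use (default all 16).
#' @param pooling `"all"` (pooled over all cells) or `"pair"`.
#' @param min_cell_size smallest admissible cell.
#' @return object of class `group_distance_map`: `distances` (symmetric
#'   matrix), `cells` (data frame of cell metadata in display order),
#'   `mode`.
#' @export
group_distance_map <- function(table, mode = c("line-pairs", "nitrate-blocks"),
                               vars = trait_vars(),
                               pooling = c("all", "pair"),
                               min_cell_size = 2L) {
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  X <- trait_matrix(table, vars)
  cell_id <- paste(table$line, table$nitrate, sep = ":")
  info <- unique(data.frame(cell = cell_id, line = table$line,
                            nupe_class = table$nupe_class,
                            nitrate = table$nitrate,
                            stringsAsFactors = FALSE))
  sizes <- table(cell_id)
  small <- names(sizes)[sizes < min_cell_size]
  if (length(small))
    stop("cells below minimum size: ", paste(small, collapse = ", "))
  if (nrow(info) < 2L) stop("need at least 2 cells")
  # display order
  info$nupe_ord <- match(info$nupe_class, c("low", "high"))
  info$nit_ord <- match(info$nitrate, c("low", "high"))
  info$line_ord <- match(info$line, unique(info$line[order(info$nupe_ord)]))
  ord <- if (mode == "line-pairs")
    order(info$nupe_ord, info$line_ord, info$nit_ord)
  else
    order(info$nupe_ord, info$nit_ord, info$line_ord)
  info <- info[ord, ]
  G <- nrow(info)
  Sw <- NULL
  if (pooling == "all") {
    sc <- scatter_matrices(X, cell_id)
    Sw <- sc$E / (nrow(X) - G)
  }
  D <- matrix(0, G, G, dimnames = list(info$cell, info$cell))
  for (i in seq_len(G - 1L)) {
    for (j in (i + 1L):G) {
      A <- X[cell_id == info$cell[i], , drop = FALSE]
      B <- X[cell_id == info$cell[j], , drop = FALSE]
      D[i, j] <- D[j, i] <- if (pooling == "all")
        mahalanobis_group_distance(A, B, "supplied", S = Sw)
      else mahalanobis_group_distance(A, B, "pair")
    }
  }
  rownames(info) <- NULL
  structure(list(distances = D,
                 cells = info[c("cell", "line", "nupe_class", "nitrate")],
                 mode = mode),
            class = "group_distance_map")
}

#' Per-group mean confidence regions in a discriminant plane
#'
#' Normal-theory confidence ellipses for the group mean scores: for group g
#' with empirical 2x2 score covariance S_g and size n_g, the region is
#' {mu_g + u : u' (S_g / n_g)^-1 u <= chi^2_2(level)}.
#'
#' @param model a [fit_lda()] result.
#' @param labels grouping used for the regions (defaults to the model's).
#' @param level confidence level (default 0.99).
#' @param dims the two discriminants to use, e.g. `c(1, 2)`.
#' @return list per group with `centre`, `shape` (S_g / n_g), `chisq`
#'   (the quantile), `n`, and `boundary` (a 100-point polygon).
#' @export
mean_confidence_regions <- function(model, labels = model$labels,
                                    level = 0.99, dims = c(1L, 2L)) {
  if (level < 0 || level >= 1) stop("'level' must lie in [0, 1)")
  if (length(dims) != 2L || any(dims > ncol(model$scores)))
    stop("'dims' must name two fitted discriminants")
  g <- factor(labels)
  if (any(table(g) < 3L)) stop("every group needs at least 3 members")
  q <- qchisq(level, df = 2L)
  theta <- seq(0, 2 * pi, length.out = 100L)
  circ <- cbind(cos(theta), sin(theta))
  out <- lapply(levels(g), function(lv) {
    Z <- model$scores[g == lv, dims, drop = FALSE]
    n <- nrow(Z)
    Sg <- cov(Z)
    if (any(!is.finite(Sg)) || det(Sg) <= 0)
      stop(sprintf("degenerate score covariance for group %s", lv))
    shape <- Sg / n
    ev <- eigen(shape, symmetric = TRUE)
    axes <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0) * q), 2L)
    list(group = lv, centre = colMeans(Z), shape = shape, chisq = q, n = n,
         boundary = sweep(circ %*% t(axes), 2L, colMeans(Z), `+`))
  })
  names(out) <- levels(g)
  out
}

#' Plants closest to each percentile of the LD1 scores
#'
#' For each percentile q in (0, step, 2 step, ..., 1) of the score vector
#' (linear-interpolation quantiles), returns the k plants whose scores are
#' closest to the percentile value, ties broken by plant id.
#'
#' @param scores named numeric vector of LD1 scores (names = plant ids).
#' @param k plants per percentile.
#' @param step percentile spacing.
#' @return data frame with columns `percentile`, `value`, `rank`,
#'   `plant_id`, `score`.
#' @export
percentile_exemplars <- function(scores, k = 5L, step = 0.1) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(scores) < k) stop("need at least k plants")
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  probs <- seq(0, 1, by = step)
  qv <- quantile(scores, probs = probs, type = 7L, names = FALSE)
  do.call(rbind, lapply(seq_along(probs), function(i) {
    ord <- order(abs(scores - qv[i]), ids)[seq_len(k)]
    data.frame(percentile = probs[i], value = qv[i], rank = seq_len(k),
               plant_id = ids[ord], score = unname(scores[ord]),
               stringsAsFactors = FALSE)
  }))
}
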