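# Variable-subset selection by the zeta-squared criterion.
#
# zeta^2 = U / (U + r), where U = tr(E_S^-1 H_S) is the Hotelling-Lawley
# trace of the subset's scatter matrices and r = min(|S|, g - 1). The
# normalisation puts the index in [0, 1]; when r = 1 it reduces to the
# squared first canonical correlation lambda_1 / (1 + lambda_1).

# fast path: zeta^2 from a data matrix and *positive* integer group codes
# (1..G), optionally with the (permutation-invariant) total scatter
# precomputed
zeta2_stat <- function(X, g, Tm = NULL) {
  g <- as.integer(g)
  ns <- tabulate(g)
  ns <- ns[ns > 0]
  G <- length(ns)
  grand <- colMeans(X)
  gm <- rowsum(X, g) / ns
  dif <- gm - matrix(grand, nrow(gm), ncol(X), byrow = TRUE)
  H <- crossprod(dif * sqrt(ns))
  if (is.null(Tm))
    Tm <- crossprod(X - matrix(grand, nrow(X), ncol(X), byrow = TRUE))
  U <- sum(diag(solve(Tm - H, H)))
  r <- min(ncol(X), G - 1L)
  U / (U + r)
}

#' The zeta-squared group-separation index of a variable subset
#'
#' @param X numeric matrix (plants x variables) with column names.
#' @param labels group label per row.
#' @param subset variable names (or column indices); default all columns.
#' @return list of class `subset_score`: `subset`, `size`, `zeta2`, `U`
#'   (Hotelling-Lawley trace), `r`.
#' @export
zeta2 <- function(X, labels, subset = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.null(subset)) subset <- colnames(X)
  if (is.numeric(subset)) subset <- colnames(X)[subset]
  sc <- scatter_matrices(X[, subset, drop = FALSE], labels)
  Es <- sc$E
  U <- tryCatch(sum(diag(solve(Es, sc$H))), error = function(e)
    stop("within-group scatter of this subset is singular"))
  r <- min(length(subset), length(sc$group_sizes) - 1L)
  structure(list(subset = subset, size = length(subset),
                 zeta2 = U / (U + r), U = U, r = r),
            class = "subset_score")
}

#' Best variable subset of each size by exhaustive search
#'
#' Enumerates every subset of each requested size and keeps the one
#' maximizing zeta-squared; ties are broken by lexicographic variable
#' order (the first maximum encountered in `combn` order). Subsets with a
#' singular within-group scatter are skipped and counted.
#'
#' @param X numeric matrix with column names.
#' @param labels group label per row.
#' @param sizes subset sizes to search (default 1..p-1).
#' @return object of class `subset_search`: `best` (list of `subset_score`
#'   per size), `incidence` (p x length(sizes) logical matrix: does each
#'   variable appear in each size's winner), `skipped` (singular subsets
#'   per size).
#' @export
best_subsets <- function(X, labels, sizes = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  p <- ncol(X)
  if (p > 20L)
    stop("exhaustive search over 2^p subsets is not sensible for p > 20")
  if (is.null(sizes)) sizes <- seq_len(p - 1L)
  if (any(sizes < 1L | sizes > p)) stop("subset sizes out of range")
  g <- factor(labels)
  G <- nlevels(g)
  sc <- scatter_matrices(X, g)
  H <- sc$H; Tm <- sc$T
  best <- vector("list", length(sizes))
  skipped <- integer(length(sizes))
  for (si in seq_along(sizes)) {
    q <- sizes[si]
    r <- min(q, G - 1L)
    combs <- combn(p, q)
    bz <- -Inf; bs <- NULL; bU <- NA_real_
    for (ci in seq_len(ncol(combs))) {
      S <- combs[, ci]
      U <- tryCatch(
        sum(diag(solve(Tm[S, S, drop = FALSE] - H[S, S, drop = FALSE],
                       H[S, S, drop = FALSE]))),
        error = function(e) NA_real_)
      if (!is.finite(U)) { skipped[si] <- skipped[si] + 1L; next }
      z <- U / (U + r)
      if (z > bz) { bz <- z; bs <- S; bU <- U }
    }
    if (is.null(bs)) stop(sprintf("all size-%d subsets were singular", q))
    best[[si]] <- structure(list(subset = colnames(X)[bs], size = q,
                                 zeta2 = bz, U = bU, r = r),
                            class = "subset_score")
  }
  incidence <- vapply(best, function(b) colnames(X) %in% b$subset,
                      logical(p))
  rownames(incidence) <- colnames(X)
  colnames(incidence) <- as.character(sizes)
  structure(list(best = best, sizes = sizes, incidence = incidence,
                 skipped = skipped),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  for (b in x$best)
    cat(sprintf("size %2d: zeta2 = %.4f  [%s]\n", b$size, b$zeta2,
                paste(b$subset, collapse = ", ")))
  invisible(x)
}
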