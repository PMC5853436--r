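# Shared fixtures and independent oracles for the test suite.

# -- hand-built root systems -------------------------------------------------

# one straight vertical seminal of given length, seed at origin
vertical_system <- function(len = 100, plant_id = "v",
                            meta = plant_meta("toy", "low", "low"),
                            n_pts = 11L) {
  pts <- cbind(0, seq(0, len, length.out = n_pts))
  root_system(plant_id, c(0, 0), list(root_curve(pts, "seminal")), meta)
}

# straight seminal from origin at `angle` degrees from the downward vertical
straight_seminal <- function(angle, len, n_pts = 11L) {
  a <- angle * pi / 180
  s <- seq(0, len, length.out = n_pts)
  root_curve(cbind(sin(a) * s, cos(a) * s), "seminal")
}

toy_meta <- function(code = 0L) {
  plant_meta("toy", c("low", "low", "high", "high")[code + 1L],
             c("low", "high", "low", "high")[code + 1L])
}

# small generated cohort shared across tests (built once per test run)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(default_cohort_spec(plants_per_cell = 4L,
                                                    rng_seed = 42L))
    cache
  }
})

# -- independent oracles -----------------------------------------------------

# brute-force assignment by permutation enumeration (n <= 7)
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 7L)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)), function(p)
    sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

# brute-force Rayleigh-quotient maximization: random search + Nelder-Mead
# polish, independent of any eigendecomposition
brute_rayleigh_max <- function(H, E, n_random = 2e5) {
  p <- nrow(H)
  rq <- function(a) {
    den <- drop(a %*% E %*% a)
    if (den <= 0) return(-Inf)
    drop(a %*% H %*% a) / den
  }
  A <- matrix(rnorm(n_random * p), n_random, p)
  vals <- rowSums((A %*% H) * A) / rowSums((A %*% E) * A)
  best <- A[which.max(vals), ]
  opt <- stats::optim(best, function(a) -rq(a),
                      control = list(maxit = 2000, reltol = 1e-14))
  v <- opt$par / sqrt(sum(opt$par^2))
  list(direction = v, value = rq(v))
}

# zeta^2 for every subset of each size, by bitmask enumeration with an
# eigenvalue-based Hotelling-Lawley trace (independent code path)
brute_best_subsets <- function(X, labels, sizes) {
  g <- factor(labels)
  G <- nlevels(g)
  ns <- as.vector(table(g))
  grand <- colMeans(X)
  gm <- rowsum(X, g) / ns
  dif <- gm - matrix(grand, G, ncol(X), byrow = TRUE)
  H <- crossprod(dif * sqrt(ns))
  Tm <- crossprod(sweep(X, 2L, grand))
  p <- ncol(X)
  out <- list()
  for (q in sizes) {
    best_z <- -Inf; best_s <- NULL
    for (mask in seq_len(2^p - 1L)) {
      S <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
      if (length(S) != q) next
      Es <- Tm[S, S, drop = FALSE] - H[S, S, drop = FALSE]
      U <- tryCatch(sum(Re(eigen(qr.solve(Es) %*% H[S, S, drop = FALSE],
                                 only.values = TRUE)$values)),
                    error = function(e) NA_real_)
      if (!is.finite(U)) next
      z <- U / (U + min(q, G - 1L))
      if (z > best_z) { best_z <- z; best_s <- S }
    }
    out[[as.character(q)]] <- list(subset = colnames(X)[best_s],
                                   zeta2 = best_z)
  }
  out
}

# ordinary Procrustes RMS (translation + rotation/reflection), closed form
procrustes_rms <- function(X, Y) {
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  sv <- svd(crossprod(Yc, Xc))
  R <- sv$u %*% t(sv$v)
  sqrt(mean(rowSums((Yc %*% R - Xc)^2)))
}

# random labelled Gaussian instance for LDA checks
random_lda_instance <- function(p, g, n_per, sep = 1.5, seed = 1) {
  set.seed(seed)
  mus <- matrix(rnorm(g * p, sd = sep), g, p)
  X <- do.call(rbind, lapply(seq_len(g), function(k)
    sweep(matrix(rnorm(n_per * p), n_per, p), 2L, mus[k, ], `+`)))
  colnames(X) <- paste0("V", seq_len(p))
  list(X = X, labels = rep(seq_len(g), each = n_per))
}
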