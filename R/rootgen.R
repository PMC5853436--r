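# Synthetic 2-D seedling root systems with group-dependent architecture.
# Coordinate convention: seed at the origin, x horizontal (mm), y increasing
# downward (image convention); angles are measured from the downward
# vertical in degrees.

#' Construct a single root curve
#'
#' A root curve is an ordered 2-D polyline, either a seminal (embryo-derived)
#' root starting at the seed or a lateral root attached to a seminal parent.
#'
#' @param points two-column numeric matrix of (x, y) coordinates in mm;
#'   at least two rows, consecutive rows distinct.
#' @param order `"seminal"` or `"lateral"`.
#' @param parent_index for laterals, index of the parent seminal curve
#'   within its root system.
#' @param attachment_arclength for laterals, arc-length position (mm) of the
#'   attachment point along the parent.
#' @return object of class `root_curve`.
#' @export
root_curve <- function(points, order = c("seminal", "lateral"),
                       parent_index = NA_integer_,
                       attachment_arclength = NA_real_) {
  order <- match.arg(order)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("'points' must have two columns (x, y)")
  if (nrow(points) < 2L) stop("a root curve needs at least 2 points")
  if (any(!is.finite(points))) stop("root curve coordinates must be finite")
  if (any(seg_lengths(points) == 0))
    stop("consecutive points of a root curve must be distinct")
  if (order == "lateral") {
    if (is.na(parent_index) || parent_index < 1L)
      stop("laterals must reference a parent seminal root")
    if (is.na(attachment_arclength) || attachment_arclength < 0)
      stop("laterals need a nonnegative attachment arc length")
  }
  structure(list(points = points, order = order,
                 parent_index = as.integer(parent_index),
                 attachment_arclength = as.double(attachment_arclength)),
            class = "root_curve")
}

seg_lengths <- function(pts) {
  n <- nrow(pts)
  dx <- pts[-1L, 1L] - pts[-n, 1L]
  dy <- pts[-1L, 2L] - pts[-n, 2L]
  sqrt(dx * dx + dy * dy)
}

#' Arc length of a polyline or root curve
#' @param x a `root_curve` or a two-column coordinate matrix.
#' @return total arc length (mm).
#' @export
arc_length <- function(x) {
  pts <- if (inherits(x, "root_curve")) x$points else as.matrix(x)
  sum(seg_lengths(pts))
}

#' Plant metadata
#'
#' Group codes follow the fixed mapping 0 = (low NUpE, low nitrate),
#' 1 = (low, high), 2 = (high, low), 3 = (high, high).
#'
#' @param line wheat line identifier (e.g. "W145").
#' @param nupe_class `"low"` or `"high"` nitrogen uptake efficiency class.
#' @param nitrate `"low"` or `"high"` nitrate level of the growth medium.
#' @param group_code optional integer 0--3; derived from the two binary
#'   labels when omitted, validated against them when supplied.
#' @return object of class `plant_meta`.
#' @export
plant_meta <- function(line, nupe_class = c("low", "high"),
                       nitrate = c("low", "high"), group_code = NULL) {
  nupe_class <- match.arg(nupe_class)
  nitrate <- match.arg(nitrate)
  code <- group_code_for(nupe_class, nitrate)
  if (!is.null(group_code) && as.integer(group_code) != code)
    stop(sprintf("group_code %s inconsistent with (%s NUpE, %s nitrate): expected %d",
                 group_code, nupe_class, nitrate, code))
  structure(list(line = as.character(line), nupe_class = nupe_class,
                 nitrate = nitrate, group_code = code),
            class = "plant_meta")
}

#' @rdname plant_meta
#' @export
group_code_for <- function(nupe_class, nitrate) {
  2L * (nupe_class == "high") + 1L * (nitrate == "high")
}

#' Construct a root system
#'
#' @param plant_id unique plant identifier.
#' @param seed_point length-2 numeric, location of the seed.
#' @param curves list of [root_curve()] objects; at least one seminal, and
#'   every seminal must start at `seed_point`.
#' @param meta a [plant_meta()] object.
#' @return object of class `root_system`.
#' @export
root_system <- function(plant_id, seed_point, curves, meta) {
  seed_point <- as.double(seed_point)
  if (length(seed_point) != 2L || any(!is.finite(seed_point)))
    stop("'seed_point' must be two finite coordinates")
  if (!all(vapply(curves, inherits, logical(1), "root_curve")))
    stop("'curves' must be a list of root_curve objects")
  orders <- vapply(curves, function(cv) cv$order, character(1))
  sem <- which(orders == "seminal")
  if (length(sem) == 0L) stop("a root system needs at least one seminal root")
  for (i in sem) {
    if (max(abs(curves[[i]]$points[1L, ] - seed_point)) > 1e-9)
      stop("every seminal root must start at the seed point")
  }
  plens <- vapply(sem, function(i) arc_length(curves[[i]]), numeric(1))
  for (i in which(orders == "lateral")) {
    cv <- curves[[i]]
    pk <- match(cv$parent_index, sem)
    if (is.na(pk))
      stop(sprintf("lateral %d references curve %d which is not a seminal",
                   i, cv$parent_index))
    if (cv$attachment_arclength > plens[pk] + 1e-9)
      stop(sprintf("lateral %d attaches beyond its parent's arc length", i))
  }
  if (!inherits(meta, "plant_meta")) stop("'meta' must be a plant_meta object")
  structure(list(plant_id = as.character(plant_id), seed_point = seed_point,
                 curves = curves, meta = meta),
            class = "root_system")
}

#' @export
print.root_system <- function(x, ...) {
  orders <- vapply(x$curves, function(cv) cv$order, character(1))
  cat(sprintf("<root_system %s: %d seminal, %d lateral; line %s, %s NUpE, %s nitrate (group %d)>\n",
              x$plant_id, sum(orders == "seminal"), sum(orders == "lateral"),
              x$meta$line, x$meta$nupe_class, x$meta$nitrate, x$meta$group_code))
  invisible(x)
}

# ---------------------------------------------------------------------------
# growth model: gravitropic correlated random walk

validate_group_params <- function(p) {
  needed <- c("seminal_count_mean", "seminal_length_meanlog",
              "seminal_length_sdlog", "emergence_angle_mean",
              "emergence_angle_sd", "gravitropism", "direction_noise_sd",
              "lateral_density", "lateral_basal_offset",
              "lateral_length_meanlog", "lateral_length_sdlog",
              "lateral_angle_mean", "lateral_angle_sd", "step")
  missing <- setdiff(needed, names(p))
  if (length(missing))
    stop("missing generator parameters: ", paste(missing, collapse = ", "))
  num <- unlist(p[needed])
  if (any(!is.finite(num))) stop("generator parameters must be finite")
  nonneg <- c("seminal_count_mean", "seminal_length_sdlog",
              "emergence_angle_sd", "direction_noise_sd", "lateral_density",
              "lateral_basal_offset", "lateral_length_sdlog",
              "lateral_angle_sd")
  if (any(unlist(p[nonneg]) < 0))
    stop("generator rates and standard deviations must be nonnegative")
  if (p$gravitropism < 0 || p$gravitropism > 1)
    stop("'gravitropism' must lie in [0, 1]")
  if (p$emergence_angle_mean < 0 || p$emergence_angle_mean >= 180 ||
      p$lateral_angle_mean < 0 || p$lateral_angle_mean >= 180)
    stop("mean angles must lie in [0, 180) degrees from vertical")
  if (p$step <= 0) stop("'step' must be positive")
  invisible(p)
}

# Grow one root as a chain of fixed-length segments. The heading is pulled
# toward the downward vertical by the gravitropism weight each step, then
# perturbed by Gaussian noise. Angles in radians from the downward vertical
# (positive toward +x).
grow_curve <- function(start, init_angle, total_length, gravitropism,
                       noise_sd, step = 1) {
  n_full <- floor(total_length / step)
  lens <- rep(step, n_full)
  rem <- total_length - n_full * step
  if (rem > 1e-9) lens <- c(lens, rem)
  if (length(lens) == 0L) lens <- total_length
  n <- length(lens)
  eps <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  grow_curve_cpp(as.double(start), init_angle, lens, gravitropism, eps)
}

# internal constructor without validation, for generator-built curves whose
# invariants hold by construction
fast_curve <- function(points, order, parent_index = NA_integer_,
                       attachment_arclength = NA_real_) {
  structure(list(points = points, order = order,
                 parent_index = as.integer(parent_index),
                 attachment_arclength = as.double(attachment_arclength)),
            class = "root_curve")
}

# vectorized linear interpolation of points at arc lengths s (ascending)
points_at_arclengths <- function(points, s, cum = NULL) {
  if (is.null(cum)) cum <- c(0, cumsum(seg_lengths(points)))
  L <- cum[length(cum)]
  s <- pmin(pmax(s, 0), L)
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
            length(cum) - 1L)
  f <- (s - cum[i]) / (cum[i + 1L] - cum[i])
  points[i, , drop = FALSE] + f * (points[i + 1L, , drop = FALSE] -
                                     points[i, , drop = FALSE])
}

point_at_arclength <- function(points, s) {
  cum <- c(0, cumsum(seg_lengths(points)))
  L <- cum[length(cum)]
  s <- min(max(s, 0), L)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  if (i >= length(cum)) return(points[nrow(points), ])
  f <- (s - cum[i]) / (cum[i + 1L] - cum[i])
  points[i, ] + f * (points[i + 1L, ] - points[i, ])
}

#' Generate one synthetic root system
#'
#' Draws a seminal root count (truncated at 1), grows each seminal as a
#' gravitropic correlated random walk of 1 mm segments to a log-normal
#' total length, then places lateral roots along each seminal as a Poisson
#' process beyond a basal offset and grows them by the same segment rule
#' with their own length and branch-angle parameters.
#'
#' @param params named list of generator parameters for one group; see
#'   [default_group_params()] for the fields and defaults.
#' @param seed optional integer seed for this plant's random stream.
#' @param plant_id plant identifier.
#' @param meta a [plant_meta()] object (a default placeholder is used when
#'   omitted).
#' @return a [root_system()].
#' @examples
#' p <- default_group_params()[["0"]]
#' rs <- generate_root_system(p, seed = 1)
#' @export
generate_root_system <- function(params, seed = NULL, plant_id = "plant",
                                 meta = plant_meta("synthetic", "low", "low")) {
  validate_group_params(params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_sem <- max(1L, rpois(1L, params$seminal_count_mean))
  curves <- vector("list", n_sem)
  cums <- vector("list", n_sem)
  for (i in seq_len(n_sem)) {
    len <- rlnorm(1L, params$seminal_length_meanlog, params$seminal_length_sdlog)
    ang <- abs(rnorm(1L, params$emergence_angle_mean, params$emergence_angle_sd))
    ang <- min(ang, 179) * sample(c(-1, 1), 1L)
    pts <- grow_curve(c(0, 0), ang * pi / 180, len, params$gravitropism,
                      params$direction_noise_sd * pi / 180, params$step)
    curves[[i]] <- fast_curve(pts, "seminal")
    cums[[i]] <- c(0, cumsum(seg_lengths(pts)))
  }
  laterals <- list()
  for (i in seq_len(n_sem)) {
    plen <- cums[[i]][length(cums[[i]])]
    avail <- max(0, plen - params$lateral_basal_offset)
    n_lat <- if (params$lateral_density > 0 && avail > 0)
      rpois(1L, params$lateral_density * avail) else 0L
    if (n_lat == 0L) next
    pos <- sort(runif(n_lat, params$lateral_basal_offset, plen))
    atts <- points_at_arclengths(curves[[i]]$points, pos, cum = cums[[i]])
    for (k in seq_len(n_lat)) {
      llen <- rlnorm(1L, params$lateral_length_meanlog, params$lateral_length_sdlog)
      lang <- abs(rnorm(1L, params$lateral_angle_mean, params$lateral_angle_sd))
      lang <- min(lang, 179) * sample(c(-1, 1), 1L)
      pts <- grow_curve(atts[k, ], lang * pi / 180, llen, params$gravitropism,
                        params$direction_noise_sd * pi / 180, params$step)
      laterals[[length(laterals) + 1L]] <-
        fast_curve(pts, "lateral", parent_index = i,
                   attachment_arclength = pos[k])
    }
  }
  root_system(plant_id, c(0, 0), c(curves, laterals), meta)
}

# ---------------------------------------------------------------------------
# cohort specification

#' Default per-group generator parameters
#'
#' Parameter means for the four (NUpE class x nitrate) groups. The planted
#' effect profile shifts seminal length and lateral density more strongly
#' between NUpE classes than between nitrate levels, with the nitrate shift
#' larger within the low-NUpE groups. `effect = "null"` returns identical
#' parameters for all four groups (no planted differences).
#'
#' @param effect `"default"` (planted group differences) or `"null"`.
#' @return named list of four parameter lists, keyed "0".."3".
#' @export
default_group_params <- function(effect = c("default", "null")) {
  effect <- match.arg(effect)
  base <- list(
    seminal_count_mean = 4.5,
    seminal_length_meanlog = log(150), seminal_length_sdlog = 0.25,
    emergence_angle_mean = 25, emergence_angle_sd = 10,
    gravitropism = 0.18, direction_noise_sd = 6,
    lateral_density = 0.10, lateral_basal_offset = 15,
    lateral_length_meanlog = log(10), lateral_length_sdlog = 0.5,
    lateral_angle_mean = 60, lateral_angle_sd = 15,
    step = 1)
  if (effect == "null")
    return(stats::setNames(rep(list(base), 4L), as.character(0:3)))
  tweak <- function(p, ...) {
    d <- list(...)
    for (nm in names(d)) p[[nm]] <- p[[nm]] + d[[nm]]
    p
  }
  g0 <- base
  g1 <- tweak(base, seminal_length_meanlog = 0.12, lateral_density = -0.015,
              emergence_angle_mean = -3)
  g2 <- tweak(base, seminal_length_meanlog = 0.25, lateral_density = 0.04,
              emergence_angle_mean = -5, seminal_count_mean = 0.4)
  g3 <- tweak(g2, seminal_length_meanlog = 0.05, lateral_density = -0.005,
              emergence_angle_mean = -1)
  list("0" = g0, "1" = g1, "2" = g2, "3" = g3)
}

default_line_table <- function() {
  data.frame(
    line = c("W145", "W149", "W199", "W705",
             "W325", "W483", "W637", "W685", "W700"),
    nupe_class = c(rep("low", 4L), rep("high", 5L)),
    length_adj = c(0.04, -0.03, 0.00, 0.06, -0.02, 0.03, -0.05, 0.00, 0.02),
    angle_adj = c(2, -2, 0, 3, -1, 1, -3, 0, 2),
    nitrate_mult = c(0.3, 1.0, 1.0, 1.8, 1.0, 1.0, 1.0, 1.0, 1.0),
    stringsAsFactors = FALSE)
}

#' Cohort specification
#'
#' @param cells data frame with columns `line`, `nupe_class`, `nitrate`,
#'   `n_plants`: the line-by-treatment cells and their plant counts.
#' @param group_params per-group generator parameters, keyed "0".."3";
#'   see [default_group_params()].
#' @param line_effects data frame with columns `line`, `length_adj`
#'   (additive tweak to the seminal length log-mean), `angle_adj` (degrees
#'   added to the mean emergence angle) and `nitrate_mult` (line-specific
#'   multiplier on the nitrate-effect parameter shift); zero/unit rows are
#'   used for lines not listed.
#' @param rng_seed integer; the cohort's master seed. Each plant draws from
#'   a substream derived from this seed and its index, so per-plant
#'   generation order is irrelevant.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(cells, group_params = default_group_params(),
                        line_effects = NULL, rng_seed = 1L) {
  stopifnot(is.data.frame(cells),
            all(c("line", "nupe_class", "nitrate", "n_plants") %in% names(cells)))
  if (any(cells$n_plants < 0)) stop("'n_plants' must be nonnegative")
  if (!all(cells$nupe_class %in% c("low", "high")) ||
      !all(cells$nitrate %in% c("low", "high")))
    stop("'nupe_class' and 'nitrate' must be 'low' or 'high'")
  if (anyDuplicated(cells[c("line", "nitrate")]))
    stop("duplicate (line, nitrate) cells in spec")
  if (!identical(sort(names(group_params)), as.character(0:3)))
    stop("'group_params' must have entries keyed \"0\"..\"3\"")
  for (p in group_params) validate_group_params(p)
  if (is.null(line_effects))
    line_effects <- data.frame(line = unique(cells$line), length_adj = 0,
                               angle_adj = 0, nitrate_mult = 1,
                               stringsAsFactors = FALSE)
  structure(list(cells = cells, group_params = group_params,
                 line_effects = line_effects, rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Default demonstration cohort specification
#'
#' Nine wheat lines (four low-NUpE, five high-NUpE) under low and high
#' nitrate, with the high-nitrate cell of line W199 absent: 17 cells. With
#' the default 17 plants per cell this gives 289 plants, matching the scale
#' of a seedling pouch experiment of roughly 300 plants.
#'
#' @param plants_per_cell plants per (line, nitrate) cell.
#' @param rng_seed master seed.
#' @param effect `"default"` for planted group differences, `"null"` for a
#'   label-independent cohort (identical parameters everywhere, no line
#'   effects).
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(plants_per_cell = 17L, rng_seed = 1L,
                                effect = c("default", "null")) {
  effect <- match.arg(effect)
  lines <- default_line_table()
  cells <- merge(lines[c("line", "nupe_class")],
                 data.frame(nitrate = c("low", "high")))
  cells <- cells[!(cells$line == "W199" & cells$nitrate == "high"), ]
  cells <- cells[order(match(cells$line, lines$line), cells$nitrate == "high"), ]
  cells$n_plants <- as.integer(plants_per_cell)
  rownames(cells) <- NULL
  le <- if (effect == "null") NULL else lines[c("line", "length_adj",
                                               "angle_adj", "nitrate_mult")]
  cohort_spec(cells, default_group_params(effect), le, rng_seed)
}

# Parameters for one (line, nitrate) cell: start from the low-nitrate
# parameters of the line's NUpE class, add the line-scaled nitrate shift
# when the medium is high nitrate, then the line's own tweaks.
cell_params <- function(spec, line, nupe_class, nitrate) {
  low <- spec$group_params[[as.character(group_code_for(nupe_class, "low"))]]
  high <- spec$group_params[[as.character(group_code_for(nupe_class, "high"))]]
  le <- spec$line_effects[spec$line_effects$line == line, ]
  mult <- if (nrow(le)) le$nitrate_mult[1] else 1
  p <- low
  if (nitrate == "high") {
    for (nm in names(p)) {
      if (is.numeric(p[[nm]]))
        p[[nm]] <- low[[nm]] + mult * (high[[nm]] - low[[nm]])
    }
  }
  if (nrow(le)) {
    p$seminal_length_meanlog <- p$seminal_length_meanlog + le$length_adj[1]
    p$emergence_angle_mean <- max(0, p$emergence_angle_mean + le$angle_adj[1])
  }
  p$lateral_density <- max(0, p$lateral_density)
  p
}

# Deterministic per-plant substream seed; a multiplicative mix keeps the
# value inside the 32-bit signed range R requires.
plant_seed <- function(master, index) {
  as.integer((as.double(master %% 2147483647L) * 48271 +
                as.double(index) * 16807) %% 2147483647)
}

#' Generate a cohort of synthetic root systems
#'
#' @param spec a [cohort_spec()].
#' @return list of [root_system()] objects (class `root_cohort`), one per
#'   requested plant, deterministic given the spec's seed.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(plants_per_cell = 2))
#' length(cohort)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  systems <- list()
  idx <- 0L
  for (ci in seq_len(nrow(spec$cells))) {
    cell <- spec$cells[ci, ]
    params <- cell_params(spec, cell$line, cell$nupe_class, cell$nitrate)
    meta <- plant_meta(cell$line, cell$nupe_class, cell$nitrate)
    ntag <- if (cell$nitrate == "high") "Nhigh" else "Nlow"
    for (k in seq_len(cell$n_plants)) {
      idx <- idx + 1L
      pid <- sprintf("%s_%s_%02d", cell$line, ntag, k)
      systems[[idx]] <- generate_root_system(
        params, seed = plant_seed(spec$rng_seed, idx), plant_id = pid,
        meta = meta)
    }
  }
  ids <- vapply(systems, function(s) s$plant_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate plant ids in generated cohort")
  structure(systems, class = "root_cohort", spec = spec)
}

#' @export
print.root_cohort <- function(x, ...) {
  cells <- unique(vapply(x, function(s)
    paste(s$meta$line, s$meta$nitrate), character(1)))
  cat(sprintf("<root_cohort: %d plants in %d line x nitrate cells>\n",
              length(x), length(cells)))
  invisible(x)
}

cohort_meta <- function(cohort) {
  data.frame(
    plant_id = vapply(cohort, function(s) s$plant_id, character(1)),
    line = vapply(cohort, function(s) s$meta$line, character(1)),
    nupe_class = vapply(cohort, function(s) s$meta$nupe_class, character(1)),
    nitrate = vapply(cohort, function(s) s$meta$nitrate, character(1)),
    group_code = vapply(cohort, function(s) s$meta$group_code, integer(1)),
    stringsAsFactors = FALSE)
}
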