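# Image-derived root traits and the plants x variables table.

#' Canonical variable names
#'
#' `rootnav_traits()` returns the eleven image-derived trait names;
#' `geom_vars()` the five shape-coordinate names from multidimensional
#' scaling; `trait_vars()` their concatenation, the sixteen analysis
#' variables in canonical order.
#' @return character vector of variable names.
#' @export
rootnav_traits <- function() {
  c("TotalLength", "AvgSeminalTipAngle", "AvgSeminalEmergAngle",
    "AvgSeminalLength", "AvgLateralLength", "LateralCount", "SeminalCount",
    "ConvexHullArea", "MaxWidth", "MaxDepth", "WidthDepthRatio")
}

#' @rdname rootnav_traits
#' @export
geom_vars <- function() paste0("Geom", 1:5)

#' @rdname rootnav_traits
#' @export
trait_vars <- function() c(rootnav_traits(), geom_vars())

meta_cols <- function() c("plant_id", "line", "nupe_class", "nitrate",
                          "group_code")

# angle (degrees, in [0, 180]) between a chord vector and the downward
# vertical (0, 1); y increases downward
angle_from_vertical <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(0)
  acos(min(1, max(-1, v[2] / n))) * 180 / pi
}

# convex hull area by the shoelace formula on the hull vertices; degenerate
# hulls (fewer than 3 non-collinear points) have area 0
hull_area <- function(pts) {
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts)
  if (length(h) < 3L) return(0)
  xy <- pts[h, , drop = FALSE]
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Compute the eleven image-derived traits of a root system
#'
#' Emergence and tip angles of a seminal root are the angles between the
#' downward vertical and the chord spanning, respectively, the proximal and
#' distal `angle_window` fraction of its arc length; both are averaged over
#' seminal roots only. Maximum depth is measured downward from the seed
#' point; the width--depth ratio is 0 when the depth is 0.
#'
#' @param system a [root_system()].
#' @param angle_window fraction of arc length used for the angle chords.
#' @return named numeric vector over [rootnav_traits()].
#' @examples
#' p <- default_group_params()[["0"]]
#' compute_traits(generate_root_system(p, seed = 1))
#' @export
compute_traits <- function(system, angle_window = 0.1) {
  stopifnot(inherits(system, "root_system"))
  if (angle_window <= 0 || angle_window > 0.5)
    stop("'angle_window' must lie in (0, 0.5]")
  orders <- vapply(system$curves, function(cv) cv$order, character(1))
  lens <- vapply(system$curves, arc_length, numeric(1))
  sem <- which(orders == "seminal")
  lat <- which(orders == "lateral")
  emerg <- tip <- numeric(length(sem))
  for (k in seq_along(sem)) {
    pts <- system$curves[[sem[k]]]$points
    L <- lens[sem[k]]
    a <- point_at_arclength(pts, angle_window * L)
    emerg[k] <- angle_from_vertical(a - pts[1L, ])
    b <- point_at_arclength(pts, (1 - angle_window) * L)
    tip[k] <- angle_from_vertical(pts[nrow(pts), ] - b)
  }
  all_pts <- do.call(rbind, lapply(system$curves, function(cv) cv$points))
  max_depth <- max(all_pts[, 2]) - system$seed_point[2]
  max_width <- max(all_pts[, 1]) - min(all_pts[, 1])
  c(TotalLength = sum(lens),
    AvgSeminalTipAngle = mean(tip),
    AvgSeminalEmergAngle = mean(emerg),
    AvgSeminalLength = mean(lens[sem]),
    AvgLateralLength = if (length(lat)) mean(lens[lat]) else 0,
    LateralCount = length(lat),
    SeminalCount = length(sem),
    ConvexHullArea = hull_area(all_pts),
    MaxWidth = max_width,
    MaxDepth = max_depth,
    WidthDepthRatio = if (max_depth > 0) max_width / max_depth else 0)
}

#' Trait matrix of a cohort
#'
#' Stacks [compute_traits()] over a cohort into a plants x 11 matrix with
#' plant ids as row names.
#' @param cohort a `root_cohort`.
#' @param angle_window passed to [compute_traits()].
#' @return numeric matrix.
#' @export
trait_record_matrix <- function(cohort, angle_window = 0.1) {
  m <- t(vapply(cohort, compute_traits, numeric(11L),
                angle_window = angle_window))
  rownames(m) <- vapply(cohort, function(s) s$plant_id, character(1))
  m
}

new_trait_table <- function(df, standardized = FALSE) {
  structure(df, class = c("trait_table", "data.frame"),
            standardized = standardized)
}

#' Assemble the plants x 16 variables trait table
#'
#' Joins the eleven image-derived traits with the five MDS shape
#' coordinates (Geom1..Geom5) and the plant metadata.
#'
#' @param cohort a `root_cohort`.
#' @param geom an [classical_mds()] embedding whose rows match the cohort
#'   order, or a plants x 5 matrix with columns Geom1..Geom5.
#' @param angle_window passed to [compute_traits()].
#' @return a `trait_table`: data frame with metadata columns followed by the
#'   16 variables; attribute `standardized` is `FALSE`.
#' @export
build_trait_table <- function(cohort, geom, angle_window = 0.1) {
  traits <- trait_record_matrix(cohort, angle_window)
  coords <- if (inherits(geom, "embedding_result")) geom$coordinates else
    as.matrix(geom)
  if (nrow(coords) != length(cohort))
    stop(sprintf("geometry rows (%d) do not match cohort size (%d)",
                 nrow(coords), length(cohort)))
  missing <- setdiff(geom_vars(), colnames(coords))
  if (length(missing))
    stop("missing shape coordinate columns: ", paste(missing, collapse = ", "))
  if (!is.null(rownames(coords)) &&
      !identical(rownames(coords), rownames(traits)))
    stop("geometry row order does not match cohort order")
  df <- cbind(cohort_meta(cohort), as.data.frame(traits),
              as.data.frame(coords[, geom_vars(), drop = FALSE]))
  rownames(df) <- NULL
  new_trait_table(df, standardized = FALSE)
}

#' Numeric variable matrix of a trait table
#' @param table a `trait_table`.
#' @param vars variables to extract (default: all 16).
#' @return numeric matrix with plant ids as row names.
#' @export
trait_matrix <- function(table, vars = trait_vars()) {
  missing <- setdiff(vars, names(table))
  if (length(missing))
    stop("trait table lacks columns: ", paste(missing, collapse = ", "))
  m <- as.matrix(as.data.frame(table)[vars])
  rownames(m) <- table$plant_id
  m
}

#' Standardize a trait table
#'
#' Centres each of the 16 variables to mean 0 and scales it to sample
#' variance 1 (divisor N-1).
#'
#' @param table a `trait_table` (or numeric matrix).
#' @return the table with standardized variable columns and attribute
#'   `standardized = TRUE`.
#' @export
standardize <- function(table) UseMethod("standardize")

#' @export
standardize.default <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 2L) stop("standardization needs at least 2 rows")
  sds <- apply(x, 2L, sd)
  bad <- colnames(x)[sds == 0]
  if (length(bad))
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' @export
standardize.trait_table <- function(table) {
  z <- standardize.default(trait_matrix(table))
  out <- as.data.frame(table)
  out[, trait_vars()] <- as.data.frame(z)
  new_trait_table(out, standardized = TRUE)
}

#' Variables with at least one strong pairwise correlation
#'
#' Selects the variables whose maximum absolute Pearson correlation with
#' any other variable reaches the threshold, the selection rule used for a
#' pairwise-correlation panel.
#'
#' @param table a `trait_table` or numeric matrix.
#' @param threshold correlation magnitude cutoff in `[0, 1]`.
#' @return list with `vars` (selected names), `cor` (full correlation
#'   matrix) and `cor_display` (rounded to 2 decimal places).
#' @export
correlated_subset <- function(table, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("'threshold' must lie in [0, 1]")
  x <- if (inherits(table, "trait_table")) trait_matrix(table) else
    as.matrix(table)
  cm <- cor(x)
  off <- abs(cm)
  diag(off) <- 0
  keep <- colnames(cm)[apply(off, 2L, max) >= threshold]
  list(vars = keep, cor = cm, cor_display = round(cm, 2L))
}
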