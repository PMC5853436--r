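# Orchestration: trait-table I/O, configuration and end-to-end runs.

# header aliases for externally produced tables: names are squashed
# (non-alphanumerics removed, lower-cased) before matching
squash_name <- function(x) tolower(gsub("[^A-Za-z0-9]", "", x))

canonical_aliases <- function() {
  vars <- c(trait_vars(), meta_cols())
  al <- setNames(vars, squash_name(vars))
  extra <- c(
    totallength = "TotalLength",
    averageseminaltipangle = "AvgSeminalTipAngle",
    averageseminalemergenceangle = "AvgSeminalEmergAngle",
    averagelengthseminalroots = "AvgSeminalLength",
    averagelengthlateralroots = "AvgLateralLength",
    lateralrootcount = "LateralCount",
    seminalrootcount = "SeminalCount",
    convexhull = "ConvexHullArea",
    areaofconvexhull = "ConvexHullArea",
    maximumwidth = "MaxWidth",
    maximumdepth = "MaxDepth",
    widthdepthratio = "WidthDepthRatio",
    id = "plant_id",
    plant = "plant_id",
    genotype = "line",
    nupe = "nupe_class",
    treatment = "nitrate",
    group = "group_code")
  c(al, extra)
}

#' Read a trait table from CSV
#'
#' Accepts both tables written by [write_trait_csv()] and externally
#' produced tables: headers are matched after stripping case and
#' punctuation, with aliases for the spelled-out trait names (e.g.
#' "Average Length - Seminal Roots"). The 16 analysis variables are
#' required; of the metadata, `group_code` and the (`nupe_class`,
#' `nitrate`) pair can each be derived from the other, and missing plant
#' ids are synthesized.
#'
#' @param path CSV file path.
#' @param standardized is the file already scaled to mean 0 / variance 1?
#'   Stored as the table's `standardized` attribute (checked, not
#'   enforced).
#' @return a `trait_table`.
#' @export
read_trait_csv <- function(path, standardized = FALSE) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  al <- canonical_aliases()
  keys <- squash_name(names(raw))
  mapped <- unname(al[keys])
  names(raw)[!is.na(mapped)] <- mapped[!is.na(mapped)]
  missing_vars <- setdiff(trait_vars(), names(raw))
  if (length(missing_vars))
    stop("missing variable column(s): ", paste(missing_vars, collapse = ", "))
  for (v in trait_vars()) {
    if (!is.numeric(raw[[v]]))
      stop(sprintf("non-numeric values in column %s", v))
    if (anyNA(raw[[v]]))
      stop(sprintf("missing values in column %s (rows %s)", v,
                   paste(head(which(is.na(raw[[v]]))), collapse = ", ")))
  }
  if (is.null(raw$plant_id))
    raw$plant_id <- sprintf("plant_%03d", seq_len(nrow(raw)))
  if (is.null(raw$group_code)) {
    if (is.null(raw$nupe_class) || is.null(raw$nitrate))
      stop("need either group_code or both nupe_class and nitrate")
    raw$group_code <- group_code_for(raw$nupe_class, raw$nitrate)
  }
  if (is.null(raw$nupe_class))
    raw$nupe_class <- c("low", "high")[raw$group_code %/% 2L + 1L]
  if (is.null(raw$nitrate))
    raw$nitrate <- c("low", "high")[raw$group_code %% 2L + 1L]
  if (is.null(raw$line)) raw$line <- "unknown"
  ok <- raw$group_code == group_code_for(raw$nupe_class, raw$nitrate)
  if (!all(ok))
    stop("group_code inconsistent with (nupe_class, nitrate) in rows ",
         paste(head(which(!ok)), collapse = ", "))
  new_trait_table(raw[c(meta_cols(), trait_vars())],
                  standardized = standardized)
}

#' Write a trait table to CSV
#' @param table a `trait_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Defaults follow the analysis conventions used throughout the package:
#' 5 MDS dimensions, 50 resample points per curve, best subsets of every
#' size, 1000 bootstrap replicates, 10000 permutations, 99% confidence
#' regions and a 0.5 correlation-panel threshold.
#'
#' @param spec a [cohort_spec()]; ignored when `trait_csv` is given.
#' @param trait_csv optional path to a precomputed trait table (skips the
#'   geometry stages).
#' @param rsml optional path to an RSML file to read the cohort from.
#' @param m curve resample count for the distance stage.
#' @param mds_dims embedding dimension.
#' @param lateral_weight weight of the lateral term in the distance.
#' @param subset_sizes sizes for the exhaustive subset search.
#' @param best_size subset size used for bootstrap and permutation stages.
#' @param B bootstrap replicates.
#' @param n_perm permutations per scheme.
#' @param schemes permutation schemes to run.
#' @param level confidence level for mean regions.
#' @param cor_threshold correlation-panel threshold.
#' @param seed master seed for all resampling stages.
#' @param out_dir output directory (created if needed); NULL for none.
#' @param plots emit figure files?
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = default_cohort_spec(), trait_csv = NULL,
                            rsml = NULL, m = 50L, mds_dims = 5L,
                            lateral_weight = 1, subset_sizes = NULL,
                            best_size = 9L, B = 1000L, n_perm = 10000L,
                            schemes = names(permutation_schemes()),
                            level = 0.99, cor_threshold = 0.5, seed = 1L,
                            out_dir = NULL, plots = !is.null(out_dir)) {
  stopifnot(mds_dims >= 1L, B >= 1L, n_perm >= 1L, level > 0, level < 1)
  structure(list(spec = spec, trait_csv = trait_csv, rsml = rsml, m = m,
                 mds_dims = mds_dims, lateral_weight = lateral_weight,
                 subset_sizes = subset_sizes, best_size = best_size, B = B,
                 n_perm = n_perm, schemes = schemes, level = level,
                 cor_threshold = cor_threshold, seed = as.integer(seed),
                 out_dir = out_dir, plots = plots),
            class = "pipeline_config")
}

# small deterministic FNV-1a hash of the deparsed config, for provenance
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 216613626
  for (b in bytes)
    h <- (bitwXor(as.integer(h), as.integer(b)) * 16777619) %% 2147483648
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Stages: cohort (generate, or read RSML/CSV) -> traits -> pairwise
#' distances -> MDS embedding -> standardized 16-variable table ->
#' correlation panel -> PCA -> Mahalanobis group-distance maps (both
#' orderings) -> LDA for the NUpE, nitrate and four-group labellings ->
#' exhaustive subset search -> bootstrap of the best-subset loadings ->
#' block-permutation tests -> LD1 percentile exemplars. Numeric results
#' are written as CSV/JSON under `out_dir` when it is set; figures are
#' best-effort artifacts, the numeric files are the contract.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report` holding every stage's result plus
#'   provenance (`config`, `config_hash`, `seed`, `paths`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(config = config, config_hash = config_hash(config),
              seed = config$seed, paths = character(0))
  emit <- function(name, writer) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(config$out_dir, name)
      writer(path)
      out$paths <<- c(out$paths, path)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (!is.null(config$trait_csv)) {
    table <- stage("read_traits", read_trait_csv(config$trait_csv))
    out$cohort <- NULL
  } else {
    out$cohort <- stage("cohort", {
      if (!is.null(config$rsml)) read_rsml(config$rsml)
      else generate_cohort(config$spec)
    })
    out$distances <- stage("distances",
      distance_matrix(out$cohort, m = config$m,
                      lateral_weight = config$lateral_weight))
    out$embedding <- stage("embedding",
      classical_mds(out$distances, k = config$mds_dims))
    table <- stage("traits", build_trait_table(out$cohort, out$embedding))
    emit("distances.csv", function(p)
      write.csv(unclass(out$distances), p))
  }
  out$table <- table
  out$table_std <- stage("standardize", standardize(table))
  emit("traits.csv", function(p) write_trait_csv(out$table, p))
  emit("traits_standardized.csv", function(p)
    write_trait_csv(out$table_std, p))

  X <- trait_matrix(out$table_std)
  meta <- as.data.frame(out$table_std)[meta_cols()]
  out$correlation <- stage("correlation",
    correlated_subset(out$table_std, config$cor_threshold))
  out$pca <- stage("pca", pca(X, k = min(3L, ncol(X))))
  out$distance_maps <- stage("mahalanobis", list(
    line_pairs = group_distance_map(out$table_std, "line-pairs"),
    nitrate_blocks = group_distance_map(out$table_std, "nitrate-blocks")))

  out$lda <- stage("lda", list(
    nupe = fit_lda(X, meta$nupe_class, orientation_ref = meta$nupe_class),
    nitrate = fit_lda(X, meta$nitrate, orientation_ref = meta$nitrate),
    four_group = fit_lda(X, meta$group_code,
                         orientation_ref = meta$nupe_class)))
  out$regions <- stage("regions",
    mean_confidence_regions(out$lda$four_group, level = config$level))

  out$subsets <- stage("subsets",
    best_subsets(X, meta$group_code, sizes = config$subset_sizes))
  sizes <- vapply(out$subsets$best, function(b) b$size, numeric(1))
  pick <- which(sizes == config$best_size)
  if (!length(pick)) pick <- which.max(sizes)
  best9 <- out$subsets$best[[pick[1L]]]$subset
  out$best_subset <- best9

  out$bootstrap <- stage("bootstrap",
    bootstrap_loadings(X, meta$group_code, subset = best9, B = config$B,
                       seed = plant_seed(config$seed, 1L),
                       orientation_ref = meta$nupe_class))
  out$permutations <- stage("permutations", {
    res <- lapply(seq_along(config$schemes), function(si)
      permutation_test(X, meta$group_code, scheme = config$schemes[si],
                       n_perm = config$n_perm,
                       seed = plant_seed(config$seed, 100L + si),
                       statistic_subset = best9))
    names(res) <- config$schemes
    res
  })
  fit9 <- fit_lda(X[, best9, drop = FALSE], meta$group_code,
                  orientation_ref = meta$nupe_class)
  out$lda_best9 <- fit9
  out$exemplars <- stage("exemplars",
    percentile_exemplars(setNames(fit9$scores[, 1L], meta$plant_id),
                         k = min(5L, nrow(X))))

  emit("model.json", function(p) {
    m4 <- out$lda$four_group
    jsonlite::write_json(list(
      config_hash = out$config_hash, seed = config$seed,
      eigenvalues = m4$eigenvalues,
      loadings = as.data.frame(m4$loadings),
      variable_names = m4$variable_names,
      group_means = as.data.frame(m4$group_means),
      best_subset = best9,
      zeta2_best = vapply(out$subsets$best, function(b) b$zeta2, numeric(1)),
      permutation_p = vapply(out$permutations, function(x) x$p_value,
                             numeric(1))),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  emit("scores.csv", function(p)
    write.csv(data.frame(meta, out$lda$four_group$scores), p,
              row.names = FALSE))
  if (isTRUE(config$plots) && !is.null(config$out_dir)) {
    if (!is.null(out$cohort))
      emit("overlay.png", function(p) save_plot(p, function()
        overlay_plot(out$cohort), width = 1600, height = 900))
    emit("distance_map_line_pairs.png", function(p) save_plot(p, function()
      plot_group_distance_map(out$distance_maps$line_pairs)))
    emit("distance_map_nitrate_blocks.png", function(p) save_plot(p, function()
      plot_group_distance_map(out$distance_maps$nitrate_blocks)))
    emit("lda_densities.png", function(p) save_plot(p, function()
      plot_score_densities(out$lda$four_group)))
    emit("confidence_regions.png", function(p) save_plot(p, function()
      plot_confidence_regions(out$regions)))
    emit("permutations.png", function(p) save_plot(p, function()
      plot_permutation_tests(out$permutations), width = 1200, height = 800))
  }
  structure(out, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report %s: %d plants, seed %d>\n", x$config_hash,
              nrow(x$table), x$seed))
  if (!is.null(x$permutations)) {
    for (nm in names(x$permutations))
      cat(sprintf("  perm %-15s p = %.4g\n", nm,
                  x$permutations[[nm]]$p_value))
  }
  invisible(x)
}
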