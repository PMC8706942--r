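# End-to-end orchestration: simulate (or ingest) a cohort, place one shared
# ROI centre per volume, extract the 93 features at each study diameter,
# run the stability statistics per scanner and sequence, and summarize the
# concordantly robust feature sets.

#' Study configuration
#'
#' @param cohort A [cohort_spec()].
#' @param diameters ROI diameters in mm (default the study sizes 10/20/30).
#' @param bin_width Discretization bin width.
#' @param alpha Significance level for the pairwise tests.
#' @param occc_threshold Excellent-agreement OCCC threshold.
#' @return A list of class `study_config`.
#' @export
study_config <- function(cohort = cohort_spec(), diameters = c(10, 20, 30),
                         bin_width = 25, alpha = 0.05,
                         occc_threshold = 0.90) {
  stopifnot(inherits(cohort, "cohort_spec"), length(diameters) >= 2L,
            all(diameters > 0), bin_width > 0,
            alpha > 0, alpha < 1, occc_threshold > 0, occc_threshold <= 1)
  structure(list(cohort = cohort, diameters = sort(as.numeric(diameters)),
                 bin_width = bin_width, alpha = alpha,
                 occc_threshold = occc_threshold),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognized keys: `subjects_per_scanner` (named map), `seed`,
#' `volume_shape`, `diameters`, `bin_width`, `alpha`, `occc_threshold`, and
#' an optional `profiles` list whose entries carry the [scanner_profile()]
#' fields. Missing keys fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  profiles <- if (!is.null(y$profiles)) {
    lapply(y$profiles, function(p)
      scanner_profile(p$name, p$sequence, p$in_plane_spacing, p$z_spacing,
                      p$mean_intensity, p$subject_sd, p$noise_sd,
                      p$correlation_length))
  } else default_profiles()
  spec_args <- list(profiles = profiles)
  if (!is.null(y$subjects_per_scanner))
    spec_args$subjects_per_scanner <- unlist(y$subjects_per_scanner)
  if (!is.null(y$seed)) spec_args$seed <- y$seed
  if (!is.null(y$volume_shape)) spec_args$volume_shape <- unlist(y$volume_shape)
  cfg_args <- list(cohort = do.call(cohort_spec, spec_args))
  for (k in c("diameters", "bin_width", "alpha", "occc_threshold"))
    if (!is.null(y[[k]])) cfg_args[[k]] <- unlist(y[[k]])
  do.call(study_config, cfg_args)
}

#' Extract features for a whole cohort
#'
#' For every volume, places the shared ROI centre (one centre per
#' subject/sequence volume, used by all diameters) and extracts the 93
#' features at each diameter.
#'
#' @param volumes List of [subject_volume()] objects.
#' @param diameters ROI diameters in mm.
#' @param bin_width Discretization bin width.
#' @return Data frame with columns `subject_id`, `scanner`, `sequence`,
#'   `diameter`, `voxel_count`, then the 93 feature columns.
#' @export
extract_cohort_features <- function(volumes, diameters = c(10, 20, 30),
                                    bin_width = 25) {
  rows <- vector("list", length(volumes) * length(diameters))
  k <- 0L
  for (v in volumes) {
    center <- place_center(v)
    for (dia in diameters) {
      mask <- sphere_mask(v$spacing, dim(v$voxels), sphere_roi(center, dia))
      fv <- extract_all(v, mask, bin_width = bin_width)
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = v$subject_id, scanner = v$scanner,
        sequence = v$sequence, diameter = dia,
        voxel_count = mask$voxel_count,
        as.list(fv), check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-feature stability records
#'
#' For every scanner x sequence x feature cell, runs the three pairwise
#' Mann-Whitney U tests (Bonferroni within the three size pairs) and the
#' OCCC over both size subsets, and derives the robustness flags. Subjects
#' are matched across sizes by `subject_id`.
#'
#' @param features Data frame from [extract_cohort_features()].
#' @param sizes The three study diameters.
#' @param alpha Significance level.
#' @param occc_threshold Excellent-agreement threshold.
#' @return Data frame with one row per feature/scanner/sequence:
#'   adjusted p-values for the three pairs, both OCCCs, and the flags
#'   `nonsignificant_all_pairs`, `excellent_all`, `excellent_large`.
#' @export
stability_records <- function(features, sizes = c(10, 20, 30), alpha = 0.05,
                              occc_threshold = 0.90) {
  sizes <- sort(sizes)
  fnames <- intersect(feature_names(), names(features))
  if (length(fnames) == 0L) .stopf("no canonical feature columns found")
  cells <- unique(features[, c("scanner", "sequence")])
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    sc <- cells$scanner[ci]; sq <- cells$sequence[ci]
    cell <- features[features$scanner == sc & features$sequence == sq, ]
    by_size_rows <- lapply(sizes, function(s) {
      g <- cell[cell$diameter == s, ]
      g[order(g$subject_id), ]
    })
    names(by_size_rows) <- as.character(sizes)
    ns <- unique(vapply(by_size_rows, nrow, integer(1)))
    if (length(ns) != 1L || ns < 3L)
      .stopf("scanner %s / %s: size groups unbalanced or too small", sc, sq)
    sub_ids <- lapply(by_size_rows, `[[`, "subject_id")
    if (length(unique(sub_ids)) != 1L)
      .stopf("scanner %s / %s: subjects not matched across sizes", sc, sq)
    for (f in fnames) {
      by_size <- lapply(by_size_rows, `[[`, f)
      pw <- pairwise_size_tests(by_size, alpha = alpha, sizes = sizes)
      oc <- occc_both_subsets(by_size, sizes = sizes,
                              threshold = occc_threshold)
      rec <- data.frame(feature = f, scanner = sc, sequence = sq)
      for (i in seq_len(nrow(pw))) {
        rec[[sprintf("p_adj_%g_%g", pw$size_a[i], pw$size_b[i])]] <- pw$p_adj[i]
      }
      rec[[sprintf("occc_%g_%g", sizes[1L], sizes[length(sizes)])]] <- oc$all$occc
      rec[[sprintf("occc_%g_%g", sizes[2L], sizes[length(sizes)])]] <- oc$large$occc
      rec$nonsignificant_all_pairs <- !any(pw$significant)
      rec$excellent_all <- isTRUE(oc$all$excellent)
      rec$excellent_large <- isTRUE(oc$large$excellent)
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Concordantly robust feature summary
#'
#' Set algebra over the stability records, per sequence: a feature is
#' *concordantly nonsignificant* iff `nonsignificant_all_pairs` holds on
#' every scanner; *concordantly excellent* (per OCCC subset) iff the
#' corresponding excellent flag holds on every scanner. The robust
#' intersection combines all three lists; `gained_excellent_large` lists
#' features excellent over the large-size subset but not over the full one.
#'
#' @param records Data frame from [stability_records()].
#' @return Named list (one element per sequence), each with
#'   `nonsignificant`, `excellent_all`, `excellent_large`,
#'   `robust_intersection` and `gained_excellent_large` character vectors.
#' @export
concordant_feature_summary <- function(records) {
  need <- c("feature", "scanner", "sequence", "nonsignificant_all_pairs",
            "excellent_all", "excellent_large")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0L)
    .stopf("records lack column(s): %s", paste(missing, collapse = ", "))
  scanners <- unique(records$scanner)
  counts <- table(records$scanner, records$sequence)
  if (any(counts != counts[1L]))
    .stopf("incomplete record set: unequal feature counts across scanner/sequence cells")
  out <- list()
  for (sq in unique(records$sequence)) {
    r <- records[records$sequence == sq, ]
    all_scanners <- function(flag) {
      agg <- tapply(r[[flag]], r$feature, all)
      names(agg)[agg]
    }
    nonsig <- all_scanners("nonsignificant_all_pairs")
    exc_all <- all_scanners("excellent_all")
    exc_lrg <- all_scanners("excellent_large")
    ord <- feature_names()
    keep_order <- function(x) ord[ord %in% x]
    out[[sq]] <- list(
      nonsignificant = keep_order(nonsig),
      excellent_all = keep_order(exc_all),
      excellent_large = keep_order(exc_lrg),
      robust_intersection = keep_order(Reduce(intersect,
                                              list(nonsig, exc_all, exc_lrg))),
      gained_excellent_large = keep_order(setdiff(exc_lrg, exc_all)))
  }
  out
}

#' Run the full ROI-size stability study
#'
#' Simulates the cohort, extracts features at every diameter, computes the
#' stability records and the concordant summary. End-to-end deterministic
#' for a fixed cohort seed. When `out_dir` is given, writes `features.csv`
#' and `stability.csv` (numbers at full double precision, so the statistics
#' stage is exactly reproducible from the intermediates), `summary.json`,
#' and a `settings.json` sidecar recording the extraction settings.
#'
#' @param config A [study_config()] (or a path to a YAML file accepted by
#'   [read_study_config()]).
#' @param out_dir Optional output directory.
#' @return List with `features`, `records`, `summary` and `settings`
#'   (invisibly when `out_dir` is given).
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  volumes <- stage("simulate", simulate_cohort(config$cohort))
  features <- stage("extract",
                    extract_cohort_features(volumes, config$diameters,
                                            config$bin_width))
  records <- stage("stats",
                   stability_records(features, sizes = config$diameters,
                                     alpha = config$alpha,
                                     occc_threshold = config$occc_threshold))
  summary <- stage("report", concordant_feature_summary(records))
  settings <- list(
    seed = config$cohort$seed,
    subjects_per_scanner = as.list(config$cohort$subjects_per_scanner),
    volume_shape = config$cohort$volume_shape,
    diameters = config$diameters,
    bin_width = config$bin_width,
    discretization = "fixed bin width, anchor = bin_width * floor(min / bin_width)",
    neighbourhood = "26-connectivity, distance 1 (index space), 13 unique directions",
    aggregation = "per-direction features averaged (GLCM, GLRLM)",
    alpha = config$alpha,
    bonferroni_family = 3,
    occc_threshold = config$occc_threshold,
    occc_divisor = "n")
  result <- list(features = features, records = records, summary = summary,
                 settings = settings)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_features_csv(features, file.path(out_dir, "features.csv"))
    write_features_csv(records, file.path(out_dir, "stability.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(settings, file.path(out_dir, "settings.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(result))
  }
  result
}
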