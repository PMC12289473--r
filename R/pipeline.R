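#' Assemble a pipeline configuration
#'
#' The end-to-end run chains: distance distributions (test cohort,
#' same-syndrome null, random null) -> ROC / Youden threshold +
#' cross-validation -> fraction-below statistic -> leave-one-out rank
#' matrix -> top-k syndrome tallies. Gallery and cohort may be given as
#' objects, file paths (wide-TSV dialect), or left `NULL` to be
#' simulated from `synthetic`.
#'
#' @param output_dir Directory for the report bundle.
#' @param gallery,cohort A `gallery`/`cohort` object, a file path, or
#'   `NULL` (simulate).
#' @param synthetic A [synthetic_config()] used when simulating (default:
#'   a desk-scale configuration, 50 syndromes x 3 subjects x 2 images at
#'   d = 64, E = 3).
#' @param n_resamples Resampling draws per distribution (default 100).
#' @param subcohort_size Null sub-cohort size; `NULL` (default) uses the
#'   test cohort's subject count.
#' @param cv_folds Cross-validation folds (default 5).
#' @param top_k Neighborhood size for syndrome tallies (default 30).
#' @param seed Master seed; per-stage seeds are derived from it by a
#'   stable hash of the stage name, so a stage rerun alone reproduces its
#'   output.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, gallery = NULL, cohort = NULL,
                            synthetic = NULL, n_resamples = 100L,
                            subcohort_size = NULL, cv_folds = 5L,
                            top_k = 30L, seed = 1L) {
  if (is.null(synthetic)) {
    synthetic <- synthetic_config(n_syndromes = 50L,
                                  subjects_per_syndrome = 3L,
                                  images_per_subject = 2L,
                                  d = 64L, E = 3L,
                                  sigma_subject = 0.2, sigma_image = 0.1,
                                  sigma_ensemble = 0.05, seed = seed)
  }
  structure(
    list(output_dir = output_dir, gallery = gallery, cohort = cohort,
         synthetic = synthetic, n_resamples = as.integer(n_resamples),
         subcohort_size = subcohort_size, cv_folds = as.integer(cv_folds),
         top_k = as.integer(top_k), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Derive a reproducible per-stage child seed
#'
#' @param seed Master integer seed.
#' @param stage Stage name.
#' @return An integer seed below 2^31, a stable function of both inputs.
#' @export
stage_seed <- function(seed, stage) {
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars)) %% 65536L
  (as.integer(seed) %% 32767L) * 65536L + h
}

resolve_gallery <- function(x, cfg) {
  if (inherits(x, "gallery")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("gallery file not found: %s", x),
                              call. = FALSE)
    return(load_embeddings(x, format = "wide"))
  }
  generate_gallery(cfg$synthetic)
}

resolve_cohort <- function(x, cfg) {
  if (inherits(x, "cohort")) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("cohort file not found: %s", x),
                              call. = FALSE)
    return(cohort(load_embeddings(x, format = "wide")$items))
  }
  generate_cohort(cfg$synthetic, n_subjects = 4L,
                  images_per_subject = c(1L, 3L), n_images = 7L,
                  seed = stage_seed(cfg$seed, "cohort"))
}

#' Run the full cohort-similarity pipeline
#'
#' Executes every stage, writes the distribution long table, rank matrix
#' and syndrome tallies as TSV plus a JSON report embedding the resolved
#' configuration and all derived seeds, and returns the report invisibly.
#' Cohort images found in the gallery are dropped from the gallery before
#' null distributions are built, keeping test and reference disjoint.
#'
#' @param config A [pipeline_config()].
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_stage <- function(stage) {
    message(sprintf("[%s] stage=%s elapsed=%.1fs", "facegestalt", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  g <- resolve_gallery(config$gallery, config)
  co <- resolve_cohort(config$cohort, config)
  overlap <- intersect(names(co$items), names(g$items))
  if (length(overlap) > 0L) g <- exclude_images(g, overlap)
  log_stage("load")

  size <- if (is.null(config$subcohort_size)) {
    length(unique(subject_ids(co)))
  } else {
    as.integer(config$subcohort_size)
  }
  dists <- distribution_set(
    test = resample_test_distribution(co, n = config$n_resamples,
                                      seed = stage_seed(config$seed, "test")),
    same = build_same_distribution(g, size, n = config$n_resamples,
                                   seed = stage_seed(config$seed, "same")),
    random = build_random_distribution(g, size, n = config$n_resamples,
                                       seed = stage_seed(config$seed,
                                                         "random")),
    subcohort_size = size, seed = config$seed
  )
  utils::write.table(as_long_table(dists),
                     file.path(config$output_dir, "distributions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("cohort-dist")

  roc <- roc_from_samples(dists$same, dists$random)
  cv <- crossvalidate(dists$same, dists$random, k = config$cv_folds,
                      seed = stage_seed(config$seed, "cv"))
  frac <- fraction_below(dists$test, roc$youden_threshold)
  log_stage("threshold")

  rkm <- pairwise_rank_matrix(co, g)
  utils::write.table(
    data.frame(probe = rownames(rkm$ranks), rkm$ranks, check.names = FALSE),
    file.path(config$output_dir, "rank_matrix.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  topk <- top_k_matches(co, g, k = min(config$top_k, length(g$items)))
  utils::write.table(topk$per_subject,
                     file.path(config$output_dir, "syndrome_tally.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("rank")

  report <- list(
    package_version = as.character(utils::packageVersion("facegestalt")),
    config = list(
      output_dir = config$output_dir,
      n_resamples = config$n_resamples,
      subcohort_size = size,
      cv_folds = config$cv_folds,
      top_k = topk$k,
      seed = config$seed,
      stage_seeds = list(
        cohort = stage_seed(config$seed, "cohort"),
        test = stage_seed(config$seed, "test"),
        same = stage_seed(config$seed, "same"),
        random = stage_seed(config$seed, "random"),
        cv = stage_seed(config$seed, "cv")
      ),
      synthetic = unclass(config$synthetic),
      gallery_source = if (is.character(config$gallery)) config$gallery
                       else if (inherits(config$gallery, "gallery"))
                         "object" else "simulated",
      cohort_source = if (is.character(config$cohort)) config$cohort
                      else if (inherits(config$cohort, "cohort"))
                        "object" else "simulated"
    ),
    gallery = list(n_images = length(g$items),
                   n_subjects = length(unique(subject_ids(g))),
                   n_syndromes = length(syndrome_index(g))),
    cohort = list(n_images = length(co$items),
                  n_subjects = length(unique(subject_ids(co)))),
    distributions = list(
      median_test = stats::median(dists$test),
      median_same = stats::median(dists$same),
      median_random = stats::median(dists$random)
    ),
    threshold = list(
      auc = roc$auc, c = roc$youden_threshold,
      sensitivity = roc$youden_sensitivity,
      specificity = roc$youden_specificity,
      cv = list(k = cv$k, mean_sensitivity = cv$mean_sensitivity,
                mean_specificity = cv$mean_specificity,
                per_fold = cv$per_fold),
      fraction_below_test = frac
    ),
    rank = list(
      gallery_size = rkm$gallery_size,
      best_cross_subject_rank =
        min(rkm$ranks[!is.na(rkm$ranks) & !rkm$same_subject]),
      modal_syndromes = topk$modal
    )
  )
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  log_stage("report")
  invisible(report)
}
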