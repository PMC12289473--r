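#' Construct a test cohort of embedding sets
#'
#' A cohort is the group of patients whose facial similarity is under
#' test (e.g. seven photos from four affected subjects). It must contain
#' at least two distinct subjects; each image belongs to exactly one
#' subject.
#'
#' @param items List of [embedding_set()] objects.
#' @return Object of class `cohort` with fields `items`, `E`, `d`.
#' @export
cohort <- function(items) {
  g <- gallery(items)
  subj <- unique(subject_ids(g))
  if (length(subj) < 2L) {
    stop("a cohort needs at least 2 distinct subjects", call. = FALSE)
  }
  structure(list(items = g$items, E = g$E, d = g$d), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d images from %d subjects (E = %d, d = %d)\n",
              length(x$items), length(unique(subject_ids(x))), x$E, x$d))
  invisible(x)
}

# sample() treats a length-1 numeric as 1:n; this does not
sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Draw one image per subject from a cohort
#'
#' Sub-cohorts never contain two images of the same individual, so
#' within-person similarity cannot inflate the cohort statistic. The draw
#' uses the current RNG state; seed upstream for reproducibility.
#'
#' @param x A `cohort` (or `gallery`).
#' @return Character vector of image ids, one per subject, uniform among
#'   that subject's images.
#' @export
sample_subcohort <- function(x) {
  idx <- subject_index(x)
  bad <- names(idx)[lengths(idx) == 0L]
  if (length(bad) > 0L) {
    stop(sprintf("subject(s) without images: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  vapply(idx, sample_one, character(1), USE.NAMES = FALSE)
}

#' Mean pairwise ensemble distance of a set of images
#'
#' Arithmetic mean of [pair_distance()] over all `n(n-1)/2` unordered
#' image pairs.
#'
#' @param ids Character vector of at least 2 image ids.
#' @param x The `gallery` or `cohort` holding the images.
#' @return A scalar in `[0, 2]`.
#' @export
mean_pairwise_distance <- function(ids, x) {
  if (length(ids) < 2L) {
    stop("need at least 2 image ids", call. = FALSE)
  }
  missing_ids <- setdiff(ids, names(x$items))
  if (length(missing_ids) > 0L) {
    stop(sprintf("unknown image id(s): %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  D <- distance_matrix(x$items[ids])
  mean(D[lower.tri(D)])
}

#' Resampled mean-pairwise-distance distribution of a test cohort
#'
#' Repeatedly draws a one-image-per-subject sub-cohort and records its
#' mean pairwise distance. The spread of this distribution reflects both
#' photo-level variation and how tightly the cohort clusters.
#'
#' @param x A `cohort`.
#' @param n Number of resamples (default 100).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
resample_test_distribution <- function(x, n = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    mean_pairwise_distance(sample_subcohort(x), x)
  }, numeric(1))
}

# syndromes usable for the same-syndrome null: labelled, >= 2 subjects
eligible_syndromes <- function(g, min_subjects = 2L) {
  idx <- syndrome_index(g)
  idx[lengths(idx) >= min_subjects]
}

#' Same-syndrome null distribution from a gallery
#'
#' Per draw: pick an eligible syndrome (>= 2 labelled subjects) uniformly,
#' sample `min(size, n_subjects)` distinct subjects of it (at least 2),
#' take one image per subject, and record the mean pairwise distance.
#' Repetitions are independent; identical sub-cohorts may recur.
#'
#' @param g A `gallery` with at least one syndrome having >= 2 subjects.
#' @param size Target sub-cohort size (subjects per draw); typically the
#'   test cohort's subject count.
#' @param n Number of draws (default 100).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
build_same_distribution <- function(g, size, n = 100L, seed = NULL) {
  elig <- eligible_syndromes(g)
  if (length(elig) == 0L) {
    stop("no syndrome with >= 2 labelled subjects in the gallery",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  subj_idx <- subject_index(g)
  vapply(seq_len(n), function(i) {
    subjects <- elig[[sample.int(length(elig), 1L)]]
    m <- max(2L, min(size, length(subjects)))
    chosen <- subjects[sample.int(length(subjects), m)]
    ids <- vapply(subj_idx[chosen], sample_one, character(1))
    mean_pairwise_distance(ids, g)
  }, numeric(1))
}

#' Random (syndrome-agnostic) null distribution from a gallery
#'
#' Per draw: sample `size` distinct subjects ignoring syndrome labels,
#' one image per subject, and record the mean pairwise distance.
#'
#' @inheritParams build_same_distribution
#' @return Numeric vector of length `n`.
#' @export
build_random_distribution <- function(g, size, n = 100L, seed = NULL) {
  subj_idx <- subject_index(g)
  if (length(subj_idx) < 2L) {
    stop("gallery has fewer than 2 subjects", call. = FALSE)
  }
  if (length(subj_idx) < size) {
    stop(sprintf("gallery has %d subjects, fewer than size = %d",
                 length(subj_idx), size), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nsub <- length(subj_idx)
  vapply(seq_len(n), function(i) {
    chosen <- sample.int(nsub, size)
    ids <- vapply(subj_idx[chosen], sample_one, character(1))
    mean_pairwise_distance(ids, g)
  }, numeric(1))
}

#' Bundle the three resampled distance distributions
#'
#' @param test,same,random Numeric vectors of resampled mean pairwise
#'   distances (test cohort, same-syndrome null, random null).
#' @param subcohort_size Subjects per draw used for the nulls.
#' @param seed Seed used (for the record).
#' @return Object of class `distribution_set`.
#' @export
distribution_set <- function(test, same, random, subcohort_size = NA_integer_,
                             seed = NA_integer_) {
  for (v in list(test, same, random)) {
    stopifnot(is.numeric(v), length(v) > 0L, all(is.finite(v)),
              all(v >= 0), all(v <= 2))
  }
  structure(list(test = test, same = same, random = random,
                 n_resamples = length(random),
                 subcohort_size = subcohort_size, seed = seed),
            class = "distribution_set")
}

#' @export
print.distribution_set <- function(x, ...) {
  cat(sprintf(
    "<distribution_set> n = %d draws, sub-cohort size %s\n  median test %.3f | same %.3f | random %.3f\n",
    x$n_resamples, x$subcohort_size,
    stats::median(x$test), stats::median(x$same), stats::median(x$random)))
  invisible(x)
}

#' Overlaid histograms of the three distance distributions
#'
#' @param x A [distribution_set()].
#' @param breaks Passed to [graphics::hist()].
#' @param threshold Optional vertical cutoff line (e.g. the Youden
#'   threshold).
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.distribution_set <- function(x, breaks = 20, threshold = NULL, ...) {
  rng <- range(c(x$test, x$same, x$random))
  brk <- seq(rng[1], rng[2], length.out = breaks + 1L)
  ht <- graphics::hist(x$test, breaks = brk, plot = FALSE)
  hs <- graphics::hist(x$same, breaks = brk, plot = FALSE)
  hr <- graphics::hist(x$random, breaks = brk, plot = FALSE)
  ylim <- c(0, max(ht$counts, hs$counts, hr$counts))
  graphics::plot(hs, col = grDevices::adjustcolor("steelblue", 0.5),
                 ylim = ylim, xlab = "mean pairwise cosine distance",
                 main = "cohort vs null distance distributions", ...)
  graphics::plot(hr, col = grDevices::adjustcolor("firebrick", 0.5),
                 add = TRUE)
  graphics::plot(ht, col = grDevices::adjustcolor("orange", 0.6), add = TRUE)
  if (!is.null(threshold)) graphics::abline(v = threshold, lwd = 2)
  graphics::legend("topleft", fill = c("orange", "steelblue", "firebrick"),
                   legend = c("test cohort", "same syndrome", "random"),
                   bty = "n")
  invisible(x)
}

#' Long-format export of a distribution set
#'
#' @param x A [distribution_set()].
#' @return A data.frame with columns `distribution`, `draw_index`, `value`.
#' @export
as_long_table <- function(x) {
  stopifnot(inherits(x, "distribution_set"))
  data.frame(
    distribution = rep(c("test", "same", "random"),
                       times = c(length(x$test), length(x$same),
                                 length(x$random))),
    draw_index = c(seq_along(x$test), seq_along(x$same),
                   seq_along(x$random)),
    value = c(x$test, x$same, x$random),
    stringsAsFactors = FALSE
  )
}
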