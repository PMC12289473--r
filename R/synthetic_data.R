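#' Configuration for the hierarchical hypersphere gallery simulator
#'
#' The simulator emulates the statistical structure of a syndromic facial
#' embedding gallery: syndromes form clusters on the unit sphere,
#' subjects sub-cluster around their syndrome center, images scatter
#' around their subject, and the `E` ensemble members of an image are
#' small perturbations of it (model ensemble / test-time augmentation
#' noise). Each level draws an isotropic Gaussian perturbation and
#' re-projects onto the sphere (a simple, reproducible surrogate for von
#' Mises-Fisher sampling with the same qualitative geometry).
#'
#' The sigma parameters are perturbation scales relative to the unit
#' sphere radius: `sigma_subject` controls how spread out subjects of a
#' syndrome are (cluster tightness), `sigma_image` the photo-to-photo
#' variation within a subject, `sigma_ensemble` the ensemble jitter.
#'
#' @param n_syndromes Number of syndrome clusters (default 50).
#' @param subjects_per_syndrome Subjects per syndrome (default 3).
#' @param images_per_subject Images per subject: a single count or a
#'   `c(lo, hi)` range sampled uniformly (default 2).
#' @param d Embedding dimension (default 512).
#' @param E Ensemble size (default 12).
#' @param sigma_subject,sigma_image,sigma_ensemble Non-negative
#'   perturbation scales (defaults 0.3, 0.15, 0.05).
#' @param seed Integer seed (default 1).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_syndromes = 50L, subjects_per_syndrome = 3L,
                             images_per_subject = 2L, d = 512L, E = 12L,
                             sigma_subject = 0.3, sigma_image = 0.15,
                             sigma_ensemble = 0.05, seed = 1L) {
  stopifnot(n_syndromes >= 1L, subjects_per_syndrome >= 1L,
            all(images_per_subject >= 1L),
            length(images_per_subject) %in% 1:2,
            E >= 1L,
            is.finite(sigma_subject), sigma_subject >= 0,
            is.finite(sigma_image), sigma_image >= 0,
            is.finite(sigma_ensemble), sigma_ensemble >= 0)
  if (d < 2L) stop("d must be >= 2", call. = FALSE)
  structure(
    list(n_syndromes = as.integer(n_syndromes),
         subjects_per_syndrome = as.integer(subjects_per_syndrome),
         images_per_subject = as.integer(images_per_subject),
         d = as.integer(d), E = as.integer(E),
         sigma_subject = sigma_subject, sigma_image = sigma_image,
         sigma_ensemble = sigma_ensemble, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

unit <- function(v) v / sqrt(sum(v * v))

# perturb a unit vector with isotropic Gaussian noise, project back
perturb <- function(center, sigma, d) {
  if (sigma == 0) return(center)
  unit(center + sigma * stats::rnorm(d))
}

n_images_draw <- function(rng_range) {
  if (length(rng_range) == 1L) return(rng_range)
  rng_range[1L] + sample.int(rng_range[2L] - rng_range[1L] + 1L, 1L) - 1L
}

# build the embedding sets for one subject around a subject center
subject_images <- function(center, n_img, cfg, subject_id, syndrome_label) {
  lapply(seq_len(n_img), function(i) {
    img <- perturb(center, cfg$sigma_image, cfg$d)
    members <- t(vapply(seq_len(cfg$E), function(k) {
      perturb(img, cfg$sigma_ensemble, cfg$d)
    }, numeric(cfg$d)))
    embedding_set(sprintf("%s_I%02d", subject_id, i), subject_id, members,
                  syndrome_label = syndrome_label, normalize = FALSE)
  })
}

#' Simulate a syndrome-structured embedding gallery
#'
#' Syndrome centers are uniform on the unit `(d-1)`-sphere; subjects,
#' images and ensemble members are generated by Gaussian-perturb-then-
#' normalize at successively smaller scales (see [synthetic_config()]).
#' Ids are systematic (`S001_P01_I01`) and encode the ground-truth
#' syndrome and subject, so recovery tests need no side table. Output is
#' fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A [gallery()].
#' @export
generate_gallery <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  items <- list()
  centers <- matrix(NA_real_, config$n_syndromes, config$d)
  rownames(centers) <- sprintf("S%03d", seq_len(config$n_syndromes))
  for (s in seq_len(config$n_syndromes)) {
    syn <- sprintf("S%03d", s)
    mu <- unit(stats::rnorm(config$d))
    centers[syn, ] <- mu
    for (p in seq_len(config$subjects_per_syndrome)) {
      subj_id <- sprintf("%s_P%02d", syn, p)
      center <- perturb(mu, config$sigma_subject, config$d)
      n_img <- n_images_draw(config$images_per_subject)
      items <- c(items, subject_images(center, n_img, config, subj_id, syn))
    }
  }
  g <- gallery(items)
  # ground-truth centers, handy for parameter-recovery tests
  attr(g, "syndrome_centers") <- centers
  g
}

#' Ground-truth syndrome centers of a simulated gallery
#'
#' @param g A gallery produced by [generate_gallery()].
#' @return Matrix of unit syndrome-center vectors (rows named by label),
#'   or `NULL` for galleries that were not simulated.
#' @export
syndrome_centers <- function(g) attr(g, "syndrome_centers")

#' Simulate a held-out test cohort
#'
#' Generates a cohort of `n_subjects` around one new syndrome center (or
#' around `attach_to`, a unit vector such as an existing gallery
#' syndrome's center) with the same hierarchical noise model as
#' [generate_gallery()]. The cohort's syndrome label is held out
#' (distinct from all systematic gallery labels), mirroring an
#' ultra-rare disorder absent from the reference database. When `tight =
#' FALSE` each subject gets its own independent syndrome center, giving a
#' biologically heterogeneous "random" cohort for negative controls.
#'
#' @param config A [synthetic_config()] (supplies `d`, `E` and sigmas).
#' @param n_subjects Number of subjects (>= 2; default 4).
#' @param images_per_subject `c(lo, hi)` per-subject range (default
#'   `c(1, 3)`).
#' @param n_images Optional total image count the allocation must hit
#'   (e.g. 7 photos over 4 subjects).
#' @param attach_to Optional unit vector to use as the syndrome center.
#' @param label Cohort syndrome label (default `"CASE"`).
#' @param seed Integer seed (defaults to `config$seed + 1`).
#' @param tight If `TRUE` (default) all subjects share one syndrome
#'   center; if `FALSE` subjects are drawn from independent centers.
#' @return A [cohort()].
#' @export
generate_cohort <- function(config, n_subjects = 4L,
                            images_per_subject = c(1L, 3L),
                            n_images = NULL, attach_to = NULL,
                            label = "CASE", seed = config$seed + 1L,
                            tight = TRUE) {
  stopifnot(inherits(config, "synthetic_config"), n_subjects >= 2L)
  set.seed(seed)
  lo <- images_per_subject[1L]
  hi <- images_per_subject[length(images_per_subject)]
  counts <- if (is.null(n_images)) {
    vapply(seq_len(n_subjects), function(i) n_images_draw(c(lo, hi)),
           integer(1))
  } else {
    if (n_images < n_subjects * lo || n_images > n_subjects * hi) {
      stop(sprintf("n_images = %d infeasible for %d subjects in [%d, %d]",
                   n_images, n_subjects, lo, hi), call. = FALSE)
    }
    ct <- rep(lo, n_subjects)
    for (extra in seq_len(n_images - n_subjects * lo)) {
      i <- sample_one(which(ct < hi))
      ct[i] <- ct[i] + 1L
    }
    ct
  }
  center <- if (is.null(attach_to)) unit(stats::rnorm(config$d))
            else unit(attach_to)
  items <- list()
  for (p in seq_len(n_subjects)) {
    subj_center <- if (tight) {
      perturb(center, config$sigma_subject, config$d)
    } else {
      perturb(unit(stats::rnorm(config$d)), config$sigma_subject, config$d)
    }
    subj_id <- sprintf("%s_P%02d", label, p)
    items <- c(items,
               subject_images(subj_center, counts[p], config, subj_id, label))
  }
  cohort(items)
}
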