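#' Rank a pool of images by distance to a test image
#'
#' The pool is sorted by ensemble-averaged cosine distance to the test
#' image, ascending; ranks are 1-based. Distance ties are broken by
#' lexicographic image id so the ordering is deterministic across
#' platforms.
#'
#' @param test An [embedding_set()]; must not itself be in the pool.
#' @param pool Non-empty list of [embedding_set()] objects (or a
#'   `gallery`).
#' @return A data.frame with columns `image_id`, `distance`, `rank`,
#'   sorted by rank.
#' @export
rank_images <- function(test, pool) {
  if (inherits(pool, "gallery") || inherits(pool, "cohort")) {
    pool <- pool$items
  }
  if (length(pool) == 0L) stop("pool is empty", call. = FALSE)
  ids <- vapply(pool, `[[`, character(1), "image_id")
  if (test$image_id %in% ids) {
    stop(sprintf("test image '%s' is present in the pool", test$image_id),
         call. = FALSE)
  }
  d <- vapply(pool, pair_distance, numeric(1), a = test)
  ord <- order(d, ids, method = "radix")
  data.frame(image_id = ids[ord], distance = d[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Leave-one-out pairwise rank matrix of a cohort against a gallery
#'
#' For each cohort image `t` (one column), the remaining cohort images
#' are inserted into the gallery and every one of them is ranked by
#' distance to `t` within that augmented pool. Low mutual ranks mean the
#' cohort members retrieve each other ahead of the reference gallery.
#' Probes from the same subject as the test image are included in the
#' pool but flagged, so summaries can exclude within-person similarity.
#'
#' @param co A [cohort()]; its image ids must be absent from the gallery.
#' @param g A [gallery()].
#' @return Object of class `rank_matrix`: `ranks` (probe x test integer
#'   matrix, `NA` diagonal), `distances` (same shape), `same_subject`
#'   (logical matrix), `gallery_size`.
#' @export
pairwise_rank_matrix <- function(co, g) {
  overlap <- intersect(names(co$items), names(g$items))
  if (length(overlap) > 0L) {
    stop(sprintf("cohort image(s) present in gallery: %s",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  }
  if (co$E != g$E || co$d != g$d) {
    stop("cohort and gallery differ in E or d", call. = FALSE)
  }
  cids <- names(co$items)
  n <- length(cids)
  ranks <- matrix(NA_integer_, n, n, dimnames = list(cids, cids))
  dists <- matrix(NA_real_, n, n, dimnames = list(cids, cids))
  subj <- subject_ids(co)
  for (t in cids) {
    pool <- c(g$items, co$items[setdiff(cids, t)])
    rk <- rank_images(co$items[[t]], pool)
    probe <- rk$image_id %in% cids
    ranks[rk$image_id[probe], t] <- rk$rank[probe]
    dists[rk$image_id[probe], t] <- rk$distance[probe]
  }
  structure(
    list(ranks = ranks, distances = dists,
         same_subject = outer(subj, subj, "==") & !diag(TRUE, n),
         gallery_size = length(g$items)),
    class = "rank_matrix"
  )
}

#' @export
print.rank_matrix <- function(x, ...) {
  off <- x$ranks[!is.na(x$ranks) & !x$same_subject]
  cat(sprintf(
    "<rank_matrix> %d cohort images vs gallery of %d; best cross-subject rank %s\n",
    nrow(x$ranks), x$gallery_size,
    if (length(off)) min(off) else NA))
  invisible(x)
}

#' Top-k syndrome matches for each cohort image
#'
#' For each cohort image, the syndrome labels of its `k` nearest gallery
#' images are tallied (cohort images never count toward the tallies).
#' Per-subject tallies sum over that subject's images; the modal syndrome
#' per subject is reported, ties broken lexicographically.
#'
#' @param co A [cohort()].
#' @param g A fully labelled [gallery()] with at least `k` images.
#' @param k Neighborhood size (default 30).
#' @return Object of class `syndrome_match_table`: `per_image` and
#'   `per_subject` long data.frames (`syndrome_label`, `count`), `modal`
#'   (one row per subject), `k`.
#' @export
top_k_matches <- function(co, g, k = 30L) {
  labs <- syndrome_labels(g)
  if (any(is.na(labs) | !nzchar(labs))) {
    stop("all gallery images must carry a syndrome label", call. = FALSE)
  }
  if (k > length(g$items)) {
    stop(sprintf("k = %d exceeds gallery size %d", k, length(g$items)),
         call. = FALSE)
  }
  per_image <- do.call(rbind, lapply(names(co$items), function(t) {
    rk <- rank_images(co$items[[t]], g$items)
    top <- rk$image_id[seq_len(k)]
    tab <- table(labs[top])
    data.frame(image_id = t,
               subject_id = co$items[[t]]$subject_id,
               syndrome_label = names(tab),
               count = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(count ~ subject_id + syndrome_label,
                          data = per_image, FUN = sum)
  agg <- agg[order(agg$subject_id, -agg$count, agg$syndrome_label), ]
  rownames(agg) <- NULL
  modal <- do.call(rbind, lapply(split(agg, agg$subject_id), function(b) {
    b[1L, c("subject_id", "syndrome_label", "count")]
  }))
  rownames(modal) <- NULL
  structure(list(per_image = per_image, per_subject = agg,
                 modal = modal, k = as.integer(k)),
            class = "syndrome_match_table")
}

#' @export
print.syndrome_match_table <- function(x, ...) {
  cat(sprintf("<syndrome_match_table> top-%d matches\n", x$k))
  for (i in seq_len(nrow(x$modal))) {
    cat(sprintf("  %s: modal syndrome %s (%d/%s hits)\n",
                x$modal$subject_id[i], x$modal$syndrome_label[i],
                x$modal$count[i],
                sum(x$per_subject$count[
                  x$per_subject$subject_id == x$modal$subject_id[i]])))
  }
  invisible(x)
}
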