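#' Construct an ensemble embedding set for one image
#'
#' An image is represented by an ensemble of `E` embedding vectors of
#' dimension `d` (one vector per model / test-time augmentation). Rows are
#' L2-normalized on construction so that cosine distance reduces to
#' `1 - dot product`.
#'
#' @param image_id Single non-empty string identifying the image.
#' @param subject_id Single non-empty string identifying the subject
#'   (individual) the image belongs to.
#' @param vectors Numeric matrix with `E >= 1` rows and `d >= 2` columns;
#'   all entries finite, no all-zero row.
#' @param syndrome_label Optional syndrome (disorder) label; `NA` if the
#'   image is unlabeled.
#' @param normalize If `TRUE` (default) rows are scaled to unit Euclidean
#'   norm. Already-unit rows are unchanged up to floating-point error.
#'
#' @return An object of class `embedding_set` with fields `image_id`,
#'   `subject_id`, `syndrome_label`, and `vectors` (E x d, unit rows).
#' @export
embedding_set <- function(image_id, subject_id, vectors,
                          syndrome_label = NA_character_,
                          normalize = TRUE) {
  stopifnot(is.character(image_id), length(image_id) == 1L, nzchar(image_id),
            is.character(subject_id), length(subject_id) == 1L,
            nzchar(subject_id))
  if (!is.matrix(vectors) || !is.numeric(vectors)) {
    stop("'vectors' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(vectors) < 1L || ncol(vectors) < 2L) {
    stop("'vectors' must have E >= 1 rows and d >= 2 columns", call. = FALSE)
  }
  if (any(!is.finite(vectors))) {
    stop(sprintf("non-finite embedding values for image '%s'", image_id),
         call. = FALSE)
  }
  if (length(syndrome_label) != 1L) {
    stop("'syndrome_label' must be a single value", call. = FALSE)
  }
  syndrome_label <- as.character(syndrome_label)
  if (normalize) {
    vectors <- normalize_rows(vectors, image_id)
  }
  structure(
    list(image_id = image_id, subject_id = subject_id,
         syndrome_label = syndrome_label, vectors = unname(vectors)),
    class = "embedding_set"
  )
}

# Scale each row of m to unit Euclidean norm; a (near-)zero row is invalid
# because its direction is undefined.
normalize_rows <- function(m, image_id = "<unknown>", tol = 1e-12) {
  nrm <- sqrt(rowSums(m * m))
  bad <- which(nrm < tol)
  if (length(bad) > 0L) {
    stop(sprintf("zero-norm embedding row(s) %s for image '%s'",
                 paste(bad, collapse = ", "), image_id), call. = FALSE)
  }
  # rows already unit to fp precision are left untouched (idempotence,
  # bit-exact round-trips)
  redo <- abs(nrm - 1) > 1e-12
  m[redo, ] <- m[redo, , drop = FALSE] / nrm[redo]
  m
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> image '%s' (subject '%s', syndrome %s): %d x %d\n",
              x$image_id, x$subject_id,
              if (is.na(x$syndrome_label)) "NA" else sQuote(x$syndrome_label),
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Assemble a labelled gallery of embedding sets
#'
#' A gallery is the reference collection that null distributions and rank
#' retrieval are computed against. All items must share the same ensemble
#' size `E` and dimension `d`, and image ids must be unique.
#'
#' @param items List of [embedding_set()] objects.
#' @return Object of class `gallery` with fields `items` (named by
#'   image_id), `E`, `d`.
#' @export
gallery <- function(items) {
  if (!is.list(items) || length(items) == 0L) {
    stop("'items' must be a non-empty list of embedding_set objects",
         call. = FALSE)
  }
  ok <- vapply(items, inherits, logical(1), "embedding_set")
  if (!all(ok)) stop("all items must be embedding_set objects", call. = FALSE)
  ids <- vapply(items, `[[`, character(1), "image_id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate image_id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  Es <- vapply(items, function(x) nrow(x$vectors), integer(1))
  ds <- vapply(items, function(x) ncol(x$vectors), integer(1))
  if (length(unique(Es)) != 1L || length(unique(ds)) != 1L) {
    stop("all items must share the same ensemble size E and dimension d",
         call. = FALSE)
  }
  names(items) <- ids
  structure(list(items = items, E = Es[1L], d = ds[1L]), class = "gallery")
}

#' @export
print.gallery <- function(x, ...) {
  labs <- syndrome_labels(x)
  cat(sprintf("<gallery> %d images, %d subjects, %d syndromes (E = %d, d = %d)\n",
              length(x$items), length(unique(subject_ids(x))),
              length(unique(labs[!is.na(labs)])), x$E, x$d))
  invisible(x)
}

#' @rdname gallery_accessors
#' @export
image_ids <- function(x) vapply(x$items, `[[`, character(1), "image_id")

#' Gallery / cohort accessors
#'
#' `image_ids()`, `subject_ids()` and `syndrome_labels()` return per-item
#' identifier vectors (in item order, named by image id).
#' `subject_index()` maps subject_id to the image ids of that subject;
#' `syndrome_index()` maps syndrome_label to the subject ids carrying it
#' (unlabeled items are omitted).
#'
#' @param x A `gallery` or `cohort`.
#' @name gallery_accessors
#' @export
subject_ids <- function(x) vapply(x$items, `[[`, character(1), "subject_id")

#' @rdname gallery_accessors
#' @export
syndrome_labels <- function(x) {
  vapply(x$items, `[[`, character(1), "syndrome_label")
}

#' @rdname gallery_accessors
#' @export
subject_index <- function(x) {
  split(unname(image_ids(x)), subject_ids(x))
}

#' @rdname gallery_accessors
#' @export
syndrome_index <- function(x) {
  labs <- syndrome_labels(x)
  subj <- subject_ids(x)
  keep <- !is.na(labs)
  lapply(split(subj[keep], labs[keep]), unique)
}

#' Cosine distance between two unit vectors
#'
#' `1 - <u, v>` for unit-norm `u`, `v`: 0 for identical directions, 1 for
#' orthogonal, 2 for antiparallel.
#'
#' @param u,v Numeric unit-norm vectors of equal length.
#' @return A scalar in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop("dimension mismatch between u and v", call. = FALSE)
  }
  clamp01_2(1 - sum(u * v))
}

# guard tiny floating-point excursions outside the theoretical range
clamp01_2 <- function(x) pmin(pmax(x, 0), 2)

#' Ensemble-averaged cosine distance between two images
#'
#' The distance between two images is the mean cosine distance across their
#' ensemble members. By default member `k` of one image is compared with
#' member `k` of the other (models/augmentations are index-aligned, one
#' distance per model); `mode = "all_pairs"` instead averages over all
#' `E^2` member pairs.
#'
#' @param a,b [embedding_set()] objects sharing `E` and `d`.
#' @param mode `"aligned"` (default) or `"all_pairs"`.
#' @return A scalar in `[0, 2]`.
#' @export
pair_distance <- function(a, b, mode = c("aligned", "all_pairs")) {
  mode <- match.arg(mode)
  if (nrow(a$vectors) != nrow(b$vectors) ||
      ncol(a$vectors) != ncol(b$vectors)) {
    stop("embedding sets differ in E or d", call. = FALSE)
  }
  if (mode == "aligned") {
    clamp01_2(mean(1 - rowSums(a$vectors * b$vectors)))
  } else {
    clamp01_2(mean(1 - tcrossprod(a$vectors, b$vectors)))
  }
}

# n x (E*d) matrix of row-major flattened ensembles, rownames = image ids.
# With unit rows, aligned pair distance is 1 - flat(A).flat(B) / E, so a
# full distance matrix is one crossproduct.
flatten_items <- function(items) {
  out <- t(vapply(items, function(x) as.vector(t(x$vectors)),
                  numeric(nrow(items[[1L]]$vectors) *
                            ncol(items[[1L]]$vectors))))
  rownames(out) <- vapply(items, `[[`, character(1), "image_id")
  out
}

#' Pairwise ensemble distance matrix
#'
#' @param items List of [embedding_set()] objects (at least 2) sharing
#'   `E` and `d`, or a `gallery` / `cohort`.
#' @inheritParams pair_distance
#' @return Symmetric matrix of ensemble-averaged cosine distances with a
#'   zero diagonal (for the default aligned mode), dimnames = image ids.
#' @export
distance_matrix <- function(items, mode = c("aligned", "all_pairs")) {
  mode <- match.arg(mode)
  if (inherits(items, "gallery") || inherits(items, "cohort")) {
    items <- items$items
  }
  if (length(items) < 2L) {
    stop("need at least 2 items for a distance matrix", call. = FALSE)
  }
  Es <- vapply(items, function(x) nrow(x$vectors), integer(1))
  ds <- vapply(items, function(x) ncol(x$vectors), integer(1))
  if (length(unique(Es)) != 1L || length(unique(ds)) != 1L) {
    stop("items differ in E or d", call. = FALSE)
  }
  if (mode == "aligned") {
    f <- flatten_items(items)
    D <- 1 - tcrossprod(f) / Es[1L]
    diag(D) <- 0
  } else {
    m <- t(vapply(items, function(x) colMeans(x$vectors), numeric(ds[1L])))
    rownames(m) <- vapply(items, `[[`, character(1), "image_id")
    D <- 1 - tcrossprod(m)
  }
  clamp01_2((D + t(D)) / 2)
}

#' Read a gallery of ensemble embeddings from disk
#'
#' Two plain-text dialects are supported. `"wide"` is a single
#' tab-separated table with columns `image_id`, `subject_id`,
#' `syndrome_label`, `E`, `d`, then `v1..v(E*d)` holding the ensemble
#' row-major (member 1 first). `"split"` is a pair of files
#' `<path>.meta.tsv` (`image_id`, `subject_id`, `syndrome_label`, `E`, `d`)
#' and `<path>.vectors.tsv` (`image_id`, `member`, `v1..vd`). Both dialects
#' round-trip bit-exactly through [write_gallery()].
#'
#' @param path File path (wide) or file prefix (split).
#' @param format `"wide"` or `"split"`.
#' @param normalize Normalize rows on load (default `TRUE`).
#' @return A [gallery()].
#' @export
load_embeddings <- function(path, format = c("wide", "split"),
                            normalize = TRUE) {
  format <- match.arg(format)
  if (format == "wide") {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                                 call. = FALSE)
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE, na.strings = "NA")
    need <- c("image_id", "subject_id", "syndrome_label", "E", "d")
    if (!all(need %in% names(tab))) {
      stop("wide embedding table must have columns image_id, subject_id, ",
           "syndrome_label, E, d, v1..v(E*d)", call. = FALSE)
    }
    if (length(unique(tab$E)) != 1L || length(unique(tab$d)) != 1L) {
      stop("mismatched E/d across images", call. = FALSE)
    }
    E <- as.integer(tab$E[1L]); d <- as.integer(tab$d[1L])
    vcols <- paste0("v", seq_len(E * d))
    if (!all(vcols %in% names(tab))) {
      stop(sprintf("expected %d vector columns v1..v%d", E * d, E * d),
           call. = FALSE)
    }
    items <- lapply(seq_len(nrow(tab)), function(i) {
      vec <- as.numeric(unlist(tab[i, vcols], use.names = FALSE))
      embedding_set(tab$image_id[i], tab$subject_id[i],
                    matrix(vec, nrow = E, ncol = d, byrow = TRUE),
                    syndrome_label = tab$syndrome_label[i],
                    normalize = normalize)
    })
  } else {
    meta_path <- paste0(path, ".meta.tsv")
    vec_path <- paste0(path, ".vectors.tsv")
    for (p in c(meta_path, vec_path)) {
      if (!file.exists(p)) stop(sprintf("file not found: %s", p),
                                call. = FALSE)
    }
    meta <- utils::read.delim(meta_path, sep = "\t",
                              stringsAsFactors = FALSE, na.strings = "NA")
    vecs <- utils::read.delim(vec_path, sep = "\t",
                              stringsAsFactors = FALSE)
    if (length(unique(meta$E)) != 1L || length(unique(meta$d)) != 1L) {
      stop("mismatched E/d across images", call. = FALSE)
    }
    E <- as.integer(meta$E[1L]); d <- as.integer(meta$d[1L])
    vcols <- paste0("v", seq_len(d))
    items <- lapply(seq_len(nrow(meta)), function(i) {
      id <- meta$image_id[i]
      block <- vecs[vecs$image_id == id, , drop = FALSE]
      if (nrow(block) != E) {
        stop(sprintf("image '%s' has %d vector rows, expected E = %d",
                     id, nrow(block), E), call. = FALSE)
      }
      block <- block[order(block$member), , drop = FALSE]
      embedding_set(id, meta$subject_id[i],
                    as.matrix(block[, vcols, drop = FALSE]),
                    syndrome_label = meta$syndrome_label[i],
                    normalize = normalize)
    })
  }
  gallery(items)
}

#' Write a gallery to disk
#'
#' @param x A `gallery` or `cohort`.
#' @inheritParams load_embeddings
#' @return `path`, invisibly.
#' @seealso [load_embeddings()] for the dialects.
#' @export
write_gallery <- function(x, path, format = c("wide", "split")) {
  format <- match.arg(format)
  items <- x$items
  ids <- vapply(items, `[[`, character(1), "image_id")
  meta <- data.frame(
    image_id = ids,
    subject_id = vapply(items, `[[`, character(1), "subject_id"),
    syndrome_label = vapply(items, `[[`, character(1), "syndrome_label"),
    E = nrow(items[[1L]]$vectors), d = ncol(items[[1L]]$vectors),
    stringsAsFactors = FALSE
  )
  fmt17 <- function(m) {
    s <- sprintf("%.17g", m)
    dim(s) <- dim(m)
    s
  }
  if (format == "wide") {
    flat <- flatten_items(items)
    num <- as.data.frame(fmt17(flat), stringsAsFactors = FALSE)
    names(num) <- paste0("v", seq_len(ncol(flat)))
    utils::write.table(cbind(meta, num), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    d <- ncol(items[[1L]]$vectors)
    rows <- do.call(rbind, lapply(items, function(it) {
      v <- fmt17(it$vectors)
      data.frame(image_id = it$image_id,
                 member = seq_len(nrow(it$vectors)),
                 v, stringsAsFactors = FALSE)
    }))
    names(rows) <- c("image_id", "member", paste0("v", seq_len(d)))
    utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(rows, paste0(path, ".vectors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Drop images from a gallery by id
#'
#' Used to keep a test cohort disjoint from the reference gallery before
#' null distributions are built.
#'
#' @param x A `gallery`.
#' @param ids Character vector of image ids to remove.
#' @return A `gallery` without those images.
#' @export
exclude_images <- function(x, ids) {
  keep <- !(image_ids(x) %in% ids)
  if (!any(keep)) stop("excluding all images leaves an empty gallery",
                       call. = FALSE)
  gallery(x$items[keep])
}
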