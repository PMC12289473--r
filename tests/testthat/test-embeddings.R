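test_that("cosine distance has the right fixed points and rejects mismatches", {
  u <- c(1, 0, 0)
  expect_equal(cosine_distance(u, u), 0)
  expect_equal(cosine_distance(u, c(0, 1, 0)), 1)
  expect_equal(cosine_distance(u, -u), 2)
  expect_error(cosine_distance(u, c(1, 0)), "dimension mismatch")
})

test_that("embedding_set validates and normalizes", {
  m <- matrix(c(3, 0, 0, 0, 4, 0), 2, 3, byrow = TRUE)
  es <- embedding_set("a", "sA", m)
  expect_equal(sqrt(rowSums(es$vectors^2)), c(1, 1))
  expect_error(embedding_set("a", "sA", matrix(0, 2, 3)), "zero-norm")
  expect_error(embedding_set("a", "sA", matrix(c(1, Inf, 0, 1, 0, 0), 2, 3)),
               "non-finite")
  expect_error(embedding_set("a", "sA", matrix(1, 2, 1)), "d >= 2")
})

test_that("normalization is idempotent on already-unit rows", {
  set.seed(7)
  m <- matrix(rnorm(4 * 6), 4, 6)
  once <- embedding_set("a", "sA", m)$vectors
  twice <- embedding_set("a", "sA", once)$vectors
  expect_lt(max(abs(once - twice)), 1e-12)
})

test_that("pair_distance matches member-wise oracle and is symmetric/bounded", {
  set.seed(42)
  # E = 1 reduces to the single-member cosine distance
  a1 <- rand_es("a", E = 1L, d = 5L)
  b1 <- rand_es("b", E = 1L, d = 5L)
  expect_equal(pair_distance(a1, b1),
               cosine_distance(a1$vectors[1, ], b1$vectors[1, ]))

  # full-size ensemble against an explicit loop over members
  a <- rand_es("a", E = 12L, d = 512L)
  b <- rand_es("b", E = 12L, d = 512L)
  manual <- mean(vapply(1:12, function(k) {
    1 - sum(a$vectors[k, ] * b$vectors[k, ])
  }, numeric(1)))
  expect_equal(pair_distance(a, b), manual, tolerance = 1e-12)
  expect_equal(pair_distance(a, b), pair_distance(b, a))
  expect_equal(pair_distance(a, a), 0)

  # all-pairs mode against an explicit E x E loop
  manual_ap <- mean(outer(1:12, 1:12, Vectorize(function(i, j) {
    1 - sum(a$vectors[i, ] * b$vectors[j, ])
  })))
  expect_equal(pair_distance(a, b, mode = "all_pairs"), manual_ap,
               tolerance = 1e-12)

  for (i in 1:20) {
    x <- rand_es("x", E = 3L, d = 4L)
    y <- rand_es("y", E = 3L, d = 4L)
    dxy <- pair_distance(x, y)
    expect_gte(dxy, 0); expect_lte(dxy, 2)
    expect_identical(dxy, pair_distance(y, x))
  }
  expect_error(pair_distance(a1, a), "differ in E or d")
})

test_that("distance_matrix equals elementwise pair_distance and is equivariant", {
  set.seed(11)
  items <- lapply(letters[1:6], rand_es, E = 2L, d = 7L)
  D <- distance_matrix(items)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(D[i, j], pair_distance(items[[i]], items[[j]]),
                 tolerance = 1e-12)
  }
  expect_equal(diag(D), rep(0, 6), ignore_attr = TRUE)
  expect_equal(D, t(D))

  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(unname(distance_matrix(items[perm])), unname(D[perm, perm]),
               tolerance = 1e-12)

  two <- list(items[[1]], items[[1]])
  two[[2]]$image_id <- "copy"
  expect_equal(unname(distance_matrix(two)), matrix(0, 2, 2))
  expect_error(distance_matrix(items[1]), "at least 2")
})

test_that("gallery enforces unique ids and shared dimensions", {
  a <- rand_es("a"); b <- rand_es("b")
  expect_s3_class(gallery(list(a, b)), "gallery")
  expect_error(gallery(list(a, a)), "duplicate image_id")
  expect_error(gallery(list(a, rand_es("c", E = 4L))), "same ensemble size")
})

test_that("galleries round-trip bit-exactly through both storage dialects", {
  set.seed(3)
  g <- tiny_gallery(n_syn = 2L, n_subj = 2L, n_img = 2L, E = 2L, d = 4L)
  for (fmt in c("wide", "split")) {
    path <- file.path(withr::local_tempdir(), "gal")
    if (fmt == "wide") path <- paste0(path, ".tsv")
    write_gallery(g, path, format = fmt)
    g2 <- load_embeddings(path, format = fmt)
    expect_identical(image_ids(g2), image_ids(g))
    expect_identical(syndrome_labels(g2), syndrome_labels(g))
    for (id in names(g$items)) {
      expect_identical(g2$items[[id]]$vectors, g$items[[id]]$vectors)
    }
    expect_identical(c(g2$E, g2$d), c(g$E, g$d))
  }
})

test_that("loader rejects malformed archives", {
  g <- tiny_gallery()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "gal.tsv")
  write_gallery(g, path, format = "wide")

  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  tab$E[2] <- "5"
  bad <- file.path(dir, "bad_e.tsv")
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_embeddings(bad), "mismatched E/d")

  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  tab[2, grep("^v", names(tab))] <- "0"
  bad <- file.path(dir, "bad_zero.tsv")
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_embeddings(bad), tab$image_id[2])

  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  tab$image_id[2] <- tab$image_id[1]
  bad <- file.path(dir, "bad_dup.tsv")
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_embeddings(bad), "duplicate image_id")

  expect_error(load_embeddings(file.path(dir, "nope.tsv")), "not found")
})
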