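test_that("rank_images sorts by distance with deterministic tie-breaks", {
  set.seed(51)
  test <- rand_es("probe", E = 2L, d = 6L)
  pool <- lapply(sprintf("p%02d", 1:5), rand_es, E = 2L, d = 6L)

  rk <- rank_images(test, pool)
  # independent full sort of pairwise distances
  d <- vapply(pool, function(x) pair_distance(test, x), numeric(1))
  ids <- vapply(pool, `[[`, character(1), "image_id")
  expect_identical(rk$image_id, ids[order(d, ids)])
  expect_identical(rk$rank, 1:5)
  expect_equal(rk$distance, sort(d))

  # permuting the pool changes nothing
  rk2 <- rank_images(test, pool[c(4, 2, 5, 1, 3)])
  expect_identical(rk, rk2)

  # an exact copy ranks first at distance zero
  copy <- test; copy$image_id <- "copy"
  rk3 <- rank_images(test, c(pool, list(copy)))
  expect_identical(rk3$image_id[1], "copy")
  expect_equal(rk3$distance[1], 0)

  # equidistant items (copies of each other) order lexicographically
  twin_a <- pool[[1]]; twin_a$image_id <- "zz_b"
  twin_b <- pool[[1]]; twin_b$image_id <- "zz_a"
  rk4 <- rank_images(test, list(twin_a, twin_b))
  expect_identical(rk4$image_id, c("zz_a", "zz_b"))

  expect_error(rank_images(test, c(pool, list(test))), "present in the pool")
})

test_that("inserting a strictly farther item leaves existing ranks unchanged", {
  set.seed(52)
  test <- rand_es("probe", E = 2L, d = 6L)
  pool <- lapply(sprintf("p%02d", 1:6), rand_es, E = 2L, d = 6L)
  rk <- rank_images(test, pool)
  far <- embedding_set("far", "far", -test$vectors)  # antipodal, distance 2
  rk_aug <- rank_images(test, c(pool, list(far)))
  expect_identical(rk_aug$image_id[7], "far")
  expect_identical(rk_aug[1:6, ], rk)
})

test_that("leave-one-out rank matrix mirrors per-image pools", {
  set.seed(53)
  g <- tiny_gallery(n_syn = 4L, n_subj = 2L, n_img = 2L, E = 2L, d = 8L)
  items <- list(rand_es("c1_1", subject = "c1", E = 2L, d = 8L),
                rand_es("c1_2", subject = "c1", E = 2L, d = 8L),
                rand_es("c2_1", subject = "c2", E = 2L, d = 8L))
  co <- cohort(items)
  rkm <- pairwise_rank_matrix(co, g)
  expect_equal(dim(rkm$ranks), c(3L, 3L))
  expect_true(all(is.na(diag(rkm$ranks))))
  expect_equal(rkm$gallery_size, length(g$items))
  # recompute one column independently
  rk <- rank_images(co$items[["c1_1"]],
                    c(g$items, co$items[c("c1_2", "c2_1")]))
  expect_equal(rkm$ranks["c1_2", "c1_1"],
               rk$rank[rk$image_id == "c1_2"])
  expect_equal(rkm$ranks["c2_1", "c1_1"],
               rk$rank[rk$image_id == "c2_1"])
  expect_true(all(rkm$ranks >= 1, na.rm = TRUE))
  expect_true(all(rkm$ranks <= length(g$items) + 2, na.rm = TRUE))
  # same-subject probes are flagged
  expect_true(rkm$same_subject["c1_2", "c1_1"])
  expect_false(rkm$same_subject["c2_1", "c1_1"])

  # rank asymmetry is permitted (no constraint tying the two directions)
  expect_false(is.na(rkm$ranks["c1_2", "c1_1"]))
  expect_false(is.na(rkm$ranks["c1_1", "c1_2"]))

  # a cohort image duplicated in the gallery is rejected
  g_bad <- gallery(c(g$items, co$items["c1_1"]))
  expect_error(pairwise_rank_matrix(co, g_bad), "present in gallery")
})

test_that("planted near-duplicates retrieve each other at rank 1", {
  cfg <- synthetic_config(n_syndromes = 50L, subjects_per_syndrome = 3L,
                          images_per_subject = 2L, d = 32L, E = 2L,
                          sigma_subject = 0.3, sigma_image = 0.15,
                          sigma_ensemble = 0.02, seed = 54L)
  g <- generate_gallery(cfg)
  set.seed(55)
  base <- matrix(rnorm(2 * 32), 2, 32)
  near1 <- embedding_set("dupA", "cdup1", base + 1e-4 * rnorm(64))
  near2 <- embedding_set("dupB", "cdup2", base + 1e-4 * rnorm(64))
  co <- cohort(list(near1, near2))
  rkm <- pairwise_rank_matrix(co, g)
  expect_equal(rkm$ranks["dupA", "dupB"], 1L)
  expect_equal(rkm$ranks["dupB", "dupA"], 1L)
})

test_that("top-k tallies count gallery syndromes only and sum to k", {
  set.seed(56)
  g <- tiny_gallery(n_syn = 3L, n_subj = 2L, n_img = 2L, E = 2L, d = 8L)
  co <- cohort(list(rand_es("c1", subject = "s1", E = 2L, d = 8L),
                    rand_es("c2", subject = "s2", E = 2L, d = 8L)))
  k <- 5L
  tk <- top_k_matches(co, g, k = k)
  sums <- tapply(tk$per_image$count, tk$per_image$image_id, sum)
  expect_true(all(sums == k))
  expect_false(any(tk$per_image$syndrome_label %in% names(co$items)))

  # k = gallery size reproduces the gallery label histogram
  tk_all <- top_k_matches(co, g, k = length(g$items))
  hist_g <- table(syndrome_labels(g))
  for (img in unique(tk_all$per_image$image_id)) {
    sub <- tk_all$per_image[tk_all$per_image$image_id == img, ]
    expect_equal(sub$count[order(sub$syndrome_label)],
                 as.integer(hist_g[sort(names(hist_g))]))
  }

  # single-syndrome gallery: every tally is {that syndrome: k}
  g1 <- tiny_gallery(n_syn = 1L, n_subj = 3L, n_img = 3L, E = 2L, d = 8L)
  tk1 <- top_k_matches(co, g1, k = 4L)
  expect_true(all(tk1$per_image$syndrome_label == "SYN1"))
  expect_true(all(tk1$per_image$count == 4L))

  # unlabeled gallery images are rejected
  g_un <- gallery(list(rand_es("u1", subject = "u1"),
                       rand_es("u2", subject = "u2")))
  expect_error(top_k_matches(co, g_un, k = 1L), "syndrome label")
  expect_error(top_k_matches(co, g, k = 100L), "exceeds gallery size")
})

test_that("a cohort attached to a gallery syndrome recovers it as modal match", {
  cfg <- synthetic_config(n_syndromes = 20L, subjects_per_syndrome = 3L,
                          images_per_subject = 2L, d = 32L, E = 2L,
                          sigma_subject = 0.2, sigma_image = 0.1,
                          sigma_ensemble = 0.05, seed = 57L)
  g <- generate_gallery(cfg)
  ctr <- syndrome_centers(g)["S007", ]
  co <- generate_cohort(cfg, n_subjects = 3L, images_per_subject = c(1L, 2L),
                        attach_to = ctr, seed = 58L)
  tk <- top_k_matches(co, g, k = 10L)
  total <- tapply(tk$per_subject$count, tk$per_subject$syndrome_label, sum)
  expect_equal(names(which.max(total)), "S007")
})
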