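# shared fixture builders for the test suite

# random unit-row embedding set
rand_es <- function(id, subject = id, E = 3L, d = 8L,
                    syndrome = NA_character_) {
  embedding_set(id, subject, matrix(rnorm(E * d), E, d),
                syndrome_label = syndrome)
}

# small labelled gallery: n_syn syndromes x n_subj subjects x n_img images,
# built directly (not via the simulator) so generator tests stay independent
tiny_gallery <- function(n_syn = 2L, n_subj = 2L, n_img = 1L,
                         E = 2L, d = 6L) {
  items <- list()
  for (s in seq_len(n_syn)) {
    for (p in seq_len(n_subj)) {
      for (i in seq_len(n_img)) {
        id <- sprintf("G%d_%d_%d", s, p, i)
        items <- c(items, list(
          rand_es(id, subject = sprintf("G%d_%d", s, p), E = E, d = d,
                  syndrome = sprintf("SYN%d", s))))
      }
    }
  }
  gallery(items)
}

# embedding sets with prescribed pairwise aligned distances: single-member
# (E = 1) vectors realized from a Gram matrix via eigendecomposition
es_with_distances <- function(D) {
  G <- 1 - D       # inner products implied by cosine distances
  e <- eigen(G, symmetric = TRUE)
  if (any(e$values < -1e-8)) stop("distance pattern not realizable")
  V <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  lapply(seq_len(nrow(D)), function(i) {
    embedding_set(sprintf("X%d", i), sprintf("X%d", i),
                  matrix(V[i, ], 1L, ncol(V)))
  })
}

# independent brute-force ROC oracle: enumerate candidate cutoffs and
# pairwise comparisons directly (kept free of the package's ROC code)
brute_roc <- function(same, random) {
  pooled <- sort(unique(c(same, random)))
  cands <- c(pooled[1] - 1,
             if (length(pooled) > 1)
               (pooled[-length(pooled)] + pooled[-1]) / 2,
             pooled[length(pooled)] + 1)
  best <- NULL
  for (ct in cands) {
    sens <- sum(same <= ct) / length(same)
    spec <- sum(random > ct) / length(random)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(c = ct, sens = sens, spec = spec, j = j)
    }
  }
  auc <- 0
  for (s in same) for (r in random) {
    auc <- auc + (s < r) + 0.5 * (s == r)
  }
  best$auc <- auc / (length(same) * length(random))
  best
}
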