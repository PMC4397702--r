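# Build separable synthetic profile matrices: n anchors per pattern,
# patterns given as lists of per-track bump positions/amplitudes.
toy_profiles <- function(patterns, n_per = 10, nbins = 20, noise = 0,
                         seed = 1) {
  withr::with_seed(seed, {
    tracks <- unique(unlist(lapply(patterns, names)))
    rows_per_track <- lapply(tracks, function(tr) {
      do.call(rbind, lapply(seq_along(patterns), function(pi) {
        base <- rep(0.5, nbins)
        spec <- patterns[[pi]][[tr]]
        if (!is.null(spec)) {
          base <- base + spec$amp *
            exp(-(seq_len(nbins) - spec$pos)^2 / (2 * 2^2))
        }
        m <- matrix(rep(base, n_per), nrow = n_per, byrow = TRUE)
        if (noise > 0) m <- m + matrix(abs(rnorm(length(m), 0, noise)),
                                       nrow = n_per)
        m
      }))
    })
    names(rows_per_track) <- tracks
    lapply(rows_per_track, make_pm)
  })
}

test_that("noise-free planted archetypes are recovered perfectly", {
  pats <- list(
    list(A = list(pos = 10, amp = 5)),
    list(B = list(pos = 10, amp = 5)),
    list(A = list(pos = 5, amp = 5), B = list(pos = 5, amp = 5)),
    list(A = list(pos = 15, amp = 5)))
  mats <- toy_profiles(pats, n_per = 8, noise = 0.01)
  res <- kmeans_profiles(mats, K = 4, seed = 1, nstart = 5)
  truth <- rep(seq_along(pats), each = 8)
  expect_equal(mclust::adjustedRandIndex(res$labels, truth), 1)

  # K = 1: everything in one group
  res1 <- kmeans_profiles(mats, K = 1, seed = 1, nstart = 1)
  expect_true(all(res1$labels == 1L))
})

test_that("K-means attains the exhaustive-enumeration optimum for K = 2", {
  # two separable shape classes; at this noise the global partition
  # optimum is also a Lloyd fixed point, so restarted K-means must hit it
  withr::with_seed(11, {
    X <- rbind(matrix(rnorm(4 * 12, 0, 0.3) + rep(sin(1:12), each = 4),
                      nrow = 4),
               matrix(rnorm(4 * 12, 0, 0.3) + rep(cos(1:12), each = 4),
                      nrow = 4))
  })
  obj <- function(labels) {
    sum(vapply(1:2, function(k) {
      rows <- X[labels == k, , drop = FALSE]
      cen <- colMeans(rows)
      d <- 1 - abs(suppressWarnings(cor(t(rows), cen)))
      d[is.na(d)] <- 1
      sum(d)
    }, numeric(1)))
  }
  # enumerate all 2-partitions (anchor 1 fixed in group 1)
  best <- Inf
  for (code in 0:(2^7 - 1)) {
    labels <- c(1L, as.integer(intToBits(code))[1:7] + 1L)
    if (length(unique(labels)) < 2) next
    best <- min(best, obj(labels))
  }
  mats <- list(t1 = make_pm(X))
  for (s in 1:20) {
    res <- kmeans_profiles(mats, K = 2, seed = s, nstart = 5)
    expect_lte(res$objective, best + 1e-9)
  }
})

test_that("asymmetry score is bounded, antisymmetric and exact on examples", {
  expect_equal(asymmetry_score(c(1, 2, 1)), 0)
  expect_equal(asymmetry_score(c(0, 0, 1, 1)), 1)
  expect_equal(asymmetry_score(c(0, 1, 3)), 1)
  expect_equal(asymmetry_score(c(3, 1, 0)), -1)
  expect_equal(asymmetry_score(rep(0, 6)), 0)
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- abs(rnorm(sample(4:41, 1)))
      a <- asymmetry_score(p)
      expect_lte(abs(a), 1)
      expect_equal(asymmetry_score(rev(p)), -a, tolerance = 1e-12)
    }
  })
})

test_that("mirror pairing pairs exact reversals and never self-pairs", {
  nbins <- 20
  bump <- function(pos) 0.2 + 5 * exp(-(seq_len(nbins) - pos)^2 / 8)
  pats <- list(
    list(A = list(pos = 6, amp = 5)),                      # left form
    list(A = list(pos = nbins - 5, amp = 5)),              # mirror of 1
    list(B = list(pos = (nbins + 1) / 2, amp = 5)),        # symmetric
    list(A = list(pos = (nbins + 1) / 2, amp = 5),
         B = list(pos = (nbins + 1) / 2, amp = 3)))        # symmetric
  mats <- toy_profiles(pats, n_per = 6, noise = 0.02)
  res <- kmeans_profiles(mats, K = 4, seed = 2, nstart = 5)
  res <- mirror_pair(res)
  expect_identical(nrow(res$mirror_pairs), 1L)
  expect_gt(res$mirror_pairs$score, 0.95)
  # the paired groups hold the two mirrored patterns
  truth <- rep(seq_along(pats), each = 6)
  paired_groups <- c(res$mirror_pairs$group_a, res$mirror_pairs$group_b)
  paired_truth <- sort(unique(truth[res$labels %in% paired_groups]))
  expect_identical(paired_truth, c(1L, 2L))
  # merged count = K - pairs
  expect_identical(length(unique(res$merged)), 3L)
})

test_that("orientation flips with profile reversal and follows mirror pairs", {
  nbins <- 20
  pats <- list(
    list("H3.3" = list(pos = 6, amp = 5)),
    list("H3.3" = list(pos = nbins - 5, amp = 5)),
    list("H2A.Z" = list(pos = (nbins + 1) / 2, amp = 5),
         "H3.3" = list(pos = (nbins + 1) / 2, amp = 5)))
  mats <- toy_profiles(pats, n_per = 6, noise = 0.02)
  res <- kmeans_profiles(mats, K = 3, seed = 4, nstart = 5)
  res <- mirror_pair(res)
  res <- classify_and_orient(res)
  truth <- rep(seq_along(pats), each = 6)
  expect_true(all(res$orientation[truth == 1] == "left"))
  expect_true(all(res$orientation[truth == 2] == "right"))
  expect_true(all(res$orientation[truth == 3] == "none"))
  # mirror partners carry opposite orientations with equal |A|
  gc <- res$group_class
  pa <- gc[gc$group == res$mirror_pairs$group_a, ]
  pb <- gc[gc$group == res$mirror_pairs$group_b, ]
  expect_true(pa$orientation != pb$orientation)
  expect_equal(abs(pa$A), abs(pb$A), tolerance = 0.05)

  # reversing every profile row negates A scores and flips orientations
  rev_mats <- lapply(mats, function(m) {
    m$values <- m$values[, rev(seq_len(ncol(m$values)))]
    m
  })
  res_r <- kmeans_profiles(rev_mats, K = 3, seed = 4, nstart = 5)
  res_r <- classify_and_orient(mirror_pair(res_r))
  ar <- asymmetry_report(res)$by_anchor
  ar_r <- asymmetry_report(res_r)$by_anchor
  expect_equal(ar_r, -ar, tolerance = 1e-12)
  flip <- c(left = "right", right = "left", none = "none")
  expect_identical(unname(flip[res$orientation]),
                   unname(res_r$orientation))
})

test_that("zero-variance rows are flagged and assigned by fallback", {
  pats <- list(list(A = list(pos = 5, amp = 5)),
               list(A = list(pos = 15, amp = 5)))
  mats <- toy_profiles(pats, n_per = 6, noise = 0.02)
  mats$A$values[1, ] <- 3  # constant row
  expect_message(res <- kmeans_profiles(mats, K = 2, seed = 1),
                 "zero-variance")
  expect_true(res$zero_variance[1])
  expect_true(res$labels[1] %in% 1:2)
})

test_that("cluster labels are permutation-equivalent across seeds", {
  pats <- list(list(A = list(pos = 5, amp = 5)),
               list(A = list(pos = 15, amp = 5)),
               list(B = list(pos = 10, amp = 5)))
  mats <- toy_profiles(pats, n_per = 7, noise = 0.02)
  r1 <- kmeans_profiles(mats, K = 3, seed = 1, nstart = 5)
  r2 <- kmeans_profiles(mats, K = 3, seed = 99, nstart = 5)
  expect_equal(mclust::adjustedRandIndex(r1$labels, r2$labels), 1)
})
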