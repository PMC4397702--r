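# Concatenate per-track profile matrices (same anchors, same bin grid)
# into one anchors x (tracks * bins) matrix.
.stack_profiles <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1,
            !is.null(names(matrices)))
  ref <- matrices[[1]]
  for (m in matrices) {
    stopifnot(inherits(m, "profile_matrix"))
    if (nrow(m$values) != nrow(ref$values) ||
        !identical(rownames(m$values), rownames(ref$values))) {
      stop("all profile matrices must cover the same anchors",
           call. = FALSE)
    }
    if (ncol(m$values) != ncol(ref$values)) {
      stop("all profile matrices must share the bin grid", call. = FALSE)
    }
  }
  X <- do.call(cbind, lapply(matrices, `[[`, "values"))
  list(X = X, tracks = names(matrices), nbins = ncol(ref$values),
       anchors = ref$anchors)
}

# 1 - |cor| (or 1 - cor) distances between rows of X and rows of C.
.cor_dist <- function(X, C, metric) {
  r <- suppressWarnings(cor(t(X), t(C)))
  r[is.na(r)] <- 0                      # zero-variance rows/centroids
  if (metric == "abs_pearson") 1 - abs(r) else 1 - r
}

.kmeanspp_init <- function(X, K, metric) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  d <- .cor_dist(X, X[centers[1], , drop = FALSE], metric)[, 1]
  if (K > 1) for (k in 2:K) {
    w <- d^2
    if (sum(w) <= 0) w <- rep(1, n)
    centers[k] <- sample.int(n, 1, prob = w)
    d <- pmin(d, .cor_dist(X, X[centers[k], , drop = FALSE], metric)[, 1])
  }
  X[centers, , drop = FALSE]
}

.kmeans_once <- function(X, K, metric, max_iter) {
  C <- .kmeanspp_init(X, K, metric)
  labels <- rep(0L, nrow(X))
  for (it in seq_len(max_iter)) {
    D <- .cor_dist(X, C, metric)
    new_labels <- max.col(-D, ties.method = "first")
    # re-seed empty clusters from the point farthest from its centroid
    for (k in which(tabulate(new_labels, K) == 0)) {
      far <- which.max(D[cbind(seq_len(nrow(X)), new_labels)])
      C[k, ] <- X[far, ]
      new_labels[far] <- k
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (k in seq_len(K)) {
      C[k, ] <- colMeans(X[labels == k, , drop = FALSE])
    }
  }
  D <- .cor_dist(X, C, metric)
  list(labels = labels, centroids = C,
       objective = sum(D[cbind(seq_len(nrow(X)), labels)]))
}

#' K-means clustering of multi-variant anchor profiles
#'
#' Each anchor is represented by the concatenation of its per-track
#' profiles (typically the four histone variants H3.1, H3.3, macroH2A,
#' H2A.Z). Distance between two profiles is \code{1 - |r|} with r the
#' Pearson correlation of the concatenated vectors (plain \code{1 - r}
#' via \code{metric = "pearson"}). Centroids are member means; iteration
#' runs to label convergence or \code{max_iter}; empty clusters are
#' re-seeded from the point farthest from its assigned centroid. Seeded
#' kmeans++ initialization with \code{nstart} restarts, keeping the run
#' with the smallest total within-cluster distance; the result is
#' deterministic given \code{seed}. Zero-variance rows (correlation
#' undefined) are assigned afterwards to the Euclidean-nearest centroid
#' and flagged.
#'
#' @param matrices named list of \code{\link{profile_matrix}} objects over
#'   the same anchors (one per track).
#' @param K number of groups (default 16; pairs of mirror-image groups are
#'   merged afterwards by \code{\link{mirror_pair}}).
#' @param seed integer seed.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param nstart number of seeded restarts.
#' @param metric "abs_pearson" (1 - |r|, default) or "pearson" (1 - r).
#' @return A \code{cluster_result}: labels (1..K, named by anchor),
#'   centroids (K x tracks*bins), the stacked data matrix, track names and
#'   bin count, zero-variance flags, plus empty slots for mirror pairs,
#'   merged clusters and orientations.
#' @export
kmeans_profiles <- function(matrices, K = 16, seed = 0L, max_iter = 100,
                            nstart = 10,
                            metric = c("abs_pearson", "pearson")) {
  metric <- match.arg(metric)
  stopifnot(K >= 1, max_iter >= 1, nstart >= 1)
  st <- .stack_profiles(matrices)
  X <- st$X
  degenerate <- apply(X, 1, sd) == 0
  if (all(degenerate)) stop("all profile rows have zero variance",
                            call. = FALSE)
  Xf <- X[!degenerate, , drop = FALSE]
  if (K > nrow(Xf)) stop("K exceeds the number of usable anchors",
                         call. = FALSE)
  best <- NULL
  withr::with_seed(seed, {
    for (s in seq_len(nstart)) {
      fit <- .kmeans_once(Xf, K, metric, max_iter)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  labels <- integer(nrow(X))
  labels[!degenerate] <- best$labels
  if (any(degenerate)) {
    # correlation undefined: fall back to Euclidean-nearest centroid
    for (i in which(degenerate)) {
      d2 <- rowSums(sweep(best$centroids, 2, X[i, ])^2)
      labels[i] <- which.min(d2)
    }
    message(sum(degenerate),
            " zero-variance profile row(s) assigned by Euclidean fallback")
  }
  names(labels) <- rownames(X)
  structure(list(labels = labels, centroids = best$centroids,
                 K = K, seed = seed, metric = metric,
                 objective = best$objective,
                 tracks = st$tracks, nbins = st$nbins,
                 anchors = st$anchors, data = X,
                 zero_variance = degenerate,
                 mirror_pairs = NULL, merged = NULL,
                 orientation = NULL, group_class = NULL),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: K =", x$K, "groups over", length(x$labels),
      "anchors (", x$metric, ", seed", x$seed, ")\n")
  print(table(group = x$labels))
  if (!is.null(x$mirror_pairs) && nrow(x$mirror_pairs) > 0) {
    cat(nrow(x$mirror_pairs), "mirror pair(s) ->",
        length(unique(x$merged)), "final clusters\n")
  }
  invisible(x)
}

# Reverse the bin order of each per-track block of a concatenated profile.
.reverse_tracks <- function(v, n_tracks, nbins) {
  idx <- unlist(lapply(seq_len(n_tracks), function(t) {
    (t - 1L) * nbins + rev(seq_len(nbins))
  }))
  if (is.matrix(v)) v[, idx, drop = FALSE] else v[idx]
}

#' Pair mirror-image clusters and merge them
#'
#' The mirror score of groups (a, b) is the Pearson correlation between
#' the concatenated centroid of a and the per-track bin-reversed
#' concatenated centroid of b (reversing bins within each track block).
#' A track without signal is flat up to noise and contributes almost no
#' variance, so the score is driven by the signal-bearing tracks; an
#' exact mirror scores 1. Groups are paired greedily on descending score
#' (ties broken toward lower group ids), keeping pairs with score >=
#' \code{min_corr}; self-pairing is forbidden and each group joins at most
#' one pair. Paired groups are merged into one final cluster, so the final
#' cluster count is K minus the number of pairs. Final clusters are
#' numbered with unpaired (typically symmetric) groups first, then merged
#' pairs, each block ordered by smallest member group id.
#'
#' @param result a \code{cluster_result} from \code{\link{kmeans_profiles}}.
#' @param min_corr minimum mirror score (default 0.8).
#' @return The \code{cluster_result} with \code{mirror_pairs} (data.frame
#'   group_a, group_b, score) and \code{merged} (group id -> final cluster
#'   id) filled in. Finding no pair is a valid outcome.
#' @export
mirror_pair <- function(result, min_corr = 0.8) {
  stopifnot(inherits(result, "cluster_result"))
  K <- result$K
  nt <- length(result$tracks)
  nb <- result$nbins
  rev_centroids <- .reverse_tracks(result$centroids, nt, nb)
  score <- matrix(NA_real_, K, K)
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      if (a == b) next
      ca <- result$centroids[a, ]
      cb <- rev_centroids[b, ]
      if (sd(ca) == 0 || sd(cb) == 0) next
      score[a, b] <- cor(ca, cb)
    }
  }
  sym <- (score + t(score)) / 2       # pairing score is symmetric by use
  pairs <- list()
  used <- logical(K)
  repeat {
    cand <- which(!is.na(sym) & upper.tri(sym), arr.ind = TRUE)
    cand <- cand[!used[cand[, 1]] & !used[cand[, 2]], , drop = FALSE]
    if (nrow(cand) == 0) break
    vals <- sym[cand]
    if (max(vals) < min_corr) break
    ord <- order(-vals, cand[, 1], cand[, 2])
    top <- cand[ord[1], ]
    pairs[[length(pairs) + 1L]] <- data.frame(
      group_a = top[1], group_b = top[2], score = sym[top[1], top[2]])
    used[top] <- TRUE
  }
  mp <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(group_a = integer(0), group_b = integer(0),
               score = numeric(0))
  rownames(mp) <- NULL

  merged <- integer(K)
  singles <- sort(setdiff(seq_len(K), c(mp$group_a, mp$group_b)))
  nxt <- 0L
  for (g in singles) {
    nxt <- nxt + 1L
    merged[g] <- nxt
  }
  if (nrow(mp)) {
    mp <- mp[order(pmin(mp$group_a, mp$group_b)), , drop = FALSE]
    for (i in seq_len(nrow(mp))) {
      nxt <- nxt + 1L
      merged[mp$group_a[i]] <- nxt
      merged[mp$group_b[i]] <- nxt
    }
  }
  result$mirror_pairs <- mp
  result$merged <- merged
  result
}

#' Left/right asymmetry score of a profile
#'
#' \code{A = (R - L) / (R + L + eps)} where L and R sum the bins strictly
#' left and right of the profile center (the middle bin of an odd-length
#' profile is excluded). A lies in [-1, 1], is 0 for symmetric profiles,
#' +1 when all mass is right of center, and is exactly negated by
#' reversing the profile.
#'
#' @param profile numeric vector of >= 2 non-negative bin values, or a
#'   matrix (rows scored independently).
#' @param eps stabilizer added to the denominator (default 1e-12); an
#'   all-zero profile scores 0.
#' @return numeric score(s) in [-1, 1].
#' @export
asymmetry_score <- function(profile, eps = 1e-12) {
  if (is.matrix(profile)) {
    return(apply(profile, 1, asymmetry_score, eps = eps))
  }
  n <- length(profile)
  stopifnot(n >= 2)
  half <- n %/% 2
  L <- sum(profile[seq_len(half)])
  R <- sum(profile[seq.int(n - half + 1L, n)])
  if (L + R == 0) return(0)
  (R - L) / (R + L + eps)
}

#' Per-cluster, per-track asymmetry report
#'
#' Computes the asymmetry score of every group centroid on every track,
#' plus per-anchor scores on every track.
#'
#' @param result a \code{cluster_result}.
#' @return list with \code{by_group} (data.frame group, track, A) and
#'   \code{by_anchor} (anchors x tracks matrix of A scores).
#' @export
asymmetry_report <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  nt <- length(result$tracks)
  nb <- result$nbins
  by_group <- do.call(rbind, lapply(seq_len(result$K), function(g) {
    data.frame(group = g, track = result$tracks,
               A = vapply(seq_len(nt), function(t) {
                 asymmetry_score(result$centroids[g, (t - 1L) * nb +
                                                    seq_len(nb)])
               }, numeric(1)))
  }))
  by_anchor <- vapply(seq_len(nt), function(t) {
    asymmetry_score(result$data[, (t - 1L) * nb + seq_len(nb),
                                drop = FALSE])
  }, numeric(length(result$labels)))
  colnames(by_anchor) <- result$tracks
  list(by_group = by_group, by_anchor = by_anchor)
}

#' Classify clusters as symmetric/asymmetric and orient their anchors
#'
#' For each group the deciding track is the first entry of
#' \code{track_priority} that carries signal in the group centroid (sum of
#' centroid bins > 0). The group is "asymmetric" when the absolute
#' centroid asymmetry on that track reaches \code{threshold}; its anchors
#' are oriented "right" when A > 0 and "left" when A < 0 (for mirror
#' pairs this makes the two member groups take opposite orientations).
#' Anchors of symmetric groups get orientation "none".
#'
#' @param result a \code{cluster_result}, after \code{\link{mirror_pair}}.
#' @param track_priority tracks to consult, in order (default H3.3 then
#'   H2A.Z, the variants that delineate orientation).
#' @param threshold minimum |A| to call a group asymmetric (default 0.2).
#' @return The \code{cluster_result} with \code{orientation} (per-anchor
#'   factor left/right/none) and \code{group_class} (per-group data.frame:
#'   group, cluster, track used, A, asymmetric, orientation).
#' @export
classify_and_orient <- function(result,
                                track_priority = c("H3.3", "H2A.Z"),
                                threshold = 0.2) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(result$merged)) result <- mirror_pair(result)
  nb <- result$nbins
  rows <- lapply(seq_len(result$K), function(g) {
    use <- NA_character_
    A <- NA_real_
    for (tr in c(track_priority, setdiff(result$tracks, track_priority))) {
      t <- match(tr, result$tracks)
      if (is.na(t)) next
      cen <- result$centroids[g, (t - 1L) * nb + seq_len(nb)]
      if (sum(cen) > 0) {
        use <- tr
        A <- asymmetry_score(cen)
        break
      }
    }
    asym <- !is.na(A) && abs(A) >= threshold
    data.frame(group = g, cluster = result$merged[g], track = use, A = A,
               asymmetric = asym,
               orientation = if (!asym) "none" else
                 if (A > 0) "right" else "left",
               stringsAsFactors = FALSE)
  })
  gc <- do.call(rbind, rows)
  ori <- gc$orientation[result$labels]
  names(ori) <- names(result$labels)
  result$orientation <- ori
  result$group_class <- gc
  result$orient_params <- list(track_priority = track_priority,
                               threshold = threshold)
  result
}

#' Orientation-aligned profile rows
#'
#' Returns the stacked per-anchor profiles with rows of left-oriented
#' anchors bin-reversed per track, so that "toward the orientation" is
#' always to the right. Used for pooled displays and directional scoring.
#'
#' @param result an oriented \code{cluster_result}.
#' @param X optional matrix to align instead of the stored profile data
#'   (same anchors/rows; e.g. a PolII profile matrix).
#' @param n_tracks number of track blocks in \code{X} (default 1 when
#'   \code{X} given, else all clustering tracks).
#' @export
oriented_profiles <- function(result, X = NULL, n_tracks = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (is.null(result$orientation)) {
    stop("run classify_and_orient() first", call. = FALSE)
  }
  if (is.null(X)) {
    X <- result$data
    n_tracks <- length(result$tracks)
  } else {
    n_tracks <- n_tracks %||% 1L
  }
  stopifnot(nrow(X) == length(result$orientation),
            ncol(X) == n_tracks * result$nbins)
  left <- result$orientation == "left"
  X[left, ] <- .reverse_tracks(X[left, , drop = FALSE], n_tracks,
                               result$nbins)
  X
}
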