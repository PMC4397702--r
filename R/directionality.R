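#' PolII skew per cluster and concordance with variant orientation
#'
#' Rows of the PolII profile matrix belonging to left-oriented anchors are
#' bin-reversed, so a positive asymmetry score means "PolII skewed toward
#' the variant orientation". Cluster skew is the mean aligned score over
#' member anchors; concordance is the fraction of anchors in asymmetric
#' clusters whose aligned PolII score is positive (i.e. the PolII skew
#' sign matches the variant orientation). Symmetric clusters report skew
#' only.
#'
#' @param polii a \code{\link{profile_matrix}} of PolII signal over the
#'   same anchors as the clustering (same order).
#' @param result an oriented \code{cluster_result}
#'   (\code{\link{classify_and_orient}}).
#' @return list with \code{by_cluster} (cluster, n, asymmetric, skew) and
#'   scalar \code{concordance} (NA when no asymmetric anchors), plus
#'   \code{per_anchor} aligned scores.
#' @export
polii_skew <- function(polii, result) {
  if (is.null(polii)) stop("PolII profile matrix is required", call. = FALSE)
  stopifnot(inherits(polii, "profile_matrix"),
            inherits(result, "cluster_result"))
  if (is.null(result$orientation)) {
    stop("run classify_and_orient() first", call. = FALSE)
  }
  if (nrow(polii$values) != length(result$labels)) {
    stop("PolII matrix and clustering cover different anchors",
         call. = FALSE)
  }
  aligned <- oriented_profiles(result, X = polii$values, n_tracks = 1L)
  A <- asymmetry_score(aligned)
  cl <- result$merged[result$labels]
  asym_group <- result$group_class$asymmetric[result$labels]
  by_cluster <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    sel <- cl == k
    data.frame(cluster = k, n = sum(sel),
               asymmetric = any(asym_group[sel]),
               skew = mean(A[sel]))
  }))
  concordance <- if (any(asym_group)) mean(A[asym_group] > 0) else NA_real_
  list(by_cluster = by_cluster, concordance = concordance, per_anchor = A)
}

#' Strand bias of nascent (eRNA) signal at oriented anchors
#'
#' For each anchor, P and M are the total plus- and minus-strand signal in
#' the +/- W window around the center; \code{B = (P - M) / (P + M + eps)}.
#' For left-oriented anchors the sign is flipped so that B > 0 always
#' means "transcription biased toward the variant orientation". Cluster
#' means come with a seeded percentile bootstrap CI.
#'
#' @param plus,minus stranded \code{signal_track}s, normalized identically.
#' @param result an oriented \code{cluster_result}.
#' @param W window half-width in bp (use the profile window).
#' @param n_boot bootstrap resamples for the cluster-mean CI.
#' @param seed seed for the bootstrap.
#' @param eps denominator stabilizer; anchors with P + M = 0 score B = 0
#'   and are flagged.
#' @return list with \code{per_anchor} (anchor, cluster, orientation, P,
#'   M, B, flagged) and \code{by_cluster} (cluster, n, mean_B, ci_lo,
#'   ci_hi; CI attributes record n_boot and seed).
#' @export
strand_bias <- function(plus, minus, result, W = 2000, n_boot = 1000,
                        seed = 0L, eps = 1e-12) {
  stopifnot(inherits(plus, "signal_track"), inherits(minus, "signal_track"),
            inherits(result, "cluster_result"))
  if (is.null(result$orientation)) {
    stop("run classify_and_orient() first", call. = FALSE)
  }
  a <- result$anchors
  P <- M <- numeric(nrow(a))
  for (chr in unique(a$chrom)) {
    sel <- which(a$chrom == chr)
    from <- a$center[sel] - W
    to <- a$center[sel] + W
    P[sel] <- .window_mean(plus, chr, from, to) * (to - from)
    M[sel] <- .window_mean(minus, chr, from, to) * (to - from)
  }
  B <- (P - M) / (P + M + eps)
  flagged <- (P + M) == 0
  B[flagged] <- 0
  flip <- result$orientation == "left"
  B[flip] <- -B[flip]
  cl <- result$merged[result$labels]
  per_anchor <- data.frame(anchor = a$name, cluster = cl,
                           orientation = result$orientation,
                           P = P, M = M, B = B, flagged = flagged)
  by_cluster <- withr::with_seed(seed, {
    do.call(rbind, lapply(sort(unique(cl)), function(k) {
      b <- B[cl == k]
      boots <- vapply(seq_len(n_boot), function(i) {
        mean(b[sample.int(length(b), replace = TRUE)])
      }, numeric(1))
      data.frame(cluster = k, n = length(b), mean_B = mean(b),
                 ci_lo = unname(quantile(boots, 0.025)),
                 ci_hi = unname(quantile(boots, 0.975)))
    }))
  })
  attr(by_cluster, "n_boot") <- n_boot
  attr(by_cluster, "seed") <- seed
  if (any(flagged)) {
    message(sum(flagged), " anchor(s) with zero eRNA signal flagged (B = 0)")
  }
  list(per_anchor = per_anchor, by_cluster = by_cluster)
}

#' One-sided rank-sum comparison of per-anchor signal between clusters
#'
#' Mann-Whitney U test on per-anchor totals (e.g. eRNA P + M), one-sided.
#' The exact null distribution is used when the smaller group has <= 20
#' anchors and there are no ties; otherwise the normal approximation with
#' continuity correction. Identical constant samples return p = 0.5 with a
#' tie warning.
#'
#' @param a,b numeric vectors of per-anchor totals for the two clusters
#'   (non-empty).
#' @param alternative "less" tests a < b (default), "greater" tests a > b.
#' @return list: \code{statistic} (U for a vs b), \code{p.value},
#'   \code{n_a}, \code{n_b}, \code{exact} (logical branch taken).
#' @export
compare_cluster_signal <- function(a, b, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1) {
    warning("identical constant samples; p = 0.5", call. = FALSE)
    return(list(statistic = length(a) * length(b) / 2, p.value = 0.5,
                n_a = length(a), n_b = length(b), exact = FALSE))
  }
  ties <- any(duplicated(c(a, b)))
  use_exact <- min(length(a), length(b)) <= 20 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = use_exact,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_a = length(a), n_b = length(b), exact = use_exact)
}
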