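#' Anchor / TF-peak overlap indicators
#'
#' An anchor overlaps a TF's peak set iff any peak intersects the
#' half-open window \code{[center - flank, center + flank)}. Unsorted
#' peaks are sorted internally.
#'
#' @param anchors an \code{anchor_set} or interval data.frame.
#' @param peaks TF peak intervals (data.frame, 0-based half-open).
#' @param flank half-width of the tested window in bp (default 500).
#' @return logical vector, one entry per anchor.
#' @export
overlap_counts <- function(anchors, peaks, flank = 500) {
  a <- .anchor_df(anchors)
  if (nrow(peaks) == 0) return(rep(FALSE, nrow(a)))
  if (is.unsorted(order(peaks$chrom, peaks$start))) {
    peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
    message("TF peaks sorted internally")
  }
  win <- data.frame(chrom = a$chrom,
                    start = pmax(0L, a$center - flank),
                    end = a$center + flank)
  hits <- GenomicRanges::countOverlaps(
    .intervals_to_granges(win), .intervals_to_granges(peaks),
    ignore.strand = TRUE)
  hits > 0
}

#' Upper-tail hypergeometric p-value for cluster overlap enrichment
#'
#' \code{P(X >= k)} for X hypergeometric: k of the n anchors in a cluster
#' overlap a TF whose peaks overlap K_pop of all N anchors. Computed via
#' the distribution's survival function (log-space internals).
#'
#' @param N total anchors in the universe (all distal anchors).
#' @param K_pop anchors overlapping the TF across the universe.
#' @param n anchors in the cluster.
#' @param k overlapping anchors in the cluster.
#' @return p in (0, 1]; k = 0 gives exactly 1.
#' @export
hypergeom_pvalue <- function(N, K_pop, n, k) {
  stopifnot(length(N) == 1, length(K_pop) == 1, length(n) == 1,
            length(k) == 1)
  if (K_pop > N || n > N || k > min(n, K_pop) || k < 0 ||
      k < n - (N - K_pop)) {
    stop("inconsistent hypergeometric counts (N=", N, ", K_pop=", K_pop,
         ", n=", n, ", k=", k, ")", call. = FALSE)
  }
  if (k == 0) return(1)
  phyper(k - 1, K_pop, N - K_pop, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of raw p-values (monotone in rank).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same length/order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' TF-by-cluster hypergeometric enrichment table
#'
#' For every TF peak set and every final cluster: N = all distal anchors,
#' K_pop = anchors overlapping the TF, n = anchors in the cluster, k =
#' overlapping anchors in the cluster, upper-tail hypergeometric p, BH
#' q across all rows, and fold = (k/n) / (K_pop/N). The enrichment
#' universe is the distal anchor set itself (the clustering universe),
#' not the whole genome.
#'
#' @param result a \code{cluster_result} with merged clusters (run
#'   \code{\link{mirror_pair}} first; raw groups are used if not).
#' @param peak_sets named list of TF peak interval data.frames.
#' @param flank overlap window half-width in bp (default 500).
#' @return An \code{enrichment_table} data.frame: tf, cluster, N, K_pop,
#'   n, k, fold, p, q.
#' @export
tf_enrichment_table <- function(result, peak_sets, flank = 500) {
  stopifnot(inherits(result, "cluster_result"), is.list(peak_sets),
            !is.null(names(peak_sets)))
  cl <- if (!is.null(result$merged)) result$merged[result$labels] else
    result$labels
  a <- result$anchors
  N <- length(cl)
  rows <- list()
  for (tf in names(peak_sets)) {
    ov <- overlap_counts(a, peak_sets[[tf]], flank = flank)
    K_pop <- sum(ov)
    for (k_id in sort(unique(cl))) {
      sel <- cl == k_id
      n <- sum(sel)
      k <- sum(ov & sel)
      fold <- if (K_pop == 0) NA_real_ else (k / n) / (K_pop / N)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, cluster = k_id, N = N, K_pop = K_pop, n = n, k = k,
        fold = fold,
        p = if (K_pop == 0) 1 else hypergeom_pvalue(N, K_pop, n, k))
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"),
            flank = flank)
}
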