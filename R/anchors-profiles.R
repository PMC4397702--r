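#' Select promoter-distal regulatory anchors
#'
#' Keeps DHS intervals whose center lies more than \code{min_dist} bp from
#' every annotated TSS and TTS (mRNA and lncRNA) and whose interval does
#' not overlap any gene body by a single bp (the strict any-overlap
#' reading). The anchor center is the interval midpoint.
#'
#' @param dhs interval data.frame (chrom/start/end, 0-based half-open).
#' @param genes gene table as returned by \code{\link{read_genes}} (needs
#'   \code{tss}, \code{tts}).
#' @param min_dist minimum center-to-TSS/TTS distance in bp (default 2000;
#'   "distal" means strictly greater).
#' @return An \code{anchor_set}: list with \code{anchors} (the retained
#'   intervals plus a \code{center} column) and \code{params}. Zero
#'   retained anchors triggers a warning, not an error.
#' @export
filter_distal <- function(dhs, genes, min_dist = 2000) {
  stopifnot(is.data.frame(dhs), is.data.frame(genes))
  if (is.null(genes$tss) || is.null(genes$tts)) {
    stop("genes must carry tss/tts columns (see read_genes())",
         call. = FALSE)
  }
  dhs <- as.data.frame(dhs)
  dhs$center <- (dhs$start + dhs$end) %/% 2
  keep <- rep(TRUE, nrow(dhs))

  # center distance to every TSS/TTS must exceed min_dist
  for (chr in unique(dhs$chrom)) {
    di <- which(dhs$chrom == chr)
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0) next
    pts <- sort(c(g$tss, g$tts))
    near <- findInterval(dhs$center[di], pts)
    lo <- pmax(near, 1L)
    hi <- pmin(near + 1L, length(pts))
    dmin <- pmin(abs(dhs$center[di] - pts[lo]),
                 abs(dhs$center[di] - pts[hi]))
    keep[di] <- keep[di] & dmin > min_dist
  }

  # zero tolerated overlap with any gene body
  if (nrow(genes) > 0 && any(keep)) {
    dgr <- .intervals_to_granges(dhs)
    ggr <- .intervals_to_granges(genes)
    hits <- GenomicRanges::countOverlaps(dgr, ggr, ignore.strand = TRUE)
    keep <- keep & hits == 0
  }

  out <- dhs[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    warning("no DHS survived the distal filter", call. = FALSE)
  }
  message(nrow(out), " of ", nrow(dhs), " DHSs retained as distal anchors")
  structure(list(anchors = out,
                 params = list(min_dist = min_dist, n_input = nrow(dhs),
                               n_retained = nrow(out))),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("anchor_set:", nrow(x$anchors), "distal anchors (min_dist =",
      x$params$min_dist, "bp)\n")
  invisible(x)
}

.anchor_df <- function(anchors) {
  a <- if (inherits(anchors, "anchor_set")) anchors$anchors else
    as.data.frame(anchors)
  if (is.null(a$center)) a$center <- (a$start + a$end) %/% 2
  if (is.null(a$name)) a$name <- paste0("anchor", seq_len(nrow(a)))
  a
}

#' Anchor-centered profile matrix
#'
#' Row i, bin j holds the mean signal over
#' \code{[center_i - W + j*b, center_i - W + (j+1)*b)} for j = 0 ..
#' 2W/b - 1. Anchors whose window would leave the chromosome are dropped
#' (count reported via message and kept as an attribute).
#'
#' @param track a \code{signal_track} (normalize first for comparability
#'   across tracks).
#' @param anchors an \code{anchor_set} or interval data.frame.
#' @param W window half-width in bp.
#' @param b profile bin width in bp; must divide W.
#' @return A \code{profile_matrix}: list with \code{values} (anchors x
#'   bins), \code{window}, \code{bin}, \code{track}, \code{anchors} (the
#'   retained anchor data.frame).
#' @export
profile_matrix <- function(track, anchors, W = 2000, b = 100) {
  stopifnot(inherits(track, "signal_track"))
  if (W %% b != 0) stop("W must be a multiple of b", call. = FALSE)
  a <- .anchor_df(anchors)
  nbins <- 2L * W %/% b
  ok <- rep(TRUE, nrow(a))
  for (chr in unique(a$chrom)) {
    len <- .chrom_length(track, chr)
    sel <- a$chrom == chr
    ok[sel] <- a$center[sel] - W >= 0 & a$center[sel] + W <= len
  }
  if (any(!ok)) {
    message(sum(!ok), " anchor(s) dropped (window outside chromosome)")
  }
  a <- a[ok, , drop = FALSE]
  m <- matrix(0, nrow(a), nbins)
  for (chr in unique(a$chrom)) {
    sel <- which(a$chrom == chr)
    for (j in seq_len(nbins)) {
      from <- a$center[sel] - W + (j - 1L) * b
      m[sel, j] <- .window_mean(track, chr, from, from + b)
    }
  }
  rownames(m) <- a$name
  structure(list(values = m, window = W, bin = b,
                 track = track$name, anchors = a,
                 n_dropped = sum(!ok)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix", if (!is.na(x$track)) x$track else "", ":",
      nrow(x$values), "anchors x", ncol(x$values), "bins ( +/-",
      x$window, "bp,", x$bin, "bp bins )\n")
  invisible(x)
}

#' Expression-stratified meta-gene profiles at TSS and TTS
#'
#' Genes are split into \code{n_groups} equal-size expression strata
#' (group 1 = lowest). For each stratum and track, the mean strand-aware
#' profile around the TSS (+/- \code{W_tss}) and TTS (+/- \code{W_tts}) is
#' returned; minus-strand gene profiles are bin-reversed so that
#' transcription always runs left to right.
#'
#' @param tracks named list of \code{signal_track}s.
#' @param genes gene table (see \code{\link{read_genes}}).
#' @param expression data.frame with \code{name}, \code{expression}, or a
#'   named numeric vector. Genes without a value are excluded (count
#'   messaged).
#' @param W_tss,W_tts window half-widths in bp.
#' @param b bin width in bp.
#' @param n_groups number of expression strata (default quintiles).
#' @return Long data.frame: \code{track}, \code{site} ("tss"/"tts"),
#'   \code{group}, \code{pos} (bp relative to the site, bin start),
#'   \code{signal}.
#' @export
meta_gene_profiles <- function(tracks, genes, expression,
                               W_tss = 2000, W_tts = 500, b = 100,
                               n_groups = 5) {
  if (is.data.frame(expression)) {
    expression <- setNames(expression$expression, expression$name)
  }
  g <- genes
  g$expression <- expression[g$name]
  n_missing <- sum(is.na(g$expression))
  if (n_missing > 0) {
    message(n_missing, " gene(s) without expression excluded")
    g <- g[!is.na(g$expression), , drop = FALSE]
  }
  rk <- rank(g$expression, ties.method = "first")
  g$group <- ceiling(rk / nrow(g) * n_groups)

  one_site <- function(track_name, site, W) {
    tr <- tracks[[track_name]]
    centers <- if (site == "tss") g$tss else g$tts
    nbins <- 2L * W %/% b
    m <- matrix(NA_real_, nrow(g), nbins)
    for (chr in unique(g$chrom)) {
      len <- .chrom_length(tr, chr)
      sel <- which(g$chrom == chr &
                     centers - W >= 0 & centers + W <= len)
      for (j in seq_len(nbins)) {
        from <- centers[sel] - W + (j - 1L) * b
        m[sel, j] <- .window_mean(tr, chr, from, from + b)
      }
    }
    minus <- g$strand == "-"
    m[minus, ] <- m[minus, rev(seq_len(nbins)), drop = FALSE]
    do.call(rbind, lapply(sort(unique(g$group)), function(q) {
      rows <- m[g$group == q, , drop = FALSE]
      data.frame(track = track_name, site = site, group = q,
                 pos = seq(-W, W - b, by = b),
                 signal = colMeans(rows, na.rm = TRUE))
    }))
  }
  out <- do.call(rbind, lapply(names(tracks), function(tn) {
    rbind(one_site(tn, "tss", W_tss), one_site(tn, "tts", W_tts))
  }))
  rownames(out) <- NULL
  out
}
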