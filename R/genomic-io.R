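#' Binned genomic signal track
#'
#' Coverage signal stored as per-chromosome vectors of values over uniform
#' bins of \code{bin_width} bp (bin j covers [j*b, (j+1)*b), 0-based).
#' Pre-normalization values are read counts per bin; \code{library_size}
#' is the total mapped-read count used for RPKM normalization.
#'
#' @param values named list (chrom -> numeric vector of per-bin values).
#' @param bin_width bin width in bp.
#' @param library_size total mapped reads; defaults to the sum of all bin
#'   values (valid when values are raw counts).
#' @param name,strand optional track label and strand tag ("+", "-").
#' @param normalized logical; TRUE once RPKM-normalized.
#' @return A \code{signal_track} object.
#' @export
signal_track <- function(values, bin_width = 100, library_size = NULL,
                         name = NA_character_, strand = NA_character_,
                         normalized = FALSE) {
  stopifnot(is.list(values), length(values) >= 1, !is.null(names(values)),
            bin_width >= 1)
  if (!normalized && any(unlist(values) < 0)) {
    stop("pre-normalization signal values must be non-negative",
         call. = FALSE)
  }
  if (is.null(library_size)) library_size <- sum(unlist(values))
  structure(list(values = values, bin_width = bin_width,
                 library_size = library_size, name = name,
                 strand = strand, normalized = normalized),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track", if (!is.na(x$name)) x$name else "",
      "| bin", x$bin_width, "bp |",
      length(x$values), "chrom(s) | library", format(x$library_size),
      "|", if (x$normalized) "RPKM-normalized" else "raw counts", "\n")
  invisible(x)
}

#' RPKM-normalize a signal track
#'
#' Per-bin reads become reads per kilobase per million mapped reads:
#' \code{count * 1e9 / (bin_width * library_size)}, then multiplied by a
#' global display constant \code{scale} (default 1; pass \code{scale = 10}
#' for tracks scaled to 10 RPKM units). Every downstream statistic in this
#' package (correlation clustering, asymmetry, strand bias, rank tests) is
#' invariant to \code{scale}.
#'
#' @param track a raw-count \code{signal_track}.
#' @param scale global multiplicative constant applied after RPKM.
#' @export
rpkm_normalize <- function(track, scale = 1) {
  stopifnot(inherits(track, "signal_track"))
  if (track$normalized) {
    stop("track is already normalized; refusing to normalize twice",
         call. = FALSE)
  }
  if (track$library_size <= 0) {
    stop("library_size must be positive", call. = FALSE)
  }
  f <- 1e9 / (track$bin_width * track$library_size) * scale
  track$values <- lapply(track$values, function(v) v * f)
  track$normalized <- TRUE
  track
}

.intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df))
      ifelse(df$strand %in% c("+", "-"), df$strand, "*") else "*")
}

#' Read / write BED intervals
#'
#' Intervals are handled as data.frames with 0-based half-open
#' coordinates: \code{chrom}, \code{start}, \code{end}, \code{name},
#' \code{score}, \code{strand} ("." when unstranded). Files are parsed and
#' written through rtracklayer (gzip transparent).
#'
#' @param path BED file path.
#' @param intervals interval data.frame.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE)
  df$name[is.na(df$name)] <- "."
  df$score[is.na(df$score)] <- 0
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(intervals$start >= 0), all(intervals$start < intervals$end))
  gr <- .intervals_to_granges(intervals)
  gr$name <- if ("name" %in% names(intervals)) intervals$name else "."
  gr$score <- if ("score" %in% names(intervals)) intervals$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write a gene table
#'
#' Plain 4+ column table (tab separated, header): \code{chrom},
#' \code{start}, \code{end}, \code{strand}, optional \code{name},
#' \code{biotype} ("mRNA"/"lncRNA"). Coordinates are 0-based half-open.
#' Strand-aware TSS and TTS positions are derived: TSS = start on "+",
#' end - 1 on "-".
#'
#' @param path file path.
#' @param genes gene data.frame.
#' @return data.frame with the columns above plus \code{tss}, \code{tts}.
#' @export
read_genes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop("gene table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  if (is.null(df$name)) df$name <- paste0("gene", seq_len(nrow(df)))
  if (is.null(df$biotype)) df$biotype <- "mRNA"
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tts <- ifelse(df$strand == "+", df$end - 1L, df$start)
  df
}

#' @rdname read_genes
#' @export
write_genes <- function(genes, path) {
  cols <- intersect(c("chrom", "start", "end", "strand", "name", "biotype",
                      "expression"), names(genes))
  write.table(genes[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write bedGraph coverage
#'
#' A bedGraph file is rasterized onto uniform bins of \code{bin_width} bp:
#' each bin's value is the coverage-weighted mean of the records that
#' overlap it (0 where no record applies). Records must not overlap each
#' other. Writing emits one record per run of equal-valued bins, skipping
#' zero runs; a read of a write is lossless for bin-aligned data.
#'
#' @param path bedGraph path (gzip transparent on read).
#' @param bin_width target bin width in bp.
#' @param library_size optional total read count; default: sum of values
#'   times covered length / bin width (valid for count-per-bin tracks).
#' @param track a \code{signal_track}.
#' @export
read_bedgraph <- function(path, bin_width = 100, library_size = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) stop("empty bedGraph: ", path, call. = FALSE)
  if (any(IRanges::countOverlaps(gr, gr) > 1)) {
    stop("overlapping bedGraph records in ", path, call. = FALSE)
  }
  values <- list()
  for (chr in unique(as.character(GenomicRanges::seqnames(gr)))) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
    s <- GenomicRanges::start(sub) - 1L
    e <- GenomicRanges::end(sub)
    v <- sub$score
    nbins <- ceiling(max(e) / bin_width)
    acc <- numeric(nbins)
    if (all(s %% bin_width == 0) && all(e %% bin_width == 0)) {
      # bin-aligned records: scatter runs directly (no partial overlaps)
      nb <- (e - s) %/% bin_width
      idx <- sequence(nvec = nb, from = s %/% bin_width + 1L)
      acc[idx] <- rep(v * bin_width, nb)
    } else {
      for (i in seq_along(s)) {
        b0 <- s[i] %/% bin_width
        b1 <- (e[i] - 1L) %/% bin_width
        for (b in b0:b1) {
          ov <- min(e[i], (b + 1) * bin_width) - max(s[i], b * bin_width)
          acc[b + 1L] <- acc[b + 1L] + v[i] * ov
        }
      }
    }
    values[[chr]] <- acc / bin_width
  }
  signal_track(values, bin_width = bin_width, library_size = library_size)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0L, head(ends, -1L))
    keep <- r$values != 0
    if (!any(keep)) next
    lines <- sprintf("%s\t%d\t%d\t%s", chr,
                     starts[keep] * track$bin_width,
                     ends[keep] * track$bin_width,
                     format(r$values[keep], scientific = FALSE, trim = TRUE,
                            digits = 10))
    writeLines(lines, con)
  }
  invisible(path)
}

# Integral of a piecewise-constant (binned) signal over [from, to) in bp,
# via cumulative sums; from/to may be fractional bin positions. Vectorized
# over from/to.
.bin_integral <- function(values, bin_width, from, to) {
  n <- length(values)
  cs <- c(0, cumsum(values))
  F <- function(x) {
    x <- pmax(0, pmin(x, n * bin_width))
    b <- pmin(floor(x / bin_width), n - 1)
    cs[b + 1] * bin_width + (x - b * bin_width) * values[b + 1]
  }
  F(to) - F(from)
}

# Mean signal of `track` over windows [start, end) on `chrom` (matrix of
# one value per window).
.window_mean <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(rep(0, length(start)))
  .bin_integral(v, track$bin_width, start, end) / (end - start)
}

.chrom_length <- function(track, chrom) {
  length(track$values[[chrom]]) * track$bin_width
}
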