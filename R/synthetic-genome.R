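#' Define a signal archetype for synthetic anchors
#'
#' An archetype is the ground-truth signal pattern planted around one
#' class of anchors: per-variant-track Gaussian bump amplitudes (expected
#' peak counts per bin), a signed bump offset from the anchor center
#' (scalar, or named per track), a bump width, a PolII bump whose offset
#' shares the sign of the variant offset, and a bidirectional eRNA bump
#' whose plus/minus split follows a signed strand bias toward the offset
#' direction. A "symmetric" archetype has offset 0 on all tracks.
#'
#' @param name archetype label (written to the anchor BED name field).
#' @param amp named numeric: bump amplitude per variant track (tracks
#'   absent from the names get no bump).
#' @param offset signed bump offset in bp; scalar applied to every track
#'   in \code{amp}, or a named vector per track.
#' @param width bump width in bp (Gaussian sigma = width / 2).
#' @param polii_amp,polii_offset PolII bump amplitude and offset; the
#'   offset defaults to half the (first nonzero) variant offset and must
#'   share its sign.
#' @param erna_amp,erna_bias eRNA bump amplitude and signed strand bias in
#'   [-1, 1] toward the offset direction (plus strand gets
#'   \code{(1 + bias)/2} of the eRNA when the offset points right).
#' @param bimodal_sep when nonzero, each track bump is split into two
#'   half-amplitude bumps at +/- \code{bimodal_sep} bp around the (offset)
#'   center -- the classic pattern of the two nucleosomes flanking a
#'   nucleosome-free region.
#' @return an \code{archetype} object.
#' @export
archetype <- function(name, amp, offset = 0, width = 300,
                      polii_amp = 30, polii_offset = NULL,
                      erna_amp = 20, erna_bias = 0, bimodal_sep = 0) {
  stopifnot(is.numeric(amp), !is.null(names(amp)), width > 0,
            abs(erna_bias) <= 1, bimodal_sep >= 0)
  offsets <- if (length(offset) == 1 && is.null(names(offset))) {
    setNames(rep(offset, length(amp)), names(amp))
  } else {
    out <- setNames(rep(0, length(amp)), names(amp))
    out[names(offset)] <- offset
    out
  }
  main <- if (any(offsets != 0)) offsets[offsets != 0][1] else 0
  # default PolII offset shares the sign of the variant offset; an explicit
  # opposite-sign value is allowed (anti-oriented control fixtures)
  if (is.null(polii_offset)) polii_offset <- main / 2
  structure(list(name = name, amp = amp, offsets = offsets, width = width,
                 polii_amp = polii_amp, polii_offset = polii_offset,
                 erna_amp = erna_amp, erna_bias = erna_bias,
                 bimodal_sep = bimodal_sep, direction = sign(main)),
            class = "archetype")
}

#' Mirror-image counterpart of an archetype
#'
#' Same amplitudes and widths with all offsets negated; the label gets the
#' matching "_L"/"_R" suffix swapped (or "_mirror" appended).
#'
#' @param a an \code{archetype}.
#' @export
mirror_archetype <- function(a) {
  stopifnot(inherits(a, "archetype"))
  nm <- if (grepl("_R$", a$name)) sub("_R$", "_L", a$name) else
    if (grepl("_L$", a$name)) sub("_L$", "_R", a$name) else
      paste0(a$name, "_mirror")
  archetype(nm, amp = a$amp, offset = -a$offsets, width = a$width,
            polii_amp = a$polii_amp, polii_offset = -a$polii_offset,
            erna_amp = a$erna_amp, erna_bias = a$erna_bias,
            bimodal_sep = a$bimodal_sep)
}

#' Default archetype panel: 4 symmetric classes + 6 mirror pairs
#'
#' Emulates the cluster structure seen at promoter-distal regulatory
#' regions: symmetric classes marked by macroH2A only, H3.1 only, H2A.Z +
#' H3.3 over the center, or H2A.Z + H3.3 flanking the nucleosome-free
#' region as a double bump; and six mirrored asymmetric classes in which H3.3
#' (variously combined with H2A.Z, H3.1 or macroH2A) is skewed 400 bp to
#' one side, PolII is skewed the same way, and eRNA carries a modest
#' strand bias (0.3) toward the skew. eRNA amplitude is weakest for the
#' macroH2A-only class (repressive) and strongest for H2A.Z/H3.3 classes.
#'
#' @param offset skew magnitude in bp for the asymmetric pairs.
#' @param erna_bias planted strand bias for the asymmetric pairs.
#' @return list of 16 \code{archetype}s.
#' @export
default_archetypes <- function(offset = 400, erna_bias = 0.3) {
  pair <- function(name, amp, erna_amp, polii_amp = 40) {
    r <- archetype(paste0(name, "_R"), amp = amp, offset = offset,
                   polii_amp = polii_amp, erna_amp = erna_amp,
                   erna_bias = erna_bias)
    list(r, mirror_archetype(r))
  }
  c(list(
    archetype("sym_macroH2A", c(macroH2A = 60), erna_amp = 5,
              polii_amp = 8),
    archetype("sym_H3.1", c(H3.1 = 60), erna_amp = 10, polii_amp = 15),
    archetype("sym_Z_33", c(H2A.Z = 50, H3.3 = 40), erna_amp = 30,
              polii_amp = 40),
    archetype("sym_NFR_flank", c(H2A.Z = 50, H3.3 = 30), erna_amp = 20,
              polii_amp = 30, bimodal_sep = 300)),
    pair("skew_33", c(H3.3 = 60), erna_amp = 35),
    pair("skew_33_Z", c(H3.3 = 40, H2A.Z = 50), erna_amp = 40),
    pair("skew_33_31", c(H3.3 = 50, H3.1 = 40), erna_amp = 25),
    pair("skew_33_macro", c(H3.3 = 40, macroH2A = 50), erna_amp = 15),
    list(archetype("skew_33_Zc_R", c(H3.3 = 60, H2A.Z = 50),
                   offset = c(H3.3 = 400), erna_amp = 30,
                   erna_bias = erna_bias, polii_amp = 40),
         mirror_archetype(
           archetype("skew_33_Zc_R", c(H3.3 = 60, H2A.Z = 50),
                     offset = c(H3.3 = 400), erna_amp = 30,
                     erna_bias = erna_bias, polii_amp = 40))),
    pair("skew_33_Z_31", c(H3.3 = 40, H2A.Z = 40, H3.1 = 40),
         erna_amp = 30))
}

#' Configuration for the synthetic genome fixture
#'
#' @param chrom,chrom_length chromosome name and length (bp; rounded up
#'   to a bin multiple).
#' @param n_genes number of genes (a random ~15\% are labelled lncRNA).
#' @param n_per_archetype anchors planted per archetype.
#' @param archetypes list of \code{\link{archetype}}s.
#' @param window profile window half-width the anchors must clear (bp).
#' @param bin_width signal bin width (bp).
#' @param background background Poisson rate per bin for ChIP tracks.
#' @param erna_background background rate per bin for the stranded eRNA
#'   tracks (default 0: intergenic nascent signal is near zero).
#' @param gene_min_dist distal rule distance (bp).
#' @param n_proximal promoter-proximal decoy DHSs (filtered out by
#'   \code{\link{filter_distal}}; 0 disables).
#' @param tf_spec named list: TF -> list(target = archetype name or vector
#'   of names, odds = fold enrichment of the overlap rate at target
#'   anchors over \code{tf_background_rate}).
#' @param tf_background_rate baseline probability that a non-target anchor
#'   carries a TF peak.
#' @param erna_width eRNA bump width in bp.
#' @param noise "poisson" (counts) or "none" (noise-free expected signal).
#' @param seed integer; fully determines the fixture.
#' @return a \code{genome_fixture_config} list.
#' @export
genome_fixture_config <- function(chrom = "chrS", chrom_length = 8e6,
                                  n_genes = 60, n_per_archetype = 40,
                                  archetypes = default_archetypes(),
                                  window = 2000, bin_width = 100,
                                  background = 2, erna_background = 0,
                                  gene_min_dist = 2000, n_proximal = 30,
                                  tf_spec = list(
                                    CTCF = list(target = "sym_H3.1",
                                                odds = 9),
                                    ZZZ3 = list(target = "sym_macroH2A",
                                                odds = 9)),
                                  tf_background_rate = 0.1,
                                  erna_width = 600,
                                  noise = c("poisson", "none"),
                                  seed = 0L) {
  noise <- match.arg(noise)
  chrom_length <- ceiling(chrom_length / bin_width) * bin_width
  structure(as.list(environment()), class = "genome_fixture_config")
}

# Add a Gaussian bump (expected counts per bin) to a lambda vector.
.add_bump <- function(lambda, bin_width, center, amp, sigma) {
  if (amp <= 0) return(lambda)
  lo <- max(1L, floor((center - 4 * sigma) / bin_width) + 1L)
  hi <- min(length(lambda), ceiling((center + 4 * sigma) / bin_width))
  if (lo > hi) return(lambda)
  mid <- (seq(lo, hi) - 0.5) * bin_width
  lambda[lo:hi] <- lambda[lo:hi] + amp * exp(-(mid - center)^2 /
                                               (2 * sigma^2))
  lambda
}

#' Generate the full synthetic genome fixture
#'
#' Lays out genes, promoter-proximal decoy DHSs and archetype anchors
#' left-to-right along one chromosome with gaps that guarantee every
#' anchor satisfies the distal rule (center > \code{gene_min_dist} from
#' all TSS/TTS, window clear of gene bodies). Plants per-track Gaussian
#' bumps (variant tracks per archetype; expression-scaled H2A.Z/PolII
#' promoter bumps; gene-body H3.1/H3.3 and inverse macroH2A signal),
#' bidirectional eRNA with the configured strand bias, and TF peaks
#' enriched at target archetypes. Counts are Poisson unless
#' \code{noise = "none"}. Fully deterministic given the config seed.
#'
#' @param config a \code{\link{genome_fixture_config}}.
#' @return A \code{genome_fixture} list: \code{genes} (with expression),
#'   \code{dhs} (anchors + decoys), \code{anchors} (distal truth, name =
#'   archetype), \code{tracks} (named raw-count \code{signal_track}s:
#'   H3.1, H3.3, macroH2A, H2A.Z, PolII), \code{erna_plus},
#'   \code{erna_minus}, \code{tf_peaks} (named list), \code{truth}
#'   (archetype labels, directions, planted bias/offsets, TF spec) and
#'   the \code{config}.
#' @export
generate_genome_fixture <- function(config = genome_fixture_config()) {
  stopifnot(inherits(config, "genome_fixture_config"))
  cfg <- config
  bw <- cfg$bin_width
  nbins <- cfg$chrom_length %/% bw
  variant_tracks <- c("H3.1", "H3.3", "macroH2A", "H2A.Z")

  fx <- withr::with_seed(cfg$seed, {
    ## ---- layout: genes and anchors on one line with guaranteed gaps ----
    n_anchor <- length(cfg$archetypes) * cfg$n_per_archetype
    ent <- data.frame(
      kind = c(rep("gene", cfg$n_genes), rep("anchor", n_anchor)),
      idx = c(seq_len(cfg$n_genes), seq_len(n_anchor)))
    ent <- ent[sample.int(nrow(ent)), , drop = FALSE]
    gene_len <- round(runif(cfg$n_genes, 2000, 8000))
    half_box <- ifelse(ent$kind == "gene", gene_len[ent$idx] / 2,
                       cfg$window)
    gap <- round(runif(nrow(ent), 2500, 4000))
    margin <- cfg$window + cfg$gene_min_dist + 1000
    # centers: cumulative boxes + gaps
    box <- 2 * half_box
    center <- margin + cumsum(gap + box) - box / 2
    if (max(center + half_box) > cfg$chrom_length - margin) {
      stop("fixture does not fit: need about ",
           round(max(center + half_box) + margin), " bp but chrom_length is ",
           cfg$chrom_length, "; enlarge chrom_length or reduce entities",
           call. = FALSE)
    }

    gi <- ent$kind == "gene"
    genes <- data.frame(
      chrom = cfg$chrom,
      start = round(center[gi] - half_box[gi]),
      end = round(center[gi] + half_box[gi]),
      strand = sample(c("+", "-"), sum(gi), replace = TRUE),
      name = paste0("gene", ent$idx[gi]),
      biotype = sample(c("mRNA", "lncRNA"), sum(gi), replace = TRUE,
                       prob = c(0.85, 0.15)),
      stringsAsFactors = FALSE)
    genes <- genes[order(genes$start), , drop = FALSE]
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    genes$tts <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
    genes$expression <- rlnorm(nrow(genes), meanlog = 2, sdlog = 1.5)

    ai <- ent$kind == "anchor"
    arch_of <- rep(seq_along(cfg$archetypes), each = cfg$n_per_archetype)
    anchors <- data.frame(
      chrom = cfg$chrom,
      start = round(center[ai]) - 150L,
      end = round(center[ai]) + 150L,
      name = vapply(cfg$archetypes, `[[`, character(1), "name")[
        arch_of[ent$idx[ai]]],
      score = 0, strand = ".",
      center = round(center[ai]),
      archetype = arch_of[ent$idx[ai]],
      stringsAsFactors = FALSE)
    anchors <- anchors[order(anchors$center), , drop = FALSE]
    rownames(anchors) <- NULL
    anchors$anchor_id <- paste0("anchor", seq_len(nrow(anchors)))

    # promoter-proximal decoys (excluded by the distal filter)
    dhs <- anchors[, c("chrom", "start", "end", "name", "score", "strand")]
    dhs$name <- paste0(anchors$anchor_id, ":", dhs$name)
    if (cfg$n_proximal > 0) {
      pg <- genes[sample.int(nrow(genes),
                             min(cfg$n_proximal, nrow(genes))), ]
      pc <- pg$tss + round(runif(nrow(pg), -500, 500))
      decoy <- data.frame(chrom = cfg$chrom, start = pc - 150L,
                          end = pc + 150L,
                          name = paste0("proximal:", pg$name),
                          score = 0, strand = ".",
                          stringsAsFactors = FALSE)
      dhs <- rbind(dhs, decoy)
      dhs <- dhs[order(dhs$start), , drop = FALSE]
      rownames(dhs) <- NULL
    }

    ## ---- expected signal per track ----
    lam <- setNames(lapply(c(variant_tracks, "PolII"), function(t)
      rep(cfg$background, nbins)), c(variant_tracks, "PolII"))
    lam_p <- rep(cfg$erna_background, nbins)
    lam_m <- rep(cfg$erna_background, nbins)

    for (i in seq_len(nrow(anchors))) {
      a <- cfg$archetypes[[anchors$archetype[i]]]
      ctr <- anchors$center[i]
      for (tr in names(a$amp)) {
        if (a$bimodal_sep > 0) {
          for (s in c(-1, 1)) {
            lam[[tr]] <- .add_bump(lam[[tr]], bw,
                                   ctr + a$offsets[[tr]] + s * a$bimodal_sep,
                                   a$amp[[tr]] / 2, a$width / 2)
          }
        } else {
          lam[[tr]] <- .add_bump(lam[[tr]], bw, ctr + a$offsets[[tr]],
                                 a$amp[[tr]], a$width / 2)
        }
      }
      lam$PolII <- .add_bump(lam$PolII, bw, ctr + a$polii_offset,
                             a$polii_amp, a$width / 2)
      dir <- a$direction
      b <- a$erna_bias * dir
      lam_p <- .add_bump(lam_p, bw, ctr, a$erna_amp * (1 + b) / 2,
                         cfg$erna_width / 2)
      lam_m <- .add_bump(lam_m, bw, ctr, a$erna_amp * (1 - b) / 2,
                         cfg$erna_width / 2)
    }

    # promoters: expression-scaled H2A.Z + PolII at the TSS, gene-body
    # H3.1/H3.3 with expression, macroH2A against it
    escale <- rank(genes$expression) / nrow(genes)
    for (i in seq_len(nrow(genes))) {
      lam$H2A.Z <- .add_bump(lam$H2A.Z, bw, genes$tss[i], 50 * escale[i],
                             150)
      lam$PolII <- .add_bump(lam$PolII, bw, genes$tss[i], 30 * escale[i],
                             150)
      body <- (genes$start[i] %/% bw + 1L):(genes$end[i] %/% bw)
      lam$H3.1[body] <- lam$H3.1[body] + 6 * escale[i]
      lam$H3.3[body] <- lam$H3.3[body] + 8 * escale[i]
      lam$macroH2A[body] <- lam$macroH2A[body] + 6 * (1 - escale[i])
    }

    draw <- function(l) if (cfg$noise == "poisson") rpois(length(l), l)
      else l
    tracks <- lapply(names(lam), function(t) {
      signal_track(setNames(list(draw(lam[[t]])), cfg$chrom),
                   bin_width = bw, name = t)
    })
    names(tracks) <- names(lam)
    erna_plus <- signal_track(setNames(list(draw(lam_p)), cfg$chrom),
                              bin_width = bw, name = "eRNA", strand = "+")
    erna_minus <- signal_track(setNames(list(draw(lam_m)), cfg$chrom),
                               bin_width = bw, name = "eRNA", strand = "-")

    ## ---- TF peaks ----
    arch_names <- vapply(cfg$archetypes, `[[`, character(1), "name")
    tf_peaks <- lapply(cfg$tf_spec, function(spec) {
      rate <- ifelse(anchors$name %in% spec$target,
                     pmin(spec$odds * cfg$tf_background_rate, 0.95),
                     cfg$tf_background_rate)
      has <- runif(nrow(anchors)) < rate
      ctr <- anchors$center[has] + round(runif(sum(has), -100, 100))
      data.frame(chrom = cfg$chrom, start = ctr - 100L, end = ctr + 100L,
                 name = ".", score = 0, strand = ".",
                 stringsAsFactors = FALSE)
    })

    list(genes = genes, dhs = dhs, anchors = anchors, tracks = tracks,
         erna_plus = erna_plus, erna_minus = erna_minus,
         tf_peaks = tf_peaks,
         truth = list(
           labels = setNames(anchors$archetype, anchors$anchor_id),
           archetype_names = arch_names,
           directions = vapply(cfg$archetypes, `[[`, numeric(1),
                               "direction"),
           erna_bias = vapply(cfg$archetypes, `[[`, numeric(1),
                              "erna_bias"),
           offsets = lapply(cfg$archetypes, `[[`, "offsets"),
           tf_spec = cfg$tf_spec))
  })
  fx$config <- cfg
  structure(fx, class = "genome_fixture")
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat("genome_fixture:", x$config$chrom, format(x$config$chrom_length),
      "bp |", nrow(x$genes), "genes |", nrow(x$anchors),
      "anchors in", length(x$config$archetypes), "archetypes |",
      "noise:", x$config$noise, "| seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a genome fixture to plain-text files
#'
#' Emits genes.tsv (4+ column gene table with expression), dhs.bed,
#' anchors.bed (name = anchor_id:archetype), one bedGraph per ChIP track,
#' a stranded bedGraph pair for eRNA, and one BED per TF peak set.
#'
#' @param fixture a \code{genome_fixture}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_genome_fixture <- function(fixture, outdir) {
  stopifnot(inherits(fixture, "genome_fixture"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(outdir, "genes.tsv"),
             dhs = file.path(outdir, "dhs.bed"),
             anchors = file.path(outdir, "anchors.bed"))
  write_genes(fixture$genes, paths["genes"])
  write_bed(fixture$dhs, paths["dhs"])
  anchors_bed <- fixture$anchors[, c("chrom", "start", "end")]
  anchors_bed$name <- paste0(fixture$anchors$anchor_id, ":",
                             fixture$anchors$name)
  anchors_bed$score <- 0
  anchors_bed$strand <- "."
  write_bed(anchors_bed, paths["anchors"])
  for (t in names(fixture$tracks)) {
    p <- file.path(outdir, paste0(t, ".bedGraph"))
    write_bedgraph(fixture$tracks[[t]], p)
    paths[t] <- p
  }
  paths["erna_plus"] <- file.path(outdir, "eRNA_plus.bedGraph")
  paths["erna_minus"] <- file.path(outdir, "eRNA_minus.bedGraph")
  write_bedgraph(fixture$erna_plus, paths["erna_plus"])
  write_bedgraph(fixture$erna_minus, paths["erna_minus"])
  for (tf in names(fixture$tf_peaks)) {
    p <- file.path(outdir, paste0("tf_", tf, ".bed"))
    write_bed(fixture$tf_peaks[[tf]], p)
    paths[paste0("tf_", tf)] <- p
  }
  invisible(paths)
}
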