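#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> ms-quant -> profiles ->
#' cluster -> direction -> tf-enrich chain. All values are echoed into
#' the report's provenance block.
#'
#' @param seed global seed; stage seeds derive from it.
#' @param fixture_config a \code{\link{genome_fixture_config}} (its seed
#'   is overridden by \code{seed}).
#' @param ms list describing the simulated ChIP-MS experiment: per-sample
#'   entries \code{list(mixture =, ptm =)} plus \code{input_sample},
#'   \code{n_nucleosomes}, \code{noise_cv}.
#' @param W,b profile window half-width and bin width (bp).
#' @param K,nstart clustering group count and restarts.
#' @param mirror_min_corr minimum mirror-pair score.
#' @param track_priority,asym_threshold orientation tunables.
#' @param flank TF overlap window half-width (bp).
#' @param scale global RPKM display constant.
#' @param pseudocount log2-enrichment pseudocount.
#' @param outdir optional directory; when set, stage outputs are written
#'   as plain files.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 0L,
                            fixture_config = genome_fixture_config(),
                            ms = default_ms_design(),
                            W = 2000, b = 100, K = 16, nstart = 10,
                            mirror_min_corr = 0.8,
                            track_priority = c("H3.3", "H2A.Z"),
                            asym_threshold = 0.2,
                            flank = 500, scale = 1, pseudocount = 1e-4,
                            outdir = NULL) {
  fixture_config$seed <- seed
  structure(as.list(environment()), class = "pipeline_config")
}

#' Default simulated ChIP-MS design
#'
#' Four samples: a whole-chromatin input (mostly canonical nucleosomes,
#' H3K27me3 at 6\%, H3K4me2 low) and three FLAG purifications --
#' heterotypic H2A.Z, heterotypic macroH2A (H3K27me3 at 18\%), and
#' heterotypic H3.3 (active marks up).
#'
#' @param n_nucleosomes pool size per sample.
#' @param noise_cv intensity noise CV.
#' @export
default_ms_design <- function(n_nucleosomes = 10000, noise_cv = 0.1) {
  list(
    input_sample = "input",
    n_nucleosomes = n_nucleosomes,
    noise_cv = noise_cv,
    samples = list(
      input = list(
        mixture = c(mixture_homotypic("H2A", prop = 0.85),
                    mixture_heterotypic("H2A.Z", prop = 0.08),
                    mixture_heterotypic("macroH2A", prop = 0.04),
                    mixture_heterotypic("H3.3", prop = 0.03)),
        ptm = list(H3K27me3 = 0.06, H3K4me2 = 0.01, H3K36me3 = 0.04,
                   H4K16ac = 0.20)),
      "FLAG-H2A.Z" = list(
        mixture = mixture_heterotypic("H2A.Z"),
        ptm = list(H3K27me3 = 0.02, H3K4me2 = 0.20, H3K36me3 = 0.15,
                   H4K16ac = 0.40)),
      "FLAG-macroH2A" = list(
        mixture = mixture_heterotypic("macroH2A"),
        ptm = list(H3K27me3 = 0.18, H3K4me2 = 0.005, H3K36me3 = 0.01,
                   H4K16ac = 0.10)),
      "FLAG-H3.3" = list(
        mixture = mixture_heterotypic("H3.3"),
        ptm = list(H3K27me3 = 0.03, H3K4me2 = 0.12, H3K36me3 = 0.07,
                   H4K16ac = 0.50))))
}

#' Run the full synthetic pipeline
#'
#' simulate -> ms-quant -> profiles -> cluster -> direction -> tf-enrich,
#' deterministic given \code{config$seed}. Any stage failure halts with
#' the stage name and cause.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return a \code{pipeline_report} list: \code{ms} (variant fractions,
#'   PTM abundances, enrichment heat-map values), \code{genomics}
#'   (anchor set, cluster result, mirror pairs, directionality report,
#'   eRNA cluster comparisons, TF enrichment), \code{counts} per stage,
#'   and \code{provenance} (all tunables).
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  counts <- list()

  ## ---- simulate ----
  fx <- stage("simulate", generate_genome_fixture(config$fixture_config))
  ms_tables <- stage("simulate", {
    dsg <- config$ms
    tabs <- lapply(seq_along(dsg$samples), function(i) {
      nm <- names(dsg$samples)[i]
      pool <- generate_nucleosome_pool(dsg$samples[[i]]$mixture,
                                       n = dsg$n_nucleosomes,
                                       seed = config$seed + i)
      generate_peptide_table(pool, sample_id = nm,
                             ptm_profile = dsg$samples[[i]]$ptm,
                             noise_cv = dsg$noise_cv,
                             seed = config$seed + 100L + i)
    })
    do.call(rbind, tabs)
  })
  counts$peptide_records <- nrow(ms_tables)

  ## ---- ms-quant ----
  ms_report <- stage("ms-quant", {
    fams <- build_families(ms_tables)
    marks <- unique(unlist(lapply(config$ms$samples,
                                  function(s) names(s$ptm))))
    abund <- ptm_relative_abundance(fams, marks = marks)
    input_nm <- config$ms$input_sample
    enr <- log2_enrichment(
      abund[abund$sample != input_nm, , drop = FALSE],
      abund[abund$sample == input_nm, , drop = FALSE],
      pseudocount = config$pseudocount)
    list(h2a_fractions = h2a_variant_fractions(fams),
         h3_fractions = h3_variant_fractions(fams),
         ptm_abundance = abund, enrichment = enr)
  })

  ## ---- profiles ----
  prof <- stage("profiles", {
    anchors <- filter_distal(fx$dhs, fx$genes,
                             min_dist = fx$config$gene_min_dist)
    tracks <- lapply(fx$tracks, rpkm_normalize, scale = config$scale)
    variant_tracks <- c("H3.1", "H3.3", "macroH2A", "H2A.Z")
    mats <- lapply(tracks[variant_tracks], profile_matrix,
                   anchors = anchors, W = config$W, b = config$b)
    polii <- profile_matrix(tracks$PolII, anchors, W = config$W,
                            b = config$b)
    list(anchors = anchors, matrices = mats, polii = polii,
         tracks = tracks)
  })
  counts$distal_anchors <- nrow(prof$anchors$anchors)

  ## ---- cluster ----
  clus <- stage("cluster", {
    res <- kmeans_profiles(prof$matrices, K = config$K,
                           seed = config$seed, nstart = config$nstart)
    res <- mirror_pair(res, min_corr = config$mirror_min_corr)
    classify_and_orient(res, track_priority = config$track_priority,
                        threshold = config$asym_threshold)
  })
  counts$groups <- clus$K
  counts$mirror_pairs <- nrow(clus$mirror_pairs)
  counts$final_clusters <- length(unique(clus$merged))

  ## ---- direction ----
  direction <- stage("direction", {
    skew <- polii_skew(prof$polii, clus)
    bias <- strand_bias(fx$erna_plus, fx$erna_minus, clus, W = config$W,
                        seed = config$seed)
    totals <- bias$per_anchor$P + bias$per_anchor$M
    cl <- clus$merged[clus$labels]
    ids <- sort(unique(cl))
    comparisons <- do.call(rbind, lapply(seq_along(ids), function(i) {
      do.call(rbind, lapply(seq_along(ids), function(j) {
        if (i >= j) return(NULL)
        ct <- compare_cluster_signal(totals[cl == ids[i]],
                                     totals[cl == ids[j]],
                                     alternative = "less")
        data.frame(cluster_a = ids[i], cluster_b = ids[j],
                   U = ct$statistic, p_a_less_b = ct$p.value,
                   n_a = ct$n_a, n_b = ct$n_b)
      }))
    }))
    list(polii = skew, erna = bias, comparisons = comparisons)
  })

  ## ---- tf-enrich ----
  enrich <- stage("tf-enrich",
                  tf_enrichment_table(clus, fx$tf_peaks,
                                      flank = config$flank))

  report <- structure(
    list(ms = ms_report,
         genomics = list(fixture = fx, anchors = prof$anchors,
                         clustering = clus, direction = direction,
                         tf_enrichment = enrich),
         counts = counts,
         provenance = c(config,
                        list(version = as.character(
                          utils::packageVersion("variantscape"))))),
    class = "pipeline_report")
  if (!is.null(config$outdir)) write_pipeline_report(report, config$outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report | seed", x$provenance$seed, "\n")
  cat("  peptide records:", x$counts$peptide_records, "\n")
  cat("  distal anchors:", x$counts$distal_anchors, "\n")
  cat("  groups:", x$counts$groups, "| mirror pairs:",
      x$counts$mirror_pairs, "| final clusters:",
      x$counts$final_clusters, "\n")
  cat("  PolII concordance:",
      round(x$genomics$direction$polii$concordance, 3), "\n")
  invisible(x)
}

#' Write the pipeline report's tables to a directory
#'
#' @param report a \code{pipeline_report}.
#' @param outdir output directory (created if needed).
#' @export
write_pipeline_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  clus <- report$genomics$clustering
  a <- clus$anchors
  out_bed <- data.frame(chrom = a$chrom, start = a$start, end = a$end,
                        name = paste0(a$name, ":cluster",
                                      clus$merged[clus$labels], ":",
                                      clus$orientation),
                        score = clus$labels, strand = ".")
  write_bed(out_bed, file.path(outdir, "clustered_anchors.bed"))
  write.csv(as.data.frame(report$genomics$tf_enrichment),
            file.path(outdir, "tf_enrichment.csv"), row.names = FALSE)
  write.csv(report$genomics$direction$polii$by_cluster,
            file.path(outdir, "polii_skew.csv"), row.names = FALSE)
  write.csv(report$genomics$direction$erna$by_cluster,
            file.path(outdir, "erna_strand_bias.csv"), row.names = FALSE)
  write.csv(report$genomics$direction$comparisons,
            file.path(outdir, "erna_cluster_comparisons.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$ms$ptm_abundance),
            file.path(outdir, "ptm_abundance.csv"), row.names = FALSE)
  write.csv(as.data.frame(report$ms$enrichment),
            file.path(outdir, "ptm_log2_enrichment.csv"),
            row.names = FALSE)
  invisible(outdir)
}
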