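#' Group peptide records into peptide families
#'
#' A family is the set of all modified and unmodified forms sharing one
#' backbone: key = (sample, histone, span, sequence). Duplicate records
#' (same key and same mods) are summed before partitioning, and mod strings
#' are canonicalized (tokens sorted by residue position).
#'
#' @param table a \code{peptide_table} data.frame (see
#'   \code{\link{read_peptide_table}}).
#' @return A \code{peptide_families} data.frame: the aggregated records
#'   plus a \code{family} key column and a \code{family_total} column
#'   (summed intensity of all forms in the family).
#' @export
build_families <- function(table) {
  df <- as.data.frame(table)
  if (any(df$intensity < 0)) {
    stop("negative peptide intensity", call. = FALSE)
  }
  df$mods[is.na(df$mods)] <- ""
  df$mods <- vapply(df$mods, function(m) .canonical_mods(.mod_tokens(m)),
                    character(1), USE.NAMES = FALSE)
  df$family <- paste(df$sample, df$histone,
                     df$span_start, df$span_end, df$sequence, sep = "|")
  agg <- aggregate(intensity ~ sample + histone + span_start + span_end +
                     sequence + mods + family, data = df, FUN = sum)
  totals <- tapply(agg$intensity, agg$family, sum)
  agg$family_total <- as.numeric(totals[agg$family])
  agg <- agg[order(agg$family, agg$mods), ]
  rownames(agg) <- NULL
  structure(agg, class = c("peptide_families", "data.frame"))
}

.as_families <- function(x) {
  if (inherits(x, "peptide_families")) x else build_families(x)
}

#' PTM relative abundance from peptide families
#'
#' The relative abundance of a modification is its summed intensity divided
#' by the summed intensity of all modified and unmodified peptides sharing
#' the same backbone sequence(s). For a single mark (e.g. "H3K27me3") every
#' co-modified form carrying the mark counts toward the numerator, and all
#' backbone families covering the residue (here: both 27-40 variant
#' peptides) are pooled. With \code{combination = TRUE} the query names a
#' full form ("H3K5acK8ac" style is expressed as histone + exact mods
#' string) and only the exactly matching form counts.
#'
#' @param families a \code{peptide_families} (or raw \code{peptide_table}).
#' @param marks character vector of single-mark names ("H3K27me3").
#' @param combinations optional character vector of combinatorial queries
#'   of the form "H3:K9acK14ac" (histone, colon, exact canonical mods
#'   string); scored by exact form match within the covering families.
#' @return A \code{ptm_abundance} data.frame: \code{sample}, \code{mark},
#'   \code{abundance} in [0,1] (\code{NA} with a warning when no family in
#'   that sample covers the mark — missing, not zero), \code{kind}
#'   ("single" or "combination").
#' @export
#' @examples
#' pool <- generate_nucleosome_pool(mixture_homotypic("H2A"), 100, seed = 1)
#' tab <- generate_peptide_table(pool, ptm_profile = list(H3K27me3 = 0.18))
#' ptm_relative_abundance(tab, marks = "H3K27me3")
ptm_relative_abundance <- function(families, marks = character(0),
                                   combinations = character(0)) {
  fam <- .as_families(families)
  samples <- unique(fam$sample)
  out <- list()
  for (s in samples) {
    fs <- fam[fam$sample == s, , drop = FALSE]
    for (mk in marks) {
      p <- .parse_mark(mk)
      targets <- .mark_targets(mk)
      sel <- fs$sequence %in% targets$sequence &
        fs$span_start <= p$residue & fs$span_end >= p$residue
      if (!any(sel)) {
        warning("mark ", mk, " has no covering peptide family in sample ",
                s, "; reported as missing", call. = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          sample = s, mark = mk, abundance = NA_real_, kind = "single")
        next
      }
      sub <- fs[sel, , drop = FALSE]
      total <- sum(sub$intensity)
      if (total <= 0) stop("family total is zero for mark ", mk,
                           " in sample ", s, call. = FALSE)
      carries <- vapply(sub$mods,
                        function(m) p$token %in% .mod_tokens(m),
                        logical(1), USE.NAMES = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        sample = s, mark = mk,
        abundance = sum(sub$intensity[carries]) / total, kind = "single")
    }
    for (cq in combinations) {
      parts <- strsplit(cq, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop("combination query must look like 'H3:K9acK14ac', got '",
             cq, "'", call. = FALSE)
      }
      hist <- parts[1]
      form <- .canonical_mods(.mod_tokens(parts[2]))
      toks <- .mod_tokens(form)
      pos <- as.integer(sub("^[KRSTY](\\d+).*$", "\\1", toks))
      sel <- fs$histone == hist &
        fs$span_start <= min(pos) & fs$span_end >= max(pos)
      if (!any(sel)) {
        warning("combination ", cq, " has no covering family in sample ",
                s, "; reported as missing", call. = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          sample = s, mark = cq, abundance = NA_real_, kind = "combination")
        next
      }
      sub <- fs[sel, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        sample = s, mark = cq,
        abundance = sum(sub$intensity[sub$mods == form]) /
          sum(sub$intensity),
        kind = "combination")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("ptm_abundance", "data.frame"))
}

#' Log2 IP/input enrichment of PTM abundances
#'
#' For every (sample, mark) in the IP table with a matching mark in the
#' input table: \code{log2((a_ip + p) / (a_in + p))} with pseudocount
#' \code{p}. The value is 0 whenever both abundances are equal (including
#' both zero), for any positive pseudocount.
#'
#' @param ip \code{ptm_abundance} for one or more FLAG-IP samples.
#' @param input \code{ptm_abundance} for the input (whole-chromatin)
#'   sample; must contain a single sample.
#' @param pseudocount positive absolute-fraction pseudocount (default
#'   1e-4).
#' @return An \code{enrichment_heatmap} data.frame: \code{sample},
#'   \code{mark}, \code{ip_abundance}, \code{input_abundance},
#'   \code{log2_ratio}; the pseudocount is kept as an attribute.
#' @export
log2_enrichment <- function(ip, input, pseudocount = 1e-4) {
  stopifnot(pseudocount > 0)
  ipd <- as.data.frame(ip)
  ind <- as.data.frame(input)
  if (length(unique(ind$sample)) != 1) {
    stop("input table must contain exactly one sample", call. = FALSE)
  }
  m <- merge(ipd, ind[, c("mark", "abundance")], by = "mark",
             suffixes = c("_ip", "_in"))
  if (nrow(m) == 0) {
    stop("no shared marks between IP and input tables", call. = FALSE)
  }
  out <- data.frame(
    sample = m$sample, mark = m$mark,
    ip_abundance = m$abundance_ip, input_abundance = m$abundance_in,
    log2_ratio = log2((m$abundance_ip + pseudocount) /
                        (m$abundance_in + pseudocount)))
  out <- out[order(out$sample, out$mark), ]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_heatmap", "data.frame"),
            pseudocount = pseudocount)
}

.family_total_by_sequence <- function(fs, sequence) {
  sel <- fs$sequence == sequence
  if (!any(sel)) return(NA_real_)
  sum(fs$intensity[sel])
}

#' H2A-family variant stoichiometry by reference-peptide normalization
#'
#' Each variant-specific peptide total (canonical H2A: KGNYAER; H2A.Z
#' 1-19; macroH2A 4-14) is divided by each of the four reference-peptide
#' totals (H2Ac_1..H2Ac_4, which track the whole H2A family), yielding four
#' ratios per variant. The per-variant summary is the arithmetic mean of
#' the four, and the three summaries are renormalized to sum to 1, giving
#' the fraction each variant contributes to the H2A-family copies of the
#' pool. Family totals sum over all modified forms.
#'
#' @param families \code{peptide_families} (or raw \code{peptide_table}).
#' @param allow_missing if TRUE, a variant peptide absent from the table is
#'   treated as absent from the pool (fraction 0); default FALSE rejects.
#' @return A \code{variant_fractions} object: list with \code{sample},
#'   \code{family = "H2A-family"}, \code{fractions} (named, sums to 1) and
#'   \code{per_reference_ratios} (variant x reference matrix, kept for QC).
#'   With several samples, a named list of such objects.
#' @export
h2a_variant_fractions <- function(families, allow_missing = FALSE) {
  fam <- .as_families(families)
  refs <- reference_peptides()
  ref_seqs <- refs$sequence[refs$name %in%
                              c("H2Ac_1", "H2Ac_2", "H2Ac_3", "H2Ac_4")]
  var_seqs <- c("H2A" = "KGNYAER",
                "H2A.Z" = "AGGKAGKDSGKAKTKAVSR",
                "macroH2A" = "GGKKKSTKTSR")
  per_sample <- lapply(unique(fam$sample), function(s) {
    fs <- fam[fam$sample == s, , drop = FALSE]
    ref_tot <- vapply(ref_seqs, function(q) .family_total_by_sequence(fs, q),
                      numeric(1))
    if (any(is.na(ref_tot)) || any(ref_tot <= 0)) {
      stop("sample ", s, ": all four H2A reference peptide families must ",
           "be present with positive totals", call. = FALSE)
    }
    var_tot <- vapply(var_seqs, function(q) .family_total_by_sequence(fs, q),
                      numeric(1))
    if (any(is.na(var_tot))) {
      if (!allow_missing) {
        stop("sample ", s, ": variant peptide(s) missing: ",
             paste(names(var_seqs)[is.na(var_tot)], collapse = ", "),
             "; set allow_missing = TRUE to treat as absent", call. = FALSE)
      }
      var_tot[is.na(var_tot)] <- 0
    }
    ratios <- outer(var_tot, ref_tot, "/")
    dimnames(ratios) <- list(names(var_seqs),
                             c("H2Ac_1", "H2Ac_2", "H2Ac_3", "H2Ac_4"))
    summary_ratio <- rowMeans(ratios)
    fractions <- summary_ratio / sum(summary_ratio)
    structure(list(sample = s, family = "H2A-family",
                   fractions = fractions,
                   per_reference_ratios = ratios),
              class = "variant_fractions")
  })
  names(per_sample) <- unique(fam$sample)
  if (length(per_sample) == 1) per_sample[[1]] else per_sample
}

#' H3-family variant stoichiometry from the 27-40 peptide pair
#'
#' The canonical (H3.1 + H3.2, KSAPATGGVKKPHR) and H3.3 (KSAPSTGGVKKPHR)
#' 27-40 peptides differ by one residue and ionize near-identically, so
#' their family totals are compared directly:
#' \code{f(H3.3) = I_3.3 / (I_canonical + I_3.3)}. H3.1 and H3.2 are not
#' distinguishable and are reported merged.
#'
#' @inheritParams h2a_variant_fractions
#' @return A \code{variant_fractions} object (or named list across
#'   samples) with fractions \code{H3-canonical} and \code{H3.3}.
#' @export
h3_variant_fractions <- function(families) {
  fam <- .as_families(families)
  per_sample <- lapply(unique(fam$sample), function(s) {
    fs <- fam[fam$sample == s, , drop = FALSE]
    i_can <- .family_total_by_sequence(fs, "KSAPATGGVKKPHR")
    i_33 <- .family_total_by_sequence(fs, "KSAPSTGGVKKPHR")
    i_can <- if (is.na(i_can)) 0 else i_can
    i_33 <- if (is.na(i_33)) 0 else i_33
    if (i_can + i_33 <= 0) {
      stop("sample ", s, ": both H3 27-40 peptide totals are zero",
           call. = FALSE)
    }
    f33 <- i_33 / (i_can + i_33)
    ratios <- matrix(c(i_can, i_33) / (i_can + i_33), ncol = 1,
                     dimnames = list(c("H3-canonical", "H3.3"), "H3_27_40"))
    structure(list(sample = s, family = "H3-family",
                   fractions = c("H3-canonical" = 1 - f33, "H3.3" = f33),
                   per_reference_ratios = ratios),
              class = "variant_fractions")
  })
  names(per_sample) <- unique(fam$sample)
  if (length(per_sample) == 1) per_sample[[1]] else per_sample
}

#' @export
print.variant_fractions <- function(x, ...) {
  cat("Histone variant stoichiometry (", x$family, "), sample ",
      x$sample, "\n", sep = "")
  print(round(x$fractions, 4))
  invisible(x)
}
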