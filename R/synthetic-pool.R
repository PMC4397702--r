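#' Simulate a pool of purified mononucleosomes
#'
#' Draws \code{n} nucleosomes from a mixture of composition patterns. Every
#' nucleosome carries exactly two H3-family slots (each H3.1, H3.2 or H3.3)
#' and two H2A-family slots (each H2A, H2A.Z or macroH2A). A "heterotypic"
#' pattern pairs one variant copy with one canonical copy in the same slot
#' pair; a "homotypic" pattern carries two identical copies.
#'
#' @param mixture_spec list of patterns; each element is a list with fields
#'   \code{h3} (character(2) from H3.1/H3.2/H3.3), \code{h2a} (character(2)
#'   from H2A/H2A.Z/macroH2A) and \code{prop} (mixture proportion).
#'   Proportions must sum to 1 (within 1e-9). See
#'   \code{\link{mixture_heterotypic}} for common shortcuts.
#' @param n number of nucleosomes to draw (>= 1).
#' @param seed integer seed; fully determines the pool.
#' @param purified_by optional variant name; when given, every pattern must
#'   carry at least one copy of that variant (a FLAG purification by V can
#'   only contain nucleosomes with >= 1 slot equal to V).
#' @return A \code{nucleosome_pool}: data.frame with columns \code{h3_a},
#'   \code{h3_b}, \code{h2a_a}, \code{h2a_b}, \code{pattern}.
#' @export
#' @examples
#' pool <- generate_nucleosome_pool(mixture_heterotypic("H2A.Z"), n = 1000, seed = 1)
#' variant_copy_fractions(pool)$h2a   # canonical H2A is half of all copies
generate_nucleosome_pool <- function(mixture_spec, n, seed = 1L,
                                     purified_by = NULL) {
  stopifnot(is.list(mixture_spec), length(mixture_spec) >= 1, n >= 1)
  props <- vapply(mixture_spec, function(p) as.numeric(p$prop), numeric(1))
  if (abs(sum(props) - 1) > 1e-9) {
    stop("mixture proportions must sum to 1 (got ", sum(props), ")",
         call. = FALSE)
  }
  h3_levels <- c("H3.1", "H3.2", "H3.3")
  h2a_levels <- c("H2A", "H2A.Z", "macroH2A")
  for (p in mixture_spec) {
    if (length(p$h3) != 2 || length(p$h2a) != 2) {
      stop("each pattern needs exactly 2 H3 slots and 2 H2A-family slots",
           call. = FALSE)
    }
    if (!all(p$h3 %in% h3_levels) || !all(p$h2a %in% h2a_levels)) {
      stop("unknown histone in pattern: H3 slots from {",
           paste(h3_levels, collapse = ", "), "}, H2A slots from {",
           paste(h2a_levels, collapse = ", "), "}", call. = FALSE)
    }
    if (!is.null(purified_by) &&
        !(purified_by %in% c(p$h3, p$h2a))) {
      stop("pattern without a ", purified_by,
           " copy cannot appear in a pool purified by ", purified_by,
           call. = FALSE)
    }
  }
  idx <- withr::with_seed(seed, {
    sample.int(length(mixture_spec), size = n, replace = TRUE, prob = props)
  })
  pool <- data.frame(
    h3_a = vapply(mixture_spec, function(p) p$h3[1], character(1))[idx],
    h3_b = vapply(mixture_spec, function(p) p$h3[2], character(1))[idx],
    h2a_a = vapply(mixture_spec, function(p) p$h2a[1], character(1))[idx],
    h2a_b = vapply(mixture_spec, function(p) p$h2a[2], character(1))[idx],
    pattern = idx,
    stringsAsFactors = FALSE
  )
  structure(pool, class = c("nucleosome_pool", "data.frame"),
            seed = seed, purified_by = purified_by,
            mixture = mixture_spec)
}

#' Common nucleosome mixture shortcuts
#'
#' \code{mixture_heterotypic(v)} is a pure pool of nucleosomes carrying one
#' copy of variant \code{v} paired with one canonical copy in the same slot
#' pair; \code{mixture_homotypic(v)} carries two copies of \code{v}. The
#' other family's slots are canonical.
#'
#' @param variant one of H3.3, H2A.Z, macroH2A (or a canonical histone for
#'   \code{mixture_homotypic}).
#' @param prop mixture proportion of the returned pattern (default 1).
#' @return a one-element mixture_spec list, concatenable with \code{c()}.
#' @export
mixture_heterotypic <- function(variant, prop = 1) {
  pat <- switch(variant,
    "H3.3" = list(h3 = c("H3.1", "H3.3"), h2a = c("H2A", "H2A")),
    "H2A.Z" = list(h3 = c("H3.1", "H3.1"), h2a = c("H2A", "H2A.Z")),
    "macroH2A" = list(h3 = c("H3.1", "H3.1"), h2a = c("H2A", "macroH2A")),
    stop("no heterotypic pattern for '", variant, "'", call. = FALSE))
  pat$prop <- prop
  list(pat)
}

#' @rdname mixture_heterotypic
#' @export
mixture_homotypic <- function(variant, prop = 1) {
  pat <- switch(variant,
    "H3.1" = , "H3.2" = , "H3.3" =
      list(h3 = c(variant, variant), h2a = c("H2A", "H2A")),
    "H2A" = , "H2A.Z" = , "macroH2A" =
      list(h3 = c("H3.1", "H3.1"), h2a = c(variant, variant)),
    stop("unknown histone '", variant, "'", call. = FALSE))
  pat$prop <- prop
  list(pat)
}

#' Copy counts and fractions of each histone variant in a pool
#'
#' @param pool a \code{nucleosome_pool}.
#' @return \code{variant_copy_counts}: list with integer tables \code{h3}
#'   and \code{h2a} (copies per variant; each family totals \code{2 * n}).
#'   \code{variant_copy_fractions}: same shape, normalized per family, with
#'   H3.1 and H3.2 merged as \code{"H3-canonical"}.
#' @export
variant_copy_counts <- function(pool) {
  stopifnot(inherits(pool, "nucleosome_pool"))
  h3 <- table(factor(c(pool$h3_a, pool$h3_b),
                     levels = c("H3.1", "H3.2", "H3.3")))
  h2a <- table(factor(c(pool$h2a_a, pool$h2a_b),
                      levels = c("H2A", "H2A.Z", "macroH2A")))
  list(h3 = h3, h2a = h2a)
}

#' @rdname variant_copy_counts
#' @export
variant_copy_fractions <- function(pool) {
  cc <- variant_copy_counts(pool)
  h3 <- c("H3-canonical" = unname(cc$h3[["H3.1"]] + cc$h3[["H3.2"]]),
          "H3.3" = unname(cc$h3[["H3.3"]]))
  h2a <- setNames(as.numeric(cc$h2a), names(cc$h2a))
  list(h3 = h3 / sum(h3), h2a = h2a / sum(h2a))
}

# Size of the copy pool a peptide's intensity tracks.
.basis_copies <- function(basis, pool) {
  cc <- variant_copy_counts(pool)
  n <- nrow(pool)
  switch(basis,
    "H2A-family" = sum(cc$h2a),
    "H2A" = cc$h2a[["H2A"]],
    "H2A.Z" = cc$h2a[["H2A.Z"]],
    "macroH2A" = cc$h2a[["macroH2A"]],
    "H3-family" = sum(cc$h3),
    "H3-canonical" = cc$h3[["H3.1"]] + cc$h3[["H3.2"]],
    "H3.3" = cc$h3[["H3.3"]],
    "H4-family" = 2L * n,
    stop("unknown basis '", basis, "'", call. = FALSE))
}

#' Forward-simulate a peptide intensity table from a nucleosome pool
#'
#' Reference-peptide intensities are proportional to the total copies of
#' their histone family in the pool; variant-specific peptide intensities to
#' that variant's copies. Each peptide family's intensity is split across
#' modified forms deterministically according to \code{ptm_profile}
#' (independent per-site fractions, so co-modified forms get the product of
#' marginals), then multiplied by log-normal noise with the requested
#' coefficient of variation (mean-preserving parameterization). With
#' \code{noise_cv = 0} and unit response factors the table inverts exactly
#' under the quantifiers in this package.
#'
#' @param pool a \code{nucleosome_pool}.
#' @param sample_id sample name written into the table.
#' @param ptm_profile named list/vector, mark name (e.g. \code{"H3K27me3"})
#'   to fraction in [0, 1]: the proportion of the residue's copies carrying
#'   the mark.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   intensity noise (>= 0).
#' @param response_factors optional named positive scalars (names = peptide
#'   sequences) emulating peptide-specific ionization response; unknown
#'   sequences are rejected. Default: all 1 (no response bias).
#' @param seed integer seed for the noise draws.
#' @return A \code{peptide_table} data.frame with columns \code{sample},
#'   \code{histone}, \code{span_start}, \code{span_end}, \code{sequence},
#'   \code{mods}, \code{intensity}.
#' @export
generate_peptide_table <- function(pool, sample_id = "sample1",
                                   ptm_profile = list(), noise_cv = 0,
                                   response_factors = NULL, seed = 1L) {
  stopifnot(inherits(pool, "nucleosome_pool"), noise_cv >= 0)
  peptides <- reference_peptides()
  rf <- setNames(rep(1, nrow(peptides)), peptides$sequence)
  if (!is.null(response_factors)) {
    bad <- setdiff(names(response_factors), peptides$sequence)
    if (length(bad)) {
      stop("response_factors for unknown peptide(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(unlist(response_factors) <= 0)) {
      stop("response factors must be positive", call. = FALSE)
    }
    rf[names(response_factors)] <- unlist(response_factors)
  }
  marks <- if (length(ptm_profile)) {
    lapply(names(ptm_profile), .parse_mark)
  } else list()
  fr <- unlist(ptm_profile, use.names = FALSE)
  if (length(fr) && (any(fr < 0) || any(fr > 1))) {
    stop("ptm_profile fractions must lie in [0, 1]", call. = FALSE)
  }

  rows <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides[i, ]
    total <- .basis_copies(pep$basis, pool) * rf[[pep$sequence]]
    # marks landing on this peptide
    hit <- vapply(marks, function(m) {
      (pep$histone == m$histone || pep$basis == m$histone) &&
        pep$span_start <= m$residue && pep$span_end >= m$residue
    }, logical(1))
    site_marks <- marks[hit]
    site_frac <- fr[hit]
    k <- length(site_marks)
    combos <- if (k == 0) matrix(FALSE, 1, 0) else
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
    share <- apply(combos, 1, function(on) {
      prod(ifelse(on, site_frac, 1 - site_frac))
    })
    mods <- apply(combos, 1, function(on) {
      .canonical_mods(vapply(site_marks[on], `[[`, character(1), "token"))
    })
    keep <- share > 0
    rows[[i]] <- data.frame(
      sample = sample_id, histone = pep$histone,
      span_start = pep$span_start, span_end = pep$span_end,
      sequence = pep$sequence, mods = mods[keep],
      intensity = total * share[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (noise_cv > 0) {
    s2 <- log(1 + noise_cv^2)
    noise <- withr::with_seed(seed, {
      exp(rnorm(nrow(out), mean = -s2 / 2, sd = sqrt(s2)))
    })
    out$intensity <- out$intensity * noise
  }
  structure(out, class = c("peptide_table", "data.frame"),
            noise_cv = noise_cv, seed = seed)
}

#' Read / write a peptide intensity table (CSV)
#'
#' Columns: sample, histone, span_start, span_end, sequence, mods,
#' intensity. \code{mods} is a canonical concatenation of residue tokens
#' ("" for the unmodified form, "K5acK8ac" for combinations).
#'
#' @param path file path (gzip transparent on read).
#' @param table a \code{peptide_table} data.frame.
#' @export
read_peptide_table <- function(path) {
  out <- read.table(path, header = TRUE, sep = ",", quote = '"',
                    colClasses = c(sample = "character",
                                   histone = "character",
                                   sequence = "character",
                                   mods = "character"),
                    stringsAsFactors = FALSE)
  need <- c("sample", "histone", "span_start", "span_end",
            "sequence", "mods", "intensity")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols)) {
    stop("peptide table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out$mods[is.na(out$mods)] <- ""
  structure(out[need], class = c("peptide_table", "data.frame"))
}

#' @rdname read_peptide_table
#' @export
write_peptide_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = ",", quote = TRUE,
              row.names = FALSE)
  invisible(path)
}
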