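#' Reference and variant-specific histone peptides
#'
#' The fixed peptide set used for histone-variant stoichiometry and PTM
#' quantification from bottom-up MS of propionylated, trypsin-digested
#' histones. Four canonical-H2A-derived peptides (H2Ac_1..H2Ac_4) act as
#' reference peptides tracking the total H2A-family amount; variant-specific
#' peptides track canonical H2A (KGNYAER), macroH2A (GGKKKSTKTSR) and H2A.Z
#' (AGGKAGKDSGKAKTKAVSR). For the H3 family, the 27-40 peptide pair
#' (KSAPATGGVKKPHR for H3.1/H3.2, KSAPSTGGVKKPHR for H3.3; one A31S
#' substitution) is compared directly. H3.1 and H3.2 are merged throughout
#' ("canonical H3"): no tryptic peptide distinguishes them. Additional H3
#' tail and H4 peptides carry the commonly assayed PTM sites.
#'
#' @return A data.frame with one row per peptide: \code{name},
#'   \code{histone} (family label used in peptide tables), \code{sequence},
#'   \code{span_start}, \code{span_end} (1-based inclusive residue span) and
#'   \code{basis}, the copy pool whose size the peptide's intensity tracks
#'   (\code{"H2A-family"}, \code{"H2A"}, \code{"H2A.Z"}, \code{"macroH2A"},
#'   \code{"H3-family"}, \code{"H3-canonical"}, \code{"H3.3"},
#'   \code{"H4-family"}).
#' @export
#' @examples
#' reference_peptides()
reference_peptides <- function() {
  data.frame(
    name = c("H2Ac_1", "H2Ac_2", "H2Ac_3", "H2Ac_4",
             "H2Ac", "macroH2A", "H2A.Z",
             "H3_3_8", "H3_9_17", "H3_18_26",
             "H3canonical_27_40", "H3.3_27_40",
             "H4_4_17"),
    histone = c(rep("H2A", 7), rep("H3", 5), "H4"),
    sequence = c("GKQGGKAR", "AKAKTR", "AGLQFPVGR", "HLQLAIR",
                 "KGNYAER", "GGKKKSTKTSR", "AGGKAGKDSGKAKTKAVSR",
                 "TKQTAR", "KSTGGKAPR", "KQLATKAAR",
                 "KSAPATGGVKKPHR", "KSAPSTGGVKKPHR",
                 "GKGGKGLGKGGAKR"),
    span_start = c(4L, 12L, 21L, 82L, 36L, 4L, 1L, 3L, 9L, 18L, 27L, 27L, 4L),
    span_end   = c(11L, 17L, 29L, 88L, 42L, 14L, 19L, 8L, 17L, 26L, 40L, 40L, 17L),
    basis = c(rep("H2A-family", 4), "H2A", "macroH2A", "H2A.Z",
              "H3-family", "H3-family", "H3-family", "H3-canonical", "H3.3",
              "H4-family"),
    stringsAsFactors = FALSE
  )
}

# Mark strings look like "H3K27me3", "H4K16ac", "H2A.ZK7ac": histone label,
# residue letter + 1-based position, then the modification.
.parse_mark <- function(mark) {
  m <- regmatches(mark, regexec(
    "^(H2A\\.Z|macroH2A|H2A|H2B|H3\\.3|H3|H4)([KRSTY])(\\d+)(me[123]|ac|ph|ub)$",
    mark))[[1]]
  if (length(m) == 0) {
    stop("Cannot parse modification name '", mark,
         "' (expected e.g. 'H3K27me3', 'H4K16ac')", call. = FALSE)
  }
  list(mark = mark, histone = m[2], residue = as.integer(m[4]),
       token = paste0(m[3], m[4], m[5]))
}

# Split a canonical mods string ("K5acK8ac") into residue tokens.
.mod_tokens <- function(mods) {
  if (is.na(mods) || !nzchar(mods)) return(character(0))
  regmatches(mods, gregexpr("[KRSTY]\\d+(me[123]|ac|ph|ub)", mods))[[1]]
}

# Canonical ordering of tokens within a mods string: by residue position.
.canonical_mods <- function(tokens) {
  if (length(tokens) == 0) return("")
  pos <- as.integer(sub("^[KRSTY](\\d+).*$", "\\1", tokens))
  paste0(tokens[order(pos)], collapse = "")
}

# Which peptides of the built-in set does a mark land on? Match on histone
# family (or exact variant label for variant-specific peptides) and on the
# residue falling inside the peptide span.
.mark_targets <- function(mark, peptides = reference_peptides()) {
  p <- .parse_mark(mark)
  hist_match <- peptides$histone == p$histone | peptides$basis == p$histone
  span_match <- peptides$span_start <= p$residue & peptides$span_end >= p$residue
  peptides[hist_match & span_match, , drop = FALSE]
}
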