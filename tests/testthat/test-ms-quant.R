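pep_row <- function(sample, histone, s, e, seq, mods, intensity) {
  data.frame(sample = sample, histone = histone, span_start = s,
             span_end = e, sequence = seq, mods = mods,
             intensity = intensity, stringsAsFactors = FALSE)
}

test_that("build_families partitions by (sample, histone, span, sequence)", {
  tab <- rbind(
    pep_row("a", "H3", 27, 40, "KSAPATGGVKKPHR", "K27me3", 3),
    pep_row("a", "H3", 27, 40, "KSAPATGGVKKPHR", "", 1),
    pep_row("b", "H3", 27, 40, "KSAPATGGVKKPHR", "", 5))
  fam <- build_families(tab)
  expect_identical(length(unique(fam$family)), 2L)
  expect_identical(sum(fam$sample == "a"), 2L)

  # duplicated identical records are summed into one member
  dup <- rbind(pep_row("a", "H3", 27, 40, "KSAPATGGVKKPHR", "K27me3", 2),
               pep_row("a", "H3", 27, 40, "KSAPATGGVKKPHR", "K27me3", 2))
  fam <- build_families(dup)
  expect_identical(nrow(fam), 1L)
  expect_identical(fam$intensity, 4)

  expect_error(build_families(pep_row("a", "H3", 27, 40, "X", "", -1)),
               "negative")
})

test_that("ptm relative abundance matches exhaustive manual enumeration", {
  # toy H4 family: forms {K5acK8ac: 2, K5ac: 1, unmod: 1}
  tab <- rbind(
    pep_row("s", "H4", 4, 17, "GKGGKGLGKGGAKR", "K5acK8ac", 2),
    pep_row("s", "H4", 4, 17, "GKGGKGLGKGGAKR", "K5ac", 1),
    pep_row("s", "H4", 4, 17, "GKGGKGLGKGGAKR", "", 1))
  ab <- ptm_relative_abundance(tab, marks = "H4K5ac",
                               combinations = "H4:K5acK8ac")
  expect_equal(ab$abundance[ab$mark == "H4K5ac"], 0.75)       # (2+1)/4
  expect_equal(ab$abundance[ab$mark == "H4:K5acK8ac"], 0.5)   # 2/4

  # printed worked example: modified 18 vs unmodified 82
  tab <- rbind(pep_row("s", "H3", 27, 40, "KSAPATGGVKKPHR", "K27me3", 18),
               pep_row("s", "H3", 27, 40, "KSAPATGGVKKPHR", "", 82))
  ab <- ptm_relative_abundance(tab, marks = "H3K27me3")
  expect_equal(ab$abundance, 0.18)

  # all intensity unmodified: each mark is 0
  tab <- pep_row("s", "H3", 27, 40, "KSAPATGGVKKPHR", "", 10)
  expect_equal(
    ptm_relative_abundance(tab, marks = "H3K27me3")$abundance, 0)

  # absent family is missing, not zero
  expect_warning(
    ab <- ptm_relative_abundance(tab, marks = "H4K16ac"), "missing")
  expect_true(is.na(ab$abundance[ab$mark == "H4K16ac"]))
})

test_that("log2 enrichment reproduces ratios and rejects disjoint tables", {
  mk <- function(sample, abundance) {
    structure(data.frame(sample = sample, mark = "H3K27me3",
                         abundance = abundance, kind = "single"),
              class = c("ptm_abundance", "data.frame"))
  }
  e <- log2_enrichment(mk("ip", 0.18), mk("in", 0.06), pseudocount = 1e-9)
  expect_equal(e$log2_ratio, log2(3), tolerance = 1e-6)
  expect_equal(log2_enrichment(mk("ip", 0.1), mk("in", 0.1))$log2_ratio, 0)
  expect_equal(log2_enrichment(mk("ip", 0), mk("in", 0))$log2_ratio, 0)

  other <- structure(data.frame(sample = "in", mark = "H4K16ac",
                                abundance = 0.5, kind = "single"),
                     class = c("ptm_abundance", "data.frame"))
  expect_error(log2_enrichment(mk("ip", 0.1), other), "shared")
})

h2a_toy_table <- function(ref = 10, can = 6, z = 2, macro = 2) {
  rbind(pep_row("s", "H2A", 4, 11, "GKQGGKAR", "", ref),
        pep_row("s", "H2A", 12, 17, "AKAKTR", "", ref),
        pep_row("s", "H2A", 21, 29, "AGLQFPVGR", "", ref),
        pep_row("s", "H2A", 82, 88, "HLQLAIR", "", ref),
        pep_row("s", "H2A", 36, 42, "KGNYAER", "", can),
        pep_row("s", "H2A", 1, 19, "AGGKAGKDSGKAKTKAVSR", "", z),
        pep_row("s", "H2A", 4, 14, "GGKKKSTKTSR", "", macro))
}

test_that("H2A variant fractions follow the four-reference scheme", {
  # ratios 0.6 / 0.2 / 0.2 against every reference -> fractions directly
  vf <- h2a_variant_fractions(h2a_toy_table())
  expect_equal(unname(vf$fractions),c(0.6, 0.2, 0.2), tolerance = 1e-12)
  expect_equal(unname(vf$per_reference_ratios["H2A.Z", ]),
               rep(0.2, 4), tolerance = 1e-12)

  # all-canonical pool
  pool <- generate_nucleosome_pool(mixture_homotypic("H2A"), 500, seed = 1)
  vf <- h2a_variant_fractions(generate_peptide_table(pool))
  expect_equal(unname(vf$fractions), c(1, 0, 0), tolerance = 1e-12)

  # zero reference total rejected; missing variant gated by flag
  bad <- h2a_toy_table(ref = 0)
  expect_error(h2a_variant_fractions(bad), "positive totals")
  nomacro <- h2a_toy_table()
  nomacro <- nomacro[nomacro$sequence != "GGKKKSTKTSR", ]
  expect_error(h2a_variant_fractions(nomacro), "allow_missing")
  vf <- h2a_variant_fractions(nomacro, allow_missing = TRUE)
  expect_equal(unname(vf$fractions[["macroH2A"]]), 0)
})

test_that("H3 variant fractions come from the 27-40 peptide pair", {
  tab <- rbind(pep_row("s", "H3", 27, 40, "KSAPATGGVKKPHR", "", 3),
               pep_row("s", "H3", 27, 40, "KSAPSTGGVKKPHR", "", 1))
  vf <- h3_variant_fractions(tab)
  expect_equal(unname(vf$fractions),c(0.75, 0.25))

  tab$intensity <- c(3, 0)
  expect_equal(unname(h3_variant_fractions(tab)$fractions[["H3.3"]]), 0)
  tab$intensity <- c(0, 0)
  expect_error(h3_variant_fractions(tab), "zero")

  # fully heterotypic H3.3 pool: half canonical, half H3.3
  pool <- generate_nucleosome_pool(mixture_heterotypic("H3.3"), 400,
                                   seed = 2)
  vf <- h3_variant_fractions(generate_peptide_table(pool))
  expect_equal(unname(vf$fractions), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("quantification is invariant to a global intensity scale", {
  pool <- generate_nucleosome_pool(
    c(mixture_heterotypic("H2A.Z", prop = 0.4),
      mixture_heterotypic("macroH2A", prop = 0.3),
      mixture_homotypic("H2A", prop = 0.3)), 2000, seed = 5)
  tab <- generate_peptide_table(pool, ptm_profile = list(H3K27me3 = 0.1),
                                noise_cv = 0.05, seed = 5)
  scaled <- tab
  scaled$intensity <- scaled$intensity * 1734.2
  expect_equal(h2a_variant_fractions(tab)$fractions,
               h2a_variant_fractions(scaled)$fractions, tolerance = 1e-12)
  expect_equal(ptm_relative_abundance(tab, marks = "H3K27me3")$abundance,
               ptm_relative_abundance(scaled, marks = "H3K27me3")$abundance,
               tolerance = 1e-12)
})

test_that("noise-free synthetic tables invert exactly (fraction error < 1e-9)", {
  mixes <- list(
    c(mixture_heterotypic("H2A.Z", prop = 0.5),
      mixture_heterotypic("macroH2A", prop = 0.2),
      mixture_homotypic("H2A", prop = 0.3)),
    c(mixture_heterotypic("H3.3", prop = 0.7),
      mixture_homotypic("H3.1", prop = 0.3)))
  for (mix in mixes) {
    pool <- generate_nucleosome_pool(mix, 3000, seed = 9)
    truth <- variant_copy_fractions(pool)
    tab <- generate_peptide_table(pool, noise_cv = 0)
    h2a <- h2a_variant_fractions(tab)
    expect_lt(max(abs(h2a$fractions - truth$h2a[names(h2a$fractions)])),
              1e-9)
    h3 <- h3_variant_fractions(tab)
    expect_lt(max(abs(h3$fractions - truth$h3[names(h3$fractions)])), 1e-9)
  }
})

test_that("peptide tables round-trip through CSV", {
  pool <- generate_nucleosome_pool(mixture_heterotypic("H2A.Z"), 100,
                                   seed = 1)
  tab <- generate_peptide_table(pool, ptm_profile = list(H3K27me3 = 0.2))
  p <- tempfile(fileext = ".csv")
  write_peptide_table(tab, p)
  back <- read_peptide_table(p)
  expect_equal(as.data.frame(back), as.data.frame(tab)[names(back)],
               tolerance = 1e-12, ignore_attr = TRUE)
  unlink(p)
})
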