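test_that("nucleosome pool composition follows the mixture", {
  # fully heterotypic H2A.Z: canonical H2A is exactly half of all copies
  pool <- generate_nucleosome_pool(mixture_heterotypic("H2A.Z"), 500,
                                   seed = 1)
  fr <- variant_copy_fractions(pool)
  expect_identical(unname(fr$h2a[c("H2A", "H2A.Z")]), c(0.5, 0.5))

  # fully homotypic canonical: 100% canonical copies
  pool <- generate_nucleosome_pool(mixture_homotypic("H2A"), 100, seed = 1)
  expect_identical(unname(variant_copy_fractions(pool)$h2a[["H2A"]]), 1)

  # 50% heterotypic H3.3 + 50% homotypic canonical: H3.3 copy fraction
  # converges to h/2 = 0.25
  mix <- c(mixture_heterotypic("H3.3", prop = 0.5),
           mixture_homotypic("H3.1", prop = 0.5))
  pool <- generate_nucleosome_pool(mix, 1e5, seed = 1)
  expect_lt(abs(variant_copy_fractions(pool)$h3[["H3.3"]] - 0.25), 0.01)
})

test_that("pool generation validates inputs and is seed-deterministic", {
  bad <- c(mixture_heterotypic("H2A.Z", prop = 0.6),
           mixture_homotypic("H2A", prop = 0.5))
  expect_error(generate_nucleosome_pool(bad, 10), "sum to 1")
  expect_error(
    generate_nucleosome_pool(mixture_homotypic("H2A"), 10,
                             purified_by = "H2A.Z"),
    "purified")

  p1 <- generate_nucleosome_pool(mixture_heterotypic("H3.3"), 200, seed = 7)
  p2 <- generate_nucleosome_pool(mixture_heterotypic("H3.3"), 200, seed = 7)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("noise-free peptide tables follow the forward model exactly", {
  # 60% heterotypic H2A.Z + 40% homotypic canonical: Z is 30% of copies
  mix <- c(mixture_heterotypic("H2A.Z", prop = 0.6),
           mixture_homotypic("H2A", prop = 0.4))
  pool <- generate_nucleosome_pool(mix, 2000, seed = 3)
  z_frac <- variant_copy_fractions(pool)$h2a[["H2A.Z"]]
  tab <- generate_peptide_table(pool, noise_cv = 0)
  refs <- reference_peptides()
  ref_seqs <- refs$sequence[grepl("^H2Ac_", refs$name)]
  i_z <- sum(tab$intensity[tab$sequence == "AGGKAGKDSGKAKTKAVSR"])
  for (rs in ref_seqs) {
    expect_equal(i_z / sum(tab$intensity[tab$sequence == rs]), z_frac,
                 tolerance = 1e-12)
  }
})

test_that("ptm_profile splits a family deterministically and noise is seeded", {
  pool <- generate_nucleosome_pool(mixture_homotypic("H2A"), 100, seed = 1)
  tab <- generate_peptide_table(pool, ptm_profile = list(H3K27me3 = 0.18),
                                noise_cv = 0)
  fam <- tab[tab$sequence == "KSAPATGGVKKPHR", ]
  expect_equal(fam$intensity[fam$mods == "K27me3"] / sum(fam$intensity),
               0.18, tolerance = 1e-12)

  t1 <- generate_peptide_table(pool, noise_cv = 0.2, seed = 7)
  t2 <- generate_peptide_table(pool, noise_cv = 0.2, seed = 7)
  t3 <- generate_peptide_table(pool, noise_cv = 0.2, seed = 8)
  expect_identical(t1, t2)
  expect_false(isTRUE(all.equal(t1$intensity, t3$intensity)))

  expect_error(generate_peptide_table(pool,
                                      response_factors = list(XX = 2)),
               "unknown peptide")
})

test_that("genome fixture plants offsets, bias and TF odds as configured", {
  cfg <- small_fixture_config(seed = 4, noise = "none")
  fx <- generate_genome_fixture(cfg)

  # archetype with +400 H3.3 offset: signal center of mass right of center
  skew_r <- fx$anchors[fx$anchors$name == "skew_33_R", ]
  v <- fx$tracks$H3.3$values[[cfg$chrom]]
  bw <- cfg$bin_width
  for (i in seq_len(5)) {
    ctr <- skew_r$center[i]
    bins <- ((ctr - 2000) %/% bw + 1):((ctr + 2000) %/% bw)
    w <- v[bins] - cfg$background
    com <- sum(w * ((bins - 0.5) * bw)) / sum(w)
    expect_gt(com, ctr + 300)
  }

  # symmetric archetypes have zero strand bias: plus and minus eRNA equal
  # exactly over their windows in the noise-free fixture
  sym <- fx$anchors[fx$truth$directions[fx$anchors$archetype] == 0, ]
  vp <- fx$erna_plus$values[[cfg$chrom]]
  vm <- fx$erna_minus$values[[cfg$chrom]]
  for (i in seq_len(nrow(sym))) {
    bins <- ((sym$center[i] - 2000) %/% bw + 1):((sym$center[i] + 2000) %/% bw)
    expect_equal(vp[bins], vm[bins], tolerance = 1e-9)
  }

  # all planted anchors honor the distal rule
  anchors <- suppressMessages(filter_distal(fx$dhs, fx$genes))
  kept <- sub(":.*", "", anchors$anchors$name)
  expect_setequal(kept, fx$anchors$anchor_id)
})

test_that("symmetric fixture has balanced eRNA only because bias is zero", {
  cfg <- small_fixture_config(
    seed = 2, noise = "none",
    archetypes = list(archetype("biased", c(H3.3 = 50), offset = 400,
                                erna_amp = 30, erna_bias = 0.3)))
  fx <- generate_genome_fixture(cfg)
  P <- sum(fx$erna_plus$values[[cfg$chrom]])
  M <- sum(fx$erna_minus$values[[cfg$chrom]])
  expect_equal((P - M) / (P + M), 0.3, tolerance = 1e-9)
})

test_that("TF peak enrichment odds are recovered within binomial error", {
  cfg <- genome_fixture_config(
    seed = 5, n_per_archetype = 200,
    archetypes = list(
      archetype("target", c(H3.3 = 50)),
      archetype("other", c(H2A.Z = 50))),
    n_genes = 10, n_proximal = 0,
    tf_spec = list(X = list(target = "target", odds = 9)),
    tf_background_rate = 0.1, chrom_length = 6e6)
  fx <- generate_genome_fixture(cfg)
  ov <- overlap_counts(fx$anchors, fx$tf_peaks$X, flank = 500)
  in_t <- fx$anchors$name == "target"
  # target rate 0.9, background 0.1; 3 binomial sigmas at n = 200
  expect_lt(abs(mean(ov[in_t]) - 0.9), 3 * sqrt(0.9 * 0.1 / 200))
  expect_lt(abs(mean(ov[!in_t]) - 0.1), 3 * sqrt(0.9 * 0.1 / 200))
})

test_that("fixtures are seed-deterministic and round-trip through files", {
  cfg <- small_fixture_config(seed = 11)
  f1 <- generate_genome_fixture(cfg)
  f2 <- generate_genome_fixture(small_fixture_config(seed = 11))
  expect_identical(f1$anchors, f2$anchors)
  expect_identical(f1$tracks$H2A.Z$values, f2$tracks$H2A.Z$values)
  f3 <- generate_genome_fixture(small_fixture_config(seed = 12))
  expect_false(identical(f1$tracks$H2A.Z$values, f3$tracks$H2A.Z$values))

  out <- file.path(tempdir(), "fixture-roundtrip")
  paths <- write_genome_fixture(f1, out)
  genes <- read_genes(paths[["genes"]])
  expect_equal(genes[c("chrom", "start", "end", "strand", "name")],
               f1$genes[c("chrom", "start", "end", "strand", "name")],
               ignore_attr = TRUE)
  dhs <- read_bed(paths[["dhs"]])
  expect_equal(dhs[c("chrom", "start", "end", "name")],
               f1$dhs[c("chrom", "start", "end", "name")],
               ignore_attr = TRUE)
  tr <- read_bedgraph(paths[["H2A.Z"]], bin_width = cfg$bin_width)
  v0 <- f1$tracks$H2A.Z$values[[cfg$chrom]]
  v1 <- tr$values[[cfg$chrom]]
  n <- length(v1)  # trailing zero bins are not written
  expect_equal(v1, v0[seq_len(n)], tolerance = 1e-9)
  expect_true(all(v0[-seq_len(n)] == 0))
  unlink(out, recursive = TRUE)
})
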