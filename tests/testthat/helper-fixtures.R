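# Shared builders for the test suite. Everything is generated in code;
# no stored fixtures.

# Wrap a plain matrix as a profile_matrix (for clustering tests that do
# not need a genomic track behind the profiles).
make_pm <- function(values, track = "t", b = 100) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("anchor", seq_len(nrow(values)))
  }
  a <- data.frame(chrom = "chrT", start = 0, end = 1,
                  name = rownames(values), center = 0)
  structure(list(values = values, window = ncol(values) * b / 2, bin = b,
                 track = track, anchors = a, n_dropped = 0L),
            class = "profile_matrix")
}

# A small, fast genome fixture (4 symmetric + 6 mirror-pair archetypes,
# fewer anchors) for unit tests; the acceptance suite uses the defaults.
small_fixture_config <- function(seed = 0L, noise = "poisson", ...) {
  genome_fixture_config(chrom_length = 4e6, n_genes = 25,
                        n_per_archetype = 15, n_proximal = 10,
                        noise = noise, seed = seed, ...)
}

# Cluster a fixture with the default pipeline settings; returns the
# oriented cluster_result plus per-row archetype truth.
cluster_fixture <- function(fx, seed = 0L, K = 16, nstart = 10) {
  anchors <- suppressMessages(filter_distal(fx$dhs, fx$genes))
  tracks <- lapply(fx$tracks, rpkm_normalize)
  mats <- lapply(tracks[c("H3.1", "H3.3", "macroH2A", "H2A.Z")],
                 profile_matrix, anchors = anchors, W = 2000, b = 100)
  res <- kmeans_profiles(mats, K = K, seed = seed, nstart = nstart)
  res <- mirror_pair(res)
  res <- classify_and_orient(res)
  ids <- sub(":.*", "", rownames(res$data))
  truth <- fx$truth$labels[ids]
  polii <- profile_matrix(tracks$PolII, anchors, W = 2000, b = 100)
  list(result = res, truth = truth, polii = polii, anchors = anchors,
       tracks = tracks)
}

# Memoized heavy fixtures shared by the acceptance blocks.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# One-sided ("a less than b") exact rank-sum p-value by full enumeration
# of all label assignments; oracle for the exact branch.
rank_sum_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  r <- rank(pooled)
  obs <- sum(r[seq_along(a)])
  sums <- colSums(matrix(r[idx], nrow = length(a)))
  mean(sums <= obs)
}

# Exact upper-tail hypergeometric by enumerating all size-n draws from a
# population of N with K successes.
hyper_enum_p <- function(N, K, n, k) {
  member <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(member[draws], nrow = n))
  mean(hits >= k)
}
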