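two_genome_set <- function(seed = 1, n = 25, min_bp = 5000, max_bp = 10000,
                           gc = c(0.29, 0.60)) {
  simulate_contigs(list(
    genome_spec("low_gc", gc = gc[1], n_contigs = n, min_bp = min_bp,
                max_bp = max_bp),
    genome_spec("high_gc", gc = gc[2], n_contigs = n, min_bp = min_bp,
                max_bp = max_bp)), seed = seed)
}

test_that("the contig length filter is strictly greater-than", {
  cs <- contig_set(data.frame(
    contig_id = c("a", "b", "c"),
    sequence = vapply(c(1999, 2000, 2001), function(n)
      strrep("ACGT", ceiling(n / 4)) |> substr(1, n), character(1))))
  kept <- filter_contigs(cs)
  expect_equal(kept$contig_id, "c")
  all_long <- contig_set(data.frame(contig_id = c("x", "y"),
                                    sequence = strrep("ACGT", 2500)))
  expect_equal(nrow(filter_contigs(all_long)), 2)
  empty <- filter_contigs(cs, min_len_bp = 1e7)
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "contig_set")
})

test_that("canonical 4-mer frequencies match hand enumeration", {
  f <- kmer_frequencies("AAAAA")
  expect_equal(unname(f["AAAA"]), 1)
  expect_equal(sum(f), 1)

  # ACGTACGT: windows ACGT, CGTA, GTAC, TACG, ACGT; canonical forms
  # ACGT, CGTA, GTAC, CGTA, ACGT
  f <- kmer_frequencies("ACGTACGT")
  expect_equal(unname(f[c("ACGT", "CGTA", "GTAC")]), c(0.4, 0.4, 0.2))
  expect_equal(sum(f > 0), 3)

  expect_error(kmer_frequencies("ACNGT"), "no valid k-mer")
  expect_error(kmer_frequencies("ACG"), "shorter than k")
  # windows containing N are skipped, the rest counted
  f <- kmer_frequencies("AAAANAAAA")
  expect_equal(unname(f["AAAA"]), 1)
})

test_that("there are exactly 136 canonical tetranucleotides", {
  cs <- two_genome_set(seed = 2, n = 3, min_bp = 3000, max_bp = 3000)
  fm <- feature_matrix(cs)
  expect_equal(ncol(fm), 136)
  expect_equal(unname(rowSums(fm)), rep(1, nrow(fm)), tolerance = 1e-9)
  expect_true(all(fm >= 0))
})

test_that("gc_content counts G+C over A/C/G/T, excluding N", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATNAT"), 0)
  expect_equal(gc_content("atgc"), 0.5)  # case-insensitive
  expect_equal(gc_content("NNNN"), 0)
})

test_that("PCA embedding is deterministic and separates distinct genomes", {
  cs <- two_genome_set(seed = 3, n = 15)
  fm <- feature_matrix(cs)
  e1 <- embed_contigs(fm, method = "pca")
  e2 <- embed_contigs(fm, method = "pca")
  expect_identical(e1, e2)
  sil <- cluster::silhouette(as.integer(factor(cs$genome)),
                             dist(cbind(e1$x, e1$y)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # identical rows collapse to one point
  rep_fm <- fm[rep(1, 6), , drop = FALSE]
  rownames(rep_fm) <- paste0("r", 1:6)
  er <- embed_contigs(rep_fm, method = "pca")
  expect_lt(max(dist(cbind(er$x, er$y))), 1e-9)
})

test_that("t-SNE embedding is seed-deterministic and separates genomes", {
  cs <- two_genome_set(seed = 4, n = 10, min_bp = 4000, max_bp = 6000)
  fm <- feature_matrix(cs)
  e1 <- embed_contigs(fm, method = "tsne", perplexity = 5, seed = 0)
  e2 <- embed_contigs(fm, method = "tsne", perplexity = 5, seed = 0)
  expect_identical(e1, e2)
  sil <- cluster::silhouette(as.integer(factor(cs$genome)),
                             dist(cbind(e1$x, e1$y)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(embed_contigs(fm[1:4, ], method = "tsne", perplexity = 5),
               "too few contigs")
})

test_that("density-based binning recovers two pure genome bins", {
  cs <- two_genome_set(seed = 5)
  fm <- feature_matrix(cs)
  bins <- cluster_bins(fm, cs)
  real <- attr(bins, "bins")
  expect_equal(nrow(real), 2)
  expect_gte(attr(bins, "purity"), 0.95)
  # per-bin GC tracks the generating genomes
  expect_equal(sort(real$gc), c(0.29, 0.60), tolerance = 0.02)
})

test_that("binning handles one genome, exact GC bins and the kmeans path", {
  one <- simulate_contigs(genome_spec("solo", gc = 0.5, n_contigs = 12,
                                      min_bp = 5000, max_bp = 8000), seed = 6)
  fm <- feature_matrix(one)
  bins <- cluster_bins(fm, one)
  expect_equal(nrow(attr(bins, "bins")), 1)

  cs <- two_genome_set(seed = 7, n = 15)
  km <- cluster_bins(feature_matrix(cs), cs, method = "kmeans", k = 2,
                     seed = 1)
  expect_equal(nrow(attr(km, "bins")), 2)
  expect_gte(attr(km, "purity"), 0.95)

  # a bin whose members all share one GC reports exactly that GC
  same <- contig_set(data.frame(
    contig_id = sprintf("s%d", 1:6),
    sequence = rep(paste(rep(c("AAACGTA", "TTTGCAT"), 50), collapse = ""), 6)))
  b <- cluster_bins(feature_matrix(same), same, method = "kmeans", k = 1)
  expect_equal(attr(b, "bins")$gc, same$gc[1])
})

test_that("binning purity holds across seeds for moderately separated genomes", {
  purities <- vapply(1:20, function(seed) {
    cs <- two_genome_set(seed = seed, n = 20, min_bp = 5000, max_bp = 7000,
                         gc = c(0.42, 0.57))
    attr(cluster_bins(feature_matrix(cs), cs), "purity")
  }, numeric(1))
  expect_true(all(purities >= 0.95))
})

test_that("k-mer containment behaves as a set overlap", {
  a <- random_contigs(4, 30000, seed = 1, prefix = "a")
  expect_equal(kmer_containment(a, a), 1)

  b <- random_contigs(4, 30000, seed = 2, prefix = "b")
  expect_lt(kmer_containment(a, b), 0.01)

  # a subset assembly is fully contained in its source, not vice versa
  half <- contig_set(data.frame(
    contig_id = "half_1",
    sequence = substr(a$sequence[1], 1, 15000)))
  expect_equal(kmer_containment(a, half), 1)
  expect_lt(kmer_containment(half, a), 0.2)
})
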