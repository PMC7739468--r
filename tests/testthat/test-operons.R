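strand_genome <- function(strands, gaps = NULL, len = 300) {
  # genes of fixed length separated by 10 bp (or given gaps)
  n <- length(strands)
  if (is.null(gaps)) gaps <- rep(10, n - 1)
  start <- integer(n); end <- integer(n)
  pos <- 50L
  for (i in seq_len(n)) {
    if (i > 1) pos <- end[i - 1] + gaps[i - 1]
    start[i] <- pos
    end[i] <- pos + len
  }
  structure(list(
    species_id = "s", contigs = list(c1 = strrep("A", max(end) + 100)),
    genes = data.frame(contig = "c1",
                       locus_tag = sprintf("g%02d", seq_len(n)),
                       start = start, end = end, strand = strands,
                       product = "", protein = "M",
                       stringsAsFactors = FALSE),
    mono_freqs = setNames(rep(0.25, 4), DNA)), class = "genome")
}

test_that("directons break exactly at strand switches", {
  g <- strand_genome(c("+", "+", "-", "-", "+"))
  expect_equal(find_directons(g), c(1, 1, 2, 2, 3))
  expect_equal(find_directons(strand_genome(rep("+", 6))), rep(1, 6))
  expect_equal(find_directons(strand_genome(c("+", "-", "+", "-"))), 1:4)
})

test_that("adaptive threshold is the mean within-directon intergenic distance", {
  g <- strand_genome(rep("+", 4), gaps = c(10, 20, 30))
  expect_equal(adaptive_operon_threshold(g), 20)
  # overlaps contribute negative distances
  g2 <- strand_genome(rep("+", 3), gaps = c(-4, 4))
  expect_equal(adaptive_operon_threshold(g2), 0)
  # gaps across a strand switch are excluded
  g3 <- strand_genome(c("+", "+", "-", "-"), gaps = c(10, 500, 30))
  expect_equal(adaptive_operon_threshold(g3), 20)
  # pathological genome without pairs falls back with a warning
  g4 <- strand_genome(c("+", "-"))
  expect_warning(thr <- adaptive_operon_threshold(g4), "fallback")
  expect_equal(thr, 50)
  # multiplier scales the mean
  expect_equal(adaptive_operon_threshold(g, multiplier = 2), 40)
})

test_that("operon prediction splits directons on large gaps only", {
  g <- strand_genome(rep("+", 4), gaps = c(5, 500, 5))
  ops <- predict_operons(g, threshold = 50)
  expect_equal(ops$operon_id, c(1, 1, 2, 2))
  # exact-threshold gaps are kept together
  g2 <- strand_genome(rep("+", 2), gaps = 50)
  expect_equal(predict_operons(g2, 50)$operon_id, c(1, 1))
  # threshold below every gap isolates every gene
  expect_equal(predict_operons(g, -10)$operon_id, 1:4)
  # operon table bookkeeping
  expect_equal(ops$operons$n_genes, c(2, 2))
  expect_equal(ops$operons$first_gene, c("g01", "g03"))
  # minus-strand operons list genes in transcription order
  gm <- strand_genome(rep("-", 3), gaps = c(5, 5))
  opm <- predict_operons(gm, 50)
  expect_equal(opm$operons$first_gene, "g03")
  expect_equal(opm$operons$genes, "g03,g02,g01")
})

test_that("operon prediction equals a brute-force splitter on random fixtures", {
  set.seed(21)
  for (i in 1:100) {
    fx <- make_operon_fixture(n_operons = sample(5:15, 1),
                              within_mean = sample(c(5, 15, 30), 1),
                              between_mean = sample(c(100, 150, 250), 1))
    thr <- adaptive_operon_threshold(fx$genome)
    ours <- predict_operons(fx$genome, thr)$operon_id
    oracle <- oracle_split_operons(fx$genome$genes,
                                   find_directons(fx$genome), thr)
    expect_equal(as.integer(factor(ours)), as.integer(factor(oracle)))
  }
})

test_that("operons partition genes and respect directon boundaries", {
  set.seed(22)
  for (i in 1:10) {
    fx <- make_operon_fixture()
    ops <- predict_operons(fx$genome)
    expect_length(ops$operon_id, nrow(fx$genome$genes))
    d <- find_directons(fx$genome)
    # every operon lies within one directon
    expect_true(all(tapply(d, ops$operon_id, function(x) {
      length(unique(x)) == 1
    })))
    # contiguity: operon ids are runs
    expect_true(all(rle(ops$operon_id)$values == unique(ops$operon_id)))
  }
})

test_that("adaptive threshold beats fixed 50 and 200 bp on average", {
  set.seed(23)
  # 20 regimes spanning dense to loose genomes, the variation that makes a
  # genome-adaptive threshold worthwhile
  regimes <- expand.grid(within = c(5, 15, 25, 35, 45),
                         between = c(100, 150, 200, 250))
  acc <- matrix(0, nrow(regimes), 3,
                dimnames = list(NULL, c("adaptive", "fix50", "fix200")))
  for (i in seq_len(nrow(regimes))) {
    fx <- make_operon_fixture(n_operons = 40,
                              within_mean = regimes$within[i],
                              within_sd = 10,
                              between_mean = regimes$between[i],
                              between_sd = 40)
    truth <- fx$truth_operon
    for (j in seq_len(3)) {
      thr <- switch(j, adaptive_operon_threshold(fx$genome), 50, 200)
      pred <- predict_operons(fx$genome, thr)$operon_id
      acc[i, j] <- promoter_accuracy(fx$genome, pred, truth)
    }
  }
  means <- colMeans(acc)
  expect_gte(means["adaptive"], means["fix50"])
  expect_gte(means["adaptive"], means["fix200"])
})

test_that("split threshold satisfies the -log2 FPR = IC rule exactly", {
  set.seed(24)
  for (i in 1:6) {
    w <- sample(4:6, 1)
    sites <- replicate(8, rand_dna(w, freqs = c(0.4, 0.2, 0.2, 0.2)))
    pswm <- build_pswm(site_collection(sites, "s"), 0.5)
    bg <- c(0.3, 0.2, 0.2, 0.3)
    pssm <- pswm_to_pssm(pswm, bg)
    ic <- information_content(pswm, bg)
    if (ic <= 0) next
    thr <- split_score_threshold(pssm, bg, ic)
    fpr <- oracle_kmer_fpr(pssm, bg, thr)
    expect_lte(fpr, 2^(-ic) + 1e-12)
    # minimality over attainable scores: the next lower attainable score
    # must violate the bound
    dist0 <- cregulon:::pssm_score_distribution(pssm, bg)
    lower <- dist0$score[dist0$score < thr - 1e-9]
    if (length(lower)) {
      fpr_below <- oracle_kmer_fpr(pssm, bg, max(lower))
      expect_gt(fpr_below, 2^(-ic))
    }
    # DP distribution agrees with enumeration at the threshold
    dist <- cregulon:::pssm_score_distribution(pssm, bg)
    dp_fpr <- sum(dist$prob[dist$score >= thr - 1e-12])
    expect_equal(dp_fpr, fpr, tolerance = 1e-9)
  }
  # degenerate, uninformative motif exercises the warning path
  u <- build_pswm(site_collection(c("AAAA", "CCCC", "GGGG", "TTTT"), "u"), 0)
  up <- pswm_to_pssm(u)
  expect_warning(t0 <- split_score_threshold(up, rep(0.25, 4), ic = 2),
                 "unattainable")
  expect_equal(t0, 0)
})

test_that("operon splitting on internal sites is exact and idempotent", {
  g <- strand_genome(rep("+", 4), gaps = c(5, 5, 5))
  ops <- predict_operons(g, 50)
  expect_equal(ops$operon_id, rep(1, 4))
  # no qualifying gene: unchanged
  s_none <- rep(0, 4)
  expect_identical(split_operons_on_sites(ops, g, s_none, 10)$operon_id,
                   ops$operon_id)
  # planted site upstream of gene 3 splits 4 -> 2 + 2
  s3 <- c(0, 0, 12, 0)
  sp <- split_operons_on_sites(ops, g, s3, 10)
  expect_equal(sp$operon_id, c(1, 1, 2, 2))
  # idempotence
  expect_equal(split_operons_on_sites(sp, g, s3, 10)$operon_id,
               sp$operon_id)
  # a qualifying first gene does not create an extra split
  s1 <- c(12, 0, 0, 0)
  expect_equal(split_operons_on_sites(ops, g, s1, 10)$operon_id, rep(1, 4))
  # multiple internal sites split at every qualifying gene
  s23 <- c(0, 12, 12, 0)
  expect_equal(split_operons_on_sites(ops, g, s23, 10)$operon_id,
               c(1, 2, 3, 3))
  # minus-strand operons split in transcription order
  gm <- strand_genome(rep("-", 4), gaps = c(5, 5, 5))
  opm <- predict_operons(gm, 50)
  # transcription order is g4, g3, g2, g1; site upstream of g2 (third in
  # transcription order) splits into (g4, g3) and (g2, g1)
  sm <- c(0, 12, 0, 0)
  spm <- split_operons_on_sites(opm, gm, sm, 10)
  expect_equal(length(unique(spm$operon_id)), 2)
  expect_equal(spm$operon_id[1], spm$operon_id[2])
  expect_equal(spm$operon_id[3], spm$operon_id[4])
})

test_that("upstream regions follow the -250..+50 window with truncation", {
  fx <- generate_fixture(fixture_spec(n_species = 2, genes_per_genome = 16,
                                      rng_seed = 31))
  g <- fx$genomes$sp1
  for (i in seq_len(nrow(g$genes))) {
    reg <- gene_upstream_region(g, i)
    expect_lte(nchar(reg$sequence), 300)
    if (nzchar(reg$sequence)) {
      expect_gte(reg$rel_start, -250)
      # the returned window is oriented 5'->3' on the gene's strand: the
      # base at offset -rel_start is the first base of the start codon
      # whenever the window reaches into the gene
      if (reg$rel_start + nchar(reg$sequence) >= 3) {
        codon_at <- substr(reg$sequence, -reg$rel_start + 1,
                           -reg$rel_start + 3)
        expect_equal(codon_at, "ATG")
      }
    }
  }
})

test_that("planted fixture sites appear at their recorded promoter offsets", {
  fx <- generate_fixture(fixture_spec(rng_seed = 33))
  for (sp in names(fx$genomes)) {
    g <- fx$genomes[[sp]]
    st <- fx$truth$sites[fx$truth$sites$species == sp, ]
    for (r in seq_len(nrow(st))) {
      i <- which(g$genes$locus_tag == st$locus_tag[r])
      reg <- gene_upstream_region(g, i)
      offset <- st$rel_start[r] - reg$rel_start
      found <- substr(reg$sequence, offset + 1,
                      offset + nchar(st$site[r]))
      expect_identical(found, st$site[r])
    }
  }
})
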