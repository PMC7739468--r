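test_that("protein distances are Poisson-corrected mismatch fractions", {
  a <- "MKVLATTREWSDFGHKLMNP"
  expect_equal(pairwise_distance(a, a), 0)
  # exactly 10% mismatches, no gaps
  set.seed(41)
  b <- rand_protein(100)
  chars <- strsplit(b, "")[[1]]
  pos <- sample(100, 10)
  chars[pos] <- vapply(chars[pos], function(x) {
    sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], x), 1)
  }, character(1))
  b2 <- paste(chars, collapse = "")
  expect_equal(pairwise_distance(b, b2), -log(0.9), tolerance = 1e-10)
  # symmetry over random pairs
  for (i in 1:5) {
    x <- rand_protein(60); y <- rand_protein(60)
    expect_equal(pairwise_distance(x, y), pairwise_distance(y, x))
  }
  expect_error(pairwise_distance("", "MK"), "empty")
})

test_that("neighbor joining recovers additive trees and midpoint-roots", {
  # two taxa: one cherry, branches d/2
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  t2 <- build_nj_tree(d2)
  expect_setequal(t2$tip.label, c("a", "b"))
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))
  # additive 4-taxon matrix from a known tree:
  # ((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.05)
  taxa <- c("a", "b", "c", "d")
  dm <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  dm["a", "b"] <- dm["b", "a"] <- 0.3
  dm["c", "d"] <- dm["d", "c"] <- 0.45
  dm["a", "c"] <- dm["c", "a"] <- 0.1 + 0.05 + 0.05 + 0.15
  dm["a", "d"] <- dm["d", "a"] <- 0.1 + 0.05 + 0.05 + 0.3
  dm["b", "c"] <- dm["c", "b"] <- 0.2 + 0.05 + 0.05 + 0.15
  dm["b", "d"] <- dm["d", "b"] <- 0.2 + 0.05 + 0.05 + 0.3
  t4 <- build_nj_tree(dm)
  # NJ on an additive matrix reproduces all pairwise path lengths
  pd <- ape::cophenetic.phylo(t4)
  expect_equal(pd[taxa, taxa], dm, tolerance = 1e-10)
  # {a,b} vs {c,d} split present
  splits <- ape::prop.part(t4)
  expect_error(build_nj_tree(dm[1, 1, drop = FALSE]), "2 taxa")
  # ultrametric matrix: midpoint root is equidistant from all leaves
  du <- matrix(0.6, 3, 3, dimnames = list(c("x", "y", "z"),
                                          c("x", "y", "z")))
  du["x", "y"] <- du["y", "x"] <- 0.2
  diag(du) <- 0
  tu <- build_nj_tree(du)
  root_depths <- ape::node.depth.edgelength(tu)[1:3]
  expect_equal(max(root_depths) - min(root_depths), 0, tolerance = 1e-10)
})

test_that("patristic distances equal path sums on the tree graph", {
  # cherry with branches 0.1 and 0.2
  tr <- ape::read.tree(text = "(a:0.1,b:0.2);")
  d <- patristic_distances(tr, "a")
  expect_equal(unname(d["a"]), 0)
  expect_equal(unname(d["b"]), 0.3)
  expect_error(patristic_distances(tr, "zz"), "not in tree")
  # random tree: compare against shortest paths in the edge graph
  set.seed(42)
  rt <- ape::rtree(8)
  el <- data.frame(from = rt$edge[, 1], to = rt$edge[, 2],
                   weight = rt$edge.length)
  gr <- igraph::graph_from_data_frame(el, directed = FALSE)
  for (leaf in rt$tip.label[1:4]) {
    ours <- patristic_distances(rt, leaf)
    ileaf <- match(leaf, rt$tip.label)
    sp <- igraph::distances(gr, v = as.character(ileaf),
                            to = as.character(seq_along(rt$tip.label)))
    expect_equal(unname(ours[rt$tip.label]), as.numeric(sp),
                 tolerance = 1e-10)
  }
})

test_that("trees are deterministic given identical input", {
  set.seed(43)
  prots <- setNames(replicate(5, rand_protein(80)), letters[1:5])
  d <- protein_distance_matrix(prots)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  t1 <- build_nj_tree(d)
  t2 <- build_nj_tree(d[c(3, 1, 5, 2, 4), c(3, 1, 5, 2, 4)])
  # same topology and lengths regardless of input order
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("TF ortholog search honours cutoffs and reciprocality", {
  fx <- generate_fixture(fixture_spec(n_species = 2, genes_per_genome = 10,
                                      rng_seed = 44))
  ref <- fx$references[[1]]
  # exact copy present in sp1 (the reference species)
  hit <- find_tf_ortholog(list(id = "r", protein = ref$protein),
                          fx$genomes$sp1)
  expect_equal(hit$locus_tag, "sp1_tf")
  expect_equal(hit$score, 1, tolerance = 1e-9)
  # diverged ortholog found in sp2
  hit2 <- find_tf_ortholog(list(id = "r", protein = ref$protein),
                           fx$genomes$sp2, min_score = 0.3)
  expect_equal(hit2$locus_tag, "sp2_tf")
  # absurd cutoff: no hit
  expect_null(find_tf_ortholog(list(id = "r", protein = ref$protein),
                               fx$genomes$sp2, min_score = 0.99))
})

test_that("reciprocality filter rejects a higher-scoring decoy paralog", {
  set.seed(45)
  mutate <- function(p, frac) {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    ch <- strsplit(p, "")[[1]]
    pos <- sample(length(ch), round(frac * length(ch)))
    ch[pos] <- vapply(ch[pos], function(a) sample(setdiff(aas, a), 1),
                      character(1))
    paste(ch, collapse = "")
  }
  fake_genome <- function(id, prots) {
    structure(list(species_id = id, contigs = list(c1 = "ACGT"),
                   genes = data.frame(contig = "c1",
                                      locus_tag = names(prots),
                                      start = seq_along(prots) * 100,
                                      end = seq_along(prots) * 100 + 50,
                                      strand = "+", product = "",
                                      protein = unname(prots),
                                      stringsAsFactors = FALSE),
                   mono_freqs = setNames(rep(0.25, 4), DNA)),
              class = "genome")
  }
  tf <- rand_protein(120)
  paralog <- mutate(tf, 0.25)
  ref_genome <- fake_genome("ref", c(tf_gene = tf, paralog_gene = paralog))
  # target: the paralog's close ortholog outscores the true (more diverged)
  # TF ortholog against the TF query
  decoy <- mutate(paralog, 0.03)       # ~27% from tf, close to paralog
  true_orth <- mutate(tf, 0.32)
  target <- fake_genome("tgt", c(aa_decoy = decoy, zz_true = true_orth))
  naive <- alignment_search_backend(tf, c(aa_decoy = decoy,
                                          zz_true = true_orth))
  expect_equal(naive$id[1], "aa_decoy")  # the trap is real
  hit <- find_tf_ortholog(list(id = "tf", protein = tf), target,
                          min_score = 0.2, reference_genome = ref_genome)
  expect_equal(hit$locus_tag, "zz_true")
})
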