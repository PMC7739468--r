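AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Synonymous codons of the bacterial genetic code (table 11), no codon that
# could extend into a stop; used for back-translation of fixture proteins.
CODON_TABLE <- local({
  gc <- Biostrings::getGeneticCode("11")
  split(names(gc), gc)
})

#' Specification for a synthetic multi-species fixture
#'
#' Describes the synthetic study system the generator emulates: several
#' bacterial species sharing one-to-one ortholog families, genes organised
#' into operons within directons, and a fraction of operons regulated by a
#' TF whose binding sites are drawn from a known planted motif into the
#' promoter region. Gap distributions mimic typical bacterial spacing:
#' short within-operon gaps and promoter-sized gaps between operons.
#'
#' @param n_species number of target species.
#' @param genes_per_genome ortholog families per genome (each present once
#'   per species).
#' @param operon_sizes integer vector sampled (uniformly) for operon gene
#'   counts.
#' @param within_gap_mean,within_gap_sd normal parameters (bp) for gaps
#'   between co-operonic genes.
#' @param between_gap_mean,between_gap_sd normal parameters (bp) for
#'   promoter-containing gaps upstream of operon first genes.
#' @param motif_width width of the planted TF-binding motif.
#' @param consensus_prob per-column probability of the consensus base in the
#'   planting PSWM (controls motif information content).
#' @param fraction_regulated fraction of operons carrying a planted site.
#' @param site_temperature sampling temperature for planted sites (1 = draw
#'   from the PSWM as-is; lower sharpens towards consensus).
#' @param protein_length length of fixture proteins (aa).
#' @param tf_divergence per-species fraction of TF residues mutated from the
#'   ancestral TF (species i gets `i * tf_divergence`).
#' @param family_divergence per-species fraction of residues mutated in each
#'   ortholog family protein.
#' @param n_reference_sites binding sites per reference collection.
#' @param rng_seed mandatory integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_species = 4, genes_per_genome = 60,
                         operon_sizes = 1:4,
                         within_gap_mean = 15, within_gap_sd = 5,
                         between_gap_mean = 150, between_gap_sd = 40,
                         motif_width = 16, consensus_prob = 0.9,
                         fraction_regulated = 0.3, site_temperature = 1,
                         protein_length = 90, tf_divergence = 0.05,
                         family_divergence = 0.04, n_reference_sites = 20,
                         rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory", call. = FALSE)
  spec <- as.list(environment())
  if (spec$motif_width + 20 > spec$between_gap_mean) {
    stop("motif wider than the typical promoter gap; infeasible spec",
         call. = FALSE)
  }
  structure(spec, class = "fixture_spec")
}

random_protein <- function(n) {
  paste0("M", paste(sample(AA20, n - 1, replace = TRUE), collapse = ""))
}

# Mutates everywhere except the initiator methionine, so back-translated CDS
# always start with ATG.
mutate_protein <- function(protein, fraction) {
  chars <- strsplit(protein, "")[[1]]
  k <- round(fraction * (length(chars) - 1L))
  if (k > 0) {
    pos <- sample(2:length(chars), k)
    chars[pos] <- vapply(chars[pos], function(a) {
      sample(setdiff(AA20, a), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa[-1], function(a) sample(CODON_TABLE[[a]], 1),
                   character(1))
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

random_dna <- function(n, freqs = rep(0.25, 4)) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE, prob = freqs), collapse = "")
}

# Informative planted motif: one consensus base per column at consensus_prob,
# the rest spread evenly.
planting_pswm <- function(width, consensus_prob) {
  mat <- matrix((1 - consensus_prob) / 3, nrow = 4, ncol = width,
                dimnames = list(DNA_BASES, NULL))
  consensus <- sample(4, width, replace = TRUE)
  for (j in seq_len(width)) mat[consensus[j], j] <- consensus_prob
  new_pswm(mat, effective_site_count = Inf)
}

sample_site <- function(pswm, temperature = 1) {
  f <- unclass(pswm)^(1 / temperature)
  f <- sweep(f, 2, colSums(f), "/")
  paste(vapply(seq_len(ncol(f)), function(j) {
    sample(DNA_BASES, 1, prob = f[, j])
  }, character(1)), collapse = "")
}

#' Generate a synthetic multi-species fixture
#'
#' Produces one genome per species with known operon structure, planted
#' TF-binding sites sampled from the planting motif at a uniform position
#' within -250..-10 bp of the first gene of each regulated operon, divergent
#' one-to-one ortholog families, and a divergent TF protein per species.
#' Reference TF instances (with site collections) are attached to the first
#' two species. All randomness flows from `spec$rng_seed`, so regeneration
#' is byte-identical.
#'
#' @param spec a `fixture_spec`.
#' @return A `fixture` list: `genomes` (named list of `genome` objects),
#'   `references` (list of TF instances with `id`, `species_id`, `protein`,
#'   `sites` as a `site_collection`), `tf_proteins` (per species),
#'   `planting_pswm`, and `truth` with data.frames `genes` (species,
#'   locus_tag, family, operon, regulated), `sites` (species, locus_tag,
#'   operon, rel_start, site), `gaps` (species, type, gap) and the spec.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$rng_seed)
  w <- spec$motif_width
  pswm <- planting_pswm(w, spec$consensus_prob)

  # shared gene/operon layout: operon sizes, directon composition, strands,
  # regulated flags (conserved across species)
  sizes <- integer(0)
  while (sum(sizes) < spec$genes_per_genome) {
    sizes <- c(sizes, sample(spec$operon_sizes, 1))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] -
    (sum(sizes) - spec$genes_per_genome)
  sizes <- sizes[sizes > 0]
  n_operons <- length(sizes)
  regulated <- runif(n_operons) < spec$fraction_regulated
  # directons of 1-2 consecutive operons, alternating strand
  directon_of <- integer(n_operons)
  d <- 0L; i <- 1L
  while (i <= n_operons) {
    d <- d + 1L
    take <- min(sample(1:2, 1), n_operons - i + 1L)
    directon_of[i:(i + take - 1L)] <- d
    i <- i + take
  }
  strands <- rep(c("+", "-"), length.out = max(directon_of))

  # ancestral proteins per family and for the TF
  family_base <- vapply(seq_len(spec$genes_per_genome), function(f) {
    random_protein(spec$protein_length)
  }, character(1))
  tf_base <- random_protein(120)

  species_ids <- sprintf("sp%d", seq_len(spec$n_species))
  tf_proteins <- setNames(vapply(seq_len(spec$n_species), function(s) {
    mutate_protein(tf_base, s * spec$tf_divergence)
  }, character(1)), species_ids)

  genomes <- list()
  truth_genes <- list()
  truth_sites <- list()
  truth_gaps <- list()
  fam_counter <- 0L
  for (s in seq_len(spec$n_species)) {
    sp <- species_ids[s]
    fam_prots <- vapply(family_base, mutate_protein,
                        fraction = s * spec$family_divergence, character(1))
    built <- build_fixture_contig(spec, sp, sizes, regulated, directon_of,
                                  strands, fam_prots, tf_proteins[[sp]],
                                  pswm)
    genomes[[sp]] <- built$genome
    truth_genes[[sp]] <- built$genes_truth
    truth_sites[[sp]] <- built$sites_truth
    truth_gaps[[sp]] <- built$gaps_truth
  }

  references <- lapply(1:2, function(r) {
    sites <- vapply(seq_len(spec$n_reference_sites), function(i) {
      sample_site(pswm, spec$site_temperature)
    }, character(1))
    list(id = sprintf("ref%d", r), species_id = species_ids[r],
         protein = tf_proteins[[r]],
         sites = site_collection(sites, sprintf("ref%d", r)))
  })

  list(genomes = genomes, references = references,
       tf_proteins = tf_proteins, planting_pswm = pswm,
       truth = list(genes = do.call(rbind, truth_genes),
                    sites = do.call(rbind, truth_sites),
                    gaps = do.call(rbind, truth_gaps),
                    n_operons = n_operons,
                    n_regulated = sum(regulated),
                    spec = spec))
}

# Lay out one species' contig. Operons are built in transcription
# orientation and mirrored for minus-strand directons, so planted sites are
# always within -250..-10 of the operon's first gene regardless of strand.
build_fixture_contig <- function(spec, sp, sizes, regulated, directon_of,
                                 strands, fam_prots, tf_protein, pswm) {
  w <- spec$motif_width
  rnorm_clamped <- function(n, mean, sd, lo, hi) {
    pmin(pmax(round(rnorm(n, mean, sd)), lo), hi)
  }
  seq_parts <- character(0)
  pos <- 100L  # left padding
  seq_parts <- c(seq_parts, random_dna(pos))
  gene_rows <- list(); truth_rows <- list(); site_rows <- list()
  gap_rows <- list()
  fam <- 0L
  op_index <- 0L
  n_dir <- max(directon_of)
  for (d in seq_len(n_dir)) {
    ops <- which(directon_of == d)
    strand <- strands[d]
    # build the directon segment in transcription orientation
    seg <- ""
    seg_genes <- list()  # offsets within segment, transcription orientation
    prev_end <- 0L
    for (oi in seq_along(ops)) {
      op <- ops[oi]
      gp <- rnorm_clamped(1, spec$between_gap_mean, spec$between_gap_sd,
                          max(60L, w + 20L), 400L)
      gap_type <- if (oi == 1L) "between_directon" else "within_directon_promoter"
      gap_rows[[length(gap_rows) + 1L]] <-
        data.frame(species = sp, type = gap_type, gap = gp)
      gap_dna <- random_dna(gp)
      site_rel <- NA_integer_; site_seq <- NA_character_
      if (regulated[op]) {
        # site start relative to the first gene's start, in [-250, -10 - w]
        lo <- max(-250L, -gp)
        hi <- -10L - w
        site_rel <- as.integer(floor(runif(1, lo, hi + 1)))
        site_seq <- sample_site(pswm, spec$site_temperature)
        off <- gp + site_rel  # 0-based offset within the gap
        substr(gap_dna, off + 1L, off + w) <- site_seq
      }
      seg <- paste0(seg, gap_dna)
      first_gene_off <- nchar(seg)
      for (gi in seq_len(sizes[op])) {
        fam <- fam + 1L
        if (gi > 1L) {
          wg <- rnorm_clamped(1, spec$within_gap_mean, spec$within_gap_sd,
                              0L, 60L)
          gap_rows[[length(gap_rows) + 1L]] <-
            data.frame(species = sp, type = "within_operon", gap = wg)
          seg <- paste0(seg, random_dna(wg))
        }
        cds <- back_translate(fam_prots[[fam]])
        a <- nchar(seg)
        seg <- paste0(seg, cds)
        seg_genes[[length(seg_genes) + 1L]] <- list(
          fam = fam, start = a, end = nchar(seg), op = op,
          protein = fam_prots[[fam]])
      }
      if (!is.na(site_rel)) {
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          species = sp, family_first = seg_genes[[length(seg_genes) -
                                                    sizes[op] + 1L]]$fam,
          operon = op, rel_start = site_rel, site = site_seq,
          stringsAsFactors = FALSE)
      }
    }
    # place the segment on the contig
    L <- nchar(seg)
    placed <- if (strand == "-") revcomp(seg) else seg
    for (g in seg_genes) {
      if (strand == "+") {
        gs <- pos + g$start; ge <- pos + g$end
      } else {
        gs <- pos + L - g$end; ge <- pos + L - g$start
      }
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        locus_tag = sprintf("%s_g%03d", sp, g$fam),
        start = as.integer(gs), end = as.integer(ge),
        strand = strand, product = sprintf("family %d protein", g$fam),
        protein = g$protein, contig = sprintf("%s_contig1", sp),
        stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        species = sp, locus_tag = sprintf("%s_g%03d", sp, g$fam),
        family = g$fam, operon = g$op, regulated = regulated[g$op],
        stringsAsFactors = FALSE)
    }
    seq_parts <- c(seq_parts, placed)
    pos <- pos + L
    # spacer between directons
    spacer <- rnorm_clamped(1, spec$between_gap_mean, spec$between_gap_sd,
                            40L, 400L)
    seq_parts <- c(seq_parts, random_dna(spacer))
    pos <- pos + spacer
  }
  # TF gene at the end, on the strand opposite the last directon so it
  # starts its own directon and leaves the gap bookkeeping untouched
  tf_strand <- if (strands[n_dir] == "+") "-" else "+"
  tf_cds <- back_translate(tf_protein)
  if (tf_strand == "-") tf_cds <- revcomp(tf_cds)
  gene_rows[[length(gene_rows) + 1L]] <- data.frame(
    locus_tag = sprintf("%s_tf", sp), start = as.integer(pos),
    end = as.integer(pos + nchar(tf_cds)),
    strand = tf_strand, product = "transcription factor",
    protein = tf_protein,
    contig = sprintf("%s_contig1", sp), stringsAsFactors = FALSE)
  truth_rows[[length(truth_rows) + 1L]] <- data.frame(
    species = sp, locus_tag = sprintf("%s_tf", sp), family = 0L,
    operon = NA_integer_, regulated = FALSE, stringsAsFactors = FALSE)
  seq_parts <- c(seq_parts, tf_cds, random_dna(100L))
  contig_seq <- paste(seq_parts, collapse = "")
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$start), c("contig", "locus_tag", "start", "end",
                                       "strand", "product", "protein")]
  rownames(genes) <- NULL
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(species = character(0), family_first = integer(0),
               operon = integer(0), rel_start = integer(0),
               site = character(0))
  if (nrow(sites)) {
    sites$locus_tag <- sprintf("%s_g%03d", sp, sites$family_first)
  } else sites$locus_tag <- character(0)
  list(genome = new_genome(sp, setNames(list(contig_seq),
                                        sprintf("%s_contig1", sp)), genes),
       genes_truth = do.call(rbind, truth_rows),
       sites_truth = sites,
       gaps_truth = do.call(rbind, gap_rows))
}

#' Write a fixture to disk
#'
#' Emits one GenBank file per species plus truth CSVs (genes, sites, gaps)
#' and a ready-to-run JSON configuration for [reconstruct_regulon()].
#'
#' @param fixture output of [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_files <- character(0)
  for (sp in names(fixture$genomes)) {
    p <- file.path(dir, paste0(sp, ".gbk"))
    write_genbank(fixture$genomes[[sp]], p)
    genome_files[sp] <- p
  }
  write.csv(fixture$truth$genes, file.path(dir, "truth_genes.csv"),
            row.names = FALSE)
  write.csv(fixture$truth$sites, file.path(dir, "truth_sites.csv"),
            row.names = FALSE)
  write.csv(fixture$truth$gaps, file.path(dir, "truth_gaps.csv"),
            row.names = FALSE)
  config <- list(
    tf_instances = lapply(fixture$references, function(r) {
      list(id = r$id, species_id = r$species_id, protein = r$protein,
           sites = r$sites$sites)
    }),
    species = lapply(names(fixture$genomes), function(sp) {
      list(species_id = sp, genome_files = unname(genome_files[sp]))
    }),
    parameters = c(
      if (fixture$truth$n_regulated > 0)
        list(n_known_regulated_promoters = fixture$truth$n_regulated),
      list(rng_seed = fixture$truth$spec$rng_seed)))
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(genome_files,
              config = cfg_path,
              truth_genes = file.path(dir, "truth_genes.csv"),
              truth_sites = file.path(dir, "truth_sites.csv"),
              truth_gaps = file.path(dir, "truth_gaps.csv")))
}
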