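default_parameters <- function() {
  list(sites_per_promoter = 1,
       posterior_cutoff = 0.5,
       min_score_ortholog = 0.3,
       min_score_tf = 0.5,
       bootstrap_replicates = 100,
       rng_seed = 1,
       prior_mode = "auto",   # site-count when a regulon size is given
       n_known_regulated_promoters = NULL,
       pseudocount = 0.5,
       threshold_multiplier = 1,
       epsilon = 0.01,
       promoter_upstream = 250,
       promoter_downstream = 50)
}

#' Load and validate a run configuration
#'
#' The configuration names at least one reference TF instance (id, protein
#' sequence, aligned binding sites), the target species with their GenBank
#' files, and runtime parameters. Accepts a JSON file path or an equivalent
#' nested list.
#'
#' @param config path to a JSON configuration or a list with elements
#'   `tf_instances`, `species`, `parameters`.
#' @return Validated config list with parameter defaults filled in.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  stopifnot(is.list(config))
  if (is.null(config$tf_instances) || length(config$tf_instances) == 0L) {
    stop("config: at least one TF instance is required", call. = FALSE)
  }
  n_ref <- 0L
  for (tf in config$tf_instances) {
    if (is.null(tf$id) || is.null(tf$protein)) {
      stop("config: every TF instance needs an id and a protein sequence",
           call. = FALSE)
    }
    if (!is.null(tf$sites) && length(tf$sites) >= 2L) n_ref <- n_ref + 1L
  }
  if (n_ref == 0L) {
    stop("config: at least one reference TF instance with >= 2 aligned ",
         "sites is required", call. = FALSE)
  }
  if (is.null(config$species) || length(config$species) == 0L) {
    stop("config: at least one target species is required", call. = FALSE)
  }
  for (sp in config$species) {
    if (is.null(sp$species_id)) {
      stop("config: every species needs a species_id", call. = FALSE)
    }
    if (is.null(sp[["genome"]]) && is.null(sp[["genome_files"]])) {
      stop("config: species '", sp$species_id,
           "' has neither genome_files nor an inline genome", call. = FALSE)
    }
    for (f in sp$genome_files) {
      if (!file.exists(f)) {
        stop("config: genome file not found: ", f, call. = FALSE)
      }
    }
  }
  params <- default_parameters()
  for (nm in names(config$parameters)) params[[nm]] <- config$parameters[[nm]]
  config$parameters <- params
  config
}

#' Reconstruct a regulon across target species
#'
#' Runs the full comparative workflow: genome parsing, TF ortholog
#' detection, TF phylogeny, phylogenetically weighted mixture motifs,
#' adaptive operon prediction with site-based splitting, Bayesian posterior
#' probabilities of regulation per operon and gene, reciprocal-best-hit
#' ortholog groups restricted to putatively regulated genes, and
#' bootstrapped ancestral-state reconstruction of regulation on the TF tree.
#' A run with identical configuration and seed reproduces identical outputs.
#'
#' @param config JSON path or config list (see [load_config()]).
#' @param output_dir when given, reports are written there via
#'   [write_reports()].
#' @param figures draw figures alongside the CSV reports.
#' @param verbose log stage progress to the console.
#' @return A `regulon_reconstruction` object with elements `species`
#'   (per-species operons, gene posteriors, site tables), `motifs` (mixture
#'   PSWM/PSSM and weights per species), `tree`, `groups`, `matrix`,
#'   `ancestral`, `config`, and `manifest` when reports were written.
#' @export
reconstruct_regulon <- function(config, output_dir = NULL, figures = FALSE,
                                verbose = FALSE) {
  config <- load_config(config)
  params <- config$parameters
  say <- function(...) if (verbose) message(sprintf(...))

  # --- stage 1: genomes ---------------------------------------------------
  genomes <- list()
  for (sp in config$species) {
    genomes[[sp$species_id]] <- if (!is.null(sp[["genome"]]))
      sp[["genome"]] else
      read_genbank(unlist(sp[["genome_files"]]), species_id = sp$species_id)
    say("parsed genome %s: %d genes", sp$species_id,
        nrow(genomes[[sp$species_id]]$genes))
  }

  references <- Filter(function(tf) length(tf$sites) >= 2L,
                       config$tf_instances)
  ref_leaf <- vapply(references, function(r) {
    if (!is.null(r$species_id)) r$species_id else r$id
  }, character(1))

  # --- stage 2: TF orthologs ---------------------------------------------
  ref_genome <- genomes[[ref_leaf[1]]]  # NULL when reference not a target
  tf_prots <- character(0)
  for (sp in names(genomes)) {
    hit <- find_tf_ortholog(references[[1]], genomes[[sp]],
                            min_score = params$min_score_tf,
                            reference_genome = ref_genome)
    if (is.null(hit)) {
      warning("no TF ortholog detected in species '", sp,
              "'; species dropped from the analysis")
      genomes[[sp]] <- NULL
    } else {
      tf_prots[sp] <- hit$protein
      say("TF ortholog in %s: %s (score %.2f)", sp, hit$locus_tag, hit$score)
    }
  }
  if (length(genomes) == 0L) {
    stop("no target species retains a TF ortholog", call. = FALSE)
  }
  # reference instances living outside the target set still anchor the tree
  for (k in seq_along(references)) {
    leaf <- ref_leaf[k]
    if (!leaf %in% names(tf_prots)) {
      tf_prots[leaf] <- references[[k]]$protein
    }
  }

  # --- stage 3: TF phylogeny ---------------------------------------------
  tree <- NULL
  if (length(tf_prots) >= 2L) {
    dmat <- protein_distance_matrix(tf_prots)
    tree <- build_nj_tree(dmat)
    say("TF tree over %d instances", length(tf_prots))
  }

  # --- stage 4: mixture motifs + per-species scan ------------------------
  species_results <- list()
  motifs <- list()
  for (sp in names(genomes)) {
    genome <- genomes[[sp]]
    bgvec <- genome$mono_freqs
    ref_pswms <- setNames(lapply(references, function(r) {
      build_pswm(site_collection(unlist(r$sites), r$id),
                 pseudocount = params$pseudocount, background = bgvec)
    }), ref_leaf)
    if (!is.null(tree) && length(references) > 1L) {
      pd <- patristic_distances(tree, sp)
      weights <- mixture_weights(pd[ref_leaf], epsilon = params$epsilon)
    } else {
      weights <- structure(setNames(rep(1 / length(ref_pswms),
                                        length(ref_pswms)),
                                    names(ref_pswms)),
                           class = "mixture_weights")
    }
    pswm <- build_mixture_pswm(ref_pswms, weights)
    pssm <- pswm_to_pssm(pswm, bgvec)
    motifs[[sp]] <- list(pswm = pswm, pssm = pssm, weights = weights)
    species_results[[sp]] <- score_species(genome, pswm, pssm, params, say)
  }

  # --- stage 5: regulated set, orthologs ---------------------------------
  groups <- list()
  ancestral <- list()
  comparative <- length(genomes) >= 2L
  if (!comparative) {
    warning("single-species run: ortholog and ancestral stages skipped")
  } else {
    gene_posteriors <- lapply(species_results, function(res) res$gene_table)
    eligible <- regulated_gene_set(gene_posteriors,
                                   params$posterior_cutoff)
    species_proteins <- lapply(names(genomes), function(sp) {
      g <- genomes[[sp]]$genes
      keep <- g$locus_tag %in% eligible[[sp]] & !is.na(g$protein) &
        nzchar(g$protein)
      setNames(g$protein[keep], g$locus_tag[keep])
    })
    names(species_proteins) <- names(genomes)
    nonempty <- sum(vapply(species_proteins, length, integer(1)) > 0)
    if (nonempty >= 2L) {
      graph <- build_rbh_graph(species_proteins,
                               min_score = params$min_score_ortholog)
      groups <- detect_ortholog_groups(graph)
      say("%d ortholog groups from %d regulated genes", length(groups),
          sum(lengths(species_proteins)))
      # per-species posterior annotation
      groups <- lapply(groups, function(g) {
        post <- vapply(names(g$members), function(sp) {
          gt <- species_results[[sp]]$gene_table
          p <- gt$p_regulated[gt$locus_tag == g$members[[sp]]]
          if (length(p)) p[1] else NA_real_
        }, numeric(1))
        g$posteriors <- post
        g
      })
      # --- stage 6: bootstrapped ancestral reconstruction ------------------
      if (!is.null(tree)) {
        for (k in seq_along(groups)) {
          g <- groups[[k]]
          seed_k <- (as.integer(params$rng_seed) + k) %% .Machine$integer.max
          ancestral[[g$group_id]] <- bootstrap_ancestral_regulation(
            tree, g$posteriors,
            n_replicates = params$bootstrap_replicates, seed = seed_k)
        }
      }
    }
  }

  mat <- build_regulon_matrix(groups, names(genomes))
  result <- structure(
    list(species = species_results, motifs = motifs, tree = tree,
         groups = groups, matrix = mat, ancestral = ancestral,
         config = config, manifest = NULL),
    class = "regulon_reconstruction")
  if (!is.null(output_dir)) {
    result$manifest <- write_reports(result, output_dir, figures = figures)
  }
  result
}

# Per-species operon prediction, splitting and posterior computation.
score_species <- function(genome, pswm, pssm, params, say = function(...) {}) {
  bgvec <- genome$mono_freqs
  threshold <- adaptive_operon_threshold(genome,
                                         multiplier = params$threshold_multiplier)
  operons <- predict_operons(genome, threshold)
  ic <- information_content(pswm, bgvec)
  split_thr <- split_score_threshold(pssm, bgvec, ic)
  # best single-strand score in every gene's upstream window (either strand)
  n_genes <- nrow(genome$genes)
  best_scores <- rep(NA_real_, n_genes)
  for (i in seq_len(n_genes)) {
    reg <- gene_upstream_region(genome, i, params$promoter_upstream,
                                params$promoter_downstream)
    if (!nzchar(reg$sequence)) next
    f <- score_windows(pssm, reg$sequence)
    r <- score_windows(pssm, revcomp(reg$sequence))
    cand <- c(f, r)
    cand <- cand[!is.na(cand)]
    if (length(cand)) best_scores[i] <- max(cand)
  }
  operons <- split_operons_on_sites(operons, genome, best_scores, split_thr)
  say("%s: threshold %.1f bp, %d operons after splitting",
      genome$species_id, threshold, nrow(operons$operons))

  promoters <- operon_promoters(genome, operons, params$promoter_upstream,
                                params$promoter_downstream)
  scans <- lapply(promoters, function(p) scan_promoter(pssm, p$sequence))
  bg_model <- fit_background_model_safe(pssm, promoters, genome, params)
  mm <- fit_motif_model(pssm, pswm)
  apl <- average_promoter_length(genome)
  alpha <- alpha_prior(params$sites_per_promoter, apl)
  n_windows <- sum(vapply(scans, function(s) {
    sum(!is.na(s$combined))
  }, numeric(1)))
  n_ops <- nrow(operons$operons)
  p_r <- if (!is.null(params$n_known_regulated_promoters) &&
             !identical(params$prior_mode, "information-content")) {
    estimate_prior_from_sites(params$n_known_regulated_promoters, n_ops)
  } else {
    estimate_prior_from_ic(max(ic, 1e-6), max(n_windows, 1), n_ops)
  }
  priors <- prior_config(alpha, p_r)
  posts <- vapply(seq_along(scans), function(i) {
    posterior_probability(scans[[i]], bg_model, mm, priors)$p_regulated
  }, numeric(1))

  genes <- genome$genes
  gene_table <- data.frame(locus_tag = genes$locus_tag,
                           operon_id = operons$operon_id,
                           p_regulated = posts[operons$operon_id],
                           stringsAsFactors = FALSE)
  site_rows <- lapply(seq_along(scans), function(i) {
    bs <- best_site(scans[[i]])
    if (is.null(bs)) return(NULL)
    pr <- promoters[[i]]
    wdt <- scans[[i]]$width
    seq <- substr(pr$sequence, bs$position, bs$position + wdt - 1L)
    if (bs$strand == "-") seq <- revcomp(seq)
    data.frame(species = genome$species_id,
               operon_id = operons$operons$operon_id[i],
               locus_tag = genes$locus_tag[pr$first_gene_index],
               position = pr$rel_start + bs$position - 1L,
               strand = bs$strand, site = seq,
               score = bs$combined, p_regulated = posts[i],
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, Filter(Negate(is.null), site_rows))
  operon_table <- operons$operons
  operon_table$p_regulated <- posts
  list(operons = operons, gene_table = gene_table, sites = sites,
       operon_table = operon_table,
       models = list(background = bg_model, motif = mm, priors = priors,
                     ic = ic, split_threshold = split_thr,
                     operon_threshold = threshold,
                     avg_promoter_length = apl))
}

# Background fit with the draft-genome fallback: when the promoter windows
# are too few, widen to windows sampled across the whole genome.
fit_background_model_safe <- function(pssm, promoters, genome, params,
                                      min_windows = 100) {
  regions <- vapply(promoters, `[[`, character(1), "sequence")
  n_windows <- sum(pmax(nchar(regions) - ncol(pssm) + 1L, 0L))
  if (n_windows < min_windows) {
    whole <- unlist(genome$contigs, use.names = FALSE)
    regions <- c(regions, whole)
  }
  fit_background_model(pssm, regions)
}

# Average promoter length, measured as the mean intergenic distance between
# the first genes of opposing (divergently transcribed) directons; 250 bp
# fallback when a genome has no such pair.
average_promoter_length <- function(genome, fallback = 250) {
  genes <- genome$genes
  n <- nrow(genes)
  if (n < 2L) return(fallback)
  same_contig <- genes$contig[-1] == genes$contig[-n]
  divergent <- genes$strand[-n] == "-" & genes$strand[-1] == "+" & same_contig
  gaps <- (genes$start[-1] - genes$end[-n])[divergent]
  gaps <- gaps[gaps > 0]
  if (length(gaps) == 0L) return(fallback)
  mean(gaps)
}

#' @export
print.regulon_reconstruction <- function(x, ...) {
  cat("Regulon reconstruction\n")
  cat(sprintf("  species: %s\n", paste(names(x$species), collapse = ", ")))
  for (sp in names(x$species)) {
    ot <- x$species[[sp]]$operon_table
    cat(sprintf("  %s: %d operons, %d predicted regulated (P > %.2f)\n",
                sp, nrow(ot),
                sum(ot$p_regulated > x$config$parameters$posterior_cutoff),
                x$config$parameters$posterior_cutoff))
  }
  cat(sprintf("  ortholog groups: %d\n", length(x$groups)))
  invisible(x)
}

#' @export
summary.regulon_reconstruction <- function(object, ...) {
  cat("Regulon reconstruction summary\n\n")
  print(object$matrix)
  if (length(object$ancestral)) {
    root_p1 <- vapply(object$ancestral, function(a) {
      a$node_probs[1, "s1"]
    }, numeric(1))
    cat("\nRoot P(regulated) per ortholog group:\n")
    print(round(sort(root_p1, decreasing = TRUE), 3))
  }
  invisible(object)
}

#' Heatmap of the regulon matrix
#'
#' Rows are ortholog groups (sorted by average posterior), columns species;
#' green encodes regulation, red no regulation, blue ortholog absence.
#'
#' @param x a `regulon_reconstruction`.
#' @param ... ignored.
#' @export
plot.regulon_reconstruction <- function(x, ...) {
  m <- x$matrix
  if (nrow(m) == 0L) {
    warning("empty regulon matrix; nothing to plot")
    return(invisible(x))
  }
  pal <- grDevices::colorRampPalette(c("#c03020", "#f0e040", "#208030"))(100)
  z <- t(unclass(m)[nrow(m):1, , drop = FALSE])
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), z,
                  col = pal, zlim = c(0, 1), axes = FALSE,
                  xlab = "", ylab = "")
  # absent cells in blue
  na_idx <- which(is.na(z), arr.ind = TRUE)
  if (nrow(na_idx)) {
    graphics::rect(na_idx[, 1] - 0.5, na_idx[, 2] - 0.5,
                   na_idx[, 1] + 0.5, na_idx[, 2] + 0.5, col = "#3050c0",
                   border = NA)
  }
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 tick = FALSE)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 1, tick = FALSE, cex.axis = 0.7)
  graphics::box()
  invisible(x)
}
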