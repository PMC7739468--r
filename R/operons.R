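#' Partition genes into directons
#'
#' A directon is a maximal run of adjacent same-strand genes on one contig
#' with no intervening gene on the opposite strand. Directons are the
#' candidate units from which operons are carved.
#'
#' @param genome a `genome` object.
#' @return Integer vector of directon ids, one per row of `genome$genes`
#'   (coordinate order); ids increase along the genome.
#' @export
find_directons <- function(genome) {
  genes <- genome$genes
  n <- nrow(genes)
  if (n == 0L) return(integer(0))
  new_block <- c(TRUE, genes$contig[-1] != genes$contig[-n] |
                   genes$strand[-1] != genes$strand[-n])
  cumsum(new_block)
}

# Intergenic distances between within-directon adjacent gene pairs.
# 0-based half-open coordinates: distance = start(downstream) - end(upstream);
# overlapping genes give negative values.
directon_gaps <- function(genome, directons = find_directons(genome)) {
  genes <- genome$genes
  n <- nrow(genes)
  if (n < 2L) return(numeric(0))
  same <- directons[-1] == directons[-n]
  genes$start[-1][same] - genes$end[-n][same]
}

#' Genome-adaptive operon distance threshold
#'
#' The intergenic-distance threshold below which adjacent same-directon genes
#' are predicted co-operonic, set adaptively per genome as the mean
#' intergenic distance over all within-directon adjacent pairs. This tracks
#' each genome's coding density instead of imposing a fixed cutoff.
#'
#' @param genome a `genome` object.
#' @param multiplier scale factor on the adaptive mean (default 1) for users
#'   who want a looser or stricter threshold.
#' @param fallback threshold (bp) used, with a warning, when a genome has no
#'   within-directon pairs.
#' @return Threshold in bp.
#' @export
adaptive_operon_threshold <- function(genome, multiplier = 1, fallback = 50) {
  gaps <- directon_gaps(genome)
  if (length(gaps) == 0L) {
    warning("no within-directon gene pairs; using fallback threshold of ",
            fallback, " bp")
    return(fallback)
  }
  multiplier * mean(gaps)
}

#' Predict operons by intergenic distance
#'
#' Within each directon, adjacent genes stay in the same operon when their
#' intergenic distance is at most the threshold (ties kept together); larger
#' gaps split the directon. Overlapping genes (negative distance) are always
#' co-operonic.
#'
#' @param genome a `genome` object.
#' @param threshold distance threshold in bp, e.g. from
#'   [adaptive_operon_threshold()].
#' @return An `operon_set`: list with `operon_id` (integer per gene, rows of
#'   `genome$genes`) and `operons`, a data.frame with one row per operon:
#'   `operon_id`, `contig`, `strand`, `first_gene` (locus tag of the
#'   promoter-proximal gene), `n_genes`, `genes` (comma-joined locus tags in
#'   transcription order).
#' @export
predict_operons <- function(genome, threshold = adaptive_operon_threshold(genome)) {
  genes <- genome$genes
  n <- nrow(genes)
  directons <- find_directons(genome)
  if (n == 0L) {
    return(new_operon_set(genome, integer(0)))
  }
  split_here <- c(TRUE, directons[-1] != directons[-n] |
                    (genes$start[-1] - genes$end[-n]) > threshold)
  new_operon_set(genome, cumsum(split_here))
}

new_operon_set <- function(genome, operon_id) {
  genes <- genome$genes
  # relabel ids 1..k in coordinate order of first appearance
  operon_id <- as.integer(factor(operon_id, levels = unique(operon_id)))
  ops <- lapply(split(seq_along(operon_id), operon_id), function(idx) {
    strand <- genes$strand[idx[1]]
    # transcription order: minus-strand operons read right-to-left
    ord <- if (strand == "-") rev(idx) else idx
    data.frame(contig = genes$contig[idx[1]], strand = strand,
               first_gene = genes$locus_tag[ord[1]],
               n_genes = length(idx),
               genes = paste(genes$locus_tag[ord], collapse = ","),
               stringsAsFactors = FALSE)
  })
  operons <- if (length(ops)) do.call(rbind, ops) else
    data.frame(contig = character(0), strand = character(0),
               first_gene = character(0), n_genes = integer(0),
               genes = character(0))
  operons$operon_id <- seq_len(nrow(operons))
  rownames(operons) <- NULL
  structure(list(operon_id = operon_id,
                 operons = operons[c("operon_id", "contig", "strand",
                                     "first_gene", "n_genes", "genes")]),
            class = "operon_set")
}

#' @export
print.operon_set <- function(x, ...) {
  cat(sprintf("Operon set: %d operons over %d genes\n",
              nrow(x$operons), length(x$operon_id)))
  invisible(x)
}

#' Extract a gene's upstream (promoter) region
#'
#' The scanned window spans -250 to +50 bp around the predicted translation
#' start, truncated at the boundary of the adjacent upstream gene, at the
#' gene's own end, and at contig edges. The sequence is returned 5'-to-3'
#' relative to the gene, so window coordinates map directly onto positions
#' relative to the translation start.
#'
#' @param genome a `genome`.
#' @param gene_index row index into `genome$genes`.
#' @param upstream,downstream window extent in bp around the translation
#'   start.
#' @return List with `sequence` and `rel_start` (offset of the first base of
#'   the returned sequence relative to the translation start, negative
#'   upstream); `sequence` may be empty after truncation.
#' @export
gene_upstream_region <- function(genome, gene_index, upstream = 250,
                                 downstream = 50) {
  genes <- genome$genes
  g <- genes[gene_index, ]
  contig_seq <- genome$contigs[[g$contig]]
  clen <- nchar(contig_seq)
  on_contig <- which(genes$contig == g$contig)
  if (g$strand == "+") {
    # nearest feature end at or before this gene's start
    prev_end <- genes$end[on_contig]
    prev_end <- prev_end[prev_end <= g$start & on_contig != gene_index]
    lower <- max(0L, g$start - upstream, if (length(prev_end)) max(prev_end))
    upper <- min(g$start + downstream, g$end, clen)
    if (upper <= lower) return(list(sequence = "", rel_start = 0L))
    list(sequence = substr(contig_seq, lower + 1L, upper),
         rel_start = lower - g$start)
  } else {
    next_start <- genes$start[on_contig]
    next_start <- next_start[next_start >= g$end & on_contig != gene_index]
    upper <- min(clen, g$end + upstream,
                 if (length(next_start)) min(next_start) else clen)
    lower <- max(g$end - downstream, g$start, 0L)
    if (upper <= lower) return(list(sequence = "", rel_start = 0L))
    list(sequence = revcomp(substr(contig_seq, lower + 1L, upper)),
         rel_start = g$end - upper)
  }
}

# Promoter region of each operon: upstream window of its first gene.
# Returns a list (one element per operon row) of gene_upstream_region outputs
# plus the first gene's row index.
operon_promoters <- function(genome, operon_set, upstream = 250,
                             downstream = 50) {
  genes <- genome$genes
  lapply(seq_len(nrow(operon_set$operons)), function(i) {
    op <- operon_set$operons[i, ]
    idx <- which(operon_set$operon_id == op$operon_id)
    first_idx <- if (op$strand == "-") idx[which.max(genes$start[idx])] else
      idx[which.min(genes$start[idx])]
    reg <- gene_upstream_region(genome, first_idx, upstream, downstream)
    reg$first_gene_index <- first_idx
    reg$operon_id <- op$operon_id
    reg
  })
}

#' PSSM score threshold for operon splitting
#'
#' The split rule marks a site as "high-scoring" when its single-strand PSSM
#' score exceeds the threshold at which the negative log2 false-positive rate
#' equals the motif's information content: the smallest score t with
#' `FPR(t) <= 2^(-IC)`, where `FPR(t)` is the probability that a random
#' background sequence scores at least t. The exact score distribution under
#' the background is computed by dynamic programming over per-position scores
#' discretised to `bin`-bit steps.
#'
#' @param pssm a `pssm`.
#' @param background length-4 probability vector the random sequence is drawn
#'   from.
#' @param ic information content of the motif in bits (> 0).
#' @param bin discretisation step in bits.
#' @return The threshold score in bits (a multiple of `bin`). If even the
#'   maximum attainable score has FPR above the target the maximum score is
#'   returned with a warning.
#' @export
split_score_threshold <- function(pssm, background = attr(pssm, "background"),
                                  ic, bin = 0.01) {
  stopifnot(ic > 0)
  background <- check_background(background)
  dist <- pssm_score_distribution(pssm, background, bin)
  target <- 2^(-ic)
  # survival function: P(score >= t), t descending over support
  surv <- rev(cumsum(rev(dist$prob)))
  ok <- which(surv <= target)
  if (length(ok) == 0L) {
    warning("requested FPR 2^-IC unattainable for this motif; ",
            "returning maximum attainable score")
    return(dist$score[length(dist$score)])
  }
  dist$score[ok[1]]
}

# Exact distribution of the single-strand PSSM score of an i.i.d. background
# sequence, over scores discretised to `bin` bits. Returns list(score, prob)
# over the support (ascending).
pssm_score_distribution <- function(pssm, background, bin = 0.01) {
  ints <- round(unclass(pssm) / bin)  # 4 x width integer matrix
  if (any(!is.finite(ints))) {
    stop("PSSM has infinite scores; use a positive pseudocount", call. = FALSE)
  }
  probs <- c(1)
  offset <- 0L  # probs[k] = P(sum = offset + k - 1)
  for (j in seq_len(ncol(ints))) {
    col <- ints[, j]
    new_lo <- offset + min(col)
    new_hi <- offset + length(probs) - 1L + max(col)
    np <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      if (background[b] == 0) next
      sh <- offset + col[b] - new_lo
      idx <- seq_along(probs) + sh
      np[idx] <- np[idx] + background[b] * probs
    }
    probs <- np
    offset <- new_lo
  }
  keep <- probs > 0
  list(score = (offset + which(keep) - 1L) * bin, prob = probs[keep])
}

#' Split operons on internal high-scoring sites
#'
#' Conservative (long) operon predictions can swallow genes that carry their
#' own regulated promoter. Every gene's upstream window is scanned; a
#' non-first operon member whose window contains a site scoring at or above
#' the split threshold becomes the first gene of a new operon. Applied at
#' every qualifying gene; idempotent.
#'
#' @param operon_set an `operon_set`.
#' @param genome the `genome` it was built from.
#' @param per_gene_best_scores numeric vector, one per gene row, of the best
#'   single-strand PSSM score in the gene's upstream window (NA when the
#'   window is empty).
#' @param split_threshold score threshold from [split_score_threshold()].
#' @return A revised `operon_set` with deterministically reassigned ids.
#' @export
split_operons_on_sites <- function(operon_set, genome, per_gene_best_scores,
                                   split_threshold) {
  genes <- genome$genes
  op_id <- operon_set$operon_id
  n <- length(op_id)
  if (n == 0L) return(operon_set)
  qualifies <- !is.na(per_gene_best_scores) &
    per_gene_best_scores >= split_threshold
  # first gene of each operon in transcription order
  is_first <- logical(n)
  for (oid in unique(op_id)) {
    idx <- which(op_id == oid)
    first_idx <- if (genes$strand[idx[1]] == "-")
      idx[which.max(genes$start[idx])] else idx[which.min(genes$start[idx])]
    is_first[first_idx] <- TRUE
  }
  new_first <- qualifies & !is_first
  if (!any(new_first)) return(operon_set)
  # walk genes in transcription order within each operon, cutting before each
  # qualifying gene
  new_ids <- integer(n)
  counter <- 0L
  for (oid in unique(op_id)) {
    idx <- which(op_id == oid)
    ord <- if (genes$strand[idx[1]] == "-") rev(idx) else idx
    counter <- counter + 1L
    for (i in ord) {
      if (new_first[i] && i != ord[1]) counter <- counter + 1L
      new_ids[i] <- counter
    }
  }
  new_operon_set(genome, new_ids)
}
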