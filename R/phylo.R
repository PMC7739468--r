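#' Poisson-corrected distance between two protein sequences
#'
#' Globally aligns the two sequences (BLOSUM62, affine gaps: open 10,
#' extend 0.5) and converts the mismatch fraction over aligned (non-gap)
#' columns into an evolutionary distance with the Poisson correction
#' `d = -ln(1 - p_dist)`, in substitutions per site. Symmetric, and zero for
#' identical sequences.
#'
#' @param a,b amino-acid sequences (character strings).
#' @param max_distance distance returned when the alignment has no usable
#'   overlap or the correction diverges (`p_dist` near 1).
#' @return Distance in substitutions/site.
#' @examples
#' pairwise_distance("MKVLAT", "MKVLAT")  # 0
#' @export
pairwise_distance <- function(a, b, max_distance = 5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- pa != "-" & ps != "-"
  if (!any(keep)) return(max_distance)
  p_dist <- mean(pa[keep] != ps[keep])
  if (p_dist >= 1 - exp(-max_distance)) return(max_distance)
  -log(1 - p_dist)
}

#' Pairwise distance matrix for a set of proteins
#'
#' @param proteins named character vector of amino-acid sequences.
#' @return Symmetric matrix of Poisson-corrected distances with zero
#'   diagonal.
#' @export
protein_distance_matrix <- function(proteins) {
  n <- length(proteins)
  stopifnot(n >= 2, !is.null(names(proteins)))
  d <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- pairwise_distance(proteins[[i]], proteins[[j]])
    }
  }
  d
}

#' Build the TF phylogeny by neighbor joining
#'
#' Neighbor-joining tree from a symmetric distance matrix, with negative
#' branch lengths clamped to zero and midpoint rooting (no outgroup is
#' assumed; ancestral reconstruction requires a root). Leaf order is made
#' deterministic by sorting taxa by name before tree construction.
#'
#' @param distance_matrix symmetric numeric matrix with zero diagonal and
#'   row/column names; at least 2 taxa.
#' @return A rooted `phylo` object (ape).
#' @export
build_nj_tree <- function(distance_matrix) {
  n <- nrow(distance_matrix)
  if (is.null(n) || n < 2) stop("need at least 2 taxa", call. = FALSE)
  stopifnot(identical(rownames(distance_matrix), colnames(distance_matrix)))
  ord <- order(rownames(distance_matrix))
  d <- distance_matrix[ord, ord]
  if (n == 2) {
    tree <- ape::read.tree(text = sprintf(
      "(%s:%f,%s:%f);", rownames(d)[1], d[1, 2] / 2,
      rownames(d)[2], d[1, 2] / 2))
    return(tree)
  }
  tree <- ape::nj(as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree <- phangorn::midpoint(tree)
  # a zero-length or absent root edge can leave a trifurcation; resolve
  tree <- ape::multi2di(tree, random = FALSE)
  tree$edge.length[is.na(tree$edge.length)] <- 0
  tree
}

#' Patristic distances from one leaf to all leaves
#'
#' Sum of branch lengths along the connecting path; drives the mixture
#' weighting of reference motifs.
#'
#' @param tree a rooted `phylo`.
#' @param target_leaf leaf (tip) label.
#' @return Named numeric vector over all leaves; zero for the target itself.
#' @export
patristic_distances <- function(tree, target_leaf) {
  if (!target_leaf %in% tree$tip.label) {
    stop("leaf '", target_leaf, "' not in tree", call. = FALSE)
  }
  dm <- ape::cophenetic.phylo(tree)
  setNames(dm[target_leaf, tree$tip.label], tree$tip.label)
}

#' Internal exhaustive protein-search backend
#'
#' Search backend used when no external sequence-search tool is configured:
#' scores the query against every subject with a global BLOSUM62 alignment
#' and reports normalised scores (raw score divided by the query's
#' self-alignment score, so 1 means identity and values near 0 mean no
#' similarity). Satisfies the pluggable backend contract: a function
#' `(query, subjects) -> data.frame(id, score)` with subjects ranked by
#' score.
#'
#' @param query amino-acid string.
#' @param subjects named character vector of amino-acid strings.
#' @return data.frame with columns `id`, `score` (normalised), sorted by
#'   decreasing score then id.
#' @export
alignment_search_backend <- function(query, subjects) {
  subjects <- subjects[nzchar(subjects) & !is.na(subjects)]
  if (length(subjects) == 0L) {
    return(data.frame(id = character(0), score = numeric(0)))
  }
  self <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(query),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global", scoreOnly = TRUE)
  raw <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(subjects)), Biostrings::AAString(query),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global", scoreOnly = TRUE)
  out <- data.frame(id = names(subjects), score = raw / self,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$id), , drop = FALSE]
}

#' Find the TF ortholog in a target genome
#'
#' Best hit of the reference TF protein among the genome's proteins, subject
#' to a significance cutoff on the normalised score; when the reference
#' genome is supplied, the hit must also be reciprocal (the candidate's best
#' hit in the reference genome is the reference TF itself), which filters
#' out diverged paralogs.
#'
#' @param reference_tf list with `id` and `protein` (amino-acid string) of
#'   the reference TF instance.
#' @param genome a `genome`.
#' @param backend search backend function (see
#'   [alignment_search_backend()]).
#' @param min_score minimum normalised score for a significant hit.
#' @param reference_genome optional `genome` containing the reference TF
#'   gene, enabling the reciprocal check.
#' @return List with `locus_tag`, `protein`, `score`, or `NULL` when no gene
#'   passes the cutoff (the species is then dropped from the analysis).
#' @export
find_tf_ortholog <- function(reference_tf, genome,
                             backend = alignment_search_backend,
                             min_score = 0.3, reference_genome = NULL) {
  prots <- setNames(genome$genes$protein, genome$genes$locus_tag)
  hits <- backend(reference_tf$protein, prots)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  for (k in seq_len(nrow(hits))) {
    cand <- hits[k, ]
    if (!is.null(reference_genome)) {
      back <- backend(prots[[cand$id]],
                      setNames(reference_genome$genes$protein,
                               reference_genome$genes$locus_tag))
      if (nrow(back) == 0L) next
      best_back <- back$id[1]
      ref_row <- reference_genome$genes$protein ==
        reference_tf$protein
      if (!best_back %in% reference_genome$genes$locus_tag[ref_row]) next
    }
    return(list(locus_tag = cand$id, protein = unname(prots[[cand$id]]),
                score = cand$score))
  }
  NULL
}
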