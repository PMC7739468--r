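#' Genes eligible for ortholog detection
#'
#' Comparative regulon reconstruction only needs orthology for genes that
#' might be regulated somewhere: the search is limited to genes in operons
#' whose posterior probability of regulation exceeds the cutoff in at least
#' one target species.
#'
#' @param species_results named list (per species) of data.frames with
#'   columns `locus_tag` and `p_regulated` (the gene's operon posterior).
#' @param probability_cutoff posterior cutoff (strict inequality).
#' @return Named list (per species) of locus tags to include.
#' @export
regulated_gene_set <- function(species_results, probability_cutoff = 0.5) {
  lapply(species_results, function(df) {
    df$locus_tag[!is.na(df$p_regulated) &
                   df$p_regulated > probability_cutoff]
  })
}

#' Reciprocal best hits between two species
#'
#' An edge (a, b) is emitted when b is a's best significant hit among
#' species B's proteins and a is b's best among species A's. Ties on score
#' are broken by lexicographic gene id, making the edge set deterministic.
#'
#' @param species_a_genes,species_b_genes named character vectors of protein
#'   sequences (names are locus tags).
#' @param backend search backend (see [alignment_search_backend()]).
#' @param min_score significance cutoff on the backend's normalised score.
#' @return data.frame with columns `a`, `b`, `score` (mean of the two
#'   directed scores).
#' @export
reciprocal_best_hits <- function(species_a_genes, species_b_genes,
                                 backend = alignment_search_backend,
                                 min_score = 0.3) {
  stopifnot(length(species_a_genes) > 0, length(species_b_genes) > 0)
  best_hit <- function(query, subjects) {
    hits <- backend(query, subjects)
    hits <- hits[hits$score >= min_score, , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
    # backend returns score-desc, id-asc; row 1 is the deterministic best
    hits[1, ]
  }
  edges <- list()
  best_ab <- lapply(species_a_genes, best_hit, subjects = species_b_genes)
  best_ba <- lapply(species_b_genes, best_hit, subjects = species_a_genes)
  for (a in names(species_a_genes)) {
    hit <- best_ab[[a]]
    if (is.null(hit)) next
    back <- best_ba[[hit$id]]
    if (!is.null(back) && back$id == a) {
      edges[[length(edges) + 1L]] <-
        data.frame(a = a, b = hit$id,
                   score = (hit$score + back$score) / 2,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(0), b = character(0), score = numeric(0))
}

#' Build the cross-species reciprocal-best-hit graph
#'
#' Vertices are (species, gene) pairs; undirected edges connect reciprocal
#' best hits for every pair of species. Vertex names are
#' `"species|locus_tag"`.
#'
#' @param species_proteins named list (per species) of named protein
#'   vectors.
#' @param backend,min_score passed to [reciprocal_best_hits()].
#' @return An `igraph` undirected graph with edge attribute `score` and
#'   vertex attributes `species` and `locus_tag`.
#' @export
build_rbh_graph <- function(species_proteins,
                            backend = alignment_search_backend,
                            min_score = 0.3) {
  sp <- names(species_proteins)
  stopifnot(length(sp) >= 2)
  verts <- data.frame(
    name = unlist(lapply(sp, function(s) {
      paste(s, names(species_proteins[[s]]), sep = "|")
    })),
    species = unlist(lapply(sp, function(s) {
      rep(s, length(species_proteins[[s]]))
    })),
    stringsAsFactors = FALSE)
  verts$locus_tag <- sub("^[^|]*\\|", "", verts$name)
  edge_rows <- list()
  for (i in seq_len(length(sp) - 1)) {
    for (j in (i + 1):length(sp)) {
      if (length(species_proteins[[i]]) == 0L ||
          length(species_proteins[[j]]) == 0L) next
      e <- reciprocal_best_hits(species_proteins[[i]], species_proteins[[j]],
                                backend, min_score)
      if (nrow(e)) {
        e$a <- paste(sp[i], e$a, sep = "|")
        e$b <- paste(sp[j], e$b, sep = "|")
        edge_rows[[length(edge_rows) + 1L]] <- e
      }
    }
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(a = character(0), b = character(0), score = numeric(0))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Detect ortholog groups as cliques of the RBH graph
#'
#' Maximal cliques of the reciprocal-best-hit graph are candidate ortholog
#' groups; since a gene can lie in several maximal cliques, genes are
#' assigned greedily to cliques by decreasing size (ties: larger total edge
#' score, then lexicographic member ids), and leftover genes become
#' singleton groups.
#'
#' @param graph an `igraph` RBH graph from [build_rbh_graph()].
#' @return List of `ortholog_group` objects, each a list with `group_id`,
#'   `members` (named character: species -> locus_tag) and `vertex_names`.
#'   Ordered by decreasing size then lexicographic members.
#' @export
detect_ortholog_groups <- function(graph) {
  vnames <- igraph::V(graph)$name
  species <- igraph::V(graph)$species
  cliques <- igraph::max_cliques(graph)
  keys <- lapply(cliques, function(cl) sort(vnames[as.integer(cl)]))
  sizes <- lengths(keys)
  scores <- vapply(cliques, function(cl) {
    sub <- igraph::induced_subgraph(graph, cl)
    s <- igraph::E(sub)$score
    if (length(s)) sum(s) else 0
  }, numeric(1))
  lex <- vapply(keys, paste, character(1), collapse = ",")
  ord <- order(-sizes, -scores, lex)
  assigned <- character(0)
  groups <- list()
  for (k in ord) {
    members <- setdiff(keys[[k]], assigned)
    if (length(members) < length(keys[[k]]))
      next  # clique broken by earlier assignment; leftovers fall through
    assigned <- c(assigned, members)
    groups[[length(groups) + 1L]] <- members
  }
  # remaining genes (from broken cliques or isolated vertices)
  leftover <- setdiff(vnames, assigned)
  for (v in sort(leftover)) groups[[length(groups) + 1L]] <- v
  # deterministic ordering and ids
  glex <- vapply(groups, paste, character(1), collapse = ",")
  groups <- groups[order(-lengths(groups), glex)]
  lapply(seq_along(groups), function(i) {
    mem <- groups[[i]]
    sp <- species[match(mem, vnames)]
    structure(list(group_id = sprintf("OG%04d", i),
                   members = setNames(sub("^[^|]*\\|", "", mem), sp),
                   vertex_names = mem),
              class = "ortholog_group")
  })
}

#' @export
print.ortholog_group <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$group_id,
              paste(names(x$members), x$members, sep = ":", collapse = ", ")))
  invisible(x)
}
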