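# Independent oracle implementations used to cross-check the package.
# These deliberately use naive direct algorithms (enumeration, direct
# arithmetic) rather than the package's own code paths.

DNA <- c("A", "C", "G", "T")

# Direct-space (non-log) evaluation of the posterior probability of
# regulation: products of densities, no log-sum-exp.
oracle_posterior <- function(scores, mu_G, sigma_G, mu_M, sigma_M, alpha,
                             p_r) {
  lik_r <- prod(alpha * dnorm(scores, mu_M, sigma_M) +
                  (1 - alpha) * dnorm(scores, mu_G, sigma_G))
  lik_b <- prod(dnorm(scores, mu_G, sigma_G))
  lik_r * p_r / (lik_r * p_r + lik_b * (1 - p_r))
}

# Brute-force operon splitter: per directon, walk adjacent pairs and cut on
# distance > threshold. Returns an integer operon label per gene row.
oracle_split_operons <- function(genes, directons, threshold) {
  labels <- integer(nrow(genes))
  current <- 0L
  for (i in seq_len(nrow(genes))) {
    if (i == 1L || directons[i] != directons[i - 1L] ||
        (genes$start[i] - genes$end[i - 1L]) > threshold) {
      current <- current + 1L
    }
    labels[i] <- current
  }
  labels
}

# Exhaustive k-mer score distribution: every sequence of the motif width,
# scored column by column with the same binned scores as the DP, weighted by
# background probability.
oracle_kmer_fpr <- function(pssm, background, threshold, bin = 0.01) {
  w <- ncol(pssm)
  ints <- round(unclass(pssm) / bin)
  kmers <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(kmers))
  probs <- numeric(nrow(kmers))
  for (i in seq_len(nrow(kmers))) {
    idx <- kmers[i, ]
    scores[i] <- sum(ints[cbind(idx, seq_len(w))]) * bin
    probs[i] <- prod(background[idx])
  }
  sum(probs[scores >= threshold - 1e-12])
}

# Independent maximal-clique enumeration by recursive extension (no igraph).
# adj: logical adjacency matrix. Returns a list of sorted vertex-name vectors.
oracle_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  vnames <- rownames(adj)
  out <- list()
  extend <- function(clique, candidates) {
    if (length(candidates) == 0L) {
      # maximal iff no vertex outside extends the clique
      extendable <- any(vapply(setdiff(seq_len(n), clique), function(v) {
        all(adj[v, clique])
      }, logical(1)))
      if (!extendable) out[[length(out) + 1L]] <<- sort(vnames[clique])
      return(invisible())
    }
    v <- candidates[1]
    extend(c(clique, v), candidates[candidates > v & adj[v, candidates]])
    extend(clique, candidates[-1])
  }
  for (v in seq_len(n)) {
    extend(v, which(adj[v, ] & seq_len(n) > v))
  }
  unique(out)
}

# Greedy clique-to-group assignment: decreasing size, ties by total edge
# score then lexicographic member string; partially-consumed cliques are
# skipped and leftovers become singletons. Mirrors the documented policy,
# implemented independently.
oracle_greedy_groups <- function(cliques, adj, scores, vnames) {
  sizes <- lengths(cliques)
  tot <- vapply(cliques, function(cl) {
    idx <- match(cl, vnames)
    s <- 0
    if (length(idx) > 1) {
      for (i in seq_len(length(idx) - 1)) {
        for (j in (i + 1):length(idx)) s <- s + scores[idx[i], idx[j]]
      }
    }
    s
  }, numeric(1))
  lex <- vapply(cliques, paste, character(1), collapse = ",")
  ord <- order(-sizes, -tot, lex)
  assigned <- character(0)
  groups <- list()
  for (k in ord) {
    if (any(cliques[[k]] %in% assigned)) next
    groups[[length(groups) + 1L]] <- cliques[[k]]
    assigned <- c(assigned, cliques[[k]])
  }
  for (v in sort(setdiff(vnames, assigned))) {
    groups[[length(groups) + 1L]] <- v
  }
  glex <- vapply(groups, paste, character(1), collapse = ",")
  groups[order(-lengths(groups), glex)]
}

# Brute-force marginal ancestral probabilities: enumerate every assignment
# of states to internal nodes, accumulate joint probabilities.
oracle_mk_marginals <- function(tree, states, rate) {
  k <- 3L
  st <- c("s0", "s1", "sa")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  internals <- ntip + seq_len(nnode)
  tipstate <- match(states[tree$tip.label], st)
  pm <- function(t) {
    e <- exp(-k * rate * t)
    m <- matrix((1 - e) / k, k, k); diag(m) <- 1 / k + (k - 1) / k * e
    m
  }
  edge_p <- lapply(seq_len(nrow(tree$edge)), function(e) {
    pm(tree$edge.length[e])
  })
  combos <- as.matrix(expand.grid(rep(list(1:k), nnode)))
  marg <- matrix(0, nnode, k, dimnames = list(internals, st))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    assign_state <- function(node) {
      if (node <= ntip) tipstate[node] else combos[r, node - ntip]
    }
    p <- 1 / k  # uniform root prior
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * edge_p[[e]][assign_state(tree$edge[e, 1]),
                           assign_state(tree$edge[e, 2])]
    }
    total <- total + p
    for (v in seq_len(nnode)) {
      marg[v, combos[r, v]] <- marg[v, combos[r, v]] + p
    }
  }
  marg / total
}

# Exact expectation of the combined two-strand score of a background window,
# by full k-mer enumeration (small widths only).
oracle_combined_score_mean <- function(pssm, background) {
  w <- ncol(pssm)
  m <- unclass(pssm)
  kmers <- as.matrix(expand.grid(rep(list(1:4), w)))
  comp <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
  total <- 0
  for (i in seq_len(nrow(kmers))) {
    idx <- kmers[i, ]
    f <- sum(m[cbind(idx, seq_len(w))])
    rc <- rev(comp[idx])
    r <- sum(m[cbind(rc, seq_len(w))])
    total <- total + prod(background[idx]) * log2(2^f + 2^r)
  }
  total
}

# Random sequence helpers for tests.
rand_dna <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(DNA, n, replace = TRUE, prob = freqs), collapse = "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Light-weight genome builder with known operon structure, for operon
# prediction tests; no promoter sequence content is needed.
make_operon_fixture <- function(n_operons = 12, within_mean = 15,
                                within_sd = 5, between_mean = 150,
                                between_sd = 40, max_genes = 4) {
  sizes <- sample(seq_len(max_genes), n_operons, replace = TRUE)
  # directons of 1-3 consecutive operons, alternating strands
  directon_of <- integer(n_operons)
  d <- 0L; i <- 1L
  while (i <= n_operons) {
    d <- d + 1L
    take <- min(sample(1:3, 1), n_operons - i + 1L)
    directon_of[i:(i + take - 1L)] <- d
    i <- i + take
  }
  strands <- rep(c("+", "-"), length.out = max(directon_of))
  rows <- list(); truth_op <- integer(0)
  pos <- 50L; gid <- 0L
  for (op in seq_len(n_operons)) {
    gap <- max(60, round(rnorm(1, between_mean, between_sd)))
    pos <- pos + gap
    for (g in seq_len(sizes[op])) {
      gid <- gid + 1L
      if (g > 1L) {
        pos <- pos + max(-10, round(rnorm(1, within_mean, within_sd)))
      }
      len <- sample(300:900, 1)
      rows[[gid]] <- data.frame(
        contig = "c1", locus_tag = sprintf("g%03d", gid),
        start = pos, end = pos + len,
        strand = strands[directon_of[op]], product = "",
        protein = "M", stringsAsFactors = FALSE)
      truth_op[gid] <- op
      pos <- pos + len
    }
  }
  genes <- do.call(rbind, rows)
  genome <- structure(list(
    species_id = "fix", contigs = list(c1 = strrep("A", pos + 100L)),
    genes = genes, mono_freqs = setNames(rep(0.25, 4), DNA)),
    class = "genome")
  list(genome = genome, truth_operon = truth_op)
}

# Fraction of genes assigned to the operon whose first gene matches the true
# operon's first gene (promoter assignment accuracy).
promoter_accuracy <- function(genome, predicted_ids, truth_ids) {
  genes <- genome$genes
  first_of <- function(ids) {
    vapply(ids, function(id) {
      idx <- which(ids == id)
      if (genes$strand[idx[1]] == "-") {
        genes$locus_tag[idx[which.max(genes$start[idx])]]
      } else {
        genes$locus_tag[idx[which.min(genes$start[idx])]]
      }
    }, character(1))
  }
  mean(first_of(predicted_ids) == first_of(truth_ids))
}
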