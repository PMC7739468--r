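REG_STATES <- c("s0", "s1", "sa")  # non-regulated, regulated, ortholog absent

# Transition probability matrix of the k-state equal-rates Markov model over
# a branch of length t: P_ii = 1/k + (k-1)/k e^{-k r t}, P_ij = 1/k (1 - e^{-k r t}).
mk_transition_matrix <- function(rate, t, k = 3L) {
  e <- exp(-k * rate * t)
  p_diff <- (1 - e) / k
  m <- matrix(p_diff, k, k)
  diag(m) <- 1 / k + (k - 1) / k * e
  m
}

#' Sample discrete leaf states for one bootstrap replicate
#'
#' Each species with an ortholog group member draws the regulated state `s1`
#' with its posterior probability of regulation and the non-regulated state
#' `s0` otherwise; species without a member are deterministically assigned
#' the absent state `sa`.
#'
#' @param leaves character vector of tree leaf names (species ids).
#' @param posteriors named numeric vector of per-species regulation
#'   posteriors; species missing from the vector (or NA) are treated as
#'   lacking an ortholog.
#' @return Named character vector over `leaves` with values in
#'   `c("s0","s1","sa")`.
#' @export
sample_leaf_states <- function(leaves, posteriors) {
  out <- setNames(rep("sa", length(leaves)), leaves)
  present <- intersect(leaves, names(posteriors))
  present <- present[!is.na(posteriors[present])]
  if (length(present)) {
    draw <- runif(length(present)) < posteriors[present]
    out[present] <- ifelse(draw, "s1", "s0")
  }
  out
}

#' Marginal ancestral state probabilities under the 3-state Mk model
#'
#' Computes, for every internal node of a rooted tree with branch lengths,
#' the marginal posterior probability of each regulation state (`s0`, `s1`,
#' `sa`) given the leaf states, under an equal-rates continuous-time Markov
#' model with a uniform root prior. Uses the pruning algorithm for the
#' downward pass and an outside (upward) pass for the marginals, so the
#' result is exact.
#'
#' @param tree rooted `phylo` with branch lengths; tip labels must cover
#'   `names(states)`.
#' @param states named character vector (leaf -> state in s0/s1/sa), one
#'   entry per tip.
#' @param rate transition rate of the Mk model (> 0).
#' @return Matrix: rows = internal node ids (ape numbering, `Ntip+1` is the
#'   root), columns = states; each row sums to 1. Attribute `log_likelihood`
#'   carries the data log-likelihood.
#' @export
mk_ancestral_marginals <- function(tree, states, rate) {
  k <- 3L
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- ntip + nnode
  stopifnot(all(tree$tip.label %in% names(states)), rate > 0)
  children <- vector("list", total)
  branch_len <- numeric(total)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    children[[par]] <- c(children[[par]], chd)
    branch_len[chd] <- tree$edge.length[e]
  }
  pmat <- lapply(seq_len(total), function(v) {
    mk_transition_matrix(rate, branch_len[v], k)
  })
  # downward (pruning) pass: D[v, s] = P(data below v | state(v) = s)
  D <- matrix(1, total, k)
  for (i in seq_len(ntip)) {
    D[i, ] <- 0
    D[i, match(states[[tree$tip.label[i]]], REG_STATES)] <- 1
  }
  # process internal nodes children-first (reverse of a root-first walk)
  depth <- numeric(total)
  root <- ntip + 1L
  stack <- root
  order_down <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_down <- c(order_down, v)
    for (c in children[[v]]) {
      depth[c] <- depth[v] + 1
      stack <- c(stack, c)
    }
  }
  internals <- order_down[order_down > ntip]
  for (v in rev(internals)) {
    for (c in children[[v]]) {
      D[v, ] <- D[v, ] * as.numeric(pmat[[c]] %*% D[c, ])
    }
  }
  root_prior <- rep(1 / k, k)
  lik <- sum(root_prior * D[root, ])
  # upward (outside) pass: U[v, s] = P(data outside subtree of v, state(v)=s)
  U <- matrix(0, total, k)
  U[root, ] <- root_prior
  for (v in internals) {
    for (c in children[[v]]) {
      sib_prod <- rep(1, k)
      for (s in setdiff(children[[v]], c)) {
        sib_prod <- sib_prod * as.numeric(pmat[[s]] %*% D[s, ])
      }
      U[c, ] <- as.numeric(t(pmat[[c]]) %*% (U[v, ] * sib_prod))
    }
  }
  marg <- D[internals, , drop = FALSE] * U[internals, , drop = FALSE]
  rs <- rowSums(marg)
  # zero-length branches with conflicting leaf states can zero out the
  # likelihood; the root prior then resolves the conflict
  marg[rs == 0, ] <- 1 / k
  rs[rs == 0] <- 1
  marg <- marg / rs
  rownames(marg) <- internals
  colnames(marg) <- REG_STATES
  marg <- marg[order(as.integer(rownames(marg))), , drop = FALSE]
  attr(marg, "log_likelihood") <- log(lik)
  marg
}

# Log-likelihood of leaf states under the Mk model (downward pruning pass
# only; no marginals).
mk_loglik <- function(tree, states, rate) {
  k <- 3L
  ntip <- length(tree$tip.label)
  total <- ntip + tree$Nnode
  D <- matrix(1, total, k)
  for (i in seq_len(ntip)) {
    D[i, ] <- 0
    D[i, match(states[[tree$tip.label[i]]], REG_STATES)] <- 1
  }
  # edges of a phylo object are grouped so that a reverse sweep visits
  # children before parents when edges are ordered by preorder; reorder
  # explicitly to be safe
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; chd <- ord$edge[e, 2]
    D[par, ] <- D[par, ] *
      as.numeric(mk_transition_matrix(rate, ord$edge.length[e], k) %*%
                   D[chd, ])
  }
  log(sum(D[ntip + 1L, ] / k))
}

# Per-replicate rate estimate: one-dimensional likelihood maximisation
# (golden-section via optimize, tol 1e-4), fixed-rate fallback when the
# optimum is degenerate (boundary or non-finite).
estimate_mk_rate <- function(tree, states, lower = 1e-3, upper = 20,
                             fallback = 1) {
  if (length(unique(states[tree$tip.label])) == 1L) return(fallback)
  opt <- tryCatch(
    optimize(function(r) mk_loglik(tree, states, r),
             interval = c(lower, upper), maximum = TRUE, tol = 1e-4),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective) ||
      opt$maximum <= lower * 1.01 || opt$maximum >= upper * 0.99) {
    return(fallback)
  }
  opt$maximum
}

#' Bootstrapped ancestral probabilities of regulation for one ortholog group
#'
#' For each replicate, discrete leaf states are sampled from the per-species
#' regulation posteriors ([sample_leaf_states()]), the Mk transition rate is
#' fitted to the sampled states, and exact marginal ancestral probabilities
#' are computed ([mk_ancestral_marginals()]). Replicate marginals are
#' averaged into the reported ancestral posterior probabilities; identical
#' seeds give bit-identical reports.
#'
#' @param tree rooted TF phylogeny (`phylo`), tips = species ids.
#' @param posteriors named numeric vector of per-species regulation
#'   posteriors for the group (species absent from the vector count as
#'   lacking the ortholog).
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed recorded in the report.
#' @return Object of class `ancestral_report`: list with `node_probs`
#'   (matrix internal-node x states, rows sum to 1), `n_replicates`, `seed`.
#' @export
bootstrap_ancestral_regulation <- function(tree, posteriors,
                                           n_replicates = 100, seed = 1) {
  stopifnot(n_replicates >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  acc <- NULL
  for (b in seq_len(n_replicates)) {
    states <- sample_leaf_states(tree$tip.label, posteriors)
    rate <- estimate_mk_rate(tree, states)
    marg <- mk_ancestral_marginals(tree, states, rate)
    acc <- if (is.null(acc)) marg else acc + marg
  }
  node_probs <- acc / n_replicates
  attr(node_probs, "log_likelihood") <- NULL
  structure(list(node_probs = node_probs, n_replicates = n_replicates,
                 seed = seed),
            class = "ancestral_report")
}

#' @export
print.ancestral_report <- function(x, ...) {
  cat(sprintf("Ancestral regulation report (%d replicates, seed %d)\n",
              x$n_replicates, x$seed))
  print(round(x$node_probs, 3))
  invisible(x)
}

#' Export a tree with ancestral regulation probabilities as Newick
#'
#' Internal nodes are labelled with their averaged probability of the
#' regulated state so the reconstruction can be inspected in standard tree
#' viewers.
#'
#' @param tree rooted `phylo`.
#' @param report an `ancestral_report` for that tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotated_tree <- function(tree, report, path) {
  lab <- sprintf("p1=%.3f", report$node_probs[, "s1"])
  tree$node.label <- lab[order(as.integer(rownames(report$node_probs)))]
  ape::write.tree(tree, file = path)
  invisible(path)
}
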