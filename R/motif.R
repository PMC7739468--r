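DNA_BASES <- c("A", "C", "G", "T")

#' Create an aligned binding-site collection
#'
#' A site collection holds the aligned, equal-width binding sites reported for
#' one transcription-factor instance. Sites must be gap-free DNA strings over
#' A/C/G/T; the alignment (trimming to a common width) is the user's
#' responsibility.
#'
#' @param sites character vector of equal-length DNA strings (at least 2).
#' @param tf_instance_id identifier of the TF instance the sites belong to.
#' @return An object of class `site_collection` with elements `tf_instance_id`,
#'   `sites` and `width`.
#' @examples
#' site_collection(c("TTGACA", "TTGACT", "TTTACA"), "lexA_eco")
#' @export
site_collection <- function(sites, tf_instance_id = "tf") {
  sites <- toupper(as.character(sites))
  if (length(sites) < 2L) {
    stop("a site collection needs at least 2 sites", call. = FALSE)
  }
  widths <- nchar(sites)
  if (length(unique(widths)) != 1L) {
    stop("sites are not aligned: unequal lengths ",
         paste(sort(unique(widths)), collapse = ", "), call. = FALSE)
  }
  if (widths[1] < 4L) {
    stop("site width must be at least 4", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", sites))) {
    stop("sites may only contain A, C, G, T", call. = FALSE)
  }
  structure(
    list(tf_instance_id = tf_instance_id, sites = sites, width = widths[1]),
    class = "site_collection"
  )
}

#' @export
print.site_collection <- function(x, ...) {
  cat(sprintf("Site collection '%s': %d sites, width %d\n",
              x$tf_instance_id, length(x$sites), x$width))
  invisible(x)
}

#' Build a position-specific weight matrix from aligned sites
#'
#' Per-column base frequencies with a background-apportioned pseudocount:
#' `f[j,b] = (count[j,b] + pseudocount * background[b]) / (n + pseudocount)`.
#' The default pseudocount of 0.5 keeps every log-odds score finite while
#' barely distorting small collections.
#'
#' @param sites a `site_collection` (or character vector of aligned sites).
#' @param pseudocount non-negative total pseudocount, split across bases in
#'   proportion to the background.
#' @param background length-4 probability vector over A, C, G, T.
#' @return A `pswm`: 4 x width probability matrix (rows A, C, G, T), with
#'   attribute `effective_site_count` (the number of contributing sites).
#' @examples
#' m <- build_pswm(site_collection(c("TTGACA", "TTGACT"), "x"))
#' colSums(m)  # each column sums to 1
#' @export
build_pswm <- function(sites, pseudocount = 0.5, background = rep(0.25, 4)) {
  if (!inherits(sites, "site_collection")) sites <- site_collection(sites)
  stopifnot(pseudocount >= 0)
  background <- check_background(background)
  n <- length(sites$sites)
  mat <- matrix(0, nrow = 4, ncol = sites$width,
                dimnames = list(DNA_BASES, NULL))
  chars <- do.call(rbind, strsplit(sites$sites, "", fixed = TRUE))
  for (j in seq_len(sites$width)) {
    cnt <- table(factor(chars[, j], levels = DNA_BASES))
    mat[, j] <- (as.numeric(cnt) + pseudocount * background) / (n + pseudocount)
  }
  new_pswm(mat, effective_site_count = n)
}

new_pswm <- function(mat, effective_site_count) {
  stopifnot(nrow(mat) == 4)
  rownames(mat) <- DNA_BASES
  if (any(abs(colSums(mat) - 1) > 1e-9) || any(mat < 0)) {
    stop("PSWM columns must be probability distributions", call. = FALSE)
  }
  structure(mat, effective_site_count = effective_site_count, class = "pswm")
}

check_background <- function(background) {
  background <- as.numeric(background)
  if (length(background) != 4 || any(background < 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be a length-4 probability vector over A,C,G,T",
         call. = FALSE)
  }
  background / sum(background)
}

#' @export
print.pswm <- function(x, ...) {
  cat(sprintf("PSWM: width %d, effective site count %.2f\n",
              ncol(x), attr(x, "effective_site_count")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Information content of a motif
#'
#' Kullback-Leibler divergence of the motif from the background, summed over
#' columns, in bits: `IC = sum_j sum_b f[j,b] log2(f[j,b]/background[b])`
#' with the convention `0 * log(0) = 0`.
#'
#' @param pswm a `pswm`.
#' @param background length-4 probability vector.
#' @return Information content in bits (non-negative for any background equal
#'   to the motif's marginal).
#' @export
information_content <- function(pswm, background = rep(0.25, 4)) {
  background <- check_background(background)
  f <- unclass(pswm)
  term <- f * log2(f / background)
  term[f == 0] <- 0
  sum(term)
}

#' Phylogenetic mixture weights from TF-tree distances
#'
#' Reference motifs are combined per target species with weights inversely
#' proportional to the patristic distance between the target's TF and each
#' reference TF on the TF phylogeny: `w_r ~ 1/(d_r + epsilon)`, normalised to
#' sum to one. The `epsilon` floor keeps a zero-distance reference (the target
#' *is* a reference) dominant without nullifying the others.
#'
#' @param distances named non-negative numeric vector, patristic distance from
#'   the target to each reference TF instance (substitutions/site).
#' @param epsilon small positive distance floor (substitutions/site).
#' @return Object of class `mixture_weights`: a named numeric vector summing
#'   to 1.
#' @examples
#' mixture_weights(c(ref1 = 0.1, ref2 = 0.3))
#' @export
mixture_weights <- function(distances, epsilon = 0.01) {
  distances <- unlist(distances)
  if (length(distances) == 0) {
    stop("no reference instances available for mixture weighting",
         call. = FALSE)
  }
  if (any(!is.finite(distances)) || any(distances < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  stopifnot(epsilon > 0)
  w <- 1 / (distances + epsilon)
  w <- w / sum(w)
  class(w) <- "mixture_weights"
  w
}

#' @export
print.mixture_weights <- function(x, ...) {
  cat("Mixture weights:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Weighted mixture of reference motifs
#'
#' Builds the species-specific motif as the convex combination of the
#' reference PSWMs: column j of the mixture is `sum_r w_r * column_j(PSWM_r)`.
#' All references must already share the same width (aligned motifs).
#'
#' @param reference_pswms named list of `pswm` objects, names matching
#'   `names(weights)`.
#' @param weights a `mixture_weights` vector (or any normalised named vector).
#' @return A `pswm` whose effective site count is the weighted sum of the
#'   references' counts.
#' @export
build_mixture_pswm <- function(reference_pswms, weights) {
  stopifnot(length(reference_pswms) >= 1)
  if (is.null(names(reference_pswms)) || is.null(names(weights))) {
    stop("reference PSWMs and weights must be named consistently",
         call. = FALSE)
  }
  missing <- setdiff(names(weights), names(reference_pswms))
  if (length(missing)) {
    stop("no PSWM supplied for reference(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  widths <- vapply(reference_pswms[names(weights)], ncol, integer(1))
  if (length(unique(widths)) != 1L) {
    stop("reference motifs have incompatible widths (",
         paste(widths, collapse = ", "),
         "); align/trim the site collections first", call. = FALSE)
  }
  w <- unclass(weights) / sum(weights)
  mix <- matrix(0, nrow = 4, ncol = widths[1],
                dimnames = list(DNA_BASES, NULL))
  esc <- 0
  for (r in names(w)) {
    mix <- mix + w[[r]] * unclass(reference_pswms[[r]])
    esc <- esc + w[[r]] * attr(reference_pswms[[r]], "effective_site_count")
  }
  new_pswm(mix, effective_site_count = esc)
}

#' Log-odds scoring matrix from a motif
#'
#' Transforms a PSWM into a position-specific scoring matrix against a
#' background composition: `score[j,b] = log2(f[j,b] / background[b])`, in
#' bits. With a positive pseudocount in the PSWM all scores are finite.
#'
#' @param pswm a `pswm`.
#' @param background length-4 probability vector, typically the target
#'   genome's mononucleotide frequencies.
#' @return A `pssm`: 4 x width matrix of scores in bits, with attribute
#'   `background`.
#' @export
pswm_to_pssm <- function(pswm, background = rep(0.25, 4)) {
  background <- check_background(background)
  scores <- log2(unclass(pswm) / background)
  structure(scores, background = background, class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: width %d (bits)\n", ncol(x)))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Export a motif as a JASPAR-style position frequency matrix
#'
#' Writes the four count rows (`A [ ... ]` etc.), scaling probabilities by the
#' effective site count.
#'
#' @param pswm a `pswm`.
#' @param file path to write to.
#' @param id motif identifier used in the header line.
#' @return The file path, invisibly.
#' @export
write_pfm <- function(pswm, file, id = "motif") {
  counts <- unclass(pswm) * attr(pswm, "effective_site_count")
  lines <- c(
    sprintf(">%s", id),
    vapply(DNA_BASES, function(b) {
      sprintf("%s [ %s ]", b, paste(sprintf("%.2f", counts[b, ]),
                                    collapse = " "))
    }, character(1))
  )
  writeLines(lines, file)
  invisible(file)
}
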