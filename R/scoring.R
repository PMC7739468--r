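#' Combine forward- and reverse-strand PSSM scores
#'
#' Two-strand score for one window: `log2(2^f + 2^r)`, computed stably so
#' that `-Inf` (an impossible window on one strand) is absorbed rather than
#' producing `NaN`. Equal scores on both strands give `x + 1`.
#'
#' @param score_forward,score_reverse scores in bits (vectors recycle).
#' @return Combined score(s) in bits; `>= pmax(f, r)` always.
#' @examples
#' combine_strand_scores(3, 1)   # log2(10)
#' combine_strand_scores(2, 2)   # 3
#' @export
combine_strand_scores <- function(score_forward, score_reverse) {
  f <- as.numeric(score_forward)
  r <- as.numeric(score_reverse)
  hi <- pmax(f, r)
  lo <- pmin(f, r)
  out <- hi + log2(1 + 2^(lo - hi))
  # both -Inf: window impossible on both strands
  out[is.infinite(hi) & hi < 0] <- -Inf
  # lo = -Inf with finite hi: 2^(lo-hi) = 0, already exact, but guard NaN
  nan <- is.nan(out)
  out[nan] <- hi[nan]
  out
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Single-strand PSSM scores for every window of a sequence.
# Returns a numeric vector (one entry per window start); windows containing
# ambiguous bases are NA. Vectorised over window starts per column.
score_windows <- function(pssm, sequence) {
  w <- ncol(pssm)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars) - w + 1L
  if (n < 1L) return(numeric(0))
  idx <- match(chars, DNA_BASES)  # NA for ambiguous bases
  scores <- numeric(n)
  bad <- logical(n)
  m <- unclass(pssm)
  for (j in seq_len(w)) {
    col_idx <- idx[j:(j + n - 1L)]
    na <- is.na(col_idx)
    bad <- bad | na
    col_idx[na] <- 1L
    scores <- scores + m[cbind(col_idx, j)]
  }
  scores[bad] <- NA_real_
  scores
}

#' Scan a promoter region on both strands
#'
#' Scores every window of the region with the PSSM on the forward strand and
#' on the reverse complement of the same window, and combines the two strand
#' scores with [combine_strand_scores()]. Windows containing ambiguous bases
#' (N) are skipped.
#'
#' @param pssm a `pssm`.
#' @param region_sequence promoter DNA string (length >= motif width for a
#'   non-empty scan).
#' @return Object of class `promoter_scan`: list with `combined`, `forward`,
#'   `reverse` score vectors (NA at skipped windows), `positions` (1-based
#'   window starts) and the region width scanned. A region shorter than the
#'   motif yields a zero-length scan.
#' @export
scan_promoter <- function(pssm, region_sequence) {
  w <- ncol(pssm)
  region_sequence <- toupper(region_sequence)
  fwd <- score_windows(pssm, region_sequence)
  if (length(fwd) == 0L) {
    return(structure(list(combined = numeric(0), forward = numeric(0),
                          reverse = numeric(0), positions = integer(0),
                          width = w, region_length = nchar(region_sequence)),
                     class = "promoter_scan"))
  }
  # reverse score of window i = forward score of window (n-i+1) on the
  # reverse-complemented region
  rev_all <- score_windows(pssm, revcomp(region_sequence))
  rev_scores <- rev(rev_all)
  comb <- combine_strand_scores(fwd, rev_scores)
  comb[is.na(fwd) | is.na(rev_scores)] <- NA_real_
  structure(list(combined = comb, forward = fwd, reverse = rev_scores,
                 positions = seq_along(fwd), width = w,
                 region_length = nchar(region_sequence)),
            class = "promoter_scan")
}

#' Fit the genome-wide background score distribution
#'
#' The background model B ~ N(mu_G, sigma_G^2) is parametrised by the sample
#' mean and standard deviation of combined two-strand PSSM scores over all
#' windows of all promoter regions of the genome.
#'
#' @param pssm a `pssm`.
#' @param all_promoter_regions character vector of promoter sequences
#'   (genome-wide).
#' @return Object of class `background_model`: list with `mu_G`, `sigma_G`
#'   and `n_windows`.
#' @export
fit_background_model <- function(pssm, all_promoter_regions) {
  scores <- unlist(lapply(all_promoter_regions, function(s) {
    scan_promoter(pssm, s)$combined
  }))
  scores <- scores[!is.na(scores) & is.finite(scores)]
  if (length(scores) == 0L) {
    stop("no scannable windows: cannot fit background model", call. = FALSE)
  }
  mu <- mean(scores)
  sig <- sd(scores)
  if (length(scores) < 2L || !is.finite(sig) || sig <= 0) {
    stop("degenerate background score distribution (sigma_G = 0); ",
         "supply more promoter sequence", call. = FALSE)
  }
  structure(list(mu_G = mu, sigma_G = sig, n_windows = length(scores)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("Background score model: mu_G = %.3f, sigma_G = %.3f (%d windows)\n",
              x$mu_G, x$sigma_G, x$n_windows))
  invisible(x)
}

#' Fit the motif score distribution analytically
#'
#' The functional-site model M ~ N(mu_M, sigma_M^2) is parametrised by the
#' expectation and variance of the single-strand PSSM score of a site drawn
#' from the PSWM, computed analytically under column independence:
#' `mu_M = sum_j sum_b f[j,b] score[j,b]` and `sigma_M^2 = sum_j Var_j`.
#'
#' @param pssm a `pssm`.
#' @param pswm the matching `pswm`.
#' @return Object of class `motif_score_model`: list with `mu_M`, `sigma_M`.
#' @export
fit_motif_model <- function(pssm, pswm) {
  f <- unclass(pswm)
  s <- unclass(pssm)
  stopifnot(ncol(f) == ncol(s))
  mu_j <- colSums(f * s)
  var_j <- colSums(f * s^2) - mu_j^2
  structure(list(mu_M = sum(mu_j), sigma_M = sqrt(sum(pmax(var_j, 0)))),
            class = "motif_score_model")
}

#' @export
print.motif_score_model <- function(x, ...) {
  cat(sprintf("Motif score model: mu_M = %.3f, sigma_M = %.3f\n",
              x$mu_M, x$sigma_M))
  invisible(x)
}

#' Mixing parameter for the regulated-promoter score mixture
#'
#' The prior probability that a given window of a regulated promoter is a
#' functional site: the typical number of sites bound per regulated promoter
#' divided by the average promoter length. One site per 250 bp promoter gives
#' alpha = 0.004, i.e. a regulated promoter draws from the background
#' component 99.6% of the time.
#'
#' @param sites_per_promoter typical number of binding sites per regulated
#'   promoter (positive).
#' @param avg_promoter_length average promoter length in bp (positive).
#' @return alpha, clipped to the open interval (0, 1).
#' @examples
#' alpha_prior(1, 250)  # 0.004
#' @export
alpha_prior <- function(sites_per_promoter, avg_promoter_length) {
  if (avg_promoter_length <= 0) {
    stop("average promoter length must be positive", call. = FALSE)
  }
  if (sites_per_promoter <= 0) {
    stop("sites per promoter must be positive", call. = FALSE)
  }
  a <- sites_per_promoter / avg_promoter_length
  min(max(a, 1e-9), 1 - 1e-9)
}

#' Regulation prior from a known regulon size
#'
#' P(R) approximated as the number of known regulated promoters in a
#' reference genome divided by its total number of operons; P(B) = 1 - P(R).
#'
#' @param n_known_regulated_promoters positive count of known regulated
#'   promoters.
#' @param n_operons total operon count (>= n_known).
#' @return P(R), clipped to (0, 1 - 1e-6].
#' @export
estimate_prior_from_sites <- function(n_known_regulated_promoters, n_operons) {
  if (n_operons <= 0) stop("operon count must be positive", call. = FALSE)
  if (n_known_regulated_promoters <= 0) {
    stop("need at least one known regulated promoter to seed the prior",
         call. = FALSE)
  }
  if (n_known_regulated_promoters > n_operons) {
    stop("known regulated promoters exceed operon count", call. = FALSE)
  }
  min(n_known_regulated_promoters / n_operons, 1 - 1e-6)
}

#' Regulation prior from motif information content
#'
#' When no reference regulon size is available, the expected number of
#' functional sites is estimated from the information content of the
#' species-specific motif: `m = n_scannable_positions * 2^(-IC)`, and
#' `P(R) = min(m / n_operons, 1 - 1e-6)`.
#'
#' @param ic motif information content in bits (> 0).
#' @param n_scannable_positions number of scored promoter windows genome-wide.
#' @param n_operons total operon count.
#' @return P(R) in (0, 1).
#' @export
estimate_prior_from_ic <- function(ic, n_scannable_positions, n_operons) {
  stopifnot(ic > 0, n_scannable_positions >= 1, n_operons >= 1)
  m <- n_scannable_positions * 2^(-ic)
  max(min(m / n_operons, 1 - 1e-6), 1e-9)
}

#' Prior configuration for the posterior computation
#'
#' @param alpha mixing parameter in (0,1); see [alpha_prior()].
#' @param p_regulation prior probability that an operon is regulated, in
#'   \[0,1\].
#' @return Object of class `prior_config`.
#' @export
prior_config <- function(alpha, p_regulation) {
  stopifnot(alpha > 0, alpha < 1, p_regulation >= 0, p_regulation <= 1)
  structure(list(alpha = alpha, p_regulation = p_regulation,
                 p_background = 1 - p_regulation),
            class = "prior_config")
}

#' Posterior probability that a promoter is regulated
#'
#' Bayesian posterior P(R|D) for the observed vector of combined window
#' scores D, under a regulated-promoter mixture
#' `R ~ alpha N(mu_M, sigma_M^2) + (1-alpha) N(mu_G, sigma_G^2)` and a
#' background `B ~ N(mu_G, sigma_G^2)`, assuming independence across
#' positions:
#' `P(R|D) = P(D|R)P(R) / (P(D|R)P(R) + P(D|B)P(B))`.
#' All likelihoods are accumulated in log space, so underflow cannot occur
#' for any promoter length.
#'
#' @param scores a `promoter_scan` or numeric vector of combined scores
#'   (NAs, from skipped windows, are dropped). A zero-length scan falls back
#'   to the prior P(R).
#' @param bg a `background_model`.
#' @param mm a `motif_score_model`.
#' @param priors a `prior_config`.
#' @return Object of class `regulation_posterior`: list with `p_regulated`,
#'   `log_lik_ratio` (log2 P(D|R)/P(D|B)) and `n_scored`.
#' @export
posterior_probability <- function(scores, bg, mm, priors) {
  if (inherits(scores, "promoter_scan")) scores <- scores$combined
  scores <- as.numeric(scores)
  if (any(is.nan(scores))) stop("NaN in score vector", call. = FALSE)
  scores <- scores[!is.na(scores) & is.finite(scores)]
  p_r <- priors$p_regulation
  if (length(scores) == 0L) {
    return(structure(list(p_regulated = p_r, log_lik_ratio = 0,
                          n_scored = 0L),
                     class = "regulation_posterior"))
  }
  if (p_r == 1) {
    return(structure(list(p_regulated = 1, log_lik_ratio = NA_real_,
                          n_scored = length(scores)),
                     class = "regulation_posterior"))
  }
  if (p_r == 0) {
    return(structure(list(p_regulated = 0, log_lik_ratio = NA_real_,
                          n_scored = length(scores)),
                     class = "regulation_posterior"))
  }
  a <- priors$alpha
  lb <- dnorm(scores, bg$mu_G, bg$sigma_G, log = TRUE)
  lm <- dnorm(scores, mm$mu_M, mm$sigma_M, log = TRUE)
  # log of the per-position mixture density: log(a e^lm + (1-a) e^lb)
  hi <- pmax(lm + log(a), lb + log1p(-a))
  lo <- pmin(lm + log(a), lb + log1p(-a))
  lr <- hi + log1p(exp(lo - hi))
  log_pd_r <- sum(lr)
  log_pd_b <- sum(lb)
  # posterior odds in log space
  log_odds <- (log_pd_r + log(p_r)) - (log_pd_b + log1p(-p_r))
  p <- 1 / (1 + exp(-log_odds))
  structure(list(p_regulated = p,
                 log_lik_ratio = (log_pd_r - log_pd_b) / log(2),
                 n_scored = length(scores)),
            class = "regulation_posterior")
}

#' @export
print.regulation_posterior <- function(x, ...) {
  cat(sprintf("P(regulated | scores) = %.4f over %d windows\n",
              x$p_regulated, x$n_scored))
  invisible(x)
}

# Best-scoring window of a scan: position (1-based window start), strand of
# the stronger single-strand score, and the combined score. NULL if no
# scorable window.
best_site <- function(scan) {
  ok <- which(!is.na(scan$combined))
  if (length(ok) == 0L) return(NULL)
  i <- ok[which.max(scan$combined[ok])]
  strand <- if (!is.na(scan$forward[i]) &&
                (is.na(scan$reverse[i]) || scan$forward[i] >= scan$reverse[i]))
    "+" else "-"
  list(position = i, strand = strand, combined = scan$combined[i],
       forward = scan$forward[i], reverse = scan$reverse[i])
}
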