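make_test_pssm <- function(sites = c("TTGACA", "TTGACA", "TTGACT", "TTTACA"),
                           pseudocount = 0.5) {
  pswm <- build_pswm(site_collection(sites, "t"), pseudocount)
  list(pswm = pswm, pssm = pswm_to_pssm(pswm))
}

test_that("two-strand score combination evaluates log2(2^f + 2^r)", {
  expect_equal(combine_strand_scores(3, 1), log2(10), tolerance = 1e-14)
  expect_equal(combine_strand_scores(2, 2), 3)
  expect_equal(combine_strand_scores(3, -Inf), 3)
  expect_equal(combine_strand_scores(-Inf, -Inf), -Inf)
  # commutativity and the f = r = x shortcut
  set.seed(4)
  f <- runif(500, -30, 20); r <- runif(500, -30, 20)
  expect_equal(combine_strand_scores(f, r), combine_strand_scores(r, f))
  expect_equal(combine_strand_scores(f, f), f + 1)
  expect_true(all(combine_strand_scores(f, r) >= pmax(f, r)))
})

test_that("promoter scans locate planted sites and respect strand symmetry", {
  tp <- make_test_pssm()
  set.seed(5)
  flank <- rand_dna(27)
  region <- paste0(flank, "TTGACA", rand_dna(27))
  scan <- scan_promoter(tp$pssm, region)
  expect_length(scan$combined, 60 - 6 + 1)
  expect_equal(which.max(scan$combined), 28)
  # exhaustive oracle: every window scored both strands directly
  m <- unclass(tp$pssm)
  direct <- vapply(seq_len(55), function(i) {
    win <- substr(region, i, i + 5)
    idx <- match(strsplit(win, "")[[1]], DNA)
    rc <- rev(c(4, 3, 2, 1)[idx])
    log2(2^sum(m[cbind(idx, 1:6)]) + 2^sum(m[cbind(rc, 1:6)]))
  }, numeric(1))
  expect_equal(scan$combined, direct, tolerance = 1e-12)
  # reverse-complementing the region permutes but preserves combined scores
  rc_scan <- scan_promoter(tp$pssm, cregulon:::revcomp(region))
  expect_equal(sort(rc_scan$combined), sort(scan$combined),
               tolerance = 1e-12)
  # region of exactly motif width gives one window
  expect_length(scan_promoter(tp$pssm, "TTGACA")$combined, 1)
  # shorter region gives an empty scan
  expect_length(scan_promoter(tp$pssm, "TTGA")$combined, 0)
  # palindromic window scores f = r, so combined = f + 1
  pal <- make_test_pssm(c("ACGT", "ACGT", "ACGT"))
  s <- scan_promoter(pal$pssm, "ACGT")
  expect_equal(s$forward, s$reverse)
  expect_equal(s$combined, s$forward + 1)
  # ambiguous windows are skipped
  sn <- scan_promoter(tp$pssm, paste0("TTGACA", "NNNNNN", "TTGACA"))
  expect_true(any(is.na(sn$combined)))
  expect_false(is.na(sn$combined[1]))
})

test_that("background model matches the exact combined-score expectation", {
  tp <- make_test_pssm(c("ACGG", "ACGT", "ACGT", "TCGT"))
  exact_mean <- oracle_combined_score_mean(tp$pssm, rep(0.25, 4))
  set.seed(6)
  regions <- replicate(200, rand_dna(53))  # 200 x 50 = 10,000 windows
  bg <- fit_background_model(tp$pssm, regions)
  expect_equal(bg$n_windows, 10000)
  se <- bg$sigma_G / sqrt(bg$n_windows)
  expect_lt(abs(bg$mu_G - exact_mean), 3 * se)
  # duplicating every region leaves the mean unchanged
  bg2 <- fit_background_model(tp$pssm, c(regions, regions))
  expect_equal(bg2$mu_G, bg$mu_G)
  # degenerate input: a single repeated window has zero variance
  expect_error(fit_background_model(tp$pssm, "ACGT"), "sigma_G")
  expect_error(fit_background_model(tp$pssm, character(0)), "window")
})

test_that("motif score model equals brute-force enumeration", {
  # width-4 motif: enumerate all 256 sequences weighted by PSWM probability
  pswm <- build_pswm(site_collection(c("ACGA", "ACGT", "ACGA", "CCGT",
                                       "ACTA", "ACGG"), "m"), 0.5)
  pssm <- pswm_to_pssm(pswm)
  mm <- fit_motif_model(pssm, pswm)
  f <- unclass(pswm); s <- unclass(pssm)
  seqs <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  p <- apply(seqs, 1, function(idx) prod(f[cbind(idx, 1:4)]))
  sc <- apply(seqs, 1, function(idx) sum(s[cbind(idx, 1:4)]))
  expect_equal(mm$mu_M, sum(p * sc), tolerance = 1e-12)
  expect_equal(mm$sigma_M, sqrt(sum(p * sc^2) - sum(p * sc)^2),
               tolerance = 1e-12)
  # PSWM equal to background scores 0 everywhere
  u <- build_pswm(site_collection(c("AAAA", "CCCC", "GGGG", "TTTT"), "u"), 0)
  mmu <- fit_motif_model(pswm_to_pssm(u), u)
  expect_equal(mmu$mu_M, 0)
})

test_that("mixing parameter and regulation priors follow their definitions", {
  expect_identical(alpha_prior(1, 250), 1 / 250)
  expect_identical(alpha_prior(1, 250), 0.004)
  expect_equal(alpha_prior(2, 250), 0.008)
  expect_equal(1 - alpha_prior(1, 250), 0.996)  # background mixture mass
  expect_error(alpha_prior(1, 0), "positive")
  expect_equal(estimate_prior_from_sites(40, 2000), 0.02)
  expect_equal(estimate_prior_from_sites(1, 1), 1 - 1e-6)
  expect_error(estimate_prior_from_sites(0, 2000), "at least one")
  expect_error(estimate_prior_from_sites(5, 0), "positive")
  # information-content route
  expect_equal(estimate_prior_from_ic(10, 10240, 500), 0.02)
  expect_equal(estimate_prior_from_ic(log2(4096), 4096, 64), 1 / 64)
  expect_lt(estimate_prior_from_ic(60, 1e6, 100), 1e-9 * 2)
})

test_that("posterior probability matches direct-arithmetic evaluation", {
  bg <- structure(list(mu_G = 0, sigma_G = 2), class = "background_model")
  mm <- structure(list(mu_M = 10, sigma_M = 2), class = "motif_score_model")
  pr <- prior_config(alpha = 0.004, p_regulation = 0.02)
  p <- posterior_probability(c(0, 1, 8), bg, mm, pr)
  direct <- oracle_posterior(c(0, 1, 8), 0, 2, 10, 2, 0.004, 0.02)
  expect_equal(p$p_regulated, direct, tolerance = 1e-10)
  # limit cases
  pr1 <- prior_config(0.004, 1)
  expect_identical(posterior_probability(c(-5, 3), bg, mm, pr1)$p_regulated, 1)
  # alpha -> 0: R and B coincide, posterior = prior
  pr0 <- prior_config(1e-300, 0.37)
  expect_equal(posterior_probability(c(0, 1, 2), bg, mm, pr0)$p_regulated,
               0.37, tolerance = 1e-10)
  # empty scan falls back to the prior
  expect_equal(posterior_probability(numeric(0), bg, mm, pr)$p_regulated,
               0.02)
  expect_error(posterior_probability(c(1, NaN), bg, mm, pr), "NaN")
})

test_that("posterior agrees with direct space over random vectors and is monotone", {
  set.seed(7)
  bg <- structure(list(mu_G = 0, sigma_G = 2), class = "background_model")
  mm <- structure(list(mu_M = 10, sigma_M = 2), class = "motif_score_model")
  for (i in 1:200) {
    alpha <- runif(1, 0.001, 0.1)
    p_r <- runif(1, 0.01, 0.5)
    scores <- rnorm(sample(1:12, 1), 0, 4)
    direct <- oracle_posterior(scores, 0, 2, 10, 2, alpha, p_r)
    ours <- posterior_probability(scores, bg, mm,
                                  prior_config(alpha, p_r))$p_regulated
    expect_equal(ours, direct, tolerance = 1e-10)
  }
  # monotone in the appended score when mu_M > mu_G
  pr <- prior_config(0.004, 0.1)
  base <- c(0, 1, -2)
  ps <- vapply(seq(-5, 15, by = 1), function(s) {
    posterior_probability(c(base, s), bg, mm, pr)$p_regulated
  }, numeric(1))
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("no underflow for long promoters with extreme scores", {
  bg <- structure(list(mu_G = -20, sigma_G = 5), class = "background_model")
  mm <- structure(list(mu_M = 18, sigma_M = 4), class = "motif_score_model")
  pr <- prior_config(0.004, 0.02)
  scores <- rnorm(5000, -20, 5)
  p <- posterior_probability(scores, bg, mm, pr)$p_regulated
  expect_true(is.finite(p))
  expect_gte(p, 0)
  expect_lte(p, 1)
})
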