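camk1 <- "GTCTTGGGGGTTTAG"
abcc11 <- "TTCTGGGAAACGAAG"

test_that("purine fraction matches hand counts and handles N", {
  expect_equal(purine_fraction(camk1), 5 / 8)
  expect_equal(purine_fraction(abcc11), 7 / 8)
  expect_equal(purine_fraction("TTTCTTTTCCTTCAG"), 0)
  # N removed from the denominator; all-N range is NA
  expect_equal(purine_fraction("TTTCTNTTCCTTCAG"), 0)
  expect_equal(purine_fraction("TTTCTNGTCCTTCAG"), 1 / 7)
  expect_true(is.na(purine_fraction(strrep("N", 15))))
  # range outside the window errors
  expect_error(purine_fraction("ACGT", -10, -3), "outside")
})

test_that("REPA call uses a strict threshold and requires the AG", {
  expect_true(is_repa_candidate(camk1)[1])                # 5/8 > 0.6
  expect_false(is_repa_candidate("TTTTTTTTTTTCCAG")[1])   # 0/8
  expect_false(is_repa_candidate("TTTTTAGAGTTTTAG")[1])   # exactly 4/8
  expect_true(is_repa_candidate("TTTTTAGAGATTTAG")[1])    # 5/8
  # purine-rich but not an AG acceptor
  expect_false(is_repa_candidate("TTTGGGAAACGAAAC")[1])
  # truncated window -> FALSE with flag
  out <- is_repa_candidate("TTTAG", truncated = TRUE)
  expect_false(out[1])
  expect_true(attr(out, "truncated")[1])
})

test_that("REPA calls are monotone in the threshold", {
  b <- sim_bundle(seed = 17, n_genes = 30)
  w <- b$windows[!b$windows$truncated, ]
  counts <- vapply(c(0.3, 0.45, 0.6, 0.75, 0.9), function(th) {
    sum(is_repa_candidate(w$window, threshold = th, exon_span = 3L))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("G-tract detection reports maximal in-range runs only", {
  t1 <- find_g_tracts(camk1)
  expect_equal(t1$first_g, -10L)
  expect_equal(t1$length, 5L)
  expect_false(t1$over_cap)

  t2 <- find_g_tracts(abcc11)
  expect_equal(t2$first_g, -11L)
  expect_equal(t2$length, 3L)

  # run of 13 ending at -3: one maximal tract, over the reporting cap
  t3 <- find_g_tracts("GGGGGGGGGGGGGAG")
  expect_equal(nrow(t3), 1L)
  expect_equal(t3$length, 13L)
  expect_true(t3$over_cap)

  # no tract at all
  expect_equal(nrow(find_g_tracts("TTTCTTTTCCTTCAG")), 0L)

  # run invading positions 3' of -3 is not a tract
  expect_equal(nrow(find_g_tracts("TTTTTTTTTTTGGGG")), 0L)
  # ...but a run ending exactly at -3 is
  expect_equal(find_g_tracts("TTTTTTTTTTGGGAG")$first_g, -5L)

  # two separate runs, reported 5' to 3'
  t4 <- find_g_tracts("TGGGTTTGGGGTTAG")
  expect_equal(t4$first_g, c(-14L, -8L))
  expect_equal(t4$length, c(3L, 4L))

  # a run lying 5' of the search interval is not reported
  w25 <- paste0("TGGGG", strrep("T", 15), "AG", "CCC")  # run at -21..-18
  expect_equal(nrow(find_g_tracts(w25, exon_span = 3L)), 0L)
  # a run straddling the 5' search boundary is not fully in range either
  w26 <- paste0("TTTTTT", "GGGG", strrep("T", 10), "AG", "CCC")  # -16..-13
  expect_equal(nrow(find_g_tracts(w26, exon_span = 3L)), 0L)
})

test_that("tract detection agrees with a regex oracle on synthetic windows", {
  b <- sim_bundle(seed = 29, n_genes = 30)
  w <- b$windows[!b$windows$truncated, ]
  intron_part <- substr(w$window, 1, w$intron_span)
  for (i in seq_len(nrow(w))) {
    got <- find_g_tracts(w$window[i], exon_span = 3L)
    exp <- oracle_g_tracts(intron_part[i])
    expect_equal(got$first_g, exp$first_g)
    expect_equal(got$length, exp$length)
  }
})

test_that("group classification matches motifs with fixed precedence", {
  expect_equal(classify_group(camk1), "ggggg")
  expect_equal(classify_group("TTTGAAAATTTTCAG"), "gaaaa")
  expect_equal(classify_group("TTTGTGGAATTTCAG"), "gtggaa")
  # both ggggg and gaaaa present -> precedence picks ggggg
  expect_equal(classify_group("TTTGGGGGAAAATAG"), "ggggg")
  # purine at -3, no motif -> consensus-violating nnnrag-like
  expect_equal(classify_group("TTTTTTTTTTTTAAG"), "nnnrag_like")
  expect_equal(classify_group("TTTTTTTTTTTTCAG"), "other")
})

test_that("position profiles are exact on singletons and linear in unions", {
  p1 <- position_profile("ACGTA")
  expect_equal(unname(p1$freq[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(p1$freq[, 3]), c(0, 0, 1, 0))
  expect_equal(p1$positions, -5:-1)

  set.seed(4)
  mk <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    }, "")
  }
  s1 <- mk(30); s2 <- mk(70)
  pu <- position_profile(c(s1, s2))
  pa <- position_profile(s1); pb <- position_profile(s2)
  expect_equal(pu$freq, (30 * pa$freq + 70 * pb$freq) / 100)
  # frequencies sum to 1 at N-free positions
  expect_equal(unname(colSums(pu$freq)), rep(1, 6))
  expect_error(position_profile(character(0)))
})

test_that("constitutive generator composition is recovered in the profile", {
  b <- sim_bundle(seed = 41, n_genes = 150, repa_fraction = 0)
  w <- b$windows[!b$windows$truncated, ]
  expect_gt(nrow(w), 300)
  pr <- position_profile(w)
  idx <- as.character(-10:-5)
  expect_lt(abs(mean(pr$purine_freq[idx]) - 0.20), 0.03)
})

test_that("scan recovers planted tract positions and lengths exactly", {
  b <- sim_bundle(seed = 19, n_genes = 60)
  calls <- scan_sites(b$windows)
  truth <- b$sim$truth
  tr <- truth[match(calls$site_id, truth$site_id), ]
  # perfect planted-site recovery at the enforced margins
  expect_equal(calls$is_repa, tr$is_repa)
  rc <- calls[calls$is_repa, ]
  rt <- tr[tr$is_repa, ]
  expect_equal(rc$first_g, rt$first_g)
  expect_equal(rc$tract_length, rt$tract_length)

  # histograms equal the planted tabulations and sum to contributing sites
  h <- first_g_histogram(rc)
  expect_equal(sum(h), nrow(rc))
  planted <- table(factor(rt$first_g, levels = names(h)))
  expect_equal(unname(h), as.integer(planted))
  d <- run_length_distribution(rc)
  expect_equal(sum(d), nrow(rc))
  expect_equal(unname(d),
               as.integer(table(factor(rt$tract_length,
                                       levels = names(d)))))
})

test_that("a planted first-G mixture is recovered at its planted ratio", {
  b <- sim_bundle(seed = 47, n_genes = 120, repa_fraction = 1,
                  first_g_probs = c("-10" = 0.6, "-8" = 0.4),
                  g_len_probs = c("3" = 1))
  calls <- scan_sites(b$windows)
  h <- first_g_histogram(calls[calls$is_repa, , drop = FALSE],
                         positions = c(-10L, -8L))
  expect_equal(sum(h), sum(calls$is_repa))
  frac <- h[["-10"]] / sum(h)
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / sum(h)) + 0.01)
})
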