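rand_seqs <- function(n, L, prob = rep(0.25, 4)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, TRUE, prob = prob),
          collapse = "")
  }, "")
}

all_kmers <- function(L) {
  apply(expand.grid(rep(list(c("A", "C", "G", "T")), L)), 1, paste,
        collapse = "")
}

test_that("singleton-constraint fit equals the product of marginals", {
  set.seed(101)
  sig <- rand_seqs(50, 4, prob = c(.4, .3, .2, .1))
  bg <- rand_seqs(50, 4)
  m <- train_strength_model(sig, bg, constraints = "singleton")

  seqs <- all_kmers(4)
  p <- exp(sequence_logprob(m, seqs, "signal"))
  expect_equal(sum(p), 1, tolerance = 1e-9)

  # closed-form oracle: product of the smoothed per-position marginals
  idx <- t(vapply(strsplit(sig, ""), function(s) {
    match(s, c("A", "C", "G", "T"))
  }, integer(4)))
  marg <- vapply(1:4, function(i) {
    (tabulate(idx[, i], 4) + 0.5) / (length(sig) + 2)
  }, numeric(4))
  p_oracle <- vapply(strsplit(seqs, ""), function(s) {
    prod(marg[cbind(match(s, c("A", "C", "G", "T")), 1:4)])
  }, 0)
  expect_equal(p, p_oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("pairwise fit is normalized and satisfies its marginals", {
  set.seed(102)
  sig <- rand_seqs(300, 5, prob = c(.4, .3, .2, .1))
  bg <- rand_seqs(300, 5)
  m <- train_strength_model(sig, bg)
  seqs <- all_kmers(5)
  for (d in c("signal", "background")) {
    expect_equal(sum(exp(sequence_logprob(m, seqs, d))), 1,
                 tolerance = 1e-6)
  }
  # every constrained marginal reproduced well within 1e-3
  expect_lt(max(m$training$residual), 1e-3)

  # exhaustive oracle for the pairwise marginals of the fitted signal model
  p <- exp(sequence_logprob(m, seqs, "signal"))
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (i in 1:4) {
    emp <- tapply(p, list(chars[, i], chars[, i + 1]), sum)
    expect_equal(as.vector(emp),
                 as.vector(matrix(m$signal$target_p[i, , ], 4, 4)),
                 tolerance = 1e-6)
  }
})

test_that("degenerate and identity trainings behave as expected", {
  set.seed(103)
  x <- rand_seqs(200, 6)
  # identical signal and background -> all scores exactly 0 bits
  m_id <- train_strength_model(x, x)
  expect_equal(score_site(m_id, x[1:20]), rep(0, 20))

  # both classes uniform random -> scores near 0 on average
  m_unif <- train_strength_model(rand_seqs(500, 6), rand_seqs(500, 6))
  sc <- score_site(m_unif, rand_seqs(200, 6))
  expect_lt(abs(mean(sc)), 1)

  # contract checks
  expect_error(train_strength_model(rand_seqs(20, 6), rand_seqs(20, 7)),
               "length")
  expect_error(train_strength_model(rand_seqs(5, 6), rand_seqs(20, 6)),
               "at least")
  expect_error(score_site(m_unif, "ACGTNN"), "A/C/G/T")
  expect_error(score_site(m_unif, "ACGT"), "length")
})

test_that("trained on generator output, pyrimidine acceptors score higher", {
  b <- sim_bundle(seed = 201, n_genes = 120)
  calls <- scan_sites(b$windows)
  w <- b$windows[!b$windows$truncated, ]
  is_repa <- calls$is_repa[match(w$site_id, calls$site_id)]
  sig <- w$window[!is_repa]
  set.seed(7)
  bg <- rand_seqs(length(sig), nchar(sig[1]))
  m <- train_strength_model(sig, bg)

  s_const <- score_site(m, sig)
  s_repa <- score_site(m, w$window[is_repa])
  expect_gt(mean(s_const), mean(s_repa))

  # inserting a G pentamer at -10..-6 strictly lowers each score
  ins <- sig[1:25]
  idx <- nchar(ins[1]) - 3L            # intron span of the 23-mer
  substr(ins, idx - 9L, idx - 5L) <- "GGGGG"
  changed <- substr(sig[1:25], idx - 9L, idx - 5L) != "GGGGG"
  expect_true(all(score_site(m, ins)[changed] <
                    score_site(m, sig[1:25])[changed]))
})

test_that("group comparison reproduces the t statistic and permutation", {
  x <- c(1, 2, 3); y <- c(11, 12, 13)
  cmp <- compare_groups(list(const = x, same = x, shifted = y))
  expect_equal(attr(cmp, "reference"), "const")
  same_row <- cmp[cmp$group == "same", ]
  expect_equal(same_row$t, 0)
  expect_equal(same_row$p, 1)

  sh <- cmp[cmp$group == "shifted", ]
  orc <- oracle_perm_t(y, x)
  expect_equal(sh$t, orc$t_obs)
  expect_gt(abs(sh$t), 10)
  expect_lt(sh$p, 0.01)
  # complete separation: the exact permutation p is the smallest possible
  expect_equal(orc$p, 2 / 20)
  # parametric p agrees with stats::t.test
  expect_equal(sh$p, t.test(y, x, var.equal = TRUE)$p.value)

  # degenerate groups are flagged, not crashed on
  cmp2 <- compare_groups(list(const = x, lone = 5))
  expect_true(cmp2$degenerate[cmp2$group == "lone"])
  expect_true(is.na(cmp2$p[cmp2$group == "lone"]))
})

test_that("models serialize to JSON and back without score drift", {
  set.seed(104)
  m <- train_strength_model(rand_seqs(100, 6, prob = c(.4, .3, .2, .1)),
                            rand_seqs(100, 6))
  path <- tempfile(fileext = ".json")
  write_strength_model(m, path)
  m2 <- read_strength_model(path)
  probe <- rand_seqs(50, 6)
  expect_equal(score_site(m2, probe), score_site(m, probe),
               tolerance = 1e-12)
})
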