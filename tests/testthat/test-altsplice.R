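# hand-built genes: exon coordinates chosen so every definition fires (or
# is correctly suppressed) without ambiguity

test_that("the four canonical event types are classified", {
  # cassette: t2 skips the internal exon of t1
  cass <- rbind(
    exon_df("t1", "g1", "chr1", "+", c(1, 201, 401), c(100, 300, 500)),
    exon_df("t2", "g1", "chr1", "+", c(1, 401), c(100, 500))
  )
  ev <- detect_as_events(cass)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "cassette_exon")
  expect_equal(c(ev$start, ev$end), c(201, 300))
  expect_equal(ev$acceptors, "200")
  # the skipping junction must not double as alt 3'/5' events
  expect_false(any(ev$event_type %in% c("alt_3ss", "alt_5ss")))

  # alternative 3'SS: acceptors 12 nt apart on a shared donor
  alt3 <- rbind(
    exon_df("tA", "g2", "chr1", "+", c(1, 201), c(100, 320)),
    exon_df("tB", "g2", "chr1", "+", c(1, 213), c(100, 320))
  )
  e3 <- detect_as_events(alt3)
  expect_equal(e3$event_type, "alt_3ss")
  expect_equal(e3$acceptors, "200,212")

  # alternative 5'SS: donors differ, acceptor shared
  alt5 <- rbind(
    exon_df("tA", "g3", "chr1", "+", c(1, 201), c(100, 320)),
    exon_df("tB", "g3", "chr1", "+", c(1, 201), c(88, 320))
  )
  e5 <- detect_as_events(alt5)
  expect_equal(e5$event_type, "alt_5ss")
  expect_equal(e5$acceptors, "200")

  # retained intron: t2's exon spans t1's intron entirely
  ret <- rbind(
    exon_df("t1", "g4", "chr1", "+", c(1, 201), c(100, 300)),
    exon_df("t2", "g4", "chr1", "+", 1, 300)
  )
  er <- detect_as_events(ret)
  expect_equal(er$event_type, "retained_intron")
  expect_equal(c(er$start, er$end), c(101, 200))
  expect_equal(er$acceptors, "200")
})

test_that("minus-strand events use transcribed-strand donor/acceptor roles", {
  alt3m <- rbind(
    exon_df("tA", "g1", "chr1", "-", c(1, 201), c(100, 320)),
    exon_df("tB", "g1", "chr1", "-", c(1, 201), c(88, 320))
  )
  # on the minus strand the shared coordinate 201 is the donor side;
  # differing upstream-exon ends are the acceptors
  e <- detect_as_events(alt3m)
  expect_equal(e$event_type, "alt_3ss")
  expect_equal(e$acceptors, "89,101")
})

test_that("event detection is symmetric in transcript order", {
  df <- rbind(
    exon_df("x2", "g1", "chr1", "+", c(1, 201, 401), c(100, 300, 500)),
    exon_df("x1", "g1", "chr1", "+", c(1, 401), c(100, 500))
  )
  df_swapped <- df
  df_swapped$transcript_id <- ifelse(df$transcript_id == "x1", "x2", "x1")
  a <- detect_as_events(df)
  b <- detect_as_events(df_swapped)
  cols <- c("event_type", "start", "end", "acceptors")
  expect_equal(a[cols], b[cols])
})

test_that("events are deduplicated across transcript pairs", {
  df <- rbind(
    exon_df("t1", "g1", "chr1", "+", c(1, 201, 401), c(100, 300, 500)),
    exon_df("t2", "g1", "chr1", "+", c(1, 401), c(100, 500)),
    exon_df("t3", "g1", "chr1", "+", c(1, 401), c(100, 520))
  )
  ev <- detect_as_events(df)
  expect_equal(sum(ev$event_type == "cassette_exon"), 1L)
})

test_that("sites are associated with events by acceptor or interval", {
  alt3 <- rbind(
    exon_df("tA", "g2", "chr1", "+", c(1, 201), c(100, 320)),
    exon_df("tB", "g2", "chr1", "+", c(1, 213), c(100, 320))
  )
  ev <- detect_as_events(alt3)
  sites <- data.frame(
    site_id = c("chr1:+:200", "chr1:+:212", "chr1:+:9999"),
    stringsAsFactors = FALSE)
  assoc <- associate_sites(ev, sites)
  expect_equal(assoc$is_alternative, c(TRUE, TRUE, FALSE))
  expect_equal(assoc$event_types, c("alt_3ss", "alt_3ss", ""))
})

test_that("type distribution recovers proportions and folds", {
  st <- data.frame(event_types = c(rep("retained_intron", 2),
                                   rep("cassette_exon", 2)),
                   stringsAsFactors = FALSE)
  ref <- c(cassette_exon = 0.5, alt_3ss = 0.25, alt_5ss = 0.2,
           retained_intron = 0.05)
  td <- type_distribution(st, ref)
  expect_equal(sum(td$proportion), 1)
  expect_equal(td$fold_enrichment[td$event_type == "retained_intron"], 10)
  expect_equal(td$fold_enrichment[td$event_type == "cassette_exon"], 1)

  # distribution identical to the reference -> all folds 1
  st2 <- data.frame(event_types = c(rep("cassette_exon", 10),
                                    rep("alt_3ss", 5),
                                    rep("alt_5ss", 4),
                                    rep("retained_intron", 1)))
  td2 <- type_distribution(st2, c(cassette_exon = .5, alt_3ss = .25,
                                  alt_5ss = .2, retained_intron = .05))
  expect_equal(td2$fold_enrichment[td2$count > 0], rep(1, 4))

  # single-type input
  td3 <- type_distribution(data.frame(event_types = "alt_5ss"))
  expect_equal(td3$proportion[td3$event_type == "alt_5ss"], 1)
  expect_error(type_distribution(data.frame(event_types = character(0))),
               "no associated sites")
})

test_that("planted events are fully recalled on generator output", {
  b <- sim_bundle(seed = 61, n_genes = 60)
  ev <- detect_as_events(b$sim$annotation)
  truth <- b$sim$events_truth
  # every planted event type is recalled at its planted acceptor
  for (i in seq_len(nrow(truth))) {
    hit <- ev$gene_id == truth$gene_id[i] &
      ev$event_type == truth$event_type[i] &
      vapply(strsplit(ev$acceptors, ","), function(a) {
        as.character(truth$acceptor[i]) %in% a
      }, TRUE)
    expect_true(any(hit), info = paste("missing", truth$gene_id[i],
                                       truth$event_type[i]))
  }
  # and nothing beyond the planted events is invented
  expect_equal(nrow(ev), nrow(truth))

  # alternative status joins back to the planted truth exactly
  assoc <- associate_sites(ev, b$windows)
  tr <- b$sim$truth[match(assoc$site_id, b$sim$truth$site_id), ]
  expect_equal(assoc$is_alternative, tr$is_alternative)
})
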