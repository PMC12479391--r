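test_that("isoform_exons is the complement of the intron chain", {
  ref <- build_reference(toy_construct())
  # no introns: one block spanning the annotated amplicon
  expect_equal(unname(isoform_exons(matrix(integer(), 0, 2), ref)),
               matrix(c(0L, 39L), 1L))
  # the reference's own chain gives back the features
  ch <- rbind(c(6L, 17L), c(23L, 33L))
  expect_equal(unname(isoform_exons(ch, ref)),
               unname(as.matrix(ref$annotation$features[, c("start", "end")])))
  # complement is involutive: blocks -> chain -> blocks
  blocks <- isoform_exons(ch, ref)
  expect_equal(unname(intron_chain(blocks)), unname(ch))
})

test_that("exon-skipping isoforms get merged skip events", {
  truth <- example_rad51d_truth(seed = 17L)
  ref <- truth$reference
  for (case in list(list(c(4, 5), "Δ(4-5)"),
                    list(c(3, 4, 5), "Δ(3-5)"),
                    list(4:9, "Δ(4-9)"))) {
    ev <- list(splice_event("skip", case[[1]][1],
                            case[[1]][length(case[[1]])]))
    real <- realize_isoform(ref, ev)
    got <- classify_events(real$blocks, ref)
    expect_length(got, 1L)
    expect_equal(got[[1]]$kind, "skip")
    expect_equal(format_annotation(got), case[[2]])
  }
  # the reference exon chain itself is full length
  fl <- realize_isoform(ref, list())
  expect_length(classify_events(fl$blocks, ref), 0L)
  expect_equal(format_annotation(classify_events(fl$blocks, ref)), "FL")
})

test_that("classification matches the exhaustive oracle over all subsets", {
  cons <- random_construct(n_exons = 6L, exon_numbers = 1:6, seed = 29L)
  ref <- build_reference(cons)
  labels <- 1:6
  for (mask in 0:63) {
    skipped <- labels[bitwAnd(mask, bitwShiftL(1L, labels - 1L)) != 0L]
    f <- ref$annotation$features
    keep <- f$role != "exon" | !(f$label %in% as.character(skipped))
    blocks <- as.matrix(f[keep, c("start", "end")])
    got <- classify_events(blocks, ref)
    want <- skip_oracle(labels, skipped)
    expect_length(got, length(want))
    for (i in seq_along(want)) {
      expect_equal(got[[i]]$kind, "skip")
      expect_equal(got[[i]]$first_exon, as.character(want[[i]]["first"]))
      expect_equal(got[[i]]$last_exon, as.character(want[[i]]["last"]))
    }
  }
})

test_that("partial deletions report side and missing size", {
  truth <- example_rad51d_truth(seed = 17L)
  ref <- truth$reference
  for (case in list(list("acceptor", "p"), list("donor", "q"))) {
    ev <- list(splice_event("partial_deletion", 4, side = case[[1]],
                            size_nt = 12L))
    real <- realize_isoform(ref, ev)
    got <- classify_events(real$blocks, ref)
    expect_length(got, 1L)
    expect_equal(got[[1]]$kind, "partial_deletion")
    expect_equal(got[[1]]$side, case[[1]])
    expect_equal(got[[1]]$size_nt, 12L)
    expect_equal(format_annotation(got),
                 paste0("Δ(4", case[[2]], "_12)"))
  }
})

test_that("retention, partial retention and novel exons are detected", {
  truth <- example_rad51d_truth(seed = 17L)
  ref <- truth$reference
  cases <- list(
    list(splice_event("intron_retention", 4, 5), "intron_retention",
         "▼(4-5)"),
    list(splice_event("partial_retention", 6, side = "donor",
                      size_nt = 12L), "partial_retention", "▼(6q_12)"),
    list(splice_event("partial_retention", 6, side = "acceptor",
                      size_nt = 9L), "partial_retention", "▼(6p_9)"),
    list(splice_event("novel_exon", 4, 5, size_nt = 30L), "novel_exon",
         "▼(4-5,30)"))
  for (case in cases) {
    real <- realize_isoform(ref, list(case[[1]]))
    got <- classify_events(real$blocks, ref)
    expect_length(got, 1L)
    expect_equal(got[[1]]$kind, case[[2]])
    expect_equal(format_annotation(got), case[[3]])
  }
})

test_that("multi-event isoforms are annotated 5' to 3'", {
  truth <- example_rad51d_truth(seed = 17L)
  ref <- truth$reference
  ev <- list(splice_event("skip", 3, 3),
             splice_event("partial_retention", 6, side = "donor",
                          size_nt = 12L))
  real <- realize_isoform(ref, ev)
  got <- classify_events(real$blocks, ref)
  expect_equal(format_annotation(got), "Δ(3),▼(6q_12)")
  # events strictly increasing in exon order
  firsts <- as.integer(vapply(got, `[[`, "", "first_exon"))
  expect_true(all(diff(firsts) > 0))
})

test_that("annotation grammar round-trips through its parser", {
  truth <- example_rad51d_truth(seed = 17L)
  ref <- truth$reference
  event_pool <- list(
    list(splice_event("skip", 3, 3)),
    list(splice_event("skip", 4, 6)),
    list(splice_event("partial_deletion", 5, side = "acceptor",
                      size_nt = 7L)),
    list(splice_event("intron_retention", 7, 8)),
    list(splice_event("partial_retention", 2, side = "donor",
                      size_nt = 15L)),
    list(splice_event("novel_exon", 8, 9, size_nt = 20L)),
    list(splice_event("skip", 3, 3),
         splice_event("intron_retention", 7, 8)))
  for (events in event_pool) {
    s <- format_annotation(events)
    back <- parse_annotation(s)
    expect_length(back, length(events))
    for (i in seq_along(events))
      expect_identical(back[[i]], events[[i]], label = s)
  }
  expect_identical(parse_annotation("FL"), list())
  expect_error(parse_annotation("garbage"), "cannot parse")
})

test_that("ASCII fallback replaces the event symbols", {
  ev <- list(splice_event("skip", 4, 5))
  expect_equal(format_annotation(ev, unicode = FALSE), "del(4-5)")
  ev2 <- list(splice_event("intron_retention", 4, 5))
  expect_equal(format_annotation(ev2, unicode = FALSE), "ins(4-5)")
})

test_that("annot_ref reflects the cloned exon span", {
  truth <- example_rad51d_truth(seed = 17L)
  expect_equal(annot_ref_string(truth$reference), "ex2_ex9")
  single <- build_reference(minigene_construct(
    paste0("ATGCAA", "GTAG", "CCCGGG", "GTAG", "TTAACC"),
    "ATGCAA", "TTAACC", c("7" = "CCCGGG"), "G", "T", "C"))
  expect_equal(annot_ref_string(single), "ex7_ex7")
  none <- build_reference(minigene_construct(
    paste0("ATGCAA", "TTAACC"), "ATGCAA", "TTAACC", character(),
    "G", "T", "C"))
  expect_equal(annot_ref_string(none), "vector_only")
})

test_that("UTR features never produce skip events", {
  truth <- example_rad51d_truth(seed = 17L)
  ref <- truth$reference
  f <- ref$annotation$features
  # isoform missing the UTRs entirely (non-full-length artifact)
  keep <- f$role == "exon"
  blocks <- as.matrix(f[keep, c("start", "end")])
  got <- classify_events(blocks, ref)
  labs <- unlist(lapply(got, function(e) c(e$first_exon, e$last_exon)))
  expect_false(any(labs %in% c("UTR5", "UTR3")))
})

test_that("realize/classify are mutually inverse on random event sets", {
  truth <- example_rad51d_truth(seed = 17L)
  ref <- truth$reference
  set.seed(31)
  pool <- list(
    function() splice_event("skip", s <- sample(2:9, 1),
                            min(9, s + sample(0:2, 1))),
    function() splice_event("intron_retention", s <- sample(2:8, 1), s + 1),
    function() splice_event("partial_deletion", sample(2:9, 1),
                            side = sample(c("acceptor", "donor"), 1),
                            size_nt = sample(5:20, 1)))
  for (i in 1:25) {
    ev <- list(pool[[sample(3, 1)]]())
    real <- tryCatch(realize_isoform(ref, ev), error = function(e) NULL)
    if (is.null(real)) next    # e.g. deletion larger than the exon
    got <- classify_events(real$blocks, ref)
    expect_equal(format_annotation(got), format_annotation(ev))
  }
})
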