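test_that("CIGAR blocks and introns follow spliced-alignment arithmetic", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, "FAKE", 500L, c(
    sam_record("spliced", 1L, "20M100N30M"),
    sam_record("plain", 11L, "50M")))
  reads <- parse_alignments(sam, "S1", 1L, "FAKE")
  expect_length(reads, 2L)
  spliced <- reads[[which(vapply(reads, `[[`, "", "read_id") == "spliced")]]
  expect_equal(unname(spliced$blocks),
               matrix(c(0L, 120L, 20L, 150L), 2L))
  expect_equal(unname(intron_chain(spliced)), matrix(c(20L, 120L), 1L))
  plain <- reads[[which(vapply(reads, `[[`, "", "read_id") == "plain")]]
  expect_equal(unname(plain$blocks), matrix(c(10L, 60L), 1L))
  expect_equal(nrow(intron_chain(plain)), 0L)
})

test_that("secondary/supplementary records and low MAPQ are excluded", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, "FAKE", 500L, c(
    sam_record("keep", 1L, "50M"),
    sam_record("secondary", 1L, "50M", flag = 256L),
    sam_record("supplementary", 1L, "50M", flag = 2048L),
    sam_record("lowq", 1L, "50M", mapq = 0L)))
  reads <- parse_alignments(sam, "S1", min_mapq = 1L, genome_name = "FAKE")
  expect_equal(vapply(reads, `[[`, "", "read_id"), "keep")
})

test_that("alignments to an unexpected reference are an error", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, "OTHER", 500L,
                 sam_record("r", 1L, "50M", rname = "OTHER"))
  expect_error(parse_alignments(sam, "S1", 1L, "FAKE"), "OTHER")
})

test_that("junction snapping moves boundaries onto annotated sites", {
  ann <- fake_annotation(c(0L, 29L), c(23L, 60L), c("UTR", "UTR"),
                         c("UTR5", "UTR3"))
  # donor at 25, annotated site at 23, wobble 8 -> snaps
  r <- make_read(rbind(c(0, 25), c(40, 60)))
  snapped <- snap_junctions(r, ann, wobble = 8L)
  expect_equal(unname(intron_chain(snapped)[1, ]), c(23L, 40L))
  # wobble 0 is the identity
  expect_identical(snap_junctions(r, ann, wobble = 0L)$blocks, r$blocks)
  # boundary beyond the window is untouched
  far <- make_read(rbind(c(0, 15), c(40, 60)))
  expect_equal(unname(intron_chain(snap_junctions(far, ann, 4L))[1, 1]), 15L)
})

test_that("snapping ties resolve to the lower coordinate", {
  # annotated sites at 23 and 29 (feature boundaries); boundary 26 is
  # equidistant -> lower coordinate wins
  ann <- fake_annotation(c(0L, 29L), c(23L, 60L), c("UTR", "UTR"),
                         c("UTR5", "UTR3"))
  r <- make_read(rbind(c(0, 26), c(45, 60)))
  expect_equal(unname(intron_chain(snap_junctions(r, ann, 8L))[1, 1]), 23L)
})

test_that("snapping is idempotent and flags impossible adjustments", {
  ann <- fake_annotation(c(0L, 30L, 70L), c(20L, 60L, 100L),
                         c("UTR", "exon", "UTR"), c("UTR5", "2", "UTR3"))
  set.seed(7)
  for (i in 1:20) {
    d <- sample(-4:4, 4, replace = TRUE)
    r <- make_read(rbind(c(0, 20 + d[1]), c(30 + d[2], 60 + d[3]),
                         c(70 + d[4], 100)))
    once <- snap_junctions(r, ann, 8L)
    twice <- snap_junctions(once, ann, 8L)
    expect_identical(twice$blocks, once$blocks)
  }
  # a 1-nt block between two annotated sites cannot be snapped consistently
  tiny <- make_read(rbind(c(0, 19), c(21, 22), c(28, 100)))
  out <- snap_junctions(tiny, ann, 8L)
  expect_true(isTRUE(attr(out, "unsnappable")))
  expect_identical(out$blocks, tiny$blocks)
})

test_that("clustering groups reads by exact intron chain with counts", {
  ann <- fake_annotation(c(0L, 120L), c(20L, 140L), c("UTR", "UTR"),
                         c("UTR5", "UTR3"))
  chainA <- rbind(c(0, 30), c(60, 140))
  chainB <- rbind(c(0, 40), c(80, 140))
  reads <- make_reads(c(
    lapply(1:50, function(i) make_read(chainA, paste0("a", i))),
    lapply(1:30, function(i) make_read(chainB, paste0("b", i)))))
  iso <- cluster_reads(reads, ann, min_end_overlap = 0.5)
  expect_length(iso, 2L)
  expect_equal(sum(iso[[1]]$counts), 50)
  expect_equal(sum(iso[[2]]$counts), 30)
  expect_equal(unname(iso[[1]]$chain), unname(intron_chain(chainA)))
})

test_that("incomplete reads fail the full-length amplicon filter", {
  ann <- fake_annotation(c(0L, 120L), c(20L, 140L), c("UTR", "UTR"),
                         c("UTR5", "UTR3"))
  # covers none of the terminal UTR3
  half <- make_reads(list(make_read(rbind(c(0, 70)))))
  expect_length(cluster_reads(half, ann, 0.5), 0L)
  # disabling the filter keeps it
  expect_length(cluster_reads(half, ann, 0), 1L)
})

test_that("clustering matches a brute-force dictionary on small inputs", {
  truth <- example_rad51d_truth(seed = 3L)
  sim <- simulate_reads(truth, 100L, error_rate = 0, jitter = 0L,
                        out_prefix = tempfile(), seed = 5L)
  reads <- parse_alignments(sim$sam, "S1", 1L, truth$reference$genome$name)
  iso <- cluster_reads(reads, truth$reference)
  # oracle: naive dictionary of intron-chain tuples
  keys <- vapply(reads, function(r)
    paste(t(intron_chain(r)), collapse = ","), character(1))
  dict <- table(keys)
  expect_equal(length(iso), length(dict))
  got <- vapply(iso, function(m)
    sum(m$counts), numeric(1))
  names(got) <- vapply(iso, function(m)
    paste(t(m$chain), collapse = ","), character(1))
  expect_equal(got[order(names(got))],
               c(dict)[order(names(dict))],
               ignore_attr = TRUE)
  expect_equal(names(got)[order(names(got))],
               names(dict)[order(names(dict))])
})

test_that("counts are conserved and clustering partitions the reads", {
  truth <- example_rad51d_truth(seed = 11L)
  sim <- simulate_reads(truth, 500L, error_rate = 0.02, jitter = 4L,
                        out_prefix = tempfile(), seed = 13L)
  reads <- parse_alignments(sim$sam, "S1", 1L, truth$reference$genome$name)
  reads <- snap_all(reads, truth$reference, 8L)
  iso <- cluster_reads(reads, truth$reference, min_end_overlap = 0)
  expect_equal(sum(vapply(iso, function(m) sum(m$counts), numeric(1))),
               length(reads))
})

test_that("reads sampled from known chains recover them multinomially", {
  truth <- example_rad51d_truth(seed = 19L)
  # three chains only
  t3 <- simulation_truth(truth$reference,
                         list(list(), list(splice_event("skip", 4, 5)),
                              list(splice_event("skip", 3, 5))),
                         c(0.5, 0.3, 0.2))
  sim <- simulate_reads(t3, 500L, error_rate = 0, jitter = 0L,
                        out_prefix = tempfile(), seed = 21L)
  reads <- parse_alignments(sim$sam, "S1", 1L, t3$reference$genome$name)
  iso <- cluster_reads(reads, t3$reference)
  expect_length(iso, 3L)
  counts <- vapply(iso, function(m) sum(m$counts), numeric(1))
  expect_equal(sort(counts, decreasing = TRUE), sort(sim$counts,
                                                     decreasing = TRUE))
  # within 3 sigma of multinomial expectation
  for (k in 1:3) {
    expe <- 500 * t3$isoforms[[k]]$weight
    sd3 <- 3 * sqrt(500 * t3$isoforms[[k]]$weight *
                      (1 - t3$isoforms[[k]]$weight))
    expect_lt(abs(sim$counts[k] - expe), sd3 + 1)
  }
})

test_that("assembled-GTF import converts transcripts to isoform models", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("FAKE", "asm", "transcript", 1, 140, ".", "+", ".",
          'gene_id "G"; transcript_id "t1"; cov "50.0";', sep = "\t"),
    paste("FAKE", "asm", "exon", 1, 30, ".", "+", ".",
          'gene_id "G"; transcript_id "t1"; cov "50.0";', sep = "\t"),
    paste("FAKE", "asm", "exon", 61, 140, ".", "+", ".",
          'gene_id "G"; transcript_id "t1"; cov "50.0";', sep = "\t")), gtf)
  iso <- read_assembled_gtf(gtf, "S1", "FAKE")
  expect_length(iso, 1L)
  expect_equal(unname(iso[[1]]$chain), matrix(c(30L, 60L), 1L))
  expect_equal(unname(iso[[1]]$counts), 50)
  expect_error(read_assembled_gtf(gtf, "S1", "OTHER"), "FAKE")
})
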