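# Shared fixtures, built in code.

# hand-countable toy construct: 4 nt pad | 6 nt constitutive | 11 nt intron |
# 6 nt exon 4 | 10 nt intron | 6 nt constitutive | 4 nt pad
toy_construct <- function() {
  minigene_construct(
    construct_sequence = paste0("GGGG", "ATGCAA", "GTAAGTTTTAG", "CCCGGG",
                                "GTACGTCCAG", "TTAACC", "GGGG"),
    upstream_exon = "ATGCAA",
    downstream_exon = "TTAACC",
    cloned_exons = c("4" = "CCCGGG"),
    gene_symbol = "TOY", transcript_name = "TOY_TX",
    construction_name = "pCAS2_TOY")
}

# a bare reference_annotation from a feature table (for unit tests that
# need full control over coordinates)
fake_annotation <- function(starts, ends, roles, labels,
                            genome_name = "FAKE") {
  structure(list(genome_name = genome_name, gene_symbol = "G",
                 transcript_name = "T",
                 features = data.frame(start = as.integer(starts),
                                       end = as.integer(ends),
                                       role = roles, label = as.character(labels),
                                       stringsAsFactors = FALSE)),
            class = "reference_annotation")
}

# minimal SAM writer for hand-built records
write_test_sam <- function(path, genome_name, genome_len, records) {
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", genome_name, "\tLN:", genome_len),
               records), path)
}

sam_record <- function(qname, pos1, cigar, flag = 0L, rname = "FAKE",
                       mapq = 60L, seqlen = NULL) {
  if (is.null(seqlen)) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIS=X]", cigar))[[1L]]
    seqlen <- sum(as.integer(sub("[MIS=X]", "", ops)))
  }
  paste(qname, flag, rname, pos1, mapq, cigar, "*", 0, 0,
        strrep("A", seqlen), strrep("I", seqlen), sep = "\t")
}

# build a mg_read directly from a blocks matrix
make_read <- function(blocks, read_id = "r1", sample_id = "S1") {
  structure(list(read_id = read_id, sample_id = sample_id,
                 blocks = cbind(start = as.integer(blocks[, 1]),
                                end = as.integer(blocks[, 2]))),
            class = "mg_read")
}

make_reads <- function(read_list, genome_name = "FAKE") {
  structure(read_list, class = "mg_reads", genome_name = genome_name)
}

# independent oracle for skip classification: per-exon membership test
# with run merging over consecutive skipped exon labels
skip_oracle <- function(exon_labels, skipped_labels) {
  miss <- exon_labels %in% skipped_labels
  out <- list()
  i <- 1L
  while (i <= length(exon_labels)) {
    if (miss[i]) {
      j <- i
      while (j < length(exon_labels) && miss[j + 1L]) j <- j + 1L
      out[[length(out) + 1L]] <- c(first = exon_labels[i],
                                   last = exon_labels[j])
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# simulate + run every pipeline stage in-memory; returns the report and
# intermediates (used by end-to-end and acceptance-level tests)
run_sim_pipeline <- function(truth, n_reads, error_rate = 0.02, jitter = 4L,
                             wobble = 8L, seed = 1L, sample_id = "S1") {
  sim <- simulate_reads(truth, n_reads, error_rate = error_rate,
                        jitter = jitter, sample_id = sample_id,
                        out_prefix = tempfile(), seed = seed)
  reads <- parse_alignments(sim$sam, sample_id, 1L,
                            truth$reference$genome$name)
  reads <- snap_all(reads, truth$reference, wobble)
  isoforms <- cluster_reads(reads, truth$reference)
  annotated <- annotate_isoforms(isoforms, truth$reference)
  report <- build_report(annotated, reference = truth$reference)
  list(sim = sim, reads = reads, isoforms = isoforms,
       annotated = annotated, report = report)
}
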