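# run expr with a local RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_intron <- function(n) {
  stopifnot(n >= 4L)
  paste0("GT", .random_dna(n - 4L), "AG")
}

#' Generate a random minigene construct
#'
#' Emulates a pCAS2-style splicing reporter: two constitutive vector exons
#' flanking `n_exons` cloned exons separated by GT..AG introns, with vector
#' sequence padding outside the amplified region. All declared sequences
#' are checked to occur uniquely in the construct (re-sampled on the rare
#' collision). Deterministic for a fixed seed.
#'
#' By default the cloned exons are numbered from 2 upward (the first exon
#' of a gene is typically not part of the cloned genomic fragment), so
#' `n_exons = 8` gives an exon 2..9 construct.
#'
#' @param n_exons Number of cloned exons (0 gives a vector-only control).
#' @param exon_numbers Integer labels, strictly increasing; default
#'   `seq(2, length.out = n_exons)`.
#' @param exon_len_range,intron_len_range Length ranges (nt) sampled
#'   uniformly for cloned exons and introns.
#' @param constitutive_len Length of each constitutive vector exon.
#' @param pad_len Vector sequence length outside each amplicon end.
#' @param gene_symbol,transcript_name Identifiers for the GTF.
#' @param construction_name Defaults to a pCAS2-style name built from the
#'   gene symbol and exon span.
#' @param seed Integer seed.
#' @return A [minigene_construct()].
#' @export
random_construct <- function(n_exons = 8L,
                             exon_numbers = NULL,
                             exon_len_range = c(60L, 150L),
                             intron_len_range = c(80L, 200L),
                             constitutive_len = 120L,
                             pad_len = 50L,
                             gene_symbol = "SYNGENE",
                             transcript_name = "TX_SYN1",
                             construction_name = NULL,
                             seed = 1L) {
  stopifnot(n_exons >= 0L, all(exon_len_range > 0L),
            all(intron_len_range >= 4L))
  if (is.null(exon_numbers))
    exon_numbers <- if (n_exons > 0L) seq(2L, length.out = n_exons) else integer()
  stopifnot(length(exon_numbers) == n_exons,
            !is.unsorted(exon_numbers, strictly = TRUE))
  if (is.null(construction_name))
    construction_name <- if (n_exons > 0L)
      sprintf("pCAS2_%s_Ex%d-%d", gene_symbol, exon_numbers[1L],
              exon_numbers[n_exons])
    else sprintf("pCAS2_%s_empty", gene_symbol)
  .with_seed(seed, {
    for (attempt in 1:100) {
      up <- .random_dna(constitutive_len)
      down <- .random_dna(constitutive_len)
      exons <- if (n_exons > 0L)
        vapply(seq_len(n_exons), function(i)
          .random_dna(sample(exon_len_range[1L]:exon_len_range[2L], 1L)),
          character(1))
      else character()
      n_introns <- n_exons + 1L
      introns <- vapply(seq_len(n_introns), function(i)
        .random_intron(sample(intron_len_range[1L]:intron_len_range[2L], 1L)),
        character(1))
      pieces <- c(.random_dna(pad_len), up)
      for (i in seq_len(n_exons))
        pieces <- c(pieces, introns[i], exons[i])
      pieces <- c(pieces, introns[n_introns], down, .random_dna(pad_len))
      construct <- paste(pieces, collapse = "")
      declared <- c(up, down, exons)
      n_occ <- vapply(declared, function(s)
        length(gregexpr(s, construct, fixed = TRUE)[[1L]]), integer(1))
      if (all(n_occ == 1L)) {
        names(exons) <- exon_numbers
        return(minigene_construct(construct, up, down, exons,
                                  gene_symbol, transcript_name,
                                  construction_name))
      }
    }
    stop("could not generate a construct with unique declared sequences")
  })
}

#' Realize an isoform from splice events
#'
#' Applies a list of [splice_event()]s to the reference exon chain and
#' returns the resulting transcript: skipping removes exons (fusing the
#' flanking introns), retention fills an intron, partial events trim or
#' extend exon edges, novel exons insert a block centred in an intron.
#'
#' @param reference A `minigene_reference` from [build_reference()].
#' @param events List of `splice_event` (may be empty: full length).
#' @return List with `blocks` (genomic exon blocks), `chain` (intron
#'   chain) and `sequence` (the spliced transcript).
#' @export
realize_isoform <- function(reference, events = list()) {
  f <- reference$annotation$features
  genome <- reference$genome$sequence
  keep <- rep(TRUE, nrow(f))
  starts <- f$start
  ends <- f$end
  fillers <- NULL
  find_feat <- function(label) {
    i <- match(as.character(label), f$label)
    if (is.na(i)) stop("no reference feature labelled '", label, "'")
    i
  }
  # skips first, so later events touching a removed exon are caught
  for (ev in events) {
    stopifnot(inherits(ev, "splice_event"))
    if (ev$kind != "skip") next
    i <- find_feat(ev$first_exon)
    j <- find_feat(ev$last_exon)
    if (any(f$role[i:j] != "exon"))
      stop("cannot skip constitutive (UTR) features")
    keep[i:j] <- FALSE
  }
  for (ev in events) {
    if (ev$kind == "skip") next
    i <- find_feat(ev$first_exon)
    j <- find_feat(ev$last_exon)
    if (!keep[i] || !keep[j])
      stop("contradictory events: '", ev$kind,
           "' references a skipped exon")
    switch(ev$kind,
      partial_deletion = {
        if (ev$side == "acceptor") starts[i] <- starts[i] + ev$size_nt
        else ends[i] <- ends[i] - ev$size_nt
        if (starts[i] >= ends[i])
          stop("partial deletion removes all of exon ", f$label[i])
      },
      intron_retention = {
        if (j != i + 1L)
          stop("intron_retention features must be adjacent")
        fillers <- rbind(fillers, c(f$end[i], f$start[j]))
      },
      partial_retention = {
        if (ev$side == "donor")
          fillers <- rbind(fillers, c(f$end[i], f$end[i] + ev$size_nt))
        else
          fillers <- rbind(fillers, c(f$start[i] - ev$size_nt, f$start[i]))
      },
      novel_exon = {
        if (j != i + 1L)
          stop("novel_exon flanking features must be adjacent")
        gap_s <- f$end[i]; gap_e <- f$start[j]
        if (ev$size_nt > gap_e - gap_s - 2L)
          stop("novel exon larger than the intron")
        mid <- (gap_s + gap_e) %/% 2L
        half <- ev$size_nt %/% 2L
        fillers <- rbind(fillers, c(mid - half, mid - half + ev$size_nt))
      })
  }
  blocks <- cbind(start = starts[keep], end = ends[keep])
  if (!is.null(fillers))
    blocks <- rbind(blocks, cbind(start = fillers[, 1L], end = fillers[, 2L]))
  blocks <- blocks[order(blocks[, 1L]), , drop = FALSE]
  # merge touching blocks; strict overlap means contradictory events
  merged <- blocks[1L, , drop = FALSE]
  for (b in seq_len(nrow(blocks))[-1L]) {
    last <- nrow(merged)
    if (blocks[b, 1L] < merged[last, 2L])
      stop("contradictory events: resulting blocks overlap")
    if (blocks[b, 1L] == merged[last, 2L])
      merged[last, 2L] <- blocks[b, 2L]
    else merged <- rbind(merged, blocks[b, , drop = FALSE])
  }
  sequence <- paste(vapply(seq_len(nrow(merged)), function(i)
    substr(genome, merged[i, 1L] + 1L, merged[i, 2L]), character(1)),
    collapse = "")
  list(blocks = merged, chain = intron_chain(merged), sequence = sequence)
}

#' Define a simulation ground truth
#'
#' Bundles a reference with a weighted mixture of isoform structures; each
#' isoform is realized on the genome and labelled with the annotation
#' string the annotator produces for it, so downstream recovery can be
#' checked against a consistent expectation.
#'
#' @param reference A `minigene_reference`.
#' @param isoform_events List of event lists (one per isoform; `list()`
#'   is the full-length isoform).
#' @param weights Mixture weights, summing to 1.
#' @param construct Optional [minigene_construct()] the reference was
#'   built from (kept so a simulation can drive the whole pipeline,
#'   construct parsing included).
#' @return A `simulation_truth` object.
#' @export
simulation_truth <- function(reference, isoform_events, weights,
                             construct = NULL) {
  stopifnot(length(isoform_events) == length(weights),
            abs(sum(weights) - 1) < 1e-8, all(weights > 0))
  isoforms <- lapply(seq_along(isoform_events), function(k) {
    real <- realize_isoform(reference, isoform_events[[k]])
    ev <- classify_events(real$blocks, reference)
    list(events = ev, annotation = format_annotation(ev),
         weight = weights[k], blocks = real$blocks, chain = real$chain,
         sequence = real$sequence)
  })
  structure(list(reference = reference, isoforms = isoforms,
                 construct = construct),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth on '", x$reference$genome$name, "':\n", sep = "")
  for (iso in x$isoforms)
    cat(sprintf("  %-12s weight %.3f (%d introns)\n", iso$annotation,
                iso$weight, nrow(iso$chain)))
  invisible(x)
}

#' Ground truth emulating a multi-exon RAD51D-style assay
#'
#' An 8-exon construct (exons numbered 2-9, pCAS2-style flanks) expressing
#' four isoforms: full length plus the skipping products of exons 4-5, 3-5
#' and 4-9, at mixture weights 0.55/0.25/0.15/0.05 — the minor isoform
#' sits at background-noise level, as observed for such assays.
#'
#' @param seed Seed for the construct sequence.
#' @return A `simulation_truth`.
#' @export
example_rad51d_truth <- function(seed = 17L) {
  construct <- random_construct(n_exons = 8L, gene_symbol = "RAD51D",
                                transcript_name = "NM_002878",
                                seed = seed)
  reference <- build_reference(construct)
  events <- list(
    list(),
    list(splice_event("skip", 4, 5)),
    list(splice_event("skip", 3, 5)),
    list(splice_event("skip", 4, 9)))
  simulation_truth(reference, events, c(0.55, 0.25, 0.15, 0.05),
                   construct = construct)
}

# map a window [qstart, qstart+qlen) of the spliced transcript back to
# genomic blocks (0-based half-open on the artificial genome)
.spliced_window <- function(blocks, qstart, qlen) {
  lens <- blocks[, 2L] - blocks[, 1L]
  offs <- cumsum(c(0L, lens))
  qend <- qstart + qlen
  out <- NULL
  for (i in seq_len(nrow(blocks))) {
    bq_s <- offs[i]; bq_e <- offs[i + 1L]
    s <- max(qstart, bq_s); e <- min(qend, bq_e)
    if (e > s)
      out <- rbind(out, c(blocks[i, 1L] + (s - bq_s),
                          blocks[i, 1L] + (e - bq_s)))
  }
  colnames(out) <- c("start", "end")
  out
}

# substitution errors at a fixed per-base rate; returns the mutated string
.mutate <- function(seq, error_rate) {
  n <- nchar(seq)
  n_err <- stats::rbinom(1L, n, error_rate)
  if (n_err == 0L) return(seq)
  pos <- sample.int(n, n_err)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  for (p in pos)
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Simulate aligned reads from a ground truth
#'
#' Draws isoform memberships multinomially from the truth weights and
#' writes one SAM record per read, with the CIGAR reflecting the isoform's
#' true blocks plus (long mode) uniform junction jitter of up to
#' `jitter` nt per splice boundary and per-base substitution errors in the
#' sequence. Short mode instead emits fixed-length fragments drawn
#' uniformly along the spliced transcript. A FASTQ file and a sidecar
#' truth TSV (read id, isoform index, annotation) are written next to the
#' SAM. Byte-deterministic for a fixed seed.
#'
#' The substitution-only error model keeps the CIGAR block-structured
#' (no indels); jitter, not indel noise, is what junction snapping must
#' absorb.
#'
#' @param truth A `simulation_truth`.
#' @param n_reads Number of reads.
#' @param error_rate Per-base substitution probability (in `[0, 0.2)`).
#' @param jitter Maximum junction displacement in nt (long mode).
#' @param mode `"long"` (full-amplicon reads) or `"short"`.
#' @param read_length Fragment length for short mode.
#' @param sample_id Sample name recorded in the truth table.
#' @param out_prefix Paths written: `<prefix>.sam`, `<prefix>.fastq`,
#'   `<prefix>.truth.tsv`.
#' @param seed Integer seed.
#' @return Invisibly, a list with the file paths and the true per-isoform
#'   read counts.
#' @export
simulate_reads <- function(truth, n_reads, error_rate = 0.02, jitter = 4L,
                           mode = c("long", "short"), read_length = 150L,
                           sample_id = "S1", out_prefix, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "simulation_truth"), n_reads > 0,
            error_rate >= 0, error_rate < 0.2)
  genome <- truth$reference$genome
  glen <- nchar(genome$sequence)
  weights <- vapply(truth$isoforms, `[[`, numeric(1), "weight")
  .with_seed(seed, {
    member <- sample.int(length(weights), n_reads, replace = TRUE,
                         prob = weights)
    header <- c("@HD\tVN:1.6\tSO:unknown",
                paste0("@SQ\tSN:", genome$name, "\tLN:", glen))
    records <- character(n_reads)
    fastq <- character(4L * n_reads)
    truth_rows <- character(n_reads)
    for (r in seq_len(n_reads)) {
      k <- member[r]
      blocks <- truth$isoforms[[k]]$blocks
      if (mode == "long") {
        if (jitter > 0L && nrow(blocks) > 1L) {
          ch <- intron_chain(blocks)
          d1 <- sample(seq(-jitter, jitter), nrow(ch), replace = TRUE)
          d2 <- sample(seq(-jitter, jitter), nrow(ch), replace = TRUE)
          ch2 <- cbind(ch[, 1L] + d1, ch[, 2L] + d2)
          nb <- cbind(c(blocks[1L, 1L], ch2[, 2L]),
                      c(ch2[, 1L], blocks[nrow(blocks), 2L]))
          ok <- all(nb[, 2L] > nb[, 1L]) && all(ch2[, 1L] < ch2[, 2L]) &&
            (nrow(nb) < 2L || all(nb[-1L, 1L] >= nb[-nrow(nb), 2L]))
          if (ok) blocks <- nb
        }
      } else {
        splen <- sum(blocks[, 2L] - blocks[, 1L])
        qlen <- min(read_length, splen)
        qstart <- if (splen > qlen)
          sample.int(splen - qlen + 1L, 1L) - 1L else 0L
        blocks <- .spliced_window(blocks, qstart, qlen)
      }
      lens <- blocks[, 2L] - blocks[, 1L]
      gaps <- if (nrow(blocks) > 1L)
        blocks[-1L, 1L] - blocks[-nrow(blocks), 2L] else integer()
      cigar <- paste0(lens, "M",
                      c(if (length(gaps)) paste0(gaps, "N"), ""),
                      collapse = "")
      seqs <- vapply(seq_len(nrow(blocks)), function(i)
        substr(genome$sequence, blocks[i, 1L] + 1L, blocks[i, 2L]),
        character(1))
      rseq <- .mutate(paste(seqs, collapse = ""), error_rate)
      qual <- strrep("I", nchar(rseq))
      rid <- sprintf("read%06d", r)
      records[r] <- paste(rid, 0L, genome$name, blocks[1L, 1L] + 1L, 60L,
                          cigar, "*", 0L, 0L, rseq, qual, sep = "\t")
      fastq[4L * r - 3L:0L] <- c(paste0("@", rid), rseq, "+", qual)
      truth_rows[r] <- paste(rid, k, truth$isoforms[[k]]$annotation,
                             sample_id, sep = "\t")
    }
    sam_path <- paste0(out_prefix, ".sam")
    fq_path <- paste0(out_prefix, ".fastq")
    truth_path <- paste0(out_prefix, ".truth.tsv")
    writeLines(c(header, records), sam_path)
    writeLines(fastq, fq_path)
    writeLines(c(paste("read_id", "isoform", "annotation", "sample",
                       sep = "\t"), truth_rows), truth_path)
    invisible(list(sam = sam_path, fastq = fq_path, truth = truth_path,
                   counts = tabulate(member, length(weights))))
  })
}
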