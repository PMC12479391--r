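#' Read spliced alignments against an artificial genome
#'
#' Loads primary alignments from a SAM or BAM file and converts each one to
#' a block/intron representation on the artificial genome: blocks are the
#' reference ranges covered by match/insertion/deletion CIGAR operations,
#' introns the `N`-gap ranges between consecutive blocks. Secondary,
#' supplementary and unmapped records are dropped, as are records below
#' `min_mapq` (records with no mapping quality, MAPQ 255, are kept).
#'
#' @param path SAM or BAM file. SAM input is converted to BAM internally.
#' @param sample_id Sample identifier attached to every read.
#' @param min_mapq Minimum mapping quality (default 1).
#' @param genome_name Expected reference name; alignments to any other
#'   reference are an error.
#' @return A `mg_reads` object: list of reads, each with `read_id`,
#'   `sample_id` and `blocks` (0-based half-open integer matrix).
#' @export
parse_alignments <- function(path, sample_id, min_mapq = 1L, genome_name) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "mapq")
  gal <- GenomicAlignments::readGAlignments(path, use.names = TRUE,
                                            param = param)
  refs <- unique(as.character(GenomeInfoDb::seqnames(gal)))
  bad <- setdiff(refs, genome_name)
  if (length(bad))
    stop("alignments reference '", paste(bad, collapse = "', '"),
         "', expected artificial genome '", genome_name, "'")
  mapq <- S4Vectors::mcols(gal)$mapq
  keep <- is.na(mapq) | mapq == 255L | mapq >= min_mapq
  gal <- gal[keep]
  blk <- GenomicAlignments::extractAlignmentRangesOnReference(
    GenomicAlignments::cigar(gal), BiocGenerics::start(gal),
    drop.D.ranges = FALSE)
  reads <- lapply(seq_along(gal), function(i) {
    r <- blk[[i]]
    structure(list(read_id = names(gal)[i], sample_id = sample_id,
                   blocks = cbind(start = IRanges::start(r) - 1L,
                                  end = IRanges::end(r))),
              class = "mg_read")
  })
  structure(reads, class = "mg_reads", genome_name = genome_name)
}

#' Intron chain of a read or isoform
#'
#' The ordered donor/acceptor gaps between consecutive aligned blocks,
#' 0-based half-open: each row is one intron `[donor_end, acceptor_start)`.
#'
#' @param x A `mg_read`, or a blocks matrix.
#' @return Integer matrix with columns `donor_end`, `acceptor_start`
#'   (zero rows for an unspliced read).
#' @export
intron_chain <- function(x) {
  b <- if (inherits(x, "mg_read")) x$blocks else x
  n <- nrow(b)
  if (n < 2L)
    return(matrix(integer(), 0L, 2L,
                  dimnames = list(NULL, c("donor_end", "acceptor_start"))))
  cbind(donor_end = b[-n, 2L], acceptor_start = b[-1L, 1L])
}

#' Snap read splice junctions onto annotated exon boundaries
#'
#' Long-read splice boundaries wobble by a few nucleotides around the true
#' donor/acceptor sites. Each intron boundary lying within `wobble` nt of an
#' annotated feature boundary (any feature start or end) is moved onto the
#' nearest such site (ties broken toward the lower coordinate); boundaries
#' with no annotated site in range are left unchanged. If snapping would
#' produce a non-positive block or intron, the read is returned unchanged
#' and flagged with attribute `unsnappable`.
#'
#' Snapping is idempotent: a boundary already on an annotated site stays put.
#'
#' @param read A `mg_read`.
#' @param annotation A `reference_annotation` or `minigene_reference`.
#' @param wobble Maximum snap distance in nt (`0` disables snapping).
#' @return The adjusted `mg_read`.
#' @export
snap_junctions <- function(read, annotation, wobble = 8L) {
  if (inherits(annotation, "minigene_reference"))
    annotation <- annotation$annotation
  stopifnot(inherits(read, "mg_read"), wobble >= 0L)
  b <- read$blocks
  if (wobble == 0L || nrow(b) < 2L) return(read)
  sites <- sort(unique(c(annotation$features$start, annotation$features$end)))
  snap1 <- function(x) {
    d <- abs(sites - x)
    i <- which.min(d)            # sites ascending: tie falls on lower coord
    if (d[i] <= wobble) sites[i] else x
  }
  ch <- intron_chain(b)
  donor <- vapply(ch[, 1L], snap1, integer(1))
  accept <- vapply(ch[, 2L], snap1, integer(1))
  nb <- cbind(start = unname(c(b[1L, 1L], accept)),
              end = unname(c(donor, b[nrow(b), 2L])))
  ok <- all(nb[, 2L] > nb[, 1L]) &&
    all(nb[-1L, 1L] >= nb[-nrow(nb), 2L]) && all(donor < accept)
  if (!ok) {
    attr(read, "unsnappable") <- TRUE
    return(read)
  }
  read$blocks <- nb
  read
}

#' @rdname snap_junctions
#' @param reads A `mg_reads` collection.
#' @export
snap_all <- function(reads, annotation, wobble = 8L) {
  out <- lapply(reads, snap_junctions, annotation = annotation,
                wobble = wobble)
  attributes(out) <- attributes(reads)
  out
}

# fraction of a feature interval covered by a read's aligned blocks
.feature_coverage <- function(blocks, start, end) {
  ov <- pmin(blocks[, 2L], end) - pmax(blocks[, 1L], start)
  sum(ov[ov > 0L]) / (end - start)
}

#' Cluster reads into isoform models by intron chain
#'
#' Reads sharing an identical intron chain (after junction snapping) are
#' one isoform: the amplicon ends are fixed by the RT-PCR primers in the
#' constitutive exons, so terminal block endpoints carry no isoform
#' information. Reads whose aligned blocks cover less than
#' `min_end_overlap` of either terminal annotated feature are discarded as
#' incomplete (full-length amplicon filter). Unspliced reads form a valid
#' model (candidate full intron-retention product).
#'
#' @param reads A `mg_reads` collection (snap junctions first for noisy
#'   long reads).
#' @param annotation A `reference_annotation` or `minigene_reference`
#'   (supplies the terminal features for the full-length filter).
#' @param min_end_overlap Minimum covered fraction of each terminal
#'   feature (default 0.5). Set to 0 to disable the filter.
#' @return A `mg_isoforms` list, ordered by descending total read count
#'   (ties by lexicographic intron chain); each element has `isoform_id`,
#'   `chain`, `span` and per-sample `counts`.
#' @export
cluster_reads <- function(reads, annotation, min_end_overlap = 0.5) {
  if (inherits(annotation, "minigene_reference"))
    annotation <- annotation$annotation
  gn <- attr(reads, "genome_name")
  f <- annotation$features
  first <- f[1L, ]
  last <- f[nrow(f), ]
  keep <- vapply(reads, function(r)
    .feature_coverage(r$blocks, first$start, first$end) >= min_end_overlap &&
    .feature_coverage(r$blocks, last$start, last$end) >= min_end_overlap,
    logical(1))
  reads <- reads[keep]
  if (!length(reads))
    return(structure(list(), class = "mg_isoforms", genome_name = gn))
  keys <- vapply(reads, function(r)
    paste(t(intron_chain(r)), collapse = ","), character(1))
  groups <- split(seq_along(reads), keys)
  models <- lapply(groups, function(idx) {
    r1 <- reads[[idx[1L]]]
    samples <- vapply(reads[idx], `[[`, character(1), "sample_id")
    spans <- vapply(reads[idx], function(r)
      c(r$blocks[1L, 1L], r$blocks[nrow(r$blocks), 2L]), integer(2))
    structure(list(isoform_id = NA_character_,
                   chain = intron_chain(r1),
                   span = c(min(spans[1L, ]), max(spans[2L, ])),
                   counts = c(table(samples))),
              class = "mg_isoform")
  })
  totals <- vapply(models, function(m) sum(m$counts), numeric(1))
  models <- models[order(-totals, names(groups))]
  for (i in seq_along(models))
    models[[i]]$isoform_id <- paste0("iso", i)
  structure(unname(models), class = "mg_isoforms", genome_name = gn)
}

#' @export
print.mg_isoforms <- function(x, ...) {
  cat("mg_isoforms:", length(x), "isoform model(s)\n")
  for (m in x)
    cat("  ", m$isoform_id, ": ", nrow(m$chain), " intron(s), total count ",
        sum(m$counts), "\n", sep = "")
  invisible(x)
}

#' Import assembled transcript models from a StringTie-style GTF
#'
#' Alternative entry point for externally assembled isoforms: transcript
#' exon lines are converted to isoform models, with expression taken from
#' the `cov` attribute (falling back to `TPM`).
#'
#' @param path GTF file with `transcript` and `exon` features.
#' @param sample_id Sample the expression values belong to.
#' @param genome_name Expected reference (seqname); mismatch is an error.
#' @return A `mg_isoforms` list ordered by descending expression.
#' @export
read_assembled_gtf <- function(path, sample_id, genome_name) {
  g <- rtracklayer::import(path, format = "gtf")
  refs <- unique(as.character(GenomicRanges::seqnames(g)))
  bad <- setdiff(refs, genome_name)
  if (length(bad))
    stop("GTF references '", paste(bad, collapse = "', '"),
         "', expected '", genome_name, "'")
  ex <- g[g$type == "exon"]
  if (!length(ex)) stop("no exon features in ", path)
  expr_of <- function(meta) {
    v <- suppressWarnings(as.numeric(
      if (!is.null(meta$cov)) meta$cov else meta$TPM))
    if (is.null(v) || is.na(v)) 0 else v
  }
  by_tx <- split(ex, ex$transcript_id)
  models <- lapply(names(by_tx), function(tx) {
    e <- by_tx[[tx]]
    b <- cbind(start = GenomicRanges::start(e) - 1L,
               end = GenomicRanges::end(e))
    b <- b[order(b[, 1L]), , drop = FALSE]
    structure(list(isoform_id = tx, chain = intron_chain(b),
                   span = c(b[1L, 1L], b[nrow(b), 2L]),
                   counts = stats::setNames(
                     expr_of(S4Vectors::mcols(e)[1L, ]), sample_id)),
              class = "mg_isoform")
  })
  totals <- vapply(models, function(m) sum(m$counts), numeric(1))
  structure(models[order(-totals)], class = "mg_isoforms",
            genome_name = genome_name)
}
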