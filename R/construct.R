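#' Minigene construct description
#'
#' Bundles the full construct sequence with the declared constitutive
#' (vector) exons and the ordered cloned exons of the gene of interest.
#' Sequences are uppercased on entry. Cloned exons must be free of N
#' characters (exact matching against the construct would otherwise be
#' ambiguous); the construct itself may contain N.
#'
#' @param construct_sequence Full construct nucleotide sequence (character
#'   scalar, IUPAC alphabet).
#' @param upstream_exon,downstream_exon Sequences of the constitutive vector
#'   exons flanking the cloned insert.
#' @param cloned_exons Named character vector of cloned exon sequences; names
#'   are the exon numbers (positive integers, e.g. `c("2" = "ACGT...")`).
#'   May be empty (vector-only control construct).
#' @param gene_symbol,transcript_name,construction_name Identifier strings
#'   used in the GTF and the report.
#' @return An object of class `minigene_construct`.
#' @export
minigene_construct <- function(construct_sequence, upstream_exon,
                               downstream_exon, cloned_exons = character(),
                               gene_symbol, transcript_name,
                               construction_name) {
  construct_sequence <- .check_seq(construct_sequence, "construct_sequence",
                                   allow_n = TRUE)
  upstream_exon <- .check_seq(upstream_exon, "upstream_exon")
  downstream_exon <- .check_seq(downstream_exon, "downstream_exon")
  if (length(cloned_exons)) {
    if (is.null(names(cloned_exons)) || any(!nzchar(names(cloned_exons))))
      stop("cloned_exons must be named by exon number")
    nums <- suppressWarnings(as.integer(names(cloned_exons)))
    if (anyNA(nums) || any(nums <= 0))
      stop("cloned exon names must be positive integers")
    if (anyDuplicated(nums))
      stop("duplicated cloned exon numbers: ",
           paste(nums[duplicated(nums)], collapse = ", "))
    cloned_exons <- vapply(seq_along(cloned_exons), function(i)
      .check_seq(cloned_exons[[i]], paste0("exon ", nums[i])), character(1))
    names(cloned_exons) <- nums
  }
  for (nm in c(gene_symbol, transcript_name, construction_name))
    if (!is.character(nm) || length(nm) != 1L || !nzchar(nm))
      stop("gene_symbol, transcript_name and construction_name must be ",
           "non-empty strings")
  structure(list(construct_sequence = construct_sequence,
                 upstream_exon = upstream_exon,
                 downstream_exon = downstream_exon,
                 cloned_exons = cloned_exons,
                 gene_symbol = gene_symbol,
                 transcript_name = transcript_name,
                 construction_name = construction_name),
            class = "minigene_construct")
}

#' @export
print.minigene_construct <- function(x, ...) {
  cat("Minigene construct '", x$construction_name, "' (",
      x$gene_symbol, " / ", x$transcript_name, ")\n", sep = "")
  cat("  construct length : ", nchar(x$construct_sequence), " nt\n", sep = "")
  cat("  constitutive     : ", nchar(x$upstream_exon), " nt / ",
      nchar(x$downstream_exon), " nt\n", sep = "")
  cat("  cloned exons     : ", length(x$cloned_exons),
      if (length(x$cloned_exons))
        paste0(" (", paste(names(x$cloned_exons), collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

# uppercases and validates a nucleotide string against the IUPAC alphabet
.check_seq <- function(x, what, allow_n = FALSE) {
  if (!is.character(x) || length(x) != 1L)
    stop(what, " must be a single character string")
  x <- toupper(x)
  if (!nzchar(x)) stop(what, " is empty")
  alphabet <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), alphabet)
  if (length(bad))
    stop(what, " contains characters outside the IUPAC nucleotide ",
         "alphabet: ", paste(bad, collapse = ", "))
  if (!allow_n && grepl("N", x, fixed = TRUE))
    stop(what, " contains N; declared exon sequences must be unambiguous")
  x
}

#' Read a construct sequence file
#'
#' Reads the full minigene construct sequence from a single-record FASTA or
#' GenBank file. For GenBank input only the ORIGIN sequence is used; the
#' feature table is ignored (exon declarations are supplied separately).
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"`, `"genbank"`, or `"auto"` (by extension:
#'   `.gb`/`.gbk`/`.genbank` is GenBank, anything else FASTA).
#' @return The uppercased construct sequence (character scalar).
#' @export
parse_construct_file <- function(path, format = c("auto", "fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gb", "gbk", "genbank")) "genbank" else "fasta"
  }
  if (format == "genbank") {
    n_rec <- sum(grepl("^LOCUS", readLines(path, warn = FALSE)))
    if (n_rec != 1L)
      stop("expected exactly one GenBank record, found ", n_rec)
    fa <- tempfile(fileext = ".fa")
    on.exit(unlink(fa))
    seqinr::gb2fasta(path, fa)
    path <- fa
  }
  # read raw (BString) so invalid letters reach our validator instead of
  # being silently dropped by the DNA alphabet
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 1L)
    stop("expected exactly one sequence record, found ", length(seqs))
  .check_seq(as.character(seqs[[1L]]), "construct sequence", allow_n = TRUE)
}

#' Locate the unique occurrence of a subsequence
#'
#' Exact, case-sensitive search after both strings have been uppercased by
#' their constructors. Zero or multiple matches are errors: constructs are
#' user-designed, so an ambiguous exon placement indicates a design problem
#' that must not be silently resolved.
#'
#' @param haystack,needle Nucleotide strings.
#' @param label Name used in error messages (defaults to the needle).
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
locate_unique <- function(haystack, needle, label = NULL) {
  if (!nzchar(needle)) stop("query sequence is empty")
  if (is.null(label))
    label <- if (nchar(needle) > 20)
      paste0(substr(needle, 1, 20), "...") else needle
  # matchPattern reports overlapping occurrences, which gregexpr misses
  m <- Biostrings::matchPattern(needle, Biostrings::BString(haystack))
  if (length(m) == 0L)
    stop("sequence not found in construct: ", label)
  if (length(m) > 1L)
    stop("sequence '", label, "' is ambiguous: matches at positions ",
         paste(BiocGenerics::start(m) - 1L, collapse = ", "), " (0-based)")
  start0 <- BiocGenerics::start(m) - 1L
  c(start = start0, end = start0 + nchar(needle))
}

#' Build the artificial genome and its annotation
#'
#' Locates the declared constitutive and cloned exon sequences inside the
#' construct, delineates the amplified splicing vector as the region from
#' the start of the upstream constitutive exon to the end of the downstream
#' one, and re-expresses all features relative to that amplicon. The two
#' constitutive exons become UTR-role features (labelled `UTR5`/`UTR3`);
#' cloned exons become exon-role features labelled by their numbers.
#'
#' The construct is assumed to be given in the transcription orientation:
#' all features are reported on the plus strand.
#'
#' @param construct A [minigene_construct()].
#' @return A `minigene_reference`: list with `genome` (name + amplicon
#'   sequence) and `annotation` (feature table with 0-based half-open
#'   `start`/`end`, `role` in `{UTR, exon}`, `label`).
#' @export
build_reference <- function(construct) {
  stopifnot(inherits(construct, "minigene_construct"))
  seqs <- construct$construct_sequence
  up <- locate_unique(seqs, construct$upstream_exon, "upstream constitutive exon")
  down <- locate_unique(seqs, construct$downstream_exon,
                        "downstream constitutive exon")
  if (down[["start"]] < up[["end"]])
    stop("downstream constitutive exon occurs before the upstream one")
  exon_nums <- as.integer(names(construct$cloned_exons))
  occ <- lapply(seq_along(construct$cloned_exons), function(i)
    locate_unique(seqs, construct$cloned_exons[[i]],
                  paste0("exon ", exon_nums[i])))
  # placement: strictly between the constitutive exons
  for (i in seq_along(occ)) {
    if (occ[[i]][["start"]] < up[["end"]] || occ[[i]][["end"]] > down[["start"]])
      stop("exon ", exon_nums[i],
           " lies outside the amplified region between the constitutive exons")
  }
  if (length(occ) > 1L) {
    starts <- vapply(occ, `[[`, integer(1), "start")
    ends <- vapply(occ, `[[`, integer(1), "end")
    o <- order(starts)
    if (any(ends[o][-length(o)] > starts[o][-1L]))
      stop("cloned exon occurrences overlap in the construct")
    if (is.unsorted(exon_nums[o], strictly = TRUE))
      stop("cloned exon numbers are not strictly increasing along the ",
           "construct: ", paste(exon_nums[o], collapse = ", "))
    occ <- occ[o]
    exon_nums <- exon_nums[o]
  }
  amp_start <- up[["start"]]
  amp_end <- down[["end"]]
  amplicon <- substr(seqs, amp_start + 1L, amp_end)
  feat <- data.frame(
    start = c(up[["start"]], vapply(occ, `[[`, integer(1), "start"),
              down[["start"]]) - amp_start,
    end = c(up[["end"]], vapply(occ, `[[`, integer(1), "end"),
            down[["end"]]) - amp_start,
    role = c("UTR", rep("exon", length(occ)), "UTR"),
    label = c("UTR5", as.character(exon_nums), "UTR3"),
    stringsAsFactors = FALSE)
  genome <- structure(list(name = construct$construction_name,
                           sequence = amplicon),
                      class = "artificial_genome")
  annotation <- structure(list(genome_name = construct$construction_name,
                               gene_symbol = construct$gene_symbol,
                               transcript_name = construct$transcript_name,
                               features = feat),
                          class = "reference_annotation")
  structure(list(genome = genome, annotation = annotation),
            class = "minigene_reference")
}

#' @export
print.minigene_reference <- function(x, ...) {
  cat("Artificial genome '", x$genome$name, "': ",
      nchar(x$genome$sequence), " nt amplicon\n", sep = "")
  f <- x$annotation$features
  cat("  features: ", sum(f$role == "UTR"), " UTR + ",
      sum(f$role == "exon"), " exon\n", sep = "")
  print(f, row.names = FALSE)
  invisible(x)
}

#' Write the artificial genome as FASTA
#'
#' Single record, header equal to the construction name, 60-column wrapped.
#'
#' @param genome An `artificial_genome` (from [build_reference()]) or a
#'   `minigene_reference`.
#' @param path Output file path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (inherits(genome, "minigene_reference")) genome <- genome$genome
  stopifnot(inherits(genome, "artificial_genome"))
  x <- Biostrings::DNAStringSet(stats::setNames(genome$sequence, genome$name))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write the reference annotation as GTF
#'
#' Emits one `gene` and one `transcript` line spanning the amplicon, then
#' one line per feature: feature column `"UTR"` for the constitutive exons,
#' `"exon"` for cloned exons (with an `exon_number` attribute). Coordinates
#' are converted from the internal 0-based half-open convention to GTF
#' 1-based inclusive; everything is on the plus strand.
#'
#' @param annotation A `reference_annotation` or `minigene_reference`.
#' @param path Output file path.
#' @export
write_reference_gtf <- function(annotation, path) {
  if (inherits(annotation, "minigene_reference"))
    annotation <- annotation$annotation
  stopifnot(inherits(annotation, "reference_annotation"))
  f <- annotation$features
  attr_gene <- sprintf('gene_id "%s";', annotation$gene_symbol)
  attr_tx <- sprintf('gene_id "%s"; transcript_id "%s";',
                     annotation$gene_symbol, annotation$transcript_name)
  line <- function(feature, start0, end0, attrs)
    paste(annotation$genome_name, "minigeneiso", feature,
          start0 + 1L, end0, ".", "+", ".", attrs, sep = "\t")
  span <- c(min(f$start), max(f$end))
  out <- c(line("gene", span[1L], span[2L], attr_gene),
           line("transcript", span[1L], span[2L], attr_tx))
  for (i in seq_len(nrow(f))) {
    attrs <- if (f$role[i] == "exon")
      paste0(attr_tx, sprintf(' exon_number "%s";', f$label[i]))
    else attr_tx
    out <- c(out, line(f$role[i], f$start[i], f$end[i], attrs))
  }
  writeLines(out, path)
  invisible(path)
}
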