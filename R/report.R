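#' Relative isoform proportions within one construct
#'
#' Each expression value divided by the per-sample total over all isoforms
#' of the construct; a zero total gives all-zero proportions rather than
#' NaN (a sample can legitimately contribute no reads to a construct).
#'
#' @param expression Non-negative numeric vector (one value per isoform).
#' @return Numeric vector of fractions, same names as the input.
#' @export
isoform_proportions <- function(expression) {
  if (any(is.na(expression)) || any(expression < 0))
    stop("expression values must be non-negative")
  total <- sum(expression)
  if (total == 0) return(expression * 0)
  expression / total
}

#' Cohort occurrence of each isoform
#'
#' Number of samples in which an isoform's proportion exceeds the presence
#' threshold. Occurrence is monotonically non-increasing in the threshold.
#'
#' @param proportions Numeric matrix, isoforms x samples.
#' @param presence_threshold Fraction in `[0, 1)`; the default 0 counts
#'   every sample with any signal (report-everything: even trace isoforms
#'   near background level are of interest).
#' @return Integer vector, one count per isoform.
#' @export
isoform_occurrence <- function(proportions, presence_threshold = 0) {
  if (presence_threshold < 0 || presence_threshold >= 1)
    stop("presence_threshold must be in [0, 1)")
  p <- as.matrix(proportions)
  as.integer(rowSums(p > presence_threshold))
}

#' Build the final annotated isoform table
#'
#' One row per isoform, sorted by descending total expression. Columns:
#' `transcript_id` (construction name + "." + rank), `construction`,
#' `gene`, `annot_ref`, `annot_find`, one expression column per sample
#' (supporting-read count for internally clustered models; coverage when
#' imported from an external assembler), `occurrence`, and one
#' `P_`-prefixed proportion column per sample.
#'
#' @param annotated A `mg_annotated` collection.
#' @param samples Character vector of sample names ordering the expression
#'   columns; defaults to the samples seen in the data, in order of
#'   appearance.
#' @param construction,gene Construction name and gene symbol for the
#'   table; default to `reference` metadata when given.
#' @param reference Optional `minigene_reference` supplying the defaults.
#' @param presence_threshold Passed to [isoform_occurrence()].
#' @return A `data.frame` (header-only when no isoforms).
#' @export
build_report <- function(annotated, samples = NULL, construction = NULL,
                         gene = NULL, reference = NULL,
                         presence_threshold = 0) {
  if (!is.null(reference)) {
    ann <- if (inherits(reference, "minigene_reference"))
      reference$annotation else reference
    if (is.null(construction)) construction <- ann$genome_name
    if (is.null(gene)) gene <- ann$gene_symbol
  }
  if (is.null(construction) || is.null(gene))
    stop("construction and gene must be given (directly or via reference)")
  if (is.null(samples))
    samples <- unique(unlist(lapply(annotated, function(a)
      names(a$isoform$counts))))
  if (anyDuplicated(samples))
    stop("duplicate sample names: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (!length(annotated)) {
    out <- data.frame(transcript_id = character(), construction = character(),
                      gene = character(), annot_ref = character(),
                      annot_find = character(), stringsAsFactors = FALSE)
    for (s in samples) out[[s]] <- numeric()
    out$occurrence <- integer()
    for (s in samples) out[[paste0("P_", s)]] <- numeric()
    return(out)
  }
  expr <- t(vapply(annotated, function(a) {
    v <- a$isoform$counts[samples]
    v[is.na(v)] <- 0
    as.numeric(v)
  }, numeric(length(samples))))
  if (length(samples) == 1L) expr <- matrix(expr, ncol = 1L)
  colnames(expr) <- samples
  ord <- order(-rowSums(expr))
  annotated <- annotated[ord]
  expr <- expr[ord, , drop = FALSE]
  props <- apply(expr, 2L, isoform_proportions)
  if (length(annotated) == 1L)
    props <- matrix(props, nrow = 1L, dimnames = list(NULL, samples))
  out <- data.frame(
    transcript_id = paste0(construction, ".", seq_along(annotated)),
    construction = construction, gene = gene,
    annot_ref = vapply(annotated, `[[`, character(1), "annot_ref"),
    annot_find = vapply(annotated, `[[`, character(1), "annot_find"),
    stringsAsFactors = FALSE)
  for (s in samples) out[[s]] <- expr[, s]
  out$occurrence <- isoform_occurrence(props, presence_threshold)
  for (s in samples) out[[paste0("P_", s)]] <- props[, s]
  rownames(out) <- NULL
  out
}

#' Write the report as TSV and xlsx
#'
#' The TSV is written natively (UTF-8, tab-separated). The xlsx export —
#' one sheet named after the construction — is delegated to Python's
#' openpyxl (`python` must be on the PATH); both files carry identical
#' values.
#'
#' @param report data.frame from [build_report()].
#' @param out_prefix Output path prefix; writes `<prefix>.tsv` and, when
#'   `xlsx = TRUE`, `<prefix>.xlsx`.
#' @param xlsx Also write the xlsx workbook (default TRUE).
#' @param sheet Sheet name; defaults to the construction column (or
#'   "report" for an empty table).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_prefix, xlsx = TRUE, sheet = NULL) {
  tsv <- paste0(out_prefix, ".tsv")
  utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  paths <- tsv
  if (xlsx) {
    if (is.null(sheet))
      sheet <- if (nrow(report)) report$construction[1L] else "report"
    xl <- paste0(out_prefix, ".xlsx")
    .write_xlsx_via_python(tsv, xl, sheet)
    paths <- c(paths, xl)
  }
  invisible(paths)
}

# converts a TSV to a one-sheet xlsx workbook using openpyxl
.write_xlsx_via_python <- function(tsv, xlsx_path, sheet) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("xlsx export needs a 'python' executable with openpyxl on the ",
         "PATH; use xlsx = FALSE for TSV-only output")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import csv, sys",
    "from openpyxl import Workbook",
    "tsv, out, sheet = sys.argv[1:4]",
    "wb = Workbook(); ws = wb.active; ws.title = sheet",
    "def conv(x, header):",
    "    if header: return x",
    "    try: return int(x)",
    "    except ValueError: pass",
    "    try: return float(x)",
    "    except ValueError: return x",
    "with open(tsv, newline='', encoding='utf-8') as fh:",
    "    for i, row in enumerate(csv.reader(fh, delimiter='\\t')):",
    "        ws.append([conv(c, i == 0) for c in row])",
    "wb.save(out)"), script)
  st <- system2(py, c(script, shQuote(tsv), shQuote(xlsx_path),
                      shQuote(sheet)), stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(st, "status")) && attr(st, "status") != 0)
    stop("xlsx export failed: ", paste(st, collapse = "\n"))
  unlink(script)
  invisible(xlsx_path)
}
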