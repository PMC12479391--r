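#' Construct a splice event
#'
#' One deviation of an isoform from the reference exon chain. Exon labels
#' are carried as strings: cloned exons use their number, the constitutive
#' flanks are `"UTR5"`/`"UTR3"` (they can appear only in retention events;
#' UTR-role features never generate skips).
#'
#' @param kind One of `skip`, `partial_deletion`, `intron_retention`,
#'   `partial_retention`, `novel_exon`.
#' @param first_exon,last_exon Labels of the first/last reference feature
#'   involved (equal for single-feature events).
#' @param side `"acceptor"` (5' edge), `"donor"` (3' edge), or `"none"`.
#' @param size_nt Event size in nt; required (> 0) for partial and novel
#'   events, 0 otherwise. Sizes, not genomic positions, keep the event
#'   amplicon-independent.
#' @return A `splice_event`.
#' @export
splice_event <- function(kind, first_exon, last_exon = first_exon,
                         side = "none", size_nt = 0L) {
  kind <- match.arg(kind, c("skip", "partial_deletion", "intron_retention",
                            "partial_retention", "novel_exon"))
  side <- match.arg(side, c("none", "acceptor", "donor"))
  size_nt <- as.integer(size_nt)
  if (kind %in% c("partial_deletion", "partial_retention", "novel_exon")) {
    if (size_nt <= 0L) stop(kind, " requires size_nt > 0")
  } else if (size_nt != 0L) stop(kind, " must have size_nt = 0")
  if (kind %in% c("partial_deletion", "partial_retention") && side == "none")
    stop(kind, " requires a side (acceptor or donor)")
  structure(list(kind = kind, first_exon = as.character(first_exon),
                 last_exon = as.character(last_exon), side = side,
                 size_nt = size_nt),
            class = "splice_event")
}

#' @export
print.splice_event <- function(x, ...) {
  cat(format_annotation(list(x)), "\n")
  invisible(x)
}

#' Exonic blocks of an isoform on the artificial genome
#'
#' The complement of the isoform's intron chain over the annotated span of
#' the amplicon: the reference UTR outer bounds serve as the transcript's
#' terminal ends (amplicon ends are primer-defined, not isoform-specific).
#'
#' @param x A `mg_isoform` or an intron-chain matrix.
#' @param annotation A `reference_annotation` or `minigene_reference`.
#' @return Integer matrix of `start`,`end` blocks, 0-based half-open.
#' @export
isoform_exons <- function(x, annotation) {
  if (inherits(annotation, "minigene_reference"))
    annotation <- annotation$annotation
  ch <- if (inherits(x, "mg_isoform")) x$chain else x
  f <- annotation$features
  lo <- min(f$start)
  hi <- max(f$end)
  if (!nrow(ch)) return(cbind(start = lo, end = hi))
  if (is.unsorted(as.vector(t(ch)), strictly = TRUE) ||
      ch[1L, 1L] <= lo || ch[nrow(ch), 2L] >= hi)
    stop("intron chain is not strictly increasing within the amplicon")
  cbind(start = c(lo, ch[, 2L]), end = c(ch[, 1L], hi))
}

#' Classify an isoform's deviations from the reference exon chain
#'
#' Compares the isoform's exonic blocks with the reference features and
#' emits splice events in 5'-to-3' order:
#' \itemize{
#'   \item a cloned exon with no covered base is skipped; maximal runs of
#'     consecutive skipped exons merge into one `skip(first, last)`;
#'   \item a cloned exon partially covered at its 5' (acceptor) or 3'
#'     (donor) edge gives a `partial_deletion` with the missing size;
#'     an interior gap (both edges covered) is out of scope and is
#'     reported as a `partial_deletion` on the larger missing side, with
#'     a warning;
#'   \item a block covering an entire reference intron gives
#'     `intron_retention` between the flanking features;
#'   \item a block extending from a feature edge into the adjacent intron
#'     gives `partial_retention` with the retained size;
#'   \item a block overlapping no reference feature gives `novel_exon`
#'     assigned to the flanking feature pair.
#' }
#'
#' @param blocks Isoform exonic blocks (from [isoform_exons()]).
#' @param annotation A `reference_annotation` or `minigene_reference`.
#' @return List of `splice_event`, ordered 5' to 3'.
#' @export
classify_events <- function(blocks, annotation) {
  if (inherits(annotation, "minigene_reference"))
    annotation <- annotation$annotation
  f <- annotation$features
  lo <- min(f$start); hi <- max(f$end)
  if (any(blocks[, 1L] < lo) || any(blocks[, 2L] > hi))
    stop("isoform blocks extend outside the amplicon [", lo, ", ", hi, ")")
  events <- list()
  pos <- integer()
  add <- function(ev, at) {
    events[[length(events) + 1L]] <<- ev
    pos[length(pos) + 1L] <<- at
  }

  # per-feature coverage: skips and partial deletions
  skipped <- logical(nrow(f))
  for (i in seq_len(nrow(f))) {
    s <- f$start[i]; e <- f$end[i]
    ov_s <- pmax(blocks[, 1L], s)
    ov_e <- pmin(blocks[, 2L], e)
    covered <- ov_e - ov_s > 0L
    if (!any(covered)) {
      skipped[i] <- TRUE       # UTR absence handled upstream, not an event
      next
    }
    if (f$role[i] != "exon") next
    cov_s <- min(ov_s[covered]); cov_e <- max(ov_e[covered])
    miss5 <- cov_s - s
    miss3 <- e - cov_e
    interior <- sum((ov_e - ov_s)[covered]) < cov_e - cov_s
    if (interior) {
      gap <- (cov_e - cov_s) - sum((ov_e - ov_s)[covered]) + miss5 + miss3
      side <- if (cov_s - s >= e - cov_e) "acceptor" else "donor"
      warning("exon ", f$label[i], " has an interior gap; reported as ",
              "partial_deletion on the ", side, " side")
      add(splice_event("partial_deletion", f$label[i], side = side,
                       size_nt = gap), s)
      next
    }
    if (miss5 > 0L)
      add(splice_event("partial_deletion", f$label[i], side = "acceptor",
                       size_nt = miss5), s)
    if (miss3 > 0L)
      add(splice_event("partial_deletion", f$label[i], side = "donor",
                       size_nt = miss3), cov_e)
  }

  # merge runs of consecutive skipped cloned exons
  i <- 1L
  while (i <= nrow(f)) {
    if (skipped[i] && f$role[i] == "exon") {
      j <- i
      while (j < nrow(f) && skipped[j + 1L] && f$role[j + 1L] == "exon")
        j <- j + 1L
      add(splice_event("skip", f$label[i], f$label[j]), f$start[i])
      i <- j + 1L
    } else i <- i + 1L
  }

  # reference introns: retention, partial retention, novel exons
  for (k in seq_len(nrow(f) - 1L)) {
    is_ <- f$end[k]; ie <- f$start[k + 1L]
    if (ie <= is_) next                          # touching features
    lab_l <- f$label[k]; lab_r <- f$label[k + 1L]
    full <- any(blocks[, 1L] <= is_ & blocks[, 2L] >= ie)
    if (full) {
      add(splice_event("intron_retention", lab_l, lab_r), is_)
      next
    }
    for (b in seq_len(nrow(blocks))) {
      bs <- blocks[b, 1L]; be <- blocks[b, 2L]
      if (be <= is_ || bs >= ie) next            # no overlap with intron
      if (bs < is_ && be > is_)                  # spills over donor of left
        add(splice_event("partial_retention", lab_l, side = "donor",
                         size_nt = min(be, ie) - is_), is_)
      else if (bs < ie && be > ie)               # spills over acceptor of right
        add(splice_event("partial_retention", lab_r, side = "acceptor",
                         size_nt = ie - max(bs, is_)), ie - (ie - bs))
      else                                       # strictly inside the intron
        add(splice_event("novel_exon", lab_l, lab_r, size_nt = be - bs), bs)
    }
  }
  events[order(pos)]
}

#' Format splice events as an annotation string
#'
#' The compact relative nomenclature used in the final report:
#' \itemize{
#'   \item no events: `"FL"` (full length);
#'   \item skip of exon i: `"Δ(i)"`, of exons i..j: `"Δ(i-j)"`;
#'   \item partial deletion of k nt at the acceptor/donor edge of exon i:
#'     `"Δ(ip_k)"` / `"Δ(iq_k)"`;
#'   \item retention of the intron between i and j: `"▼(i-j)"`;
#'   \item partial retention of k nt at the donor/acceptor edge of exon i:
#'     `"▼(iq_k)"` / `"▼(ip_k)"`;
#'   \item novel exon of k nt between i and j: `"▼(i-j,k)"`.
#' }
#' Multiple events are joined by `","` in 5'-to-3' order; ranges use the
#' ASCII hyphen. With `unicode = FALSE` the symbols degrade to `"del"` and
#' `"ins"` for fully ASCII output.
#'
#' @param events List of `splice_event` (5' to 3').
#' @param unicode Use the Δ/▼ symbols (default) or ASCII fallbacks.
#' @return A single annotation string.
#' @export
format_annotation <- function(events, unicode = TRUE) {
  del <- if (unicode) "\u0394" else "del"
  ins <- if (unicode) "\u25BC" else "ins"
  if (!length(events)) return("FL")
  one <- function(ev) {
    with(ev, switch(kind,
      skip = if (first_exon == last_exon) sprintf("%s(%s)", del, first_exon)
             else sprintf("%s(%s-%s)", del, first_exon, last_exon),
      partial_deletion = sprintf("%s(%s%s_%d)", del, first_exon,
                                 if (side == "acceptor") "p" else "q", size_nt),
      intron_retention = sprintf("%s(%s-%s)", ins, first_exon, last_exon),
      partial_retention = sprintf("%s(%s%s_%d)", ins, first_exon,
                                  if (side == "acceptor") "p" else "q",
                                  size_nt),
      novel_exon = sprintf("%s(%s-%s,%d)", ins, first_exon, last_exon,
                           size_nt)))
  }
  paste(vapply(events, one, character(1)), collapse = ",")
}

#' Parse an annotation string back into splice events
#'
#' Exact inverse of [format_annotation()] (unicode form); used to
#' round-trip annotations and to consume previously written reports.
#'
#' @param s Annotation string (e.g. `"Δ(4-5)"`, `"FL"`).
#' @return List of `splice_event` (empty for `"FL"`).
#' @export
parse_annotation <- function(s) {
  if (identical(s, "FL")) return(list())
  toks <- regmatches(s, gregexpr("[\u0394\u25BC]\\([^)]*\\)", s))[[1L]]
  if (!length(toks) || nchar(s) != sum(nchar(toks)) + length(toks) - 1L)
    stop("cannot parse annotation string: ", s)
  lab <- "([0-9]+|UTR5|UTR3)"
  lapply(toks, function(tk) {
    sym <- substr(tk, 1L, 1L)
    body <- sub("^.\\((.*)\\)$", "\\1", tk)
    pside <- regmatches(body, regexec(paste0("^", lab, "([pq])_([0-9]+)$"),
                                      body))[[1L]]
    if (length(pside)) {
      side <- if (pside[3L] == "p") "acceptor" else "donor"
      kind <- if (sym == "\u0394") "partial_deletion" else "partial_retention"
      return(splice_event(kind, pside[2L], side = side,
                          size_nt = as.integer(pside[4L])))
    }
    novel <- regmatches(body, regexec(paste0("^", lab, "-", lab,
                                             ",([0-9]+)$"), body))[[1L]]
    if (length(novel) && sym == "\u25BC")
      return(splice_event("novel_exon", novel[2L], novel[3L],
                          size_nt = as.integer(novel[4L])))
    rng <- regmatches(body, regexec(paste0("^", lab, "(-", lab, ")?$"),
                                    body))[[1L]]
    if (!length(rng)) stop("cannot parse annotation token: ", tk)
    first <- rng[2L]
    last <- if (nzchar(rng[4L])) rng[4L] else first
    if (sym == "\u0394") splice_event("skip", first, last)
    else splice_event("intron_retention", first, last)
  })
}

#' Reference annotation label of the cloned insert
#'
#' `"exN_exM"` for a construct carrying cloned exons N..M;
#' `"vector_only"` for a control construct without cloned exons.
#'
#' @param annotation A `reference_annotation` or `minigene_reference`.
#' @return A single string.
#' @export
annot_ref_string <- function(annotation) {
  if (inherits(annotation, "minigene_reference"))
    annotation <- annotation$annotation
  ex <- annotation$features$label[annotation$features$role == "exon"]
  if (!length(ex)) return("vector_only")
  sprintf("ex%s_ex%s", ex[1L], ex[length(ex)])
}

#' Annotate isoform models against the reference
#'
#' Runs [isoform_exons()], [classify_events()] and [format_annotation()]
#' on every model.
#'
#' @param isoforms A `mg_isoforms` collection.
#' @param reference A `minigene_reference` (or `reference_annotation`).
#' @return A `mg_annotated` list; each element carries the model, its
#'   `events`, `annot_find` and the shared `annot_ref`.
#' @export
annotate_isoforms <- function(isoforms, reference) {
  aref <- annot_ref_string(reference)
  out <- lapply(isoforms, function(m) {
    blocks <- isoform_exons(m, reference)
    ev <- classify_events(blocks, reference)
    structure(list(isoform = m, events = ev,
                   annot_find = format_annotation(ev), annot_ref = aref),
              class = "mg_annotated_isoform")
  })
  structure(out, class = "mg_annotated")
}

#' @export
print.mg_annotated <- function(x, ...) {
  cat("mg_annotated:", length(x), "isoform(s)\n")
  for (a in x)
    cat("  ", a$isoform$isoform_id, ": ", a$annot_find,
        " (total count ", sum(a$isoform$counts), ")\n", sep = "")
  invisible(x)
}

#' Tabulate splice events of annotated isoforms
#'
#' @param annotated A `mg_annotated` collection.
#' @return data.frame with one row per event (isoform_id, kind, exon
#'   labels, side, size_nt, annotation).
#' @export
events_table <- function(annotated) {
  rows <- lapply(annotated, function(a) {
    if (!length(a$events))
      return(data.frame(isoform_id = a$isoform$isoform_id, kind = "none",
                        first_exon = NA, last_exon = NA, side = "none",
                        size_nt = 0L, annotation = a$annot_find,
                        stringsAsFactors = FALSE))
    do.call(rbind, lapply(a$events, function(e)
      data.frame(isoform_id = a$isoform$isoform_id, kind = e$kind,
                 first_exon = e$first_exon, last_exon = e$last_exon,
                 side = e$side, size_nt = e$size_nt,
                 annotation = a$annot_find, stringsAsFactors = FALSE)))
  })
  do.call(rbind, rows)
}
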