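#' Construct a transcript model
#'
#' A transcript model is the unit scored by the classifier: the ordered
#' coding segments (CDS exons) of one transcript, stored in translation
#' order (5' to 3' of the mRNA), together with its identifiers, strand
#' and an optional training label.
#'
#' @param transcript_id Transcript identifier.
#' @param gene_id Gene identifier (defaults to the transcript id).
#' @param seq_id Chromosome/contig identifier shared by all segments.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of 1-based inclusive genomic
#'   coordinates, one entry per coding segment, given in translation
#'   order: for `"+"` transcripts coordinates increase, for `"-"`
#'   they decrease.
#' @param label One of `"family"`, `"non_family"`, `"unlabeled"`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id = transcript_id,
                             seq_id, strand, starts, ends,
                             label = "unlabeled") {
  stopifnot(length(starts) == length(ends), length(starts) >= 1L)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  if (!label %in% c("family", "non_family", "unlabeled"))
    stop("unknown label '", label, "' for transcript ", transcript_id)
  structure(list(
    transcript_id = as.character(transcript_id),
    gene_id       = as.character(gene_id),
    seq_id        = as.character(seq_id),
    strand        = strand,
    segments      = data.frame(start = as.integer(starts),
                               end   = as.integer(ends)),
    label         = label
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s%s, %d CDS segment(s), label=%s\n",
              x$transcript_id, x$gene_id, x$seq_id, x$strand,
              nrow(x$segments), x$label))
  invisible(x)
}

segment_lengths <- function(t) t$segments$end - t$segments$start + 1L

#' Validate a transcript model
#'
#' Checks the structural invariants a coding gene model must satisfy
#' before features can be extracted: every segment has positive length,
#' segments do not overlap, coordinates run in translation order
#' consistent with the strand, and the total coding length is a
#' multiple of 3.  Returns a report rather than raising, so broken
#' models from fragmented assemblies can be flagged and carried along.
#'
#' @param t A `transcript_model`.
#' @return A list with elements `pass` (logical) and `reasons`
#'   (character vector, empty when passing).
#' @export
validate_transcript <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  reasons <- character(0)
  seg <- t$segments
  if (any(seg$end < seg$start))
    reasons <- c(reasons, "segment with start > end (length < 1)")
  # overlap: check on the genome axis
  ord <- order(seg$start)
  if (nrow(seg) > 1L) {
    s <- seg[ord, , drop = FALSE]
    if (any(s$start[-1L] <= s$end[-nrow(s)]))
      reasons <- c(reasons, "overlap")
    # translation order must match strand
    expected <- if (t$strand == "+") seq_len(nrow(seg)) else rev(seq_len(nrow(seg)))
    if (!identical(ord, expected))
      reasons <- c(reasons, "segments not in translation order for strand")
  }
  total <- sum(pmax(segment_lengths(t), 0L))
  if (total %% 3L != 0L)
    reasons <- c(reasons, "CDS length not multiple of 3")
  list(pass = length(reasons) == 0L, reasons = reasons,
       transcript_id = t$transcript_id)
}

read_label_table <- function(path) {
  lab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("transcript_id", "label"),
                           colClasses = "character", comment.char = "#")
  # tolerate a header row
  if (nrow(lab) && identical(tolower(lab$transcript_id[1]), "transcript_id"))
    lab <- lab[-1L, , drop = FALSE]
  bad <- setdiff(unique(lab$label), c("family", "non_family"))
  if (length(bad))
    stop("unknown label value(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  stats::setNames(lab$label, lab$transcript_id)
}

# Locate the 1-based line numbers of GFF3 data rows whose start exceeds
# their end, for error messages that name the offending line.
bad_coordinate_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(data)
  if (!length(idx)) return(integer(0))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- vapply(fields, function(f) {
    length(f) >= 5L &&
      suppressWarnings(!is.na(as.numeric(f[4])) && !is.na(as.numeric(f[5]))) &&
      as.numeric(f[4]) > as.numeric(f[5])
  }, logical(1))
  idx[bad]
}

#' Read transcript models from a GFF3 annotation
#'
#' Parses CDS features (via [rtracklayer::readGFF()]), groups them by
#' transcript (the `Parent` attribute, falling back to `transcript_id`
#' or `ID`), and returns one [transcript_model()] per transcript with
#' segments sorted into translation order.  Phases are always
#' recomputed from coordinates downstream; with `strict_phase = TRUE`
#' a disagreement between the file's phase column and the recomputed
#' phase of a validating transcript is a hard error, since fragmented
#' annotations commonly carry wrong phases.
#'
#' @param path Path to a GFF3 file whose CDS rows carry
#'   transcript-identifying attributes.
#' @param label_table Optional path to a two-column TSV
#'   (transcript_id, label) with labels `family`/`non_family`;
#'   transcripts absent from the table are labeled `unlabeled`.
#' @param strict_phase Error if a validating transcript's annotated
#'   phase column disagrees with the phase recomputed from coordinates.
#' @return A list of `transcript_model` objects.
#' @export
read_gff3 <- function(path, label_table = NULL, strict_phase = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  bad <- bad_coordinate_lines(path)
  if (length(bad))
    stop("malformed coordinates (start > end) at line ", bad[1L],
         " of ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(!startsWith(raw, "#") & nzchar(raw))) return(list())

  gff <- as.data.frame(rtracklayer::readGFF(path))
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(list())

  pick_id <- function(row_parent, row_tid, row_id) {
    if (!is.na(row_parent) && nzchar(row_parent)) row_parent
    else if (!is.na(row_tid) && nzchar(row_tid)) row_tid
    else row_id
  }
  parent <- if ("Parent" %in% names(cds)) {
    vapply(cds$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(cds))
  tid_attr <- if ("transcript_id" %in% names(cds)) as.character(cds$transcript_id)
              else rep(NA_character_, nrow(cds))
  id_attr <- if ("ID" %in% names(cds)) as.character(cds$ID)
             else rep(NA_character_, nrow(cds))
  tid <- mapply(pick_id, parent, tid_attr, id_attr, USE.NAMES = FALSE)
  if (anyNA(tid))
    stop("CDS feature without Parent/transcript_id/ID attribute in ", path)

  # mRNA -> gene mapping where the file provides the hierarchy
  mrna <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  gene_of <- character(0)
  if (nrow(mrna) && "Parent" %in% names(mrna) && "ID" %in% names(mrna)) {
    gp <- vapply(mrna$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                 character(1))
    gene_of <- stats::setNames(gp, as.character(mrna$ID))
  }

  labels <- if (!is.null(label_table)) read_label_table(label_table) else character(0)

  out <- lapply(split(seq_len(nrow(cds)), tid), function(i) {
    rows <- cds[i, , drop = FALSE]
    id <- tid[i[1L]]
    if (length(unique(rows$strand)) != 1L)
      stop("conflicting strands within transcript ", id)
    if (length(unique(as.character(rows$seqid))) != 1L)
      stop("conflicting seqids within transcript ", id)
    strand <- as.character(rows$strand[1L])
    if (!strand %in% c("+", "-"))
      stop("missing/unstranded CDS for transcript ", id)
    ord <- order(rows$start, decreasing = (strand == "-"))
    rows <- rows[ord, , drop = FALSE]
    gid <- gene_of[id]
    if (is.na(gid) || !length(gid) || !nzchar(gid)) gid <- id
    lab <- if (id %in% names(labels)) unname(labels[id]) else "unlabeled"
    tm <- transcript_model(id, gid, as.character(rows$seqid[1L]), strand,
                           rows$start, rows$end, label = lab)
    if (strict_phase && validate_transcript(tm)$pass &&
        "phase" %in% names(rows) && !anyNA(rows$phase)) {
      got <- as.integer(rows$phase)
      want <- exon_phases(tm)
      if (!identical(got, want))
        stop("annotated phase column disagrees with recomputed phases ",
             "for transcript ", id, " (annotated ",
             paste(got, collapse = ","), "; recomputed ",
             paste(want, collapse = ","), ")")
    }
    tm
  })
  unname(out[unique(tid)])  # preserve file order of first appearance
}

#' Keep only the longest-CDS transcript of each gene
#'
#' Optional isoform collapse: for genes with several transcript models,
#' retains the one with the greatest total coding length (ties broken
#' by transcript id). Off by default throughout the package; each
#' transcript is otherwise scored independently.
#'
#' @param transcripts List of `transcript_model`s.
#' @return Filtered list.
#' @export
longest_cds_per_gene <- function(transcripts) {
  if (!length(transcripts)) return(transcripts)
  gid <- vapply(transcripts, `[[`, character(1), "gene_id")
  len <- vapply(transcripts, function(t) sum(segment_lengths(t)), numeric(1))
  tid <- vapply(transcripts, `[[`, character(1), "transcript_id")
  keep <- unlist(lapply(split(seq_along(transcripts), gid), function(i) {
    i[order(-len[i], tid[i])][1L]
  }), use.names = FALSE)
  transcripts[sort(keep)]
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write transcript models to GFF3
#'
#' Emits gene/mRNA/CDS rows with the CDS phase column computed from
#' cumulative coding length (see [exon_phases()]).  All transcripts
#' must pass [validate_transcript()]; the round trip
#' `read_gff3(write_gff3(x))` reproduces segments, strands and ids
#' exactly.
#'
#' @param transcripts List of `transcript_model`s.
#' @param path Output file path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(transcripts, path, source = "bicyclr") {
  for (t in transcripts) {
    v <- validate_transcript(t)
    if (!v$pass)
      stop("transcript ", t$transcript_id, " fails validation: ",
           paste(v$reasons, collapse = "; "))
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (t in transcripts) {
    seg <- t$segments
    phases <- exon_phases(t)
    gstart <- min(seg$start); gend <- max(seg$end)
    tid <- gff3_escape(t$transcript_id)
    gid <- gff3_escape(t$gene_id)
    lines <- c(
      sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              t$seq_id, source, gstart, gend, t$strand, gid),
      sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              t$seq_id, source, gstart, gend, t$strand, tid, gid)
    )
    ord <- order(seg$start)  # genomic order on disk
    lines <- c(lines, sprintf(
      "%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
      t$seq_id, source, seg$start[ord], seg$end[ord], t$strand,
      phases[ord], tid, seq_along(ord), tid))
    writeLines(lines, con)
  }
  invisible(path)
}
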