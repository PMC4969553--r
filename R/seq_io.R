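# Sequence and interval I/O. One coordinate convention everywhere: internal
# coordinates are 0-based half-open; BED is consumed as 0-based half-open and
# GFF3 is written/read as 1-based inclusive, with conversion confined to this
# file.

#' Construct a sequence record
#'
#' A `SequenceRecord` is a named DNA sequence normalized to uppercase over the
#' alphabet `{A, C, G, T, N}`. IUPAC ambiguity codes are accepted on input and
#' mapped to `N` (they never match a purity or alternation class); any other
#' character is an error.
#'
#' @param id Sequence name.
#' @param seq DNA string; lowercase (soft-masked) input is uppercased.
#' @return An object of class `SequenceRecord`: a list with elements `id`,
#'   `seq` and `length`.
#' @examples
#' sequence_record("s1", "acgt")
#' @export
sequence_record <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  seq <- chartr("RYSWKMBDHVU", "NNNNNNNNNNN", seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop(sprintf("sequence '%s': illegal character '%s' at position %d",
                 id, substr(seq, bad, bad), bad), call. = FALSE)
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "SequenceRecord")
}

#' @export
print.SequenceRecord <- function(x, ...) {
  shown <- if (x$length > 60L) paste0(substr(x$seq, 1L, 57L), "...") else x$seq
  cat(sprintf("<SequenceRecord> %s (%d bp)\n  %s\n", x$id, x$length, shown))
  invisible(x)
}

#' @export
as.character.SequenceRecord <- function(x, ...) x$seq

# Accept a SequenceRecord, a plain string, or a named string.
as_sequence_record <- function(x, id = "seq1") {
  if (inherits(x, "SequenceRecord")) return(x)
  if (is.character(x) && length(x) == 1L) {
    nm <- names(x) %||% id
    return(sequence_record(if (nzchar(nm)) nm else id, unname(x)))
  }
  stop("expected a SequenceRecord or a single DNA string", call. = FALSE)
}

as_record_list <- function(x) {
  if (inherits(x, "SequenceRecord")) return(list(x))
  if (is.list(x)) return(lapply(x, as_sequence_record))
  if (is.character(x))
    return(lapply(seq_along(x), function(i)
      as_sequence_record(x[i], id = paste0("seq", i))))
  stop("expected SequenceRecord(s)", call. = FALSE)
}

#' Read a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()]; entries keep file order, multi-line
#' sequences are concatenated, and sequences are normalized (uppercase,
#' ambiguity codes to `N`).
#'
#' @param path Path to a FASTA file.
#' @return A list of [sequence_record()] objects (empty list for an empty
#'   file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e)
               stop(sprintf("FASTA parse error in '%s': %s",
                            path, conditionMessage(e)), call. = FALSE)),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        # locate the offending line for the error message
        lines <- readLines(path, warn = FALSE)
        bad <- which(!startsWith(lines, ">") &
                       grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv[:space:]]",
                             lines))
        stop(sprintf("FASTA parse error in '%s' at line %s: illegal character",
                     path, if (length(bad)) bad[1] else "?"), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    sequence_record(ids[i], as.character(set[[i]])))
}

#' Write sequence records to FASTA
#'
#' @param records A `SequenceRecord` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_record_list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read breakpoints from a BED file
#'
#' BED (0-based half-open) records are converted to single-base point
#' positions. Unit intervals map directly; wider records are reduced to their
#' midpoint `floor((start + end) / 2)` with a warning (breakpoints are point
#' events). Labels come from column 4 when present, else `bp1`, `bp2`, ...
#'
#' @param path Path to a BED3/BED4 (or wider) file. `track`/`browser` and `#`
#'   comment lines are skipped.
#' @return A `breakpoint_set` data frame with columns `seq_id`, `pos`
#'   (0-based) and `label`.
#' @export
read_bed_points <- function(path) {
  tab <- read_bed_table(path)
  if (nrow(tab) == 0L)
    return(breakpoint_set(character(0), integer(0), character(0)))
  wide <- tab$end - tab$start > 1L
  if (any(wide))
    warning(sprintf("%d BED record(s) wider than 1 bp reduced to midpoints",
                    sum(wide)), call. = FALSE)
  pos <- as.integer(floor((tab$start + tab$end) / 2))
  label <- if (!is.null(tab$name)) tab$name else paste0("bp", seq_len(nrow(tab)))
  breakpoint_set(tab$seq_id, pos, label)
}

#' Read regions from a BED file
#'
#' @param path Path to a BED3+ file.
#' @return Data frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open).
#' @export
read_bed_regions <- function(path) {
  tab <- read_bed_table(path)
  data.frame(seq_id = tab$seq_id, start = tab$start, end = tab$end,
             stringsAsFactors = FALSE)
}

read_bed_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 lineno[which(nf < 3L)[1]]), call. = FALSE)
  first <- function(k) vapply(fields, `[[`, "", k)
  start_c <- first(2); end_c <- first(3)
  num_ok <- grepl("^[0-9]+$", start_c) & grepl("^[0-9]+$", end_c)
  if (!all(num_ok))
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 lineno[which(!num_ok)[1]]), call. = FALSE)
  start <- as.integer(start_c); end <- as.integer(end_c)
  if (any(end <= start))
    stop(sprintf("invalid BED record at line %d: end <= start",
                 lineno[which(end <= start)[1]]), call. = FALSE)
  out <- data.frame(seq_id = first(1), start = start, end = end,
                    stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$name <- first(4)
  out
}

#' Construct a breakpoint set
#'
#' @param seq_id Sequence names.
#' @param pos 0-based single-base positions.
#' @param label Optional labels (default `bp1`, `bp2`, ...).
#' @return A data frame of class `breakpoint_set`.
#' @export
breakpoint_set <- function(seq_id, pos, label = NULL) {
  if (length(seq_id) == 1L) seq_id <- rep_len(seq_id, length(pos))
  stopifnot(length(seq_id) == length(pos))
  if (length(pos) && (any(is.na(pos)) || any(pos < 0L)))
    stop("breakpoint positions must be non-negative", call. = FALSE)
  label <- label %||% (if (length(pos)) paste0("bp", seq_along(pos)) else character(0))
  structure(data.frame(seq_id = as.character(seq_id), pos = as.integer(pos),
                       label = as.character(label), stringsAsFactors = FALSE),
            class = c("breakpoint_set", "data.frame"))
}

hit_kind <- function(hits) {
  if ("arm_len" %in% names(hits)) "triplex_motif"
  else if ("score" %in% names(hits)) "Z_DNA_motif"
  else stop("unrecognized hit table", call. = FALSE)
}

#' Write motif hits to GFF3
#'
#' Converts 0-based half-open hit intervals to the 1-based inclusive GFF3
#' convention and writes through [rtracklayer::export()]. Mirror-repeat hits
#' get type `triplex_motif` with `arm_len`/`spacer_len`/`mismatches`/
#' `tract_type` attributes; Z-DNA hits get type `Z_DNA_motif` with the score
#' column plus `n_steps`/`frame_offset`. Output is ordered by (seq_id, start,
#' longer-first).
#'
#' @param hits A hit data frame from [find_mirror_repeats()] or [find_zdna()],
#'   or a list of such tables (merged into one file).
#' @param path Output path.
#' @param seq_lengths Optional named vector of sequence lengths; when given,
#'   hits extending past a sequence end are an error.
#' @return `path`, invisibly.
#' @export
write_hits_gff3 <- function(hits, path, seq_lengths = NULL) {
  if (is.data.frame(hits)) hits <- list(hits)
  grs <- lapply(hits, function(h) {
    kind <- if (nrow(h)) hit_kind(h) else "triplex_motif"
    if (!is.null(seq_lengths) && nrow(h)) {
      lim <- seq_lengths[h$seq_id]
      if (any(is.na(lim)) || any(h$end > lim) || any(h$start < 0L))
        stop("hit outside sequence bounds", call. = FALSE)
    }
    if (nrow(h) == 0L) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(h$seq_id,
                                 IRanges::IRanges(h$start + 1L, h$end))
    S4Vectors::mcols(gr)$source <- "nonbscan"
    S4Vectors::mcols(gr)$type <- kind
    if (kind == "triplex_motif") {
      S4Vectors::mcols(gr)$arm_len <- h$arm_len
      S4Vectors::mcols(gr)$spacer_len <- h$spacer_len
      S4Vectors::mcols(gr)$mismatches <- h$mismatches
      S4Vectors::mcols(gr)$tract_type <- h$tract_type
    } else {
      S4Vectors::mcols(gr)$score <- h$score
      S4Vectors::mcols(gr)$n_steps <- h$n_steps
      S4Vectors::mcols(gr)$frame_offset <- h$frame_offset
    }
    gr
  })
  gr <- suppressWarnings(do.call(c, grs))
  if (length(gr)) {
    o <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), -GenomicRanges::width(gr))
    gr <- gr[o]
    S4Vectors::mcols(gr)$ID <- sprintf("hit%05d", seq_along(gr))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read motif hits back from GFF3
#'
#' Inverse of [write_hits_gff3()] on the coordinate level: returns 0-based
#' half-open intervals with the stored attributes.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `seq_id`, `start`, `end`, `type` plus any
#'   stored attributes.
#' @export
read_hits_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  out <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    type = as.character(S4Vectors::mcols(gr)$type),
                    stringsAsFactors = FALSE)
  for (col in c("arm_len", "spacer_len", "mismatches", "n_steps", "frame_offset"))
    if (col %in% names(S4Vectors::mcols(gr)))
      out[[col]] <- as.integer(S4Vectors::mcols(gr)[[col]])
  if ("score" %in% names(S4Vectors::mcols(gr)))
    out$score <- as.numeric(S4Vectors::mcols(gr)$score)
  if ("tract_type" %in% names(S4Vectors::mcols(gr)))
    out$tract_type <- as.character(S4Vectors::mcols(gr)$tract_type)
  out
}

#' Write a hit table as TSV
#'
#' @param hits Hit data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
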