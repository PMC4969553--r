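# Z-DNA candidate search: alternating purine-pyrimidine tracts scored by
# non-overlapping dinucleotide steps. Left-handed Z-DNA propagates in
# dinucleotide repeat units (syn/anti alternation), so steps are phased
# (frame 0 or 1 within a tract) and never overlap; overlapping counting would
# double-weight every base.

#' Parameters for the Z-DNA search
#'
#' Defaults encode the standard dinucleotide weights: each GC step scores 25
#' and each GT or CA step scores 3, with a reporting threshold of 75.
#' Complement/reversal-equivalent steps score identically (CG like GC; TG and
#' AC like GT/CA) -- forced by strand symmetry. Alternating A/T steps are
#' formally purine-pyrimidine but carry no weight by default.
#'
#' @param score_gc Weight of a GC/CG step (default 25).
#' @param score_gtca Weight of a GT/TG/CA/AC step (default 3).
#' @param score_at Weight of an AT/TA step (default 0).
#' @param min_score Reporting threshold (default 75).
#' @param min_tract_len Minimum alternating-tract length scanned (default 6,
#'   the shortest fragment able to reach the default threshold).
#' @return A list of class `zdna_params`.
#' @export
zdna_params <- function(score_gc = 25, score_gtca = 3, score_at = 0,
                        min_score = 75, min_tract_len = 6L) {
  stopifnot(is.numeric(score_gc), is.numeric(score_gtca), is.numeric(score_at),
            is.numeric(min_score))
  structure(list(score_gc = score_gc, score_gtca = score_gtca,
                 score_at = score_at, min_score = min_score,
                 min_tract_len = assert_count(min_tract_len, "min_tract_len", 2L)),
            class = "zdna_params")
}

#' Find alternating purine-pyrimidine tracts
#'
#' Maximal runs in which purines (`A`/`G`) and pyrimidines (`C`/`T`) strictly
#' alternate; `N` breaks runs. Alternation is a class property -- repeat-unit
#' identity is not required (`ACGT` alternates).
#'
#' @param record A [sequence_record()] or DNA string.
#' @param min_len Minimum tract length to report (>= 2).
#' @return Data frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), sorted by start.
#' @examples
#' find_alternating_tracts("TTGCGCGCTT", min_len = 4)
#' @export
find_alternating_tracts <- function(record, min_len = 6L) {
  rec <- as_sequence_record(record)
  min_len <- assert_count(min_len, "min_len", 2L)
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (rec$length < 2L) return(empty)
  cl <- base_classes(rec$seq)
  alt <- cl[-1] != cl[-length(cl)]
  alt[is.na(alt)] <- FALSE
  r <- rle(alt)
  pair_end <- cumsum(r$lengths)
  pair_start <- pair_end - r$lengths + 1L
  keep <- r$values
  # run of consecutive alternating pairs [i, j] spans bases [i-1, j+1) 0-based
  start <- pair_start[keep] - 1L
  end <- pair_end[keep] + 1L
  ok <- (end - start) >= min_len
  data.frame(seq_id = rep_len(rec$id, sum(ok)),
             start = as.integer(start[ok]), end = as.integer(end[ok]),
             stringsAsFactors = FALSE)
}

# Per-step weights for a character matrix of step halves (vectorised).
step_weights <- function(b1, b2, params) {
  w <- numeric(length(b1))
  gc <- (b1 == "G" & b2 == "C") | (b1 == "C" & b2 == "G")
  at <- (b1 == "A" & b2 == "T") | (b1 == "T" & b2 == "A")
  w[gc] <- params$score_gc
  w[at] <- params$score_at
  w[!gc & !at] <- params$score_gtca
  w
}

score_frame <- function(ch, offset, params) {
  L <- length(ch)
  n_steps <- (L - offset) %/% 2L
  if (n_steps == 0L)
    return(list(score = 0, n_steps = 0L,
                breakdown = c(gc = 0L, gtca = 0L, at = 0L)))
  i <- offset + 2L * seq_len(n_steps) - 1L
  b1 <- ch[i]; b2 <- ch[i + 1L]
  w <- step_weights(b1, b2, params)
  gc <- sum((b1 == "G" & b2 == "C") | (b1 == "C" & b2 == "G"))
  at <- sum((b1 == "A" & b2 == "T") | (b1 == "T" & b2 == "A"))
  list(score = sum(w), n_steps = n_steps,
       breakdown = c(gc = gc, gtca = n_steps - gc - at, at = at))
}

#' Score an alternating fragment
#'
#' Partitions the fragment into non-overlapping dinucleotide steps starting at
#' offset 0 or 1 (a leading/trailing unpaired base contributes nothing), sums
#' the step weights in each frame, and returns the better frame; ties go to
#' frame 0.
#'
#' @param seq A contiguous alternating purine/pyrimidine DNA string.
#' @param params [zdna_params()].
#' @return List with `score`, `frame_offset` (0 or 1), `n_steps`, and
#'   `breakdown` (step counts named `gc`, `gtca`, `at`).
#' @examples
#' score_fragment("GC")$score      # 25
#' score_fragment("GCGCGC")$score  # 75, frame 0
#' @export
score_fragment <- function(seq, params = zdna_params()) {
  stopifnot(inherits(params, "zdna_params"))
  rec <- as_sequence_record(seq)
  cl <- base_classes(rec$seq)
  if (length(cl) == 0L)
    stop("cannot score an empty fragment", call. = FALSE)
  if (any(is.na(cl)) ||
      (length(cl) > 1L && any(cl[-1] == cl[-length(cl)])))
    stop("not an alternating purine/pyrimidine fragment", call. = FALSE)
  ch <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
  f0 <- score_frame(ch, 0L, params)
  f1 <- score_frame(ch, 1L, params)
  best <- if (f1$score > f0$score) c(f1, frame_offset = 1L)
          else c(f0, frame_offset = 0L)
  best[c("score", "frame_offset", "n_steps", "breakdown")]
}

#' Find Z-DNA candidates
#'
#' Scans every alternating purine-pyrimidine tract of at least
#' `params$min_tract_len` bp, scores it with [score_fragment()], and reports
#' the best-frame step span when the score meets `params$min_score`. Because
#' all step weights are non-negative, the maximal-scoring segment of a tract
#' in a frame is the whole tract's step span, so the default output carries
#' one hit per qualifying tract. The hit interval covers exactly the scored
#' steps (an unpaired flanking base of the tract is excluded).
#'
#' @param record A [sequence_record()], DNA string, or list of records.
#' @param params [zdna_params()].
#' @param subsegments If `TRUE`, report each frame of a tract that meets the
#'   threshold separately instead of only the best frame.
#' @return Data frame with one row per hit: `seq_id`, `start`, `end` (0-based
#'   half-open), `score`, `n_steps`, `frame_offset`, and step counts `n_gc`,
#'   `n_gtca`, `n_at`.
#' @examples
#' find_zdna("TTTTGCGCGCGCTTTT")
#' @seealso [brute_force_zdna()] for the exhaustive reference implementation.
#' @export
find_zdna <- function(record, params = zdna_params(), subsegments = FALSE) {
  stopifnot(inherits(params, "zdna_params"))
  recs <- as_record_list(record)
  if (length(recs) != 1L) {
    out <- do.call(rbind, lapply(recs, find_zdna, params = params,
                                 subsegments = subsegments))
    rownames(out) <- NULL
    return(out)
  }
  rec <- recs[[1]]
  tracts <- find_alternating_tracts(rec, min_len = params$min_tract_len)
  if (nrow(tracts) == 0L) return(empty_zdna_hits())
  ch <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
  rows <- vector("list", nrow(tracts))
  for (t in seq_len(nrow(tracts))) {
    ts <- tracts$start[t]; te <- tracts$end[t]
    sub <- ch[(ts + 1L):te]
    frames <- list(score_frame(sub, 0L, params), score_frame(sub, 1L, params))
    take <- if (subsegments) c(1L, 2L)
            else if (frames[[2]]$score > frames[[1]]$score) 2L else 1L
    hits <- lapply(take, function(fi) {
      f <- frames[[fi]]
      if (f$score < params$min_score || f$n_steps == 0L) return(NULL)
      off <- fi - 1L
      data.frame(seq_id = rec$id, start = ts + off,
                 end = ts + off + 2L * f$n_steps, score = f$score,
                 n_steps = f$n_steps, frame_offset = off,
                 n_gc = as.integer(f$breakdown[["gc"]]),
                 n_gtca = as.integer(f$breakdown[["gtca"]]),
                 n_at = as.integer(f$breakdown[["at"]]),
                 stringsAsFactors = FALSE)
    })
    rows[[t]] <- do.call(rbind, hits)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(empty_zdna_hits())
  out <- out[order(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exhaustive Z-DNA reference search
#'
#' Independently recomputes alternating tracts by literal pairwise checking,
#' scores every even-length in-tract segment directly, keeps
#' threshold-passing segments that cannot be extended by a step within their
#' tract, and reports the best (leftmost on ties) per tract. Intended as a
#' correctness oracle for [find_zdna()] on short sequences.
#'
#' @inheritParams find_zdna
#' @return Same layout as [find_zdna()].
#' @export
brute_force_zdna <- function(record, params = zdna_params()) {
  stopifnot(inherits(params, "zdna_params"))
  rec <- as_sequence_record(record)
  ch <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
  cl <- base_classes(rec$seq)
  L <- rec$length
  is_alt <- function(i, j) {         # 0-based half-open [i, j)
    idx <- (i + 1L):j
    if (any(is.na(cl[idx]))) return(FALSE)
    if (length(idx) == 1L) return(TRUE)
    all(cl[idx][-1] != cl[idx][-length(idx)])
  }
  rows <- list()
  i <- 0L
  while (i < L) {
    # find the maximal alternating tract starting at i, literally
    j <- i + 1L
    while (j < L && is_alt(i, j + 1L)) j <- j + 1L
    if (!is_alt(i, j)) { i <- i + 1L; next }
    if (j - i >= params$min_tract_len) {
      # all maximal even-length segments within [i, j): one per parity
      cands <- list()
      for (off in 0L:1L) {
        s <- i + off
        n_steps <- (j - s) %/% 2L
        if (n_steps == 0L) next
        e <- s + 2L * n_steps
        sc <- 0; gc <- 0L; at <- 0L
        for (p in seq_len(n_steps)) {
          b1 <- ch[s + 2L * p - 1L]; b2 <- ch[s + 2L * p]
          pair <- paste0(b1, b2)
          if (pair %in% c("GC", "CG")) { sc <- sc + params$score_gc; gc <- gc + 1L }
          else if (pair %in% c("AT", "TA")) { sc <- sc + params$score_at; at <- at + 1L }
          else sc <- sc + params$score_gtca
        }
        if (sc >= params$min_score)
          cands[[length(cands) + 1L]] <-
            data.frame(seq_id = rec$id, start = s, end = e, score = sc,
                       n_steps = n_steps, frame_offset = off,
                       n_gc = gc, n_gtca = n_steps - gc - at, n_at = at,
                       stringsAsFactors = FALSE)
      }
      if (length(cands)) {
        scores <- vapply(cands, function(d) d$score, numeric(1))
        rows[[length(rows) + 1L]] <- cands[[which.max(scores)]]
      }
    }
    i <- j
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_zdna_hits())
  rownames(out) <- NULL
  out
}
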