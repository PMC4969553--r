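# H-DNA (intramolecular triplex) candidate search: mirror-repeat symmetries
# inside homopurine/homopyrimidine tracts. A mirror repeat is same-strand
# reversal WITHOUT complementation (arm2 == reverse(arm1)) -- the geometry
# required for Hoogsteen third-strand pairing, and deliberately distinct from
# inverted-repeat (reverse-complement) logic.

#' Parameters for the H-DNA mirror-repeat search
#'
#' Defaults encode the standard search rules: a minimum repeat arm of 6 bp, a
#' 1-12 bp spacer between the arms, and one symmetry mismatch tolerated only
#' when the arms are at least 10 bp.
#'
#' @param min_arm Minimum arm length in bp (default 6).
#' @param min_spacer,max_spacer Spacer length bounds in bp (defaults 1 and 12).
#' @param mismatch_arm_threshold Arm length from which `max_mismatches`
#'   symmetry mismatches are tolerated (default 10); shorter arms must be
#'   perfect mirrors.
#' @param max_mismatches Mismatch budget for the whole arm pair (default 1).
#' @param require_pure_spacer If `TRUE`, the spacer must share the arms' purity
#'   class; by default spacer composition is unconstrained (the triplex third
#'   strand does not pair across the spacer).
#' @return A list of class `hdna_params`.
#' @export
hdna_params <- function(min_arm = 6L, min_spacer = 1L, max_spacer = 12L,
                        mismatch_arm_threshold = 10L, max_mismatches = 1L,
                        require_pure_spacer = FALSE) {
  p <- list(min_arm = assert_count(min_arm, "min_arm", 1L),
            min_spacer = assert_count(min_spacer, "min_spacer", 0L),
            max_spacer = assert_count(max_spacer, "max_spacer", 0L),
            mismatch_arm_threshold = assert_count(mismatch_arm_threshold,
                                                  "mismatch_arm_threshold", 1L),
            max_mismatches = assert_count(max_mismatches, "max_mismatches", 0L),
            require_pure_spacer = isTRUE(require_pure_spacer))
  if (p$max_spacer < p$min_spacer)
    stop("max_spacer must be >= min_spacer", call. = FALSE)
  structure(p, class = "hdna_params")
}

#' Find homopurine/homopyrimidine tracts
#'
#' Maximal runs in which every base is a purine (`A`/`G`) or every base is a
#' pyrimidine (`C`/`T`). `N` belongs to neither class and terminates runs.
#'
#' @param record A [sequence_record()] or DNA string.
#' @param min_len Minimum tract length to report (>= 1).
#' @return Data frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open) and `tract_type` (`"purine"`/`"pyrimidine"`), sorted by start.
#' @examples
#' find_purity_tracts("AGGAAGCTCT", min_len = 3)
#' @export
find_purity_tracts <- function(record, min_len = 6L) {
  rec <- as_sequence_record(record)
  min_len <- assert_count(min_len, "min_len", 1L)
  cl <- base_classes(rec$seq)
  if (!length(cl)) return(purity_tracts_df(character(0)))
  r <- rle(cl)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  keep <- !is.na(r$values) & r$lengths >= min_len
  purity_tracts_df(rec$id, start[keep], end[keep],
                   c("purine", "pyrimidine")[r$values[keep]])
}

purity_tracts_df <- function(seq_id, start = integer(0), end = integer(0),
                             tract_type = character(0)) {
  data.frame(seq_id = rep_len(as.character(seq_id), length(start)),
             start = as.integer(start), end = as.integer(end),
             tract_type = as.character(tract_type), stringsAsFactors = FALSE)
}

#' Find mirror-repeat (H-DNA) candidates
#'
#' Scans for mirror-repeat symmetries whose two arms are each a pure
#' homopurine or homopyrimidine run of the same class, separated by a spacer
#' of `min_spacer`-`max_spacer` bp. Mirror symmetry is same-strand reversal:
#' position `i` of arm 1 pairs with position `arm_len - 1 - i` of arm 2 without
#' complementation. One symmetry mismatch (an unequal same-class pair) is
#' tolerated when the final arm length reaches `mismatch_arm_threshold`; a
#' mismatched base must still respect the arms' purity class.
#'
#' For each spacer placement the longest admissible arm is kept, and a hit
#' whose interval is wholly contained in another hit with an arm at least as
#' long is suppressed, so nested sub-repeats of the same motif are not
#' re-reported. Output is ordered by (start ascending, arm length descending,
#' spacer length ascending).
#'
#' @param record A [sequence_record()], DNA string, or list of records.
#' @param params [hdna_params()].
#' @return Data frame with one row per hit: `seq_id`, `start`, `end` (0-based
#'   half-open, spanning arm1+spacer+arm2), `arm_len`, `spacer_len`,
#'   `mismatches`, `tract_type`, `arm1_seq`, `spacer_seq`, `arm2_seq`.
#' @examples
#' find_mirror_repeats("TTAAGGAGTGAGGAATT")
#' @seealso [brute_force_mirror_repeats()] for the exhaustive reference
#'   implementation used in validation.
#' @export
find_mirror_repeats <- function(record, params = hdna_params()) {
  stopifnot(inherits(params, "hdna_params"))
  recs <- as_record_list(record)
  if (length(recs) != 1L) {
    out <- do.call(rbind, lapply(recs, find_mirror_repeats, params = params))
    rownames(out) <- NULL
    return(out)
  }
  rec <- recs[[1]]
  if (rec$length < 2L * params$min_arm + params$min_spacer)
    return(empty_mirror_hits())
  cand <- mirror_scan_cpp(rec$seq, params$min_arm, params$min_spacer,
                          params$max_spacer, params$mismatch_arm_threshold,
                          params$max_mismatches, params$require_pure_spacer)
  finalize_mirror_hits(rec, cand$start, cand$arm_len, cand$spacer_len,
                       cand$mismatches, cand$class)
}

# Containment suppression + ordering + sequence annotation, shared by the fast
# scanner; the oracle applies the same rule with its own code.
finalize_mirror_hits <- function(rec, start, arm, spacer, mism, klass) {
  n <- length(start)
  if (n == 0L) return(empty_mirror_hits())
  end <- start + 2L * arm + spacer
  keep <- !vapply(seq_len(n), function(i) {
    inside <- start <= start[i] & end >= end[i] & arm >= arm[i]
    inside[i] <- FALSE
    any(inside)
  }, logical(1))
  start <- start[keep]; arm <- arm[keep]; spacer <- spacer[keep]
  mism <- mism[keep]; klass <- klass[keep]; end <- end[keep]
  o <- order(start, -arm, spacer)
  start <- start[o]; arm <- arm[o]; spacer <- spacer[o]
  mism <- mism[o]; klass <- klass[o]; end <- end[o]
  sub <- function(s, e) substr(rep(rec$seq, length(s)), s + 1L, e)
  data.frame(seq_id = rep_len(rec$id, length(start)),
             start = as.integer(start), end = as.integer(end),
             arm_len = as.integer(arm), spacer_len = as.integer(spacer),
             mismatches = as.integer(mism),
             tract_type = c("purine", "pyrimidine")[klass],
             arm1_seq = sub(start, start + arm),
             spacer_seq = sub(start + arm, start + arm + spacer),
             arm2_seq = sub(end - arm, end),
             stringsAsFactors = FALSE)
}

#' Exhaustive mirror-repeat reference search
#'
#' Literal enumeration of every (spacer position, spacer length, arm length)
#' triple with direct evaluation of the purity, symmetry-mismatch and
#' containment rules. Intended as an independent correctness oracle for
#' [find_mirror_repeats()] on short sequences; it is quadratic-to-cubic and
#' not meant for genome-scale input.
#'
#' @inheritParams find_mirror_repeats
#' @return Same layout as [find_mirror_repeats()].
#' @export
brute_force_mirror_repeats <- function(record, params = hdna_params()) {
  stopifnot(inherits(params, "hdna_params"))
  rec <- as_sequence_record(record)
  L <- rec$length
  if (L < 2L * params$min_arm + params$min_spacer) return(empty_mirror_hits())
  ch <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
  cl <- base_classes(rec$seq)
  starts <- integer(0); arms <- integer(0); spacers <- integer(0)
  mms <- integer(0); klass <- integer(0)
  for (c in 1:(L - 1L)) {
    for (g in params$min_spacer:params$max_spacer) {
      if (c + g >= L) break
      kmax <- min(c, L - (c + g))
      if (kmax < params$min_arm) next
      k <- seq_len(kmax)
      li <- c - k + 1L            # 1-based left arm positions, outward
      ri <- c + g + k             # 1-based right arm positions, outward
      cl_ok <- !is.na(cl[li]) & !is.na(cl[ri]) & cl[li] == cl[ri] &
        cl[li] == cl[li[1]]
      cl_ok[is.na(cl_ok)] <- FALSE
      pure_upto <- cumsum(!cl_ok) == 0L
      mm <- cumsum(ch[li] != ch[ri])
      allowed <- ifelse(k >= params$mismatch_arm_threshold,
                        params$max_mismatches, 0L)
      admissible <- pure_upto & mm <= allowed & k >= params$min_arm
      if (params$require_pure_spacer && g > 0L) {
        sp <- cl[(c + 1L):(c + g)]
        if (any(is.na(sp)) || any(sp != cl[li[1]])) admissible[] <- FALSE
      }
      if (!any(admissible)) next
      a <- max(k[admissible])
      starts <- c(starts, c - a); arms <- c(arms, a); spacers <- c(spacers, g)
      mms <- c(mms, mm[a]); klass <- c(klass, cl[li[1]])
    }
  }
  if (!length(starts)) return(empty_mirror_hits())
  # Independent containment-suppression pass (same rule, separate code).
  ends <- starts + 2L * arms + spacers
  n <- length(starts)
  suppressed <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (starts[j] <= starts[i] && ends[j] >= ends[i] && arms[j] >= arms[i]) {
        suppressed[i] <- TRUE
        break
      }
    }
  }
  finalize_mirror_hits(rec, starts[!suppressed], arms[!suppressed],
                       spacers[!suppressed], mms[!suppressed],
                       klass[!suppressed])
}
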