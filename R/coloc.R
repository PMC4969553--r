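# Co-localization of motif hits with breakpoints and permutation-based
# enrichment. Breakpoints are points; motifs are intervals; a breakpoint is
# co-localized when some motif overlaps the symmetric +/- window around it.
# The null repositions breakpoints (motif positions are fixed sequence
# properties), uniformly within user-supplied regions.

#' Parameters for co-localization analysis
#'
#' @param window Half-width of the symmetric window in bp; 100 and 200 are the
#'   conventional choices for hotspot analyses.
#' @param n_permutations Number of null permutations (default 1000).
#' @param seed Integer seed for the permutation RNG.
#' @param regions Optional data frame (`seq_id`, `start`, `end`, 0-based
#'   half-open) restricting the null to sub-regions (e.g. gene bodies); by
#'   default breakpoints are repositioned over whole sequences.
#' @return A list of class `coloc_params`.
#' @export
coloc_params <- function(window = 200L, n_permutations = 1000L, seed = 1L,
                         regions = NULL) {
  structure(list(window = assert_count(window, "window", 0L),
                 n_permutations = assert_count(n_permutations,
                                               "n_permutations", 1L),
                 seed = assert_count(seed, "seed", -2147483647L),
                 regions = regions),
            class = "coloc_params")
}

motif_intervals <- function(motifs) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(motifs)))
  motifs[, c("seq_id", "start", "end")]
}

# Merged +/- window expansions of motif intervals, per sequence.
expanded_by_seq <- function(motifs, window) {
  m <- motif_intervals(motifs)
  lapply(split(m, m$seq_id), function(d)
    merge_intervals(pmax(d$start - window, 0L), d$end + window))
}

coloc_flags <- function(seq_id, pos, expanded) {
  flags <- logical(length(pos))
  for (sid in unique(seq_id)) {
    sel <- seq_id == sid
    ex <- expanded[[sid]]
    if (!is.null(ex)) flags[sel] <- points_in_intervals(pos[sel], ex)
  }
  flags
}

#' Count breakpoints co-localized with motifs
#'
#' A breakpoint at position `p` is co-localized when some motif interval
#' overlaps `[p - window, p + window + 1)` (half-open); each breakpoint counts
#' at most once regardless of how many motifs are nearby.
#'
#' @param breakpoints A [breakpoint_set()].
#' @param motifs Data frame of motif intervals (`seq_id`, `start`, `end`,
#'   0-based half-open), e.g. a hit table.
#' @param window Window half-width in bp (>= 0).
#' @return Integer count.
#' @export
count_colocalized <- function(breakpoints, motifs, window) {
  window <- assert_count(window, "window", 0L)
  if (nrow(breakpoints) == 0L || nrow(motifs) == 0L) return(0L)
  sum(coloc_flags(breakpoints$seq_id, breakpoints$pos,
                  expanded_by_seq(motifs, window)))
}

#' Permutation test for breakpoint-motif enrichment
#'
#' Compares the observed co-localization count with a null in which every
#' breakpoint is independently repositioned uniformly within its region for
#' each permutation. The empirical p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)` and is therefore
#' never exactly zero.
#'
#' @param breakpoints A [breakpoint_set()].
#' @param motifs Motif interval data frame.
#' @param params [coloc_params()]; `params$regions` may restrict the null.
#' @param seq_lengths Named integer vector of sequence lengths, required when
#'   `params$regions` is `NULL` (whole-sequence null).
#' @return An `enrichment_result` list: `observed`, `n_breakpoints`,
#'   `null_mean`, `null_sd`, `fold_enrichment` (`NA` when the null mean is 0),
#'   `p_empirical`, `n_permutations`, `seed`, `window`.
#' @export
permutation_enrichment <- function(breakpoints, motifs, params = coloc_params(),
                                   seq_lengths = NULL) {
  stopifnot(inherits(params, "coloc_params"))
  regions <- params$regions
  if (is.null(regions)) {
    if (is.null(seq_lengths) || is.null(names(seq_lengths)))
      stop("supply `seq_lengths` (named) or `params$regions`", call. = FALSE)
    regions <- data.frame(seq_id = names(seq_lengths), start = 0L,
                          end = as.integer(seq_lengths),
                          stringsAsFactors = FALSE)
  }
  n <- nrow(breakpoints)
  if (n == 0L) stop("no breakpoints", call. = FALSE)
  # assign each breakpoint to the first region containing it
  ridx <- vapply(seq_len(n), function(i) {
    hit <- which(regions$seq_id == breakpoints$seq_id[i] &
                 regions$start <= breakpoints$pos[i] &
                 breakpoints$pos[i] < regions$end)
    if (!length(hit))
      stop(sprintf("breakpoint '%s' (%s:%d) outside all regions",
                   breakpoints$label[i], breakpoints$seq_id[i],
                   breakpoints$pos[i]), call. = FALSE)
    hit[1]
  }, integer(1))
  expanded <- expanded_by_seq(motifs, params$window)
  observed <- sum(coloc_flags(breakpoints$seq_id, breakpoints$pos, expanded))
  B <- params$n_permutations
  rs <- regions$start[ridx]; rw <- regions$end[ridx] - rs
  null_counts <- with_seed(params$seed, {
    # B x n positions drawn at once; column i belongs to breakpoint i
    pos <- matrix(rs[col(matrix(0L, B, n))] +
                    floor(runif(B * n) * rw[col(matrix(0L, B, n))]),
                  nrow = B)
    flags <- matrix(coloc_flags(rep(breakpoints$seq_id, each = B),
                                as.integer(pos), # column-major: bp varies slow
                                expanded),
                    nrow = B)
    as.integer(rowSums(flags))
  })
  structure(list(observed = as.integer(observed), n_breakpoints = n,
                 null_mean = mean(null_counts), null_sd = sd(null_counts),
                 fold_enrichment = if (mean(null_counts) > 0)
                   observed / mean(null_counts) else NA_real_,
                 p_empirical = (1 + sum(null_counts >= observed)) / (1 + B),
                 n_permutations = B, seed = params$seed,
                 window = params$window, null_counts = null_counts),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("Breakpoint-motif enrichment (+/-%d bp, %d permutations, ",
                     "seed %d)\n  observed: %d / %d breakpoints\n",
                     "  null: mean %.2f, sd %.2f\n",
                     "  fold enrichment: %s\n  empirical p: %.4g\n"),
              x$window, x$n_permutations, x$seed, x$observed, x$n_breakpoints,
              x$null_mean, x$null_sd,
              if (is.na(x$fold_enrichment)) "NA"
              else sprintf("%.2f", x$fold_enrichment),
              x$p_empirical))
  invisible(x)
}

#' Enrichment over several windows with BH correction
#'
#' Runs [permutation_enrichment()] at each window and, when more than one
#' window is analyzed jointly, adds Benjamini-Hochberg adjusted p-values.
#'
#' @inheritParams permutation_enrichment
#' @param windows Integer vector of window half-widths (e.g. `c(100, 200)`).
#' @return Data frame with one row per window (`window`, `observed`,
#'   `null_mean`, `fold_enrichment`, `p_empirical`, and `p_adjusted` when
#'   `length(windows) > 1`).
#' @export
enrichment_scan <- function(breakpoints, motifs, windows = c(100L, 200L),
                            params = coloc_params(), seq_lengths = NULL) {
  rows <- lapply(seq_along(windows), function(i) {
    p <- params
    p$window <- assert_count(windows[i], "window", 0L)
    p$seed <- params$seed + i - 1L
    r <- permutation_enrichment(breakpoints, motifs, p, seq_lengths)
    data.frame(window = p$window, observed = r$observed,
               n_breakpoints = r$n_breakpoints, null_mean = r$null_mean,
               fold_enrichment = r$fold_enrichment,
               p_empirical = r$p_empirical, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(windows) > 1L)
    out$p_adjusted <- p.adjust(out$p_empirical, method = "BH")
  out
}

#' Distance from each breakpoint to its nearest motif
#'
#' @param breakpoints A [breakpoint_set()].
#' @param motifs Motif interval data frame.
#' @return Data frame with columns `label`, `seq_id`, `pos` and `distance`:
#'   0 when the breakpoint lies inside a motif, otherwise the bp gap to the
#'   nearest motif edge, or `NA` when the sequence carries no motif.
#' @export
distance_profile <- function(breakpoints, motifs) {
  m <- if (nrow(motifs)) motif_intervals(motifs) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0))
  dist <- vapply(seq_len(nrow(breakpoints)), function(i) {
    d <- m[m$seq_id == breakpoints$seq_id[i], , drop = FALSE]
    if (nrow(d) == 0L) return(NA_real_)
    p <- breakpoints$pos[i]
    inside <- d$start <= p & p < d$end
    if (any(inside)) return(0)
    min(ifelse(p < d$start, d$start - p, p - (d$end - 1L)))
  }, numeric(1))
  data.frame(label = breakpoints$label, seq_id = breakpoints$seq_id,
             pos = breakpoints$pos, distance = as.integer(dist),
             stringsAsFactors = FALSE)
}
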