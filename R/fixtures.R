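# Synthetic-data generator: sequences with guard-protected planted motifs,
# breakpoints with a controllable degree of motif association, and
# binomially-sampled assay counts. Guard bases flanking each plant break
# purity (mirror repeats) or alternation (Z tracts) so the planted geometry is
# provably the maximal geometry the scanners can report -- the key to exact
# ground truth.

#' Specification of a synthetic dataset
#'
#' @param seq_len Total sequence length in bp.
#' @param gc_content Background GC fraction in (0, 1); bases are i.i.d. with
#'   `P(G) = P(C) = gc_content / 2`.
#' @param motifs List of motif descriptions, each a list with `kind` one of
#'   `"mirror_repeat"` (fields `arm`, `spacer`, optional `mismatches` and
#'   `tract_type`), `"zdna_gc"` or `"zdna_ca"` (field `n_steps`); an optional
#'   `position` fixes the 0-based start of the motif proper (guards excluded).
#'   Unpositioned motifs are spread over the sequence in order.
#' @param breakpoint_model List with `n_points`, `association` in `[0, 1]`
#'   (fraction of points placed within `window` bp of a planted motif) and
#'   `window` (default 100).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(seq_len, gc_content = 0.5, motifs = list(),
                       breakpoint_model = list(n_points = 0L, association = 0,
                                               window = 100L),
                       seed = 1L) {
  stopifnot(gc_content > 0, gc_content < 1)
  bm <- breakpoint_model
  bm$window <- bm$window %||% 100L
  if (bm$association < 0 || bm$association > 1)
    stop("association must be in [0, 1]", call. = FALSE)
  structure(list(seq_len = assert_count(seq_len, "seq_len", 1L),
                 gc_content = gc_content, motifs = motifs,
                 breakpoint_model = bm,
                 seed = assert_count(seed, "seed", -2147483647L)),
            class = "plant_spec")
}

random_background <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Build one guarded motif block. Returns the block characters, the offset of
# the motif proper within the block, and the truth row (start relative to the
# motif proper).
build_motif_block <- function(m, gc) {
  kind <- m$kind
  if (kind == "mirror_repeat") {
    arm <- assert_count(m$arm, "arm", 1L)
    spacer <- assert_count(m$spacer, "spacer", 1L)
    mism <- assert_count(m$mismatches %||% 0L, "mismatches", 0L)
    type <- m$tract_type %||% "purine"
    alph <- if (type == "purine") c("A", "G") else c("C", "T")
    guard <- if (type == "purine") c("T", "T") else c("A", "A")
    arm1 <- sample(alph, arm, replace = TRUE)
    arm2 <- rev(arm1)
    if (mism > 0L) {
      flip <- sample.int(arm, mism)
      arm2[flip] <- ifelse(arm2[flip] == alph[1], alph[2], alph[1])
    }
    # spacer ends must be of the opposite class to the arms: otherwise a
    # longer-arm/shorter-spacer reading of the same interval can be a valid
    # mirror by chance and would out-compete the planted geometry
    spc <- random_background(spacer, gc)
    opp <- if (type == "purine") c("C", "T") else c("A", "G")
    spc[1] <- sample(opp, 1)
    spc[spacer] <- sample(opp, 1)
    block <- c(guard, arm1, spc, arm2, guard)
    truth <- data.frame(kind = kind, start = 0L, end = 2L * arm + spacer,
                        arm_len = arm, spacer_len = spacer, mismatches = mism,
                        tract_type = type, score = NA_real_,
                        n_steps = NA_integer_, stringsAsFactors = FALSE)
    list(block = block, offset = 2L, truth = truth)
  } else if (kind %in% c("zdna_gc", "zdna_ca")) {
    n_steps <- assert_count(m$n_steps, "n_steps", 1L)
    unit <- if (kind == "zdna_gc") c("G", "C") else c("C", "A")
    # guards break alternation on both sides regardless of the background:
    # a same-class base abuts each end of the repeat
    guard_l <- if (kind == "zdna_gc") c("A", "A") else c("T", "T")
    guard_r <- if (kind == "zdna_gc") c("T", "T") else c("A", "A")
    score <- n_steps * if (kind == "zdna_gc") 25 else 3
    block <- c(guard_l, rep(unit, n_steps), guard_r)
    truth <- data.frame(kind = kind, start = 0L, end = 2L * n_steps,
                        arm_len = NA_integer_, spacer_len = NA_integer_,
                        mismatches = NA_integer_, tract_type = NA_character_,
                        score = score, n_steps = n_steps,
                        stringsAsFactors = FALSE)
    list(block = block, offset = 2L, truth = truth)
  } else stop("unknown motif kind: ", kind, call. = FALSE)
}

#' Generate a synthetic sequence with planted motifs
#'
#' Background bases are i.i.d. at the requested GC content; each planted
#' motif is flanked by guard bases that break purity/alternation so its
#' geometry is maximal and the scanners must report it at exactly the truth
#' coordinates. Generation is deterministic for a given spec (including
#' seed).
#'
#' @param spec A [plant_spec()].
#' @return List with `record` (a [sequence_record()]) and `truth` (data frame
#'   of planted motifs with 0-based half-open coordinates and geometry).
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, {
    blocks <- lapply(spec$motifs, build_motif_block, gc = spec$gc_content)
    blen <- vapply(blocks, function(b) length(b$block), integer(1))
    n <- length(blocks)
    fixed_pos <- vapply(spec$motifs, function(m)
      as.integer(m$position %||% NA_integer_), integer(1))
    if (n > 0L) {
      if (all(is.na(fixed_pos))) {
        # spread blocks over the sequence with at least 2 background bases
        # between them and at the ends
        need <- sum(blen) + 2L * (n + 1L)
        if (need > spec$seq_len)
          stop(sprintf("infeasible packing: %d bp of motifs+guards into %d bp",
                       need, spec$seq_len), call. = FALSE)
        slack <- spec$seq_len - need
        extra <- if (slack > 0L)
          tabulate(sample.int(n + 1L, slack, replace = TRUE), n + 1L)
        else rep(0L, n + 1L)
        gaps <- 2L + extra
        block_start <- as.integer(cumsum(gaps[seq_len(n)]) +
                                    c(0L, cumsum(blen))[seq_len(n)])
      } else if (all(!is.na(fixed_pos))) {
        block_start <- fixed_pos - vapply(blocks, `[[`, 0L, "offset")
        o <- order(block_start)
        if (any(block_start < 0L) ||
            any(block_start + blen > spec$seq_len) ||
            (n > 1L && any(block_start[o][-1] <
                           (block_start + blen)[o][-n])))
          stop("infeasible packing: motifs overlap or exceed bounds",
               call. = FALSE)
      } else stop("give positions for all motifs or none", call. = FALSE)
    } else block_start <- integer(0)
    ch <- random_background(spec$seq_len, spec$gc_content)
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      b <- blocks[[i]]
      s <- block_start[i]
      ch[(s + 1L):(s + length(b$block))] <- b$block
      tr <- b$truth
      tr$start <- tr$start + s + b$offset
      tr$end <- tr$end + s + b$offset
      truth_rows[[i]] <- tr
    }
    truth <- if (n) do.call(rbind, truth_rows) else
      data.frame(kind = character(0), start = integer(0), end = integer(0),
                 arm_len = integer(0), spacer_len = integer(0),
                 mismatches = integer(0), tract_type = character(0),
                 score = numeric(0), n_steps = integer(0),
                 stringsAsFactors = FALSE)
    truth$seq_id <- rep_len("sim1", nrow(truth))
    record <- sequence_record("sim1", paste(ch, collapse = ""))
    list(record = record, truth = truth[order(truth$start), , drop = FALSE])
  })
}

#' Generate breakpoints with a controlled motif association
#'
#' `round(association * n_points)` breakpoints are placed uniformly within
#' +/- `window` bp of a randomly chosen planted motif; the remainder are
#' uniform over the whole sequence.
#'
#' @param record The [sequence_record()] the points live on.
#' @param truth Truth table from [generate_sequence()].
#' @param model List with `n_points`, `association` and `window` (default
#'   100).
#' @param seed Integer seed.
#' @return A [breakpoint_set()].
#' @export
generate_breakpoints <- function(record, truth, model, seed = 1L) {
  n <- assert_count(model$n_points, "n_points", 0L)
  assoc <- model$association %||% 0
  window <- assert_count(model$window %||% 100L, "window", 0L)
  if (assoc < 0 || assoc > 1) stop("association must be in [0, 1]", call. = FALSE)
  n_assoc <- as.integer(round(assoc * n))
  if (n_assoc > 0L && nrow(truth) == 0L)
    stop("association > 0 requires planted motifs", call. = FALSE)
  L <- record$length
  with_seed(seed, {
    pos <- integer(0)
    if (n_assoc > 0L) {
      mi <- sample.int(nrow(truth), n_assoc, replace = TRUE)
      lo <- pmax(truth$start[mi] - window, 0L)
      hi <- pmin(truth$end[mi] + window, L)   # half-open upper bound
      pos <- c(pos, lo + floor(runif(n_assoc) * (hi - lo)))
    }
    if (n - n_assoc > 0L)
      pos <- c(pos, floor(runif(n - n_assoc) * L))
    breakpoint_set(rep_len(record$id, n), as.integer(pos))
  })
}

#' Generate synthetic fluctuation-assay counts
#'
#' Structure-construct FOA-resistant counts are drawn
#' `Binomial(total, base_freq * fold)` and control counts
#' `Binomial(total, base_freq)`, one pair per replicate.
#'
#' @param fold True fold induction (>= 0).
#' @param base_freq Control mutation frequency.
#' @param total Total colony count per replicate (> 0).
#' @param n_reps Number of replicates (default 1).
#' @param seed Integer seed.
#' @param strain Strain label (default `"sim"`).
#' @return An [assay_counts()] table with `2 * n_reps` rows.
#' @export
generate_assay_counts <- function(fold, base_freq, total, n_reps = 1L,
                                  seed = 1L, strain = "sim") {
  total <- assert_count(total, "total", 1L)
  n_reps <- assert_count(n_reps, "n_reps", 1L)
  if (fold < 0) stop("fold must be >= 0", call. = FALSE)
  p_s <- base_freq * fold
  if (base_freq < 0 || base_freq > 1 || p_s > 1)
    stop("invalid probabilities: need 0 <= base_freq and base_freq * fold <= 1",
         call. = FALSE)
  with_seed(seed, {
    assay_counts(strain = rep(strain, 2L * n_reps),
                 construct = rep(c("structure", "control"), each = n_reps),
                 foa_r = c(rbinom(n_reps, total, p_s),
                           rbinom(n_reps, total, base_freq)),
                 total = rep(total, 2L * n_reps),
                 replicate = rep(seq_len(n_reps), 2L))
  })
}
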