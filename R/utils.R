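# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so seeded
#' generators and permutation tests do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# Base class codes: purine (A/G) = 1L, pyrimidine (C/T) = 2L, N/other = NA.
# Vectorised over the characters of one sequence.
base_classes <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  cl <- rep(NA_integer_, length(ch))
  cl[ch %in% c("A", "G")] <- 1L
  cl[ch %in% c("C", "T")] <- 2L
  cl
}

reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Merge 0-based half-open intervals (start, end) into disjoint sorted runs.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(list(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  hi <- cummax(end)
  new_run <- c(TRUE, start[-1] > hi[-length(hi)])
  grp <- cumsum(new_run)
  list(start = as.integer(tapply(start, grp, min)),
       end   = as.integer(tapply(end, grp, max)))
}

# Membership of 0-based points in merged disjoint half-open intervals.
points_in_intervals <- function(pos, merged) {
  if (length(merged$start) == 0L) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, merged$start)
  idx > 0L & pos < merged$end[pmax(idx, 1L)]
}

empty_mirror_hits <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             arm_len = integer(0), spacer_len = integer(0),
             mismatches = integer(0), tract_type = character(0),
             arm1_seq = character(0), spacer_seq = character(0),
             arm2_seq = character(0), stringsAsFactors = FALSE)
}

empty_zdna_hits <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             score = numeric(0), n_steps = integer(0), frame_offset = integer(0),
             n_gc = integer(0), n_gtca = integer(0), n_at = integer(0),
             stringsAsFactors = FALSE)
}
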