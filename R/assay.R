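# Fluctuation-assay (YAC/FOA) statistics: mutation frequencies from colony
# counts, fold inductions of a structure-forming construct over its B-form
# control, and per-strain screen summaries. Frequencies, not rates: no
# Luria-Delbruck m-estimation is attempted here.

#' Construct an assay-count table
#'
#' One row per plating: a strain, a construct (`"structure"` for the
#' non-B-forming insert, `"control"` for the B-form control), the number of
#' FOA-resistant colonies, the total colony count, and a replicate index.
#' `foa_r > total` is permitted (selective and titer plates take different
#' volumes); `total` must be positive.
#'
#' @param strain,construct,foa_r,total,replicate Vectors of equal length
#'   (replicate defaults to `1`).
#' @return A data frame of class `assay_counts`.
#' @export
assay_counts <- function(strain, construct, foa_r, total,
                         replicate = 1L) {
  d <- data.frame(strain = as.character(strain),
                  construct = as.character(construct),
                  foa_r = as.integer(foa_r), total = as.integer(total),
                  replicate = as.integer(rep_len(replicate, length(strain))),
                  stringsAsFactors = FALSE)
  if (!all(d$construct %in% c("structure", "control")))
    stop("construct must be 'structure' or 'control'", call. = FALSE)
  if (any(is.na(d$foa_r)) || any(d$foa_r < 0L))
    stop("foa_r must be >= 0", call. = FALSE)
  if (any(is.na(d$total)) || any(d$total <= 0L))
    stop("total colony count must be > 0", call. = FALSE)
  structure(d, class = c("assay_counts", "data.frame"))
}

#' Read assay counts from TSV
#'
#' Expects columns `strain`, `construct`, `foa_r`, `total` and optionally
#' `replicate`.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return An [assay_counts()] data frame.
#' @export
read_assay_counts <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("strain", "construct", "foa_r", "total")
  if (!all(need %in% names(d)))
    stop("assay TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  assay_counts(d$strain, d$construct, d$foa_r, d$total,
               d$replicate %||% seq_len(nrow(d)))
}

#' Mutation frequency from colony counts
#'
#' The mutation frequency is the number of FOA-resistant colonies divided by
#' the total colony count, optionally scaled by a dilution factor to account
#' for differential plating volumes.
#'
#' @param foa_r FOA-resistant colony count(s), or an [assay_counts()] table.
#' @param total Total colony count(s) (> 0); ignored when `foa_r` is a table.
#' @param dilution_factor Multiplicative plating correction (> 0, default 1).
#' @return Numeric frequency vector.
#' @examples
#' mutation_frequency(50, 1e6)  # 5e-05
#' @export
mutation_frequency <- function(foa_r, total = NULL, dilution_factor = 1) {
  if (is.data.frame(foa_r)) {
    total <- foa_r$total
    foa_r <- foa_r$foa_r
  }
  if (!is.numeric(dilution_factor) || any(dilution_factor <= 0))
    stop("dilution_factor must be > 0", call. = FALSE)
  if (any(is.na(total)) || any(total <= 0))
    stop("total colony count must be > 0", call. = FALSE)
  if (any(foa_r < 0)) stop("foa_r must be >= 0", call. = FALSE)
  foa_r / total * dilution_factor
}

#' Fold induction of mutation frequency
#'
#' Ratio of the mean per-replicate mutation frequency of the structure-forming
#' construct to that of the control. With paired replicates (equal counts and
#' matching replicate indices) the standard error is that of the per-replicate
#' structure:control ratios; otherwise it is propagated from the two group
#' standard errors by the delta method. Single-replicate inputs yield `NA`
#' standard errors, and a zero control mean yields an `NA` fold with a
#' warning.
#'
#' @param structure_reps,control_reps [assay_counts()] rows (or compatible
#'   data frames) for one strain each; strains must match.
#' @param dilution_factor Passed to [mutation_frequency()].
#' @return One-row data frame: `strain`, `freq_structure`, `freq_control`,
#'   `fold`, `se`, `n_replicates`.
#' @examples
#' s <- assay_counts("WT", "structure", 94, 1e6)
#' c <- assay_counts("WT", "control", 10, 1e6)
#' fold_induction(s, c)$fold  # 9.4
#' @export
fold_induction <- function(structure_reps, control_reps, dilution_factor = 1) {
  if (length(unique(c(structure_reps$strain, control_reps$strain))) != 1L)
    stop("structure and control replicates must come from one strain",
         call. = FALSE)
  if (nrow(structure_reps) == 0L || nrow(control_reps) == 0L)
    stop("need at least one replicate of each construct", call. = FALSE)
  fs <- mutation_frequency(structure_reps$foa_r, structure_reps$total,
                           dilution_factor)
  fc <- mutation_frequency(control_reps$foa_r, control_reps$total,
                           dilution_factor)
  ms <- mean(fs); mc <- mean(fc)
  ns <- length(fs); nc <- length(fc)
  paired <- ns == nc && ns > 1L &&
    !is.null(structure_reps$replicate) && !is.null(control_reps$replicate) &&
    identical(sort(structure_reps$replicate), sort(control_reps$replicate))
  if (mc == 0) {
    warning("control mutation frequency is 0; fold induction undefined",
            call. = FALSE)
    fold <- NA_real_; se <- NA_real_
  } else {
    fold <- ms / mc
    if (paired) {
      os <- order(structure_reps$replicate); oc <- order(control_reps$replicate)
      ratio <- ifelse(fc[oc] > 0, fs[os] / fc[oc], NA_real_)
      se <- stats::sd(ratio) / sqrt(sum(!is.na(ratio)))
    } else if (ns > 1L && nc > 1L) {
      se_s <- stats::sd(fs) / sqrt(ns)
      se_c <- stats::sd(fc) / sqrt(nc)
      se <- sqrt(se_s^2 / mc^2 + ms^2 * se_c^2 / mc^4)
    } else se <- NA_real_
  }
  data.frame(strain = structure_reps$strain[1], freq_structure = ms,
             freq_control = mc, fold = fold, se = se,
             n_replicates = ns, stringsAsFactors = FALSE)
}

#' Summarize a mutability screen
#'
#' One row per strain with its fold induction and standard error, sorted by
#' fold descending. A strain missing either construct is reported as an `NA`
#' row with a warning rather than dropped.
#'
#' @param all_counts An [assay_counts()] table covering one or more strains.
#' @param dilution_factor Passed to [mutation_frequency()].
#' @return Data frame with columns `strain`, `freq_structure`, `freq_control`,
#'   `fold`, `se`, `n_replicates`.
#' @export
summarize_screen <- function(all_counts, dilution_factor = 1) {
  rows <- lapply(split(all_counts, all_counts$strain), function(d) {
    s <- d[d$construct == "structure", , drop = FALSE]
    ctl <- d[d$construct == "control", , drop = FALSE]
    if (nrow(s) == 0L || nrow(ctl) == 0L) {
      warning(sprintf("strain '%s' is missing a construct; NA row emitted",
                      d$strain[1]), call. = FALSE)
      return(data.frame(strain = d$strain[1], freq_structure = NA_real_,
                        freq_control = NA_real_, fold = NA_real_,
                        se = NA_real_, n_replicates = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    fold_induction(s, ctl, dilution_factor)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fold, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
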