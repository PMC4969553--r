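# Shared helpers: fixture sequences are built in code, never stored.

random_seq <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

# Guard-flanked mirror repeat with purine arms: TT | arm1 | spacer | arm2 | TT.
# arm2 is reverse(arm1) with `flip_pairs` symmetry pairs flipped A<->G
# (pair 1 = innermost, adjacent to the spacer).
mirror_construct <- function(arm1, spacer = "T", flip_pairs = integer(0)) {
  a1 <- strsplit(arm1, "")[[1]]
  a2 <- rev(a1)
  if (length(flip_pairs)) {
    # pair k compares a1[len - k + 1] with a2[k]; flip on the arm2 side
    a2[flip_pairs] <- ifelse(a2[flip_pairs] == "A", "G", "A")
  }
  paste0("TT", arm1, spacer, paste(a2, collapse = ""), "TT")
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
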