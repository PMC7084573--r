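# Independent naive oracles, kept free of the package's code paths.

# per-position, per-strand log-odds recomputation with explicit loops
oracle_scan <- function(seq, mat, bg = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  L <- nrow(mat)
  chars <- strsplit(toupper(seq), "")[[1]]
  out <- list()
  for (off in 0:(length(chars) - L)) {
    win <- chars[(off + 1):(off + L)]
    if (any(!win %in% bases)) next
    sp <- sum(sapply(seq_len(L), function(j)
      log2(mat[j, match(win[j], bases)] / bg[match(win[j], bases)])))
    rc <- rev(unname(comp[win]))
    sm <- sum(sapply(seq_len(L), function(j)
      log2(mat[j, match(rc[j], bases)] / bg[match(rc[j], bases)])))
    out[[length(out) + 1]] <- data.frame(offset = off, plus = sp, minus = sm)
  }
  do.call(rbind, out)
}
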