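# Internal helpers shared across modules.

# Union-find over 1..n with path compression; used for merging overlapping
# peaks/regions across two sets into connected components.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union_all <- function(n, from, to) {
  parent <- uf_new(n)
  for (k in seq_along(from)) {
    ra <- uf_find(parent, from[k])
    rb <- uf_find(parent, to[k])
    if (ra != rb) parent[rb] <- ra
  }
  # flatten so every element points at its root
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

# Plain TSV writers with fixed formatting so reruns are byte-identical.
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

write_matrix_tsv <- function(mat, path, rowname_header = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- rowname_header
  write_tsv_file(df, path)
}

num_fmt <- function(x, digits = 6) {
  ifelse(is.finite(x), formatC(x, digits = digits, format = "g"), as.character(x))
}
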