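# in-code fixtures shared across test files

# write a small GPR-like spot table; nets = f - b per channel
write_spot_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

spot_df <- function(n = 3, f5 = 500, b5 = 100, f3 = 400, b3 = 100,
                    flag = 100L) {
  data.frame(ID = sprintf("s%d", seq_len(n)),
             Name = sprintf("g%d", seq_len(n)),
             F635 = rep_len(f5, n), B635 = rep_len(b5, n),
             F532 = rep_len(f3, n), B532 = rep_len(b3, n),
             Flags = rep_len(flag, n))
}

# deterministic three-class matrix with given per-class means per gene
means_matrix <- function(mc, me, mi, n_per_class = c(4, 3, 3)) {
  vals <- cbind(
    matrix(rep(mc, n_per_class[1]), ncol = n_per_class[1]),
    matrix(rep(me, n_per_class[2]), ncol = n_per_class[2]),
    matrix(rep(mi, n_per_class[3]), ncol = n_per_class[3]))
  rownames(vals) <- sprintf("g%04d", seq_along(mc))
  expression_matrix(vals, rep(c("control", "E2", "E2_ICI"), n_per_class))
}

# IUPAC consensus -> regex character classes
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste0(vapply(strsplit(toupper(pattern), "")[[1]], function(ch) {
    opts <- map[[ch]]
    if (nchar(opts) == 1) opts else paste0("[", opts, "]")
  }, ""), collapse = "")
}

# brute-force overlapping-match motif scan over both strands with
# palindrome deduplication; returns 0-based positions per strand
regex_scan_oracle <- function(seq_char, pattern) {
  rex <- paste0("(?=", iupac_regex(pattern), ")")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pattern)))
  find0 <- function(p) {
    m <- gregexpr(paste0("(?=", iupac_regex(p), ")"), seq_char,
                  perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  fwd <- find0(pattern)
  if (toupper(pattern) == rc) {
    data.frame(pos = fwd, strand = rep("+", length(fwd)))
  } else {
    rev <- find0(rc)
    out <- rbind(data.frame(pos = fwd, strand = rep("+", length(fwd))),
                 data.frame(pos = rev, strand = rep("-", length(rev))))
    out[order(out$pos, out$strand), , drop = FALSE]
  }
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# hypergeometric upper tail P(X >= k) by direct summation over the support
hyper_tail_oracle <- function(k, m, n, kk) {
  # m white, n black, draw kk; sum dhyper over x = k..min(kk, m)
  if (k <= 0) return(1)
  hi <- min(kk, m)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(x) stats::dhyper(x, m, n, kk), 1.0))
}
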