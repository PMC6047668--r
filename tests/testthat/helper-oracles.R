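# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths: naive loops and
# direct substring scans only.

# Naive k-mer counter: substring scan with step 1, skipping k-mers that
# contain a non-ACGT letter; optionally also counts reverse complements.
naive_kmer_counts <- function(windows, k, both_strands = FALSE) {
  counts <- setNames(integer(4^k), lex_kmers(k))
  rc1 <- function(v) vapply(v, function(s)
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1L]]), collapse = "")),
    "", USE.NAMES = FALSE)
  add <- function(counts, kms) {
    tab <- table(kms)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    counts
  }
  for (w in windows) {
    w <- toupper(w)
    n <- nchar(w)
    if (n < k) next
    kms <- substring(w, seq_len(n - k + 1L), k:n)
    kms <- kms[!grepl("[^ACGT]", kms)]
    counts <- add(counts, kms)
    if (both_strands) counts <- add(counts, rc1(kms))
  }
  counts
}

# Per-base brute-force signal oracle: expand bins to bases, average over
# the interval, scale to signal-per-million.
naive_signal <- function(track, contig, start, end) {
  per_base <- rep(track$values[[contig]], each = track$bin_size)
  mean(per_base[(start + 1L):end]) * 1e6 / track$library_total
}

# Random A/C/G/T sequence (uniform), independent of generate_genome.
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Count matches of the degenerate 6-mer W W C G W W in a sequence by a
# direct regex scan at every offset.
naive_wwcgww_hits <- function(s) {
  n <- nchar(s)
  if (n < 6L) return(0L)
  sum(vapply(seq_len(n - 5L), function(i)
    grepl("^[AT][AT]CG[AT][AT]$", substr(s, i, i + 5L)), TRUE))
}

# Build a ranked catalog directly from a named count vector (must cover
# all 4^k k-mers), bypassing count_kmers.
catalog_from_counts <- function(counts, k, strand_mode = "forward") {
  rank_catalog(structure(
    list(k = as.integer(k), counts = counts, ranks = NULL,
         display_order = NULL, n_windows = NA_integer_,
         strand_mode = strand_mode),
    class = "kmer_catalog"))
}

# All 4^k k-mers in lexicographic order without Biostrings.
lex_kmers <- function(k) {
  sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1,
                                                              drop = FALSE],
             1L, paste, collapse = ""))
}
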