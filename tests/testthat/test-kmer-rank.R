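# Window extraction, k-mer catalogs, degenerate classes and the
# rank-enrichment statistics.

test_that("extract_windows returns 2*half_width+1 bases and drops edges", {
  genome <- c(c1 = random_seq(1000), c2 = random_seq(600))
  centers <- data.frame(contig = c("c1", "c1", "c2", "c1"),
                        center = c(400L, 10L, 300L, 990L))
  expect_warning(w <- extract_windows(genome, centers, 250L), "dropped")
  expect_identical(length(w), 2L)
  expect_true(all(nchar(w) == 501L))
  # window content equals the direct substring (0-based inclusive bounds)
  expect_identical(w[[1L]], substr(genome[["c1"]], 151, 651))
  expect_identical(w[[2L]], substr(genome[["c2"]], 51, 551))
  expect_error(extract_windows(genome, data.frame(contig = "cX",
                                                  center = 1L), 250L),
               "unknown contig")
})

test_that("count_kmers matches the frozen hand-counted example", {
  cat4 <- count_kmers("ACGTACGT", 4, "forward")
  expect_identical(length(cat4$counts), 256L)
  expect_identical(cat4$counts[["ACGT"]], 2L)
  expect_identical(cat4$counts[["CGTA"]], 1L)
  expect_identical(cat4$counts[["GTAC"]], 1L)
  expect_identical(cat4$counts[["TACG"]], 1L)
  expect_identical(sum(cat4$counts), 5L)

  expect_identical(length(count_kmers("ACGTACGT", 6)$counts), 4096L)
  expect_error(count_kmers(c("ACG", "TT"), 6), "larger than every window")
})

test_that("count_kmers agrees with the naive scan oracle, both modes", {
  set.seed(17)
  for (k in c(4L, 6L)) {
    wins <- replicate(25, random_seq(sample(40:80, 1)))
    # sprinkle ambiguous letters into a few windows
    wins[1] <- sub("A", "N", wins[1])
    wins[2] <- paste0("NN", wins[2])
    fwd <- count_kmers(wins, k, "forward")
    expect_identical(fwd$counts, naive_kmer_counts(wins, k, FALSE))
    both <- count_kmers(wins, k, "both")
    expect_identical(both$counts, naive_kmer_counts(wins, k, TRUE))
    # reverse-complement symmetry and doubled total
    expect_identical(unname(both$counts[revcomp(names(both$counts))]),
                     unname(both$counts))
    expect_identical(sum(both$counts), 2L * sum(fwd$counts))
  }
})

test_that("rank_catalog produces midranks with conserved rank sum", {
  # frozen midrank example: two k-mers tied at the top, the rest at zero
  counts <- setNames(integer(256), lex_kmers(4))
  counts[c("AAAA", "CCCC")] <- 5L
  cat4 <- catalog_from_counts(counts, 4L)
  expect_identical(unname(cat4$ranks[c("AAAA", "CCCC")]), c(1.5, 1.5))
  expect_identical(unname(cat4$ranks[["GGGG"]]), (3 + 256) / 2)
  expect_equal(sum(cat4$ranks), 256 * 257 / 2)
  # display order: count descending, lexicographic tie-break
  expect_identical(cat4$display_order[1:3], c("AAAA", "CCCC", "AAAC"))

  # all-distinct counts: ranks are a permutation of 1..4^k
  counts2 <- setNames(seq_len(256), lex_kmers(4))
  cat2 <- catalog_from_counts(counts2, 4L)
  expect_setequal(cat2$ranks, as.numeric(1:256))
  expect_identical(cat2$display_order[1L], names(which.max(counts2)))

  # rank-sum conservation on random tied catalogs
  set.seed(5)
  for (i in 1:5) {
    counts3 <- setNames(rpois(256, 3), lex_kmers(4))
    expect_equal(sum(catalog_from_counts(counts3, 4L)$ranks), 256 * 257 / 2)
  }
})

test_that("expand_pattern covers IUPAC strings, rules and unions", {
  expect_identical(length(expand_pattern("WWCGWW")$members), 16L)
  expect_identical(expand_pattern("ACGT")$members, "ACGT")
  expect_error(expand_pattern("WWNGWW"), "unsupported IUPAC")

  # brute-force composition oracle: >= 5 S among all 4096 6-mers
  all6 <- lex_kmers(6)
  n_s <- vapply(strsplit(all6, ""), function(b) sum(b %in% c("C", "G")), 0)
  gc_rich <- expand_pattern("SSSSSS or five S and one W")
  expect_identical(length(gc_rich$members), 448L)
  expect_setequal(gc_rich$members, all6[n_s >= 5])
  w_rich <- expand_pattern("WWWWWW or five W and one S")
  expect_setequal(w_rich$members, all6[n_s <= 1])
  # digit form of the same rule
  expect_setequal(expand_pattern("5 S and 1 W")$members, all6[n_s == 5])

  # WWCGWW's reverse-complement pattern is itself: members closed under RC
  wwcgww <- expand_pattern("WWCGWW")
  expect_setequal(revcomp(wwcgww$members), wwcgww$members)
})

test_that("class_rank_ks reproduces closed-form D on constructed catalogs", {
  # evenly spaced ranks (entire catalog as the class): D = 1/4^k, no
  # direction
  counts <- setNames(seq_len(256), lex_kmers(4))
  cat4 <- catalog_from_counts(counts, 4L)
  all_cls <- structure(list(name = "all", members = lex_kmers(4),
                            definition = "all", k = 4L),
                       class = "degenerate_class")
  res <- class_rank_ks(cat4, all_cls)
  expect_equal(res$ks_statistic, 1 / 256, tolerance = 1e-12)
  expect_identical(res$direction, "none")

  # all 64 W-only 6-mers planted at ranks 1..64 of 4096:
  # D = 1 - 64/4096, p below the reporting floor
  set.seed(61)
  w6 <- expand_pattern("WWWWWW")
  counts6 <- setNames(integer(4096), lex_kmers(6))
  counts6[w6$members] <- 1000L + seq_len(64)    # distinct top counts
  counts6[setdiff(lex_kmers(6), w6$members)] <-
    sample(seq_len(900), 4096 - 64, replace = TRUE)
  cat6 <- catalog_from_counts(counts6, 6L)
  res6 <- class_rank_ks(cat6, w6)
  expect_equal(res6$ks_statistic, 1 - 64 / 4096, tolerance = 1e-9)
  expect_identical(res6$p_value, 1e-15)
  expect_identical(res6$direction, "upward")

  # cross-check D against the textbook one-sample KS routine
  x <- cat6$ranks[w6$members] / 4096
  ref <- suppressWarnings(stats::ks.test(x, "punif"))
  expect_equal(res6$ks_statistic, unname(ref$statistic), tolerance = 1e-12)

  expect_error(class_rank_ks(count_kmers("ACGTACGT", 4), w6), "not ranked")
})

test_that("asymptotic KS p-values track stats::ks.test away from ties", {
  set.seed(41)
  for (n in c(30, 64, 200)) {
    x <- runif(n)
    mine <- ks_uniform(x)
    ref <- stats::ks.test(x, "punif")
    expect_equal(mine$D, unname(ref$statistic), tolerance = 1e-12)
    # asymptotic vs exact p: close for moderate n and p
    if (ref$p.value > 1e-6)
      expect_lt(abs(log(mine$p) - log(ref$p.value)), 0.35)
  }
  # two-sample D against stats::ks.test
  x <- runif(80); y <- runif(50)
  m2 <- ks_two_sample(x, y)
  r2 <- stats::ks.test(x, y)
  expect_equal(m2$D, unname(r2$statistic), tolerance = 1e-12)
})

test_that("compare_class detects planted rank shifts between catalogs", {
  set.seed(71)
  w6 <- expand_pattern("WWWWWW")
  other <- setdiff(lex_kmers(6), w6$members)
  top <- setNames(integer(4096), lex_kmers(6))
  top[w6$members] <- 4096L + seq_len(64)
  top[other] <- sample(seq_len(4000), length(other), replace = TRUE)
  bottom <- setNames(integer(4096), lex_kmers(6))
  bottom[w6$members] <- 0L
  bottom[other] <- 100L + sample(seq_len(4000), length(other),
                                 replace = TRUE)
  cat_top <- catalog_from_counts(top, 6L)
  cat_bottom <- catalog_from_counts(bottom, 6L)

  # identical catalogs: D = 0, p = 1
  same <- compare_class(cat_top, cat_top, cls = w6)
  expect_identical(same$ks_statistic, 0)
  expect_identical(same$p_value, 1)

  # top in a, bottom in b: the class sinks (downward), p at the floor
  shift <- compare_class(cat_top, cat_bottom, cls = w6)
  expect_identical(shift$direction, "downward")
  expect_identical(shift$p_value, 1e-15)
  # closed-form two-sample D: completely separated rank sets
  expect_equal(shift$ks_statistic, 1, tolerance = 1e-12)

  # class_vs_class: identical classes give D = 0, p = 1
  self <- compare_class(cat_top, cls = w6, cls2 = w6,
                        mode = "class_vs_class")
  expect_identical(self$ks_statistic, 0)
  expect_identical(self$p_value, 1)
  # planted class vs a background class within the top catalog: upward
  bg <- structure(list(name = "bg", members = other[1:64],
                       definition = "bg", k = 6L),
                  class = "degenerate_class")
  vs <- compare_class(cat_top, cls = w6, cls2 = bg, mode = "class_vs_class")
  expect_identical(vs$direction, "upward")

  cat4 <- catalog_from_counts(setNames(seq_len(256), lex_kmers(4)), 4L)
  expect_error(compare_class(cat_top, cat4, cls = w6), "different k")
})

test_that("top_summary computes GC mean and SE of the display top-n", {
  counts <- setNames(integer(4096), lex_kmers(6))
  counts["GCGCGC"] <- 10L
  counts["ATATAT"] <- 9L
  cat6 <- catalog_from_counts(counts, 6L)
  ts <- top_summary(cat6, 2)
  expect_identical(ts$kmers, c("GCGCGC", "ATATAT"))
  expect_equal(ts$gc_mean, 50)
  expect_equal(ts$gc_se, 50)  # sd(c(100, 0))/sqrt(2)

  # degenerate top: all W-only k-mers -> GC 0 +/- 0
  counts2 <- setNames(integer(4096), lex_kmers(6))
  counts2[expand_pattern("WWWWWW")$members] <- 100L + seq_len(64)
  ts2 <- top_summary(catalog_from_counts(counts2, 6L), 10)
  expect_equal(ts2$gc_mean, 0)
  expect_equal(ts2$gc_se, 0)

  expect_identical(top_summary(cat6, 1)$gc_se, 0)
  expect_error(top_summary(cat6, 5000), "between 1 and")
})

test_that("best_class_rank equals a linear scan of the display order", {
  set.seed(13)
  counts <- setNames(sample.int(500, 4096, replace = TRUE), lex_kmers(6))
  cat6 <- catalog_from_counts(counts, 6L)
  for (pat in c("WWCGWW", "SSSSSS", "WWWWWW")) {
    cls <- expand_pattern(pat)
    scan <- min(which(cat6$display_order %in% cls$members))
    expect_identical(best_class_rank(cat6, cls), scan)
  }
  # class containing the overall most frequent k-mer is rank 1
  top1 <- cat6$display_order[1L]
  cls1 <- structure(list(name = "t", members = top1, definition = "t",
                         k = 6L), class = "degenerate_class")
  expect_identical(best_class_rank(cat6, cls1), 1L)
})

test_that("count conservation holds against the oracle total", {
  set.seed(23)
  wins <- replicate(10, random_seq(60))
  wins[3] <- sub("G", "N", wins[3])
  for (k in c(4L, 6L)) {
    fwd <- count_kmers(wins, k, "forward")
    expect_identical(sum(fwd$counts), sum(naive_kmer_counts(wins, k, FALSE)))
  }
})
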