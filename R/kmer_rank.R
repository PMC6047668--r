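# Core analysis: exhaustive k-mer frequency catalogs over peak-center
# windows, degenerate W/S sequence classes, and Kolmogorov-Smirnov
# rank-enrichment tests.

#' Extract fixed windows around region centers
#'
#' Each window covers positions `center - half_width .. center + half_width`
#' (0-based, inclusive), i.e. `2 * half_width + 1` bases with the center
#' base included.  Centers whose window would cross a contig boundary are
#' dropped with a warning; the order of the survivors is preserved.
#'
#' @param genome Named character vector, contig -> sequence (as returned by
#'   [read_fasta()] or [generate_genome()]).
#' @param centers data.frame with columns `contig` and `center` (0-based).
#' @param half_width Window half-width in bases (> 0).
#' @return Character vector of window sequences.
#' @export
extract_windows <- function(genome, centers, half_width = 250L) {
  stopifnot(half_width > 0)
  unknown <- setdiff(unique(centers$contig), names(genome))
  if (length(unknown))
    stop("unknown contig(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  lens <- nchar(genome)[centers$contig]
  ok <- centers$center - half_width >= 0 &
    centers$center + half_width <= lens - 1L
  if (any(!ok))
    warning(sum(!ok), " window(s) crossing a contig boundary dropped",
            call. = FALSE)
  kept <- centers[ok, , drop = FALSE]
  vapply(seq_len(nrow(kept)), function(i) {
    substr(genome[[kept$contig[i]]],
           kept$center[i] - half_width + 1L,
           kept$center[i] + half_width + 1L)
  }, "")
}

#' Count all 4^k k-mers over a set of windows
#'
#' Overlapping k-mers are counted with step 1.  k-mers containing a
#' non-ACGT letter are skipped.  In `strand_mode = "both"` every position
#' additionally contributes its reverse-complement k-mer, so
#' `counts[x] == counts[revcomp(x)]` and the total doubles.  The catalog is
#' complete: all 4^k k-mers are present, zero counts included.
#'
#' @param windows Character vector of window sequences.
#' @param k k-mer length (>= 1).
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @return An object of class `kmer_catalog` with fields `k`, `counts`
#'   (named over all 4^k k-mers in lexicographic order), `ranks` (`NULL`
#'   until [rank_catalog()]), `display_order`, `n_windows`, `strand_mode`.
#' @export
count_kmers <- function(windows, k, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(k >= 1L, k <= 12L)
  windows <- toupper(as.character(windows))
  if (length(windows) > 0L && all(nchar(windows) < k))
    stop("k is larger than every window", call. = FALSE)
  if (length(windows) == 0L) {
    counts <- setNames(integer(4^k),
                       Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))
  } else {
    m <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(windows), width = k, step = 1L)
    counts <- as.integer(colSums(m))
    names(counts) <- colnames(m)
  }
  if (strand_mode == "both") {
    rc <- revcomp(names(counts))
    counts <- counts + as.integer(counts[rc])  # names of first operand kept
  }
  structure(list(k = as.integer(k), counts = counts, ranks = NULL,
                 display_order = NULL, n_windows = length(windows),
                 strand_mode = strand_mode),
            class = "kmer_catalog")
}

#' Reverse complement of DNA strings (A/C/G/T/W/S preserved)
#'
#' @param x Character vector.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTWS", "TGCAWS",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

#' @export
print.kmer_catalog <- function(x, ...) {
  cat("kmer_catalog: k =", x$k, "|", length(x$counts), "k-mers |",
      "total count", sum(x$counts), "|", x$n_windows, "window(s) |",
      x$strand_mode, "strand mode |",
      if (is.null(x$ranks)) "unranked" else "ranked", "\n")
  invisible(x)
}

#' Rank a k-mer catalog by frequency of appearance
#'
#' Statistical ranks are midranks over descending counts (the most frequent
#' k-mer has rank about 1, the least frequent about 4^k; tied counts share
#' the average of the positions they span), so the rank sum is always
#' `4^k (4^k + 1) / 2`.  `display_order` is the total order used for
#' listings: count descending with lexicographic tie-break.
#'
#' @param catalog A [count_kmers()] result.
#' @return The catalog with `ranks` and `display_order` filled in.
#' @export
rank_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "kmer_catalog"))
  catalog$ranks <- rank(-catalog$counts, ties.method = "average")
  names(catalog$ranks) <- names(catalog$counts)
  catalog$display_order <- names(catalog$counts)[
    order(-catalog$counts, names(catalog$counts))]
  catalog
}

# number words accepted in compositional rules
.num_words <- c(one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
                seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11,
                twelve = 12)

.parse_count_word <- function(w) {
  w <- tolower(w)
  if (w %in% names(.num_words)) return(.num_words[[w]])
  n <- suppressWarnings(as.integer(w))
  if (is.na(n)) stop("cannot parse count '", w, "' in rule", call. = FALSE)
  n
}

# Expand one IUPAC pattern over {A,C,G,T,W,S} into concrete k-mers.
.expand_iupac <- function(pattern) {
  letters <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  sets <- lapply(letters, function(ch) switch(
    ch,
    A = "A", C = "C", G = "G", T = "T",
    W = c("A", "T"), S = c("C", "G"),
    stop("unsupported IUPAC letter '", ch, "' in pattern", call. = FALSE)))
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

# Expand a compositional rule "<m> S and <n> W" (order-free) at length k.
.expand_composition <- function(n_s, n_w) {
  k <- n_s + n_w
  w_pos <- if (n_w == 0L) list(integer(0)) else
    asplit(combn(k, n_w), 2L)
  out <- character(0)
  for (pos in w_pos) {
    template <- rep("S", k)
    template[pos] <- "W"
    out <- c(out, .expand_iupac(paste(template, collapse = "")))
  }
  out
}

#' Expand an IUPAC pattern or compositional rule into a degenerate class
#'
#' Accepts patterns over `A C G T W S` (W = A or T, S = C or G),
#' compositional rules of the form `"five S and one W"` (digits or number
#' words), and unions of either joined by `" or "` — e.g.
#' `"SSSSSS or five S and one W"`, the GC-rich class of the 6-mer analysis.
#'
#' @param pattern Pattern / rule string.
#' @param name Optional class name; defaults to the pattern string.
#' @return An object of class `degenerate_class` with fields `name`,
#'   `members` (sorted unique k-mers), `definition`, `k`.
#' @export
#' @examples
#' length(expand_pattern("WWCGWW")$members)                    # 16
#' length(expand_pattern("SSSSSS or five S and one W")$members) # 448
expand_pattern <- function(pattern, name = pattern) {
  parts <- strsplit(pattern, " or ", fixed = TRUE)[[1L]]
  members <- character(0)
  for (part in parts) {
    part <- trimws(part)
    rule <- regmatches(part, regexec(
      "^([A-Za-z0-9]+) ([WS]) and ([A-Za-z0-9]+) ([WS])$", part))[[1L]]
    if (length(rule) == 5L) {
      counts <- setNames(c(.parse_count_word(rule[2L]),
                           .parse_count_word(rule[4L])),
                         c(rule[3L], rule[5L]))
      if (!setequal(names(counts), c("S", "W")))
        stop("compositional rule must mention S and W once each",
             call. = FALSE)
      members <- c(members,
                   .expand_composition(counts[["S"]], counts[["W"]]))
    } else {
      members <- c(members, .expand_iupac(part))
    }
  }
  members <- sort(unique(members))
  ks <- unique(nchar(members))
  if (length(ks) != 1L)
    stop("pattern parts expand to different k-mer lengths", call. = FALSE)
  structure(list(name = name, members = members, definition = pattern,
                 k = ks),
            class = "degenerate_class")
}

#' @export
print.degenerate_class <- function(x, ...) {
  cat("degenerate_class '", x$name, "': ", length(x$members), " ", x$k,
      "-mers (", x$definition, ")\n", sep = "")
  invisible(x)
}

# normalized ranks of class members in a ranked catalog
.class_norm_ranks <- function(catalog, cls) {
  if (is.null(catalog$ranks))
    stop("catalog is not ranked; call rank_catalog() first", call. = FALSE)
  if (length(cls$members) == 0L) stop("empty class", call. = FALSE)
  if (cls$k != catalog$k)
    stop("class k does not match catalog k", call. = FALSE)
  catalog$ranks[cls$members] / length(catalog$counts)
}

.direction <- function(mean_class, mean_ref, eps = 1e-12) {
  if (mean_class < mean_ref - eps) "upward"
  else if (mean_class > mean_ref + eps) "downward"
  else "none"
}

rank_enrichment_result <- function(class_name, n_members, D, p, direction,
                                   mode) {
  structure(list(class_name = class_name, n_members = n_members,
                 ks_statistic = D, p_value = floor_p(p),
                 direction = direction, mode = mode),
            class = "rank_enrichment")
}

#' @export
print.rank_enrichment <- function(x, ...) {
  cat(sprintf("rank_enrichment [%s] '%s': n = %d, D = %.4g, P %s %.3g, %s\n",
              x$mode, x$class_name, x$n_members, x$ks_statistic,
              if (x$p_value <= P_FLOOR) "<" else "=",
              if (x$p_value <= P_FLOOR) P_FLOOR else x$p_value,
              x$direction))
  invisible(x)
}

#' One-sample KS rank-enrichment test of a class against its catalog
#'
#' The class members' ranks, normalized by 4^k, are compared with the
#' uniform distribution on (0, 1] by a one-sample Kolmogorov-Smirnov test.
#' A class crowding the top of the frequency ranking has small normalized
#' ranks ("upward" enrichment); one crowding the bottom is "downward".  The
#' p-value comes from the asymptotic Kolmogorov distribution and is floored
#' at 1e-15 for reporting.  Direction compares the class's mean normalized
#' rank with the catalog-wide mean.
#'
#' @param catalog A ranked [kmer_catalog][count_kmers()].
#' @param cls A [degenerate_class][expand_pattern()].
#' @return A `rank_enrichment` object: `class_name`, `n_members`,
#'   `ks_statistic`, `p_value`, `direction`, `mode = "class_vs_catalog"`.
#' @export
class_rank_ks <- function(catalog, cls) {
  x <- .class_norm_ranks(catalog, cls)
  ks <- ks_uniform(x)
  ref <- mean(catalog$ranks) / length(catalog$counts)
  rank_enrichment_result(cls$name, length(x), ks$D, ks$p,
                         .direction(mean(x), ref), "class_vs_catalog")
}

#' Two-sample KS comparisons of rank distributions
#'
#' Two modes:
#' \describe{
#'   \item{`between_catalogs`}{Compares one class's normalized ranks in
#'     catalog `a` versus catalog `b` (e.g. two treatments).  `direction`
#'     describes the change from `a` to `b`: `"upward"` if the class rises
#'     in the ranking (smaller mean normalized rank in `b`), `"downward"`
#'     if it sinks.}
#'   \item{`class_vs_class`}{Compares the ranks of `cls` versus `cls2`
#'     within catalog `a`.  `direction` is `"upward"` if `cls` sits higher
#'     (smaller mean normalized rank) than `cls2`.}
#' }
#'
#' @param catalog_a Ranked catalog.
#' @param catalog_b Second ranked catalog (`between_catalogs` mode only).
#' @param cls A [degenerate_class][expand_pattern()].
#' @param cls2 Second class (`class_vs_class` mode only).
#' @param mode `"between_catalogs"` or `"class_vs_class"`.
#' @return A `rank_enrichment` object.
#' @export
compare_class <- function(catalog_a, catalog_b = NULL, cls, cls2 = NULL,
                          mode = c("between_catalogs", "class_vs_class")) {
  mode <- match.arg(mode)
  if (mode == "between_catalogs") {
    if (is.null(catalog_b)) stop("catalog_b required", call. = FALSE)
    if (catalog_a$k != catalog_b$k)
      stop("catalogs have different k", call. = FALSE)
    xa <- .class_norm_ranks(catalog_a, cls)
    xb <- .class_norm_ranks(catalog_b, cls)
    ks <- ks_two_sample(xa, xb)
    dir <- .direction(mean(xb), mean(xa))  # change a -> b
    rank_enrichment_result(cls$name, length(xa), ks$D, ks$p, dir, mode)
  } else {
    if (is.null(cls2)) stop("cls2 required", call. = FALSE)
    if (cls$k != cls2$k) stop("classes have different k", call. = FALSE)
    xa <- .class_norm_ranks(catalog_a, cls)
    xb <- .class_norm_ranks(catalog_a, cls2)
    ks <- ks_two_sample(xa, xb)
    dir <- .direction(mean(xa), mean(xb))
    rank_enrichment_result(paste(cls$name, "vs", cls2$name),
                           length(xa), ks$D, ks$p, dir, mode)
  }
}

#' Summary of the top-ranked k-mers
#'
#' Lists the first `n` k-mers in display order (count descending,
#' lexicographic tie-break) together with the mean and standard error of
#' their per-k-mer GC percentages (GC% of a k-mer is
#' `100 * (#G + #C) / k`).  With `n = 1` the standard error is reported
#' as 0.
#'
#' @param catalog A ranked catalog.
#' @param n Number of top k-mers (1 <= n <= 4^k).
#' @return List of class `top_summary`: `top_n`, `kmers`, `gc_mean`,
#'   `gc_se` (percent).
#' @export
top_summary <- function(catalog, n) {
  stopifnot(inherits(catalog, "kmer_catalog"))
  if (is.null(catalog$display_order))
    stop("catalog is not ranked; call rank_catalog() first", call. = FALSE)
  if (n < 1L || n > length(catalog$counts))
    stop("n must be between 1 and 4^k", call. = FALSE)
  kmers <- catalog$display_order[seq_len(n)]
  gc <- 100 * vapply(strsplit(kmers, "", fixed = TRUE),
                     function(b) mean(b %in% c("G", "C")), 0)
  se <- if (n == 1L) 0 else sd(gc) / sqrt(n)
  structure(list(top_n = as.integer(n), kmers = kmers,
                 gc_mean = mean(gc), gc_se = se),
            class = "top_summary")
}

#' @export
print.top_summary <- function(x, ...) {
  cat(sprintf("top %d k-mers: %s\nGC%% = %.1f +/- %.1f (mean +/- SE)\n",
              x$top_n, paste(x$kmers, collapse = " "), x$gc_mean, x$gc_se))
  invisible(x)
}

#' Best (smallest) display rank of a class
#'
#' The minimum display position over class members — the "top rank" a
#' degenerate class reaches in the frequency listing.
#'
#' @param catalog A ranked catalog.
#' @param cls A [degenerate_class][expand_pattern()].
#' @return Integer display rank (1 = most frequent k-mer overall).
#' @export
best_class_rank <- function(catalog, cls) {
  if (is.null(catalog$display_order))
    stop("catalog is not ranked; call rank_catalog() first", call. = FALSE)
  if (length(cls$members) == 0L) stop("empty class", call. = FALSE)
  min(match(cls$members, catalog$display_order))
}
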