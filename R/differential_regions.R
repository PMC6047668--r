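# Binned coverage tracks, fold-change region calling, and
# promoter/enhancer/other classification.

#' Construct a binned coverage track
#'
#' A coverage track holds, per contig, one non-negative signal value per
#' fixed-width bin.  `library_total` (the summed raw bin signal over all
#' contigs) is the normalization denominator used by [quantify_signal()].
#'
#' @param values Named list, contig -> numeric vector of per-bin values.
#' @param bin_size Bin width in bases.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, bin_size = 25L) {
  stopifnot(is.list(values), bin_size >= 1L)
  if (length(values) > 0L && is.null(names(values)))
    stop("contig vectors must be named", call. = FALSE)
  vals <- unlist(values, use.names = FALSE)
  if (length(vals) && (anyNA(vals) || any(vals < 0)))
    stop("coverage values must be non-negative", call. = FALSE)
  structure(list(values = values,
                 bin_size = as.integer(bin_size),
                 library_total = sum(vals)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$values), "contig(s), bin size",
      x$bin_size, "bp, library total", format(x$library_total), "\n")
  invisible(x)
}

# Normalize raw bin values to signal-per-million of the library total.
normalized_values <- function(track, contig) {
  v <- track$values[[contig]]
  if (is.null(v)) stop("unknown contig: ", contig, call. = FALSE)
  if (track$library_total == 0) return(v)
  v * 1e6 / track$library_total
}

#' Mean normalized signal over an interval
#'
#' Returns the length-weighted mean bin value over the 0-based half-open
#' interval `[start, end)`, scaled to signal-per-million of the track's
#' library total.  Bins partially overlapping the interval contribute in
#' proportion to the overlap length.
#'
#' @param track A [coverage_track()].
#' @param contig Contig name.
#' @param start,end 0-based half-open interval bounds.
#' @return A single normalized density value.
#' @export
quantify_signal <- function(track, contig, start, end) {
  stopifnot(inherits(track, "coverage_track"))
  v <- track$values[[contig]]
  if (is.null(v)) stop("unknown contig: ", contig, call. = FALSE)
  bs <- track$bin_size
  if (start < 0 || end > length(v) * bs || start >= end)
    stop("interval outside track bounds", call. = FALSE)
  b0 <- start %/% bs
  b1 <- (end - 1L) %/% bs
  bins <- (b0:b1)
  ov <- pmin(end, (bins + 1) * bs) - pmax(start, bins * bs)
  raw <- sum(v[bins + 1L] * ov) / sum(ov)
  if (track$library_total == 0) return(0)
  raw * 1e6 / track$library_total
}

#' Detect contiguous high-signal runs in a track
#'
#' Finds maximal runs of bins whose normalized signal exceeds `min_signal`,
#' merges runs separated by less than `merge_distance` bases, and reports
#' each run with its center: the midpoint of the leftmost maximal bin.
#'
#' @param track A [coverage_track()].
#' @param min_signal Threshold on the normalized (signal-per-million) bin
#'   value; must be positive.
#' @param merge_distance Runs closer than this many bases are merged.
#' @return data.frame with columns `contig`, `start`, `end`, `center`.
#' @export
detect_peaks <- function(track, min_signal, merge_distance = 0L) {
  stopifnot(inherits(track, "coverage_track"), min_signal > 0)
  bs <- track$bin_size
  out <- list()
  for (ct in names(track$values)) {
    nv <- normalized_values(track, ct)
    above <- nv > min_signal
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(first = starts[r$values], last = ends[r$values])
    # merge runs whose gap is smaller than merge_distance
    if (nrow(runs) > 1L) {
      keep <- runs[1L, , drop = FALSE]
      for (i in 2L:nrow(runs)) {
        gap <- (runs$first[i] - 1L - keep$last[nrow(keep)]) * bs
        if (gap < merge_distance) {
          keep$last[nrow(keep)] <- runs$last[i]
        } else keep <- rbind(keep, runs[i, ])
      }
      runs <- keep
    }
    centers <- vapply(seq_len(nrow(runs)), function(i) {
      idx <- runs$first[i]:runs$last[i]
      apex <- idx[which.max(nv[idx])]          # leftmost maximum on ties
      as.integer((apex - 1L) * bs + bs %/% 2L)
    }, 0L)
    out[[ct]] <- data.frame(contig = ct,
                            start = (runs$first - 1L) * bs,
                            end = runs$last * bs,
                            center = centers)
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), center = integer()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Analysis parameter set
#'
#' Bundles the tunable thresholds of the pipeline: the primary fold-change
#' threshold for calling activated regions (default 3: regions must show
#' *more than* 3-fold increase), a secondary threshold for the weaker
#' stratification (default 1.5), the half-width of the sequence window
#' around region centers (default 250 bp), the k-mer lengths catalogued
#' (default 4 and 6), the number of top-ranked k-mers summarized (default
#' 10), the maximum TSS distance for promoter classification (default
#' 2 kb), the pseudocount added to normalized signals before forming fold
#' changes (default 1 signal-per-million), and the strand mode for k-mer
#' counting.
#'
#' @param fold_threshold Primary fold-change threshold (strict inequality).
#' @param secondary_fold_threshold Secondary, weaker threshold.
#' @param half_width Window half-width around region centers, bases.
#' @param kmer_lengths Integer vector of k-mer lengths, each in 1..12.
#' @param top_n Number of top-ranked k-mers to summarize.
#' @param promoter_tss_distance Max |center - TSS| for promoters, bases.
#' @param pseudocount Added to both signals before the fold ratio.
#' @param strand_mode `"both"` (count each window and its reverse
#'   complement) or `"forward"`.
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(fold_threshold = 3,
                            secondary_fold_threshold = 1.5,
                            half_width = 250L,
                            kmer_lengths = c(4L, 6L),
                            top_n = 10L,
                            promoter_tss_distance = 2000L,
                            pseudocount = 1,
                            strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(fold_threshold > 1, half_width > 0,
            all(kmer_lengths >= 1L), all(kmer_lengths <= 12L),
            top_n >= 1L, promoter_tss_distance >= 0, pseudocount >= 0)
  structure(list(fold_threshold = fold_threshold,
                 secondary_fold_threshold = secondary_fold_threshold,
                 half_width = as.integer(half_width),
                 kmer_lengths = as.integer(kmer_lengths),
                 top_n = as.integer(top_n),
                 promoter_tss_distance = as.integer(promoter_tss_distance),
                 pseudocount = pseudocount,
                 strand_mode = strand_mode),
            class = "analysis_params")
}

#' Call regions with increased signal between two conditions
#'
#' For each candidate interval the treated and control tracks are
#' quantified with [quantify_signal()], the fold change
#' `(treated + pseudocount) / (control + pseudocount)` is formed, and
#' exactly the candidates with fold change strictly greater than
#' `fold_threshold` are returned, sorted by descending fold change.
#'
#' @param treated,control [coverage_track()]s sharing bin size and contigs.
#' @param candidates data.frame of candidate intervals with columns
#'   `contig`, `start`, `end` and optionally `center` (defaults to the
#'   interval midpoint).
#' @param mark Mark name recorded in the output (e.g. `"H3K27ac"`).
#' @param params An [analysis_params()].
#' @param fold_threshold Threshold override; defaults to
#'   `params$fold_threshold`. Pass `params$secondary_fold_threshold` for
#'   the weaker stratification.
#' @return data.frame with columns `contig`, `start`, `end`, `center`,
#'   `mark`, `signal_treated`, `signal_control`, `fold_change`, `state`
#'   (`NA` until [classify_regions()] assigns one).
#' @export
call_increased_regions <- function(treated, control, candidates, mark,
                                   params = analysis_params(),
                                   fold_threshold = params$fold_threshold) {
  stopifnot(inherits(treated, "coverage_track"),
            inherits(control, "coverage_track"))
  if (treated$bin_size != control$bin_size)
    stop("bin size mismatch between tracks", call. = FALSE)
  if (!setequal(names(treated$values), names(control$values)))
    stop("contig mismatch between tracks", call. = FALSE)
  n <- nrow(candidates)
  center <- if ("center" %in% names(candidates)) candidates$center else
    (candidates$start + candidates$end) %/% 2L
  st <- vapply(seq_len(n), function(i) quantify_signal(
    treated, candidates$contig[i], candidates$start[i], candidates$end[i]), 0)
  sc <- vapply(seq_len(n), function(i) quantify_signal(
    control, candidates$contig[i], candidates$start[i], candidates$end[i]), 0)
  fold <- (st + params$pseudocount) / (sc + params$pseudocount)
  out <- data.frame(contig = candidates$contig, start = candidates$start,
                    end = candidates$end, center = center,
                    mark = mark, signal_treated = st, signal_control = sc,
                    fold_change = fold, state = NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[fold > fold_threshold, , drop = FALSE]
  out <- out[order(-out$fold_change), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify differential regions as promoter, enhancer or other
#'
#' A region is a `PROMOTER` when its H3K4me3 signal exceeds
#' `mark_threshold` and its center lies within
#' `params$promoter_tss_distance` of the nearest TSS; otherwise an
#' `ENHANCER` when H3K4me2 exceeds the threshold while H3K4me3 does not;
#' otherwise `OTHER`.  The default `mark_threshold` is twice the
#' genome-wide median normalized bin value of the corresponding track.
#'
#' @param regions data.frame as returned by [call_increased_regions()].
#' @param tss data.frame with columns `contig`, `pos` (0-based TSS
#'   positions); must be non-empty.
#' @param h3k4me2,h3k4me3 [coverage_track()]s of the two marks.
#' @param params An [analysis_params()].
#' @param mark_threshold Normalized-density threshold for mark positivity;
#'   a single value applied to both marks, or `NULL` for the per-track
#'   default.
#' @return `regions` with the `state` column filled in.
#' @export
classify_regions <- function(regions, tss, h3k4me2, h3k4me3,
                             params = analysis_params(),
                             mark_threshold = NULL) {
  if (nrow(tss) == 0L) stop("empty TSS list", call. = FALSE)
  track_threshold <- function(track) {
    v <- unlist(lapply(names(track$values), normalized_values,
                       track = track), use.names = FALSE)
    2 * median(v)
  }
  thr2 <- mark_threshold %||% track_threshold(h3k4me2)
  thr3 <- mark_threshold %||% track_threshold(h3k4me3)
  if (thr2 <= 0 || thr3 <= 0)
    stop("mark thresholds must be positive", call. = FALSE)
  state <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s2 <- quantify_signal(h3k4me2, regions$contig[i],
                          regions$start[i], regions$end[i])
    s3 <- quantify_signal(h3k4me3, regions$contig[i],
                          regions$start[i], regions$end[i])
    tss_ct <- tss$pos[tss$contig == regions$contig[i]]
    d_tss <- if (length(tss_ct)) min(abs(tss_ct - regions$center[i])) else Inf
    state[i] <- if (s3 > thr3 && d_tss <= params$promoter_tss_distance) {
      "PROMOTER"
    } else if (s2 > thr2 && s3 <= thr3) {
      "ENHANCER"
    } else "OTHER"
  }
  regions$state <- state
  regions
}
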