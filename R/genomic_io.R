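# Readers and writers for the plain-text formats the pipeline touches.
# Coordinates are 0-based half-open (BED convention) everywhere, both on
# disk and in memory.  Readers reject malformed records rather than
# repairing them; every writer produces files its matching reader parses
# back to equal values.

#' Read a FASTA file
#'
#' Sequences are upper-cased on input.  Contigs containing IUPAC letters
#' other than A/C/G/T are kept verbatim but flagged in the `"ambiguous"`
#' attribute (a named logical vector).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per contig, with an
#'   `"ambiguous"` attribute.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' write_fasta(c(chr1 = "acgtACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) stop("duplicate contig names in FASTA", call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  attr(seqs, "ambiguous") <- setNames(grepl("[^ACGT]", seqs), nm)
  seqs
}

#' Write sequences as FASTA (60-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Accepts 3 to 6 columns (contig, start, end, name, score, strand).
#' Lines starting with `#`, `track` or `browser` are skipped.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand` (missing trailing columns filled with defaults).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || ncol < 3L)
    stop("ragged or short BED records", call. = FALSE)
  get_col <- function(i) vapply(fields, `[`, "", i)
  out <- data.frame(
    contig = get_col(1L),
    start  = suppressWarnings(as.integer(get_col(2L))),
    end    = suppressWarnings(as.integer(get_col(3L))),
    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end))
    stop("non-integer BED coordinates", call. = FALSE)
  if (any(out$start < 0L)) stop("negative BED start", call. = FALSE)
  if (any(out$start >= out$end))
    stop("BED interval with start >= end", call. = FALSE)
  out$name   <- if (ncol >= 4L) get_col(4L) else "."
  out$score  <- if (ncol >= 5L) as.numeric(get_col(5L)) else 0
  out$strand <- if (ncol >= 6L) get_col(6L) else "."
  out
}

#' Write genomic intervals as BED6
#'
#' @param intervals data.frame with at least `contig`, `start`, `end`;
#'   optional `name`, `score`, `strand`.
#' @param path Output path.
#' @param comment Optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, comment = NULL) {
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    stop("BED interval with start >= end", call. = FALSE)
  df <- data.frame(
    contig = intervals$contig,
    start  = format(intervals$start, scientific = FALSE, trim = TRUE),
    end    = format(intervals$end, scientific = FALSE, trim = TRUE),
    name   = intervals$name %||% ".",
    score  = intervals$score %||% 0,
    strand = intervals$strand %||% ".")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file into a binned track
#'
#' Source intervals are re-binned to a fixed `bin_size` by length-weighted
#' averaging; positions not covered by any interval count as zero signal.
#' Overlapping source intervals and negative values are rejected.
#'
#' @param path Path to a 4-column bedGraph file (contig, start, end, value).
#' @param bin_size Width of the fixed bins, in bases.
#' @param contigs Optional named integer vector of contig lengths; needed to
#'   size all-zero contigs (e.g. when the file is empty) and to pad the
#'   track beyond the last covered base.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, bin_size = 25L, contigs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  recs <- if (length(lines) == 0L) {
    data.frame(contig = character(), start = integer(), end = integer(),
               value = numeric())
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 4L))
      stop("bedGraph records must have 4 columns", call. = FALSE)
    data.frame(
      contig = vapply(fields, `[`, "", 1L),
      start  = as.integer(vapply(fields, `[`, "", 2L)),
      end    = as.integer(vapply(fields, `[`, "", 3L)),
      value  = as.numeric(vapply(fields, `[`, "", 4L)),
      stringsAsFactors = FALSE)
  }
  if (anyNA(recs$start) || anyNA(recs$end) || anyNA(recs$value))
    stop("malformed bedGraph record", call. = FALSE)
  if (any(recs$value < 0)) stop("negative bedGraph value", call. = FALSE)
  if (any(recs$start >= recs$end))
    stop("bedGraph interval with start >= end", call. = FALSE)

  contig_names <- union(names(contigs), unique(recs$contig))
  values <- list()
  for (ct in contig_names) {
    sub <- recs[recs$contig == ct, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping bedGraph intervals on ", ct, call. = FALSE)
    declared <- if (!is.null(contigs) && ct %in% names(contigs))
      contigs[[ct]] else 0L
    len <- max(declared, if (nrow(sub)) max(sub$end) else 0L)
    n_bins <- ceiling(len / bin_size)
    v <- numeric(n_bins)
    for (r in seq_len(nrow(sub))) {
      b0 <- sub$start[r] %/% bin_size
      b1 <- (sub$end[r] - 1L) %/% bin_size
      for (b in b0:b1) {
        ov <- min(sub$end[r], (b + 1L) * bin_size) -
          max(sub$start[r], b * bin_size)
        v[b + 1L] <- v[b + 1L] + sub$value[r] * ov / bin_size
      }
    }
    values[[ct]] <- v
  }
  coverage_track(values, bin_size)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent bins with equal values are merged into single intervals, so a
#' file written here and re-read with [read_bedgraph()] at the same
#' `bin_size` reproduces the track exactly.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @param comment Optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, comment = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  bs <- track$bin_size
  for (ct in names(track$values)) {
    v <- track$values[[ct]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths) * bs
    starts <- ends - r$lengths * bs
    writeLines(sprintf("%s\t%d\t%d\t%s", ct, starts, ends,
                       format(r$values, scientific = FALSE, trim = TRUE,
                              digits = 15)), con)
  }
  invisible(path)
}

#' Read / write a two-condition expression table
#'
#' Tab-separated, header `gene  control  treated`, FPKM-like non-negative
#' values, unique gene identifiers.
#'
#' @param path File path.
#' @return data.frame with columns `gene`, `control`, `treated`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!identical(names(df)[1:3], c("gene", "control", "treated")))
    stop("expression table must have header gene/control/treated",
         call. = FALSE)
  if (anyDuplicated(df$gene)) stop("duplicate gene ids", call. = FALSE)
  if (any(df$control < 0) || any(df$treated < 0))
    stop("negative expression value", call. = FALSE)
  df[, c("gene", "control", "treated")]
}

#' @rdname read_expression
#' @param table data.frame with columns `gene`, `control`, `treated`.
#' @param comment Optional character vector written as leading `#` lines.
#' @export
write_expression <- function(table, path, comment = NULL) {
  stopifnot(all(c("gene", "control", "treated") %in% names(table)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(table[, c("gene", "control", "treated")], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
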