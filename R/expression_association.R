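# Nearest-gene assignment of activated regions and the paired
# expression-shift test.

#' Assign each region to the gene with the nearest TSS
#'
#' Distance is `|TSS - center|` on the region's contig.  Ties are broken
#' toward the smaller TSS coordinate, then toward the lexicographically
#' smaller gene id.  Regions on a contig with no TSS are assigned `NA`
#' with a warning.  The assignment is independent of input region order.
#'
#' @param regions data.frame with columns `contig` and `center`.
#' @param tss data.frame with columns `contig`, `pos` (0-based TSS
#'   position) and `gene`; must be non-empty.
#' @return `regions` with columns `gene` and `tss_distance` appended.
#' @export
nearest_gene <- function(regions, tss) {
  if (nrow(tss) == 0L) stop("empty TSS list", call. = FALSE)
  # order TSSs so that the first hit at minimal distance follows the
  # tie-break rule: smaller coordinate, then lexicographic gene id
  tss <- tss[order(tss$contig, tss$pos, tss$gene), , drop = FALSE]
  gene <- rep(NA_character_, nrow(regions))
  dist <- rep(NA_real_, nrow(regions))
  for (ct in unique(regions$contig)) {
    ridx <- which(regions$contig == ct)
    sub <- tss[tss$contig == ct, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no TSS on contig ", ct, "; regions left unassigned",
              call. = FALSE)
      next
    }
    pos <- sub$pos
    for (i in ridx) {
      cen <- regions$center[i]
      j <- findInterval(cen, pos)            # pos[j] <= cen < pos[j+1]
      cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(pos)))
      d <- abs(pos[cand] - cen)
      best_d <- min(d)
      # all TSSs at the minimal distance (handles co-located TSSs)
      hits <- which(abs(pos - cen) == best_d)
      gene[i] <- sub$gene[hits[1L]]          # sub is sorted by pos, gene
      dist[i] <- best_d
    }
  }
  regions$gene <- gene
  regions$tss_distance <- dist
  regions
}

#' Paired expression-shift test for a gene set
#'
#' Tests whether a gene set's expression shifts between conditions with a
#' paired two-sided Student's t-test on
#' `d_g = log2(treated + 1) - log2(control + 1)`.  If all differences are
#' identical (zero variance) the result is flagged degenerate with
#' `p = 1`.
#'
#' @param gene_set Character vector of gene ids (>= 2, all present in
#'   `table`).
#' @param table Expression data.frame with columns `gene`, `control`,
#'   `treated`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List of class `shift_test`: `n_genes`, `mean_log2_shift`,
#'   `t_statistic`, `p_value`, `degenerate`, `transform`, `alternative`.
#' @export
expression_shift_test <- function(gene_set, table,
                                  alternative = c("two.sided", "greater",
                                                  "less")) {
  alternative <- match.arg(alternative)
  gene_set <- unique(gene_set)
  if (length(gene_set) < 2L)
    stop("gene_set must contain at least 2 genes", call. = FALSE)
  missing_ids <- setdiff(gene_set, table$gene)
  if (length(missing_ids))
    stop("gene id(s) not in expression table: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  sub <- table[match(gene_set, table$gene), , drop = FALSE]
  d <- log2(sub$treated + 1) - log2(sub$control + 1)
  degenerate <- sd(d) == 0
  if (degenerate) {
    t_stat <- NA_real_
    p <- 1
  } else {
    fit <- t.test(d, alternative = alternative)
    t_stat <- unname(fit$statistic)
    p <- fit$p.value
  }
  structure(list(n_genes = length(d), mean_log2_shift = mean(d),
                 t_statistic = t_stat, p_value = p, degenerate = degenerate,
                 transform = "paired t on log2(x + 1) differences",
                 alternative = alternative),
            class = "shift_test")
}

#' @export
print.shift_test <- function(x, ...) {
  cat(sprintf(
    "shift_test: n = %d genes, mean log2 shift = %.3f, t = %s, P = %.3g%s\n",
    x$n_genes, x$mean_log2_shift,
    if (is.na(x$t_statistic)) "NA" else sprintf("%.3f", x$t_statistic),
    x$p_value, if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}
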