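# Synthetic-data generators: toy genome, planted composition windows,
# three-mark two-condition coverage, gene annotation, and expression
# tables.  Every generator is a pure function of its arguments including
# the seed, so identical configurations reproduce identical outputs.

#' Simulation configuration
#'
#' Bundles the parameters of a full synthetic dataset.  The defaults define
#' the standard validation conditions used throughout the package: a 200 kb
#' genome at GC fraction 0.5, 50 genes, 5 planted peaks per composition
#' class at 4-fold enrichment (comfortably above the 3-fold calling
#' threshold), +-250 bp flanks, baseline signal 100 with 5% coefficient of
#' variation, 25 bp bins.
#'
#' @param genome_length Genome length in bases.
#' @param gc_fraction Genome-wide GC fraction in `[0, 1]`.
#' @param n_genes Number of genes to annotate.
#' @param n_peaks_per_class Planted peaks per composition class.
#' @param peak_fold Coverage fold change (treated/control) of planted peaks.
#' @param flank_half_width Half-width of the planted flank window, bases.
#' @param seed Mandatory integer random seed.
#' @param read_depth_scale Baseline coverage signal, arbitrary units.
#' @param noise_cv Coefficient of variation of the baseline noise.
#' @param bin_size Coverage bin width, bases.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L, gc_fraction = 0.5,
                       n_genes = 50L, n_peaks_per_class = 5L,
                       peak_fold = 4, flank_half_width = 250L, seed,
                       read_depth_scale = 100, noise_cv = 0.05,
                       bin_size = 25L) {
  if (missing(seed)) stop("`seed` is mandatory in sim_config", call. = FALSE)
  stopifnot(genome_length > 0, gc_fraction >= 0, gc_fraction <= 1,
            n_genes >= 0, n_peaks_per_class >= 0, peak_fold > 0,
            flank_half_width > 0, read_depth_scale > 0, noise_cv >= 0,
            bin_size >= 1)
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
                 n_peaks_per_class = as.integer(n_peaks_per_class),
                 peak_fold = peak_fold,
                 flank_half_width = as.integer(flank_half_width),
                 seed = as.integer(seed),
                 read_depth_scale = read_depth_scale, noise_cv = noise_cv,
                 bin_size = as.integer(bin_size)),
            class = "sim_config")
}

#' Specification of one planted peak
#'
#' @param center 0-based center position.
#' @param composition_class One of `"GC_RICH"`, `"AT_RICH"`,
#'   `"WCGW_SEEDED"`, `"NEUTRAL"` — the sequence composition planted in the
#'   flank window around the center.
#' @param mark_folds Named list/vector, mark -> fold change
#'   (treated/control), all > 0.
#' @param target_gene Optional gene id the peak is associated with.
#' @return A list of class `planted_peak`.
#' @export
planted_peak <- function(center, composition_class, mark_folds,
                         target_gene = NA_character_) {
  composition_class <- match.arg(composition_class,
                                 c("GC_RICH", "AT_RICH", "WCGW_SEEDED",
                                   "NEUTRAL"))
  mark_folds <- as.list(mark_folds)
  if (length(mark_folds) == 0L || is.null(names(mark_folds)) ||
      any(unlist(mark_folds) <= 0))
    stop("mark_folds must be a named list of positive folds", call. = FALSE)
  structure(list(center = as.integer(center),
                 composition_class = composition_class,
                 mark_folds = mark_folds, target_gene = target_gene),
            class = "planted_peak")
}

#' Generate an i.i.d. random genome sequence
#'
#' Bases are drawn independently with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`.
#'
#' @param length Sequence length in bases (>= 0).
#' @param gc_fraction Target GC fraction in `[0, 1]`.
#' @param seed Integer random seed.
#' @return A single upper-case A/C/G/T string of exactly `length` bases.
#' @export
generate_genome <- function(length, gc_fraction = 0.5, seed) {
  if (length < 0) stop("length must be non-negative", call. = FALSE)
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  if (length == 0) return("")
  with_seed(seed, {
    probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
               G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = "")
  })
}

# draw a window of i.i.d. bases with P(A)+P(T) = at_fraction
.random_window <- function(n, at_fraction) {
  probs <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
             G = (1 - at_fraction) / 2, T = at_fraction / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

#' Rewrite a window of the genome with a planted composition
#'
#' The window `center - half_width .. center + half_width` (0-based,
#' inclusive) is rewritten according to the composition class:
#' `AT_RICH` draws bases with `P(A) + P(T) = intensity`; `GC_RICH` with
#' `P(G) + P(C) = intensity`; `WCGW_SEEDED` lays a neutral (50% GC)
#' background and places non-overlapping random instantiations of the
#' degenerate 6-mer `WWCGWW` at a density controlled by `intensity`
#' (fraction of window positions covered by seeded copies); `NEUTRAL`
#' leaves the sequence untouched.  Bases outside the window are unchanged.
#'
#' @param sequence Contig sequence (single string).
#' @param center 0-based window center.
#' @param composition_class See [planted_peak()].
#' @param half_width Window half-width, bases.
#' @param intensity Composition intensity in `[0, 1]`.
#' @param seed Integer random seed.
#' @return The modified sequence.
#' @export
plant_composition <- function(sequence, center, composition_class,
                              half_width = 250L, intensity = 0.9, seed) {
  composition_class <- match.arg(composition_class,
                                 c("GC_RICH", "AT_RICH", "WCGW_SEEDED",
                                   "NEUTRAL"))
  stopifnot(intensity >= 0, intensity <= 1)
  lo <- center - half_width          # 0-based inclusive
  hi <- center + half_width
  if (lo < 0 || hi > nchar(sequence) - 1L)
    stop("planting window out of bounds", call. = FALSE)
  if (composition_class == "NEUTRAL") return(sequence)
  n <- 2L * half_width + 1L
  window <- with_seed(seed, {
    if (composition_class == "AT_RICH") {
      .random_window(n, at_fraction = intensity)
    } else if (composition_class == "GC_RICH") {
      .random_window(n, at_fraction = 1 - intensity)
    } else {                         # WCGW_SEEDED
      w <- strsplit(.random_window(n, at_fraction = 0.5), "",
                    fixed = TRUE)[[1L]]
      n_copies <- floor(intensity * n / 6)
      slots <- seq_len(n %/% 6L)     # non-overlapping 6-base slots
      chosen <- sample(slots, min(n_copies, length(slots)))
      for (s in chosen) {
        inst <- c(sample(c("A", "T"), 2L, replace = TRUE), "C", "G",
                  sample(c("A", "T"), 2L, replace = TRUE))
        w[((s - 1L) * 6L + 1L):(s * 6L)] <- inst
      }
      paste(w, collapse = "")
    }
  })
  paste0(substr(sequence, 1L, lo), window,
         substr(sequence, hi + 2L, nchar(sequence)))
}

.mark_index <- c(H3K4me2 = 1L, H3K4me3 = 2L, H3K27ac = 3L)

#' Generate a coverage track with planted peak enrichments
#'
#' The baseline is positive i.i.d. noise per bin (normal with mean
#' `read_depth_scale` and coefficient of variation `noise_cv`, truncated at
#' zero).  Each planted peak adds a symmetric triangular enrichment of
#' half-width `flank_half_width` centered at its `center`, scaled so that
#' the mean signal over the peak window equals `read_depth_scale *
#' mark_folds[mark]` in the treated condition and `read_depth_scale` in the
#' control (apex amplitude `2 * read_depth_scale * (fold - 1)`).  The noise
#' realization for a given (mark, condition, seed) triple is deterministic,
#' and treated/control share no noise.
#'
#' @param genome_length Genome length in bases.
#' @param peaks List of [planted_peak()]s; each `mark_folds` must contain
#'   `mark`.
#' @param mark One of `"H3K4me2"`, `"H3K4me3"`, `"H3K27ac"`.
#' @param condition `"treated"` or `"control"`.
#' @param config A [sim_config()].
#' @param contig Contig name of the single simulated chromosome.
#' @return A [coverage_track()].
#' @export
generate_coverage <- function(genome_length, peaks, mark,
                              condition = c("treated", "control"), config,
                              contig = "chrS") {
  condition <- match.arg(condition)
  if (!mark %in% names(.mark_index))
    stop("unknown mark: ", mark, call. = FALSE)
  stopifnot(inherits(config, "sim_config"))
  bs <- config$bin_size
  n_bins <- ceiling(genome_length / bs)
  scale <- config$read_depth_scale
  hw <- config$flank_half_width
  seed <- derive_seed(config$seed, paste("coverage", mark, condition))
  noise <- with_seed(seed, {
    x <- rnorm(n_bins, mean = scale, sd = config$noise_cv * scale)
    while (any(x <= 0))              # truncate at zero, keep positivity
      x[x <= 0] <- rnorm(sum(x <= 0), mean = scale,
                         sd = config$noise_cv * scale)
    x
  })
  v <- noise
  mids <- (seq_len(n_bins) - 0.5) * bs
  for (pk in peaks) {
    if (pk$center - hw < 0 || pk$center + hw > genome_length - 1L)
      stop("peak window out of genome bounds", call. = FALSE)
    if (!mark %in% names(pk$mark_folds))
      stop("unknown mark: ", mark, call. = FALSE)
    fold <- if (condition == "treated") pk$mark_folds[[mark]] else 1
    amp <- 2 * scale * (fold - 1)
    v <- v + amp * pmax(0, 1 - abs(mids - pk$center) / hw)
  }
  coverage_track(setNames(list(pmax(v, 0)), contig), bs)
}

#' Generate a non-overlapping gene annotation
#'
#' Genes are placed in disjoint slots across the genome with random extents
#' and strands; the TSS is the interval start on `+` and `end - 1` on `-`.
#' Records are sorted by coordinate with unique ids.
#'
#' @param genome_length Genome length in bases.
#' @param n_genes Number of genes (>= 0).
#' @param seed Integer random seed.
#' @param contig Contig name.
#' @return data.frame with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand`, `tss`.
#' @export
generate_annotation <- function(genome_length, n_genes, seed,
                                contig = "chrS") {
  stopifnot(n_genes >= 0)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), tss = integer())
  if (n_genes == 0L) return(empty)
  min_span <- 100L                   # minimal slot a gene needs
  if (as.numeric(n_genes) * min_span > genome_length)
    stop("n_genes x minimal spacing exceeds genome length", call. = FALSE)
  slot <- genome_length %/% n_genes
  with_seed(seed, {
    starts <- (seq_len(n_genes) - 1L) * slot +
      sample.int(slot %/% 4L, n_genes, replace = TRUE)
    lens <- pmin(slot %/% 2L,
                 sample(200L:1000L, n_genes, replace = TRUE))
    ends <- pmin(starts + lens, (seq_len(n_genes)) * slot - 1L)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    df <- data.frame(contig = contig, start = as.integer(starts),
                     end = as.integer(ends),
                     name = sprintf("gene%04d", seq_len(n_genes)),
                     score = 0, strand = strand,
                     tss = as.integer(ifelse(strand == "+", starts,
                                             ends - 1L)))
    df[order(df$start), , drop = FALSE]
  })
}

#' Generate a two-condition expression table
#'
#' Control values are FPKM-like draws from a log-normal distribution.  For
#' genes in `activated_genes` the treated value satisfies
#' `log2(treated + 1) = log2(control + 1) + effect_size + noise`; for the
#' rest the shift is `0 + noise`, with `noise ~ N(0, noise_sd)` in log2
#' units.  With `noise_sd = 0` and `effect_size = 0` the treated column
#' equals the control column exactly.
#'
#' @param annotation Gene annotation as from [generate_annotation()].
#' @param activated_genes Character vector of gene ids (subset of
#'   `annotation$name`).
#' @param effect_size Planted log2 fold change of activated genes.
#' @param noise_sd Standard deviation of the log2 shift noise.
#' @param seed Integer random seed.
#' @return data.frame with columns `gene`, `control`, `treated`.
#' @export
generate_expression <- function(annotation, activated_genes = character(),
                                effect_size = 1.5, noise_sd = 0.5, seed) {
  ids <- annotation$name
  bad <- setdiff(activated_genes, ids)
  if (length(bad))
    stop("unknown gene id(s) in activated set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  with_seed(seed, {
    control <- 2^rnorm(length(ids), mean = 4, sd = 2)
    d <- ifelse(ids %in% activated_genes, effect_size, 0) +
      if (noise_sd > 0) rnorm(length(ids), 0, noise_sd) else 0
    treated <- ifelse(d == 0, control,
                      pmax(2^(log2(control + 1) + d) - 1, 0))
    data.frame(gene = ids, control = control, treated = treated,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Builds the full study layout from a [sim_config()]: a random genome; one
#' planted peak set with `n_peaks_per_class` peaks of each composition
#' class (GC_RICH, AT_RICH, WCGW_SEEDED, NEUTRAL), evenly spaced, each with
#' fold `peak_fold` for H3K4me2 and H3K27ac and fold 1 for H3K4me3 (an
#' LSD1-inhibition-like signature); six coverage tracks (3 marks x 2
#' conditions); a gene annotation; and an expression table in which the
#' genes nearest the planted peaks are shifted upward.
#'
#' @param config A [sim_config()].
#' @param composition_intensity Intensity passed to [plant_composition()].
#' @param effect_size,noise_sd Expression-shift parameters
#'   (see [generate_expression()]).
#' @return List with elements `genome` (named character vector), `peaks`
#'   (list of [planted_peak()]s), `truth` (data.frame of planted peak
#'   intervals with class labels), `tracks` (nested list
#'   `tracks[[mark]][[condition]]`), `annotation`, `expression`,
#'   `activated_genes`, `config`.
#' @export
simulate_dataset <- function(config, composition_intensity = 0.9,
                             effect_size = 1.5, noise_sd = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  classes <- c("GC_RICH", "AT_RICH", "WCGW_SEEDED", "NEUTRAL")
  n_peaks <- config$n_peaks_per_class * length(classes)
  hw <- config$flank_half_width
  L <- config$genome_length
  if (n_peaks > 0 && L < n_peaks * (2L * hw + 2L))
    stop("genome too short for the requested peaks", call. = FALSE)

  seq0 <- generate_genome(L, config$gc_fraction, config$seed)
  marks_folds <- list(H3K4me2 = config$peak_fold, H3K4me3 = 1,
                      H3K27ac = config$peak_fold)
  peaks <- list()
  if (n_peaks > 0) {
    spacing <- L %/% (n_peaks + 1L)
    centers <- spacing * seq_len(n_peaks)
    cls <- rep(classes, each = config$n_peaks_per_class)
    cls <- with_seed(derive_seed(config$seed, "class order"), sample(cls))
    for (i in seq_len(n_peaks)) {
      seq0 <- plant_composition(seq0, centers[i], cls[i], hw,
                                composition_intensity,
                                derive_seed(config$seed, paste("plant", i)))
      peaks[[i]] <- planted_peak(centers[i], cls[i], marks_folds)
    }
  }
  genome <- c(chrS = seq0)

  tracks <- list()
  for (mk in names(.mark_index)) {
    tracks[[mk]] <- list(
      treated = generate_coverage(L, peaks, mk, "treated", config),
      control = generate_coverage(L, peaks, mk, "control", config))
  }

  annotation <- generate_annotation(L, config$n_genes,
                                    derive_seed(config$seed, "annotation"))
  truth <- if (n_peaks > 0) data.frame(
    contig = "chrS",
    start = vapply(peaks, function(p) p$center - hw, 0L),
    end = vapply(peaks, function(p) p$center + hw + 1L, 0L),
    name = vapply(peaks, function(p) p$composition_class, ""),
    score = 0, strand = ".",
    center = vapply(peaks, function(p) p$center, 0L)) else
      data.frame(contig = character(), start = integer(), end = integer(),
                 name = character(), score = numeric(), strand = character(),
                 center = integer())

  activated <- character()
  if (nrow(annotation) > 0 && n_peaks > 0) {
    tss <- data.frame(contig = annotation$contig, pos = annotation$tss,
                      gene = annotation$name)
    activated <- unique(nearest_gene(truth, tss)$gene)
    activated <- activated[!is.na(activated)]
  }
  expression <- generate_expression(annotation, activated, effect_size,
                                    noise_sd,
                                    derive_seed(config$seed, "expression"))
  list(genome = genome, peaks = peaks, truth = truth, tracks = tracks,
       annotation = annotation, expression = expression,
       activated_genes = activated, config = config)
}

#' Write a simulated dataset to an output directory
#'
#' Writes the genome as wrapped FASTA, each coverage track as bedGraph, the
#' annotation as BED6, the planted-peak truth as BED (class in the name
#' column), and the expression table as TSV.  All formats that allow
#' comment lines embed the simulation seed in a header comment.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed_note <- paste0("seed=", dataset$config$seed)
  paths <- c(genome = file.path(outdir, "genome.fa"))
  write_fasta(dataset$genome, paths[["genome"]])
  for (mk in names(dataset$tracks)) {
    for (cond in names(dataset$tracks[[mk]])) {
      p <- file.path(outdir, sprintf("%s_%s.bedgraph", mk, cond))
      write_bedgraph(dataset$tracks[[mk]][[cond]], p, comment = seed_note)
      paths[[paste(mk, cond, sep = "_")]] <- p
    }
  }
  paths[["annotation"]] <- file.path(outdir, "genes.bed")
  write_bed(dataset$annotation, paths[["annotation"]], comment = seed_note)
  paths[["truth"]] <- file.path(outdir, "peaks_truth.bed")
  write_bed(dataset$truth, paths[["truth"]], comment = seed_note)
  paths[["expression"]] <- file.path(outdir, "expression.tsv")
  write_expression(dataset$expression, paths[["expression"]],
                   comment = seed_note)
  invisible(paths)
}
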