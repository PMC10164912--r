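#' Positional amino-acid frequency matrix of a peptide set
#'
#' For each window offset (including the center, offset 0) the frequency of
#' each of the 20 canonical amino acids among the non-pad, non-X residues
#' observed there. At offsets where at least one scorable residue is
#' present the column sums to 1; for a valid set the offset-0 column is
#' all S and T. This is the heatmap-style diagnostic used to compare
#' positive and negative training datasets.
#'
#' @param set A `peptide_set` or `peptide_windows` data frame (non-empty).
#' @return A 20 x L numeric matrix of class `frequency_matrix` with
#'   amino-acid rownames and signed-offset colnames; attribute `counts`
#'   holds the number of counted residues per offset.
#' @export
positional_frequency <- function(set) {
  windows <- set_windows(set)
  if (nrow(windows) == 0L) {
    stop("cannot compute positional frequencies of an empty set")
  }
  L <- unique(nchar(windows$window))
  stopifnot(length(L) == 1L)
  flank <- (L - 1L) %/% 2L
  offsets <- seq.int(-flank, flank)
  chars <- matrix(unlist(strsplit(windows$window, "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = nrow(windows), ncol = L, byrow = TRUE)
  freq <- matrix(0, nrow = length(AA_CANONICAL), ncol = L,
                 dimnames = list(AA_CANONICAL, as.character(offsets)))
  counts <- integer(L)
  for (j in seq_len(L)) {
    tab <- table(factor(chars[, j], levels = AA_CANONICAL))
    counts[j] <- sum(tab)
    if (counts[j] > 0L) freq[, j] <- as.numeric(tab) / counts[j]
  }
  structure(freq, counts = counts,
            class = c("frequency_matrix", "matrix", "array"))
}

#' Write a frequency matrix to TSV
#' @param freq A `frequency_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_tsv <- function(freq, path) {
  d <- data.frame(aa = rownames(freq), as.data.frame(unclass(freq)),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Background amino-acid frequencies from a sequence set
#'
#' Pools residue counts over all sequences and normalizes over the 20
#' canonical residues ('X' is ignored). Use this to derive a background
#' composition (e.g. of a proteome or of a disordered-protein set) for
#' [compositional_bias()].
#'
#' @param sequences A non-empty list of [protein_record()]s.
#' @return Named numeric vector over the canonical residues, summing to 1.
#' @export
background_from_sequences <- function(sequences) {
  if (inherits(sequences, "protein_record")) sequences <- list(sequences)
  if (length(sequences) == 0L) {
    stop("need at least one sequence to derive a background")
  }
  counts <- pooled_counts(sequences)
  total <- sum(counts)
  if (total == 0L) {
    stop("no canonical residues in the input sequences")
  }
  counts / total
}

pooled_counts <- function(sequences) {
  chars <- unlist(strsplit(vapply(sequences, function(r) r$sequence,
                                  character(1)),
                           "", fixed = TRUE), use.names = FALSE)
  tab <- table(factor(chars, levels = AA_CANONICAL))
  stats::setNames(as.integer(tab), AA_CANONICAL)
}

#' Amino-acid composition of one protein
#'
#' @param protein A [protein_record()].
#' @return Named numeric vector: fraction of the sequence made up by each
#'   residue present (including 'X' when present); sums to 1.
#' @export
composition <- function(protein) {
  stopifnot(inherits(protein, "protein_record"))
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  tab <- table(chars)
  stats::setNames(as.numeric(tab) / length(chars), names(tab))
}

#' Whole-set compositional bias (exact binomial upper tail)
#'
#' For each canonical residue, the probability of observing at least the
#' pooled count of that residue under a binomial null with the given
#' background frequency — the Harrison-Gerstein-style bias statistic
#' applied to a whole sequence set. Small values flag enrichment relative
#' to the background. Counts are pooled over region sequences rather than
#' over (redundant, overlapping) peptide windows. The tail is computed in
#' log space, so values as small as 1e-264 are reported exactly; no
#' multiple-testing correction is applied.
#'
#' @param sequences Non-empty list of [protein_record()]s.
#' @param background Named numeric vector of positive background
#'   frequencies over the 20 canonical residues, summing to 1 (+- 1e-6).
#' @return A data frame of class `bias_table`: one row per canonical
#'   residue with `residue`, `observed_count`, `total_residues`,
#'   `background_frequency`, `p_bias` and `log10_p`.
#' @export
compositional_bias <- function(sequences, background) {
  if (inherits(sequences, "protein_record")) sequences <- list(sequences)
  if (length(sequences) == 0L) {
    stop("need at least one sequence")
  }
  if (is.null(names(background)) ||
      !setequal(names(background), AA_CANONICAL)) {
    stop("background must be named over the 20 canonical residues")
  }
  background <- background[AA_CANONICAL]
  if (any(background <= 0)) {
    stop("background frequencies must all be positive")
  }
  if (abs(sum(background) - 1) > 1e-6) {
    stop("background frequencies must sum to 1 (found ",
         format(sum(background)), ")")
  }
  counts <- pooled_counts(sequences)
  n <- sum(counts)
  logp <- stats::pbinom(counts - 1L, n, background, lower.tail = FALSE,
                        log.p = TRUE)
  structure(
    data.frame(
      residue = AA_CANONICAL,
      observed_count = as.integer(counts),
      total_residues = n,
      background_frequency = as.numeric(background),
      p_bias = exp(logp),
      log10_p = logp / log(10),
      stringsAsFactors = FALSE
    ),
    class = c("bias_table", "data.frame")
  )
}

#' Summarize site predictions against known sites
#'
#' Builds the confusion table over a protein's S/T sites: predicted and
#' known positives are position sets, everything else among `all_sites` is
#' a true negative. Returns raw counts plus sensitivity, specificity,
#' accuracy and precision (NA when a denominator is zero).
#'
#' @param predicted_positive,known_positive Integer vectors of site
#'   positions; both must be subsets of `all_sites`.
#' @param all_sites Integer vector of every S/T position considered.
#' @return An object of class `confusion_summary`.
#' @examples
#' evaluate_predictions(c(2, 3), 2, 1:4)
#' @export
evaluate_predictions <- function(predicted_positive, known_positive,
                                 all_sites) {
  predicted_positive <- unique(as.integer(predicted_positive))
  known_positive <- unique(as.integer(known_positive))
  all_sites <- unique(as.integer(all_sites))
  bad_p <- setdiff(predicted_positive, all_sites)
  bad_k <- setdiff(known_positive, all_sites)
  if (length(bad_p) > 0L || length(bad_k) > 0L) {
    stop("position(s) outside all_sites: ",
         paste(sort(c(bad_p, bad_k)), collapse = ", "))
  }
  tp <- length(intersect(predicted_positive, known_positive))
  fp <- length(setdiff(predicted_positive, known_positive))
  fn <- length(setdiff(known_positive, predicted_positive))
  tn <- length(all_sites) - tp - fp - fn
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp),
         accuracy = ratio(tp + tn, tp + fp + tn + fn),
         precision = ratio(tp, tp + fp)),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else paste0(round(100 * v), "%")
  cat("<confusion_summary>\n",
      "  Positive sites found      ", x$tp, "\n",
      "  Total sites found         ", x$tp + x$fp, "\n",
      "  Predicted sites verified  ", pct(x$precision), "\n",
      "  Sensitivity               ", pct(x$sensitivity), "\n",
      "  Specificity               ", pct(x$specificity), "\n",
      "  Accuracy                  ", pct(x$accuracy), "\n", sep = "")
  invisible(x)
}

#' Confusion summary as a one-row data frame
#'
#' Raw ratios are kept at full precision; the `*_pct` columns carry the
#' whole-percent rounding used for display.
#'
#' @param x A `confusion_summary`.
#' @param ... Unused.
#' @return A one-row data frame.
#' @export
as.data.frame.confusion_summary <- function(x, ...) {
  data.frame(
    tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
    sensitivity = x$sensitivity, specificity = x$specificity,
    accuracy = x$accuracy, precision = x$precision,
    sensitivity_pct = round(100 * x$sensitivity),
    specificity_pct = round(100 * x$specificity),
    accuracy_pct = round(100 * x$accuracy),
    precision_pct = round(100 * x$precision)
  )
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation of two equal-length vectors with the usual
#' t-distributed test on n - 2 degrees of freedom — used e.g. to compare
#' predicted site counts with observed glycosylation stoichiometries
#' across mutant constructs.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with elements `r` and `p`.
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop("x and y must have equal length")
  }
  if (length(x) < 3L) {
    stop("need at least 3 paired observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
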