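#' Construct a position-specific scoring matrix
#'
#' The matrix assigns a real score to each of 18 amino acids (the 20
#' canonical residues minus W and C, which are too rare to train) at each
#' non-center offset of a window of odd length `length`: offsets
#' `-(L-1)/2 ... -1, +1 ... +(L-1)/2`. The center S/T itself is not scored
#' — for the default L = 39 the table is 18 x 38. A window's score is the
#' sum of the matrix entries for its flanking residues; W, C, X and the pad
#' character contribute exactly zero.
#'
#' @param length Odd window length >= 3 (default 39).
#' @param values Either a single number used to fill the matrix (default
#'   0), or an 18 x (L-1) numeric matrix. Row order is the fixed
#'   alphabetical order `A,D,E,F,G,H,I,K,L,M,N,P,Q,R,S,T,V,Y`.
#' @param name Free-text matrix name.
#' @return A numeric matrix of class `scoring_matrix` with amino-acid
#'   rownames and signed-offset colnames.
#' @examples
#' m <- scoring_matrix(5)
#' dim(m)  # 18 x 4
#' @export
scoring_matrix <- function(length = 39L, values = 0, name = "matrix") {
  length <- check_window_length(length)
  offsets <- matrix_offsets(length)
  if (is.matrix(values)) {
    if (!all(dim(values) == c(length(AA_MATRIX), length - 1L))) {
      stop("values must be ", length(AA_MATRIX), " x ", length - 1L,
           " for window length ", length, "; got ",
           paste(dim(values), collapse = " x "))
    }
    m <- values
  } else {
    stopifnot(is.numeric(values), length(values) == 1L)
    m <- matrix(values, nrow = length(AA_MATRIX), ncol = length - 1L)
  }
  if (!all(is.finite(m))) {
    stop("scoring matrix values must all be finite")
  }
  dimnames(m) <- list(AA_MATRIX, as.character(offsets))
  structure(m, name = name, class = c("scoring_matrix", "matrix", "array"))
}

matrix_offsets <- function(length) {
  flank <- (length - 1L) %/% 2L
  c(seq.int(-flank, -1L), seq.int(1L, flank))
}

#' Window length of a scoring matrix
#' @param matrix A `scoring_matrix`.
#' @return Odd integer window length (ncol + 1).
#' @export
matrix_length <- function(matrix) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  ncol(matrix) + 1L
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("<scoring_matrix> '", attr(x, "name"), "': ", nrow(x), " residues x ",
      ncol(x), " offsets (window length ", matrix_length(x), ")\n", sep = "")
  cat("  value range [", format(min(x)), ", ", format(max(x)), "]\n",
      sep = "")
  invisible(x)
}

#' Score one peptide window
#'
#' The score is the sum over non-center offsets of the matrix entry for the
#' residue at that offset. Residues without a matrix row (W, C, X) and the
#' terminal pad `-` contribute zero; the center residue is never scored.
#'
#' @param matrix A [scoring_matrix()].
#' @param window A window string of the matrix's length, or one row of a
#'   `peptide_windows` data frame.
#' @return A single numeric score.
#' @examples
#' m <- scoring_matrix(5)
#' m["A", ] <- 1
#' score_window(m, "AASAA")  # 4
#' @export
score_window <- function(matrix, window) {
  if (is.data.frame(window)) window <- window$window
  stopifnot(is.character(window), length(window) == 1L)
  score_window_strings(matrix, window)
}

#' Score every window of a peptide set
#'
#' @param matrix A [scoring_matrix()].
#' @param set A `peptide_set` or `peptide_windows` data frame.
#' @return Numeric vector of scores, in window order.
#' @export
score_set <- function(matrix, set) {
  windows <- set_windows(set)
  score_window_strings(matrix, windows$window)
}

set_windows <- function(set) {
  if (inherits(set, "peptide_set")) return(set$windows)
  if (is.data.frame(set) && "window" %in% names(set)) return(set)
  stop("expected a peptide_set or a data frame with a 'window' column")
}

# vectorized scorer over window strings
score_window_strings <- function(matrix, windows) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  L <- matrix_length(matrix)
  if (length(windows) == 0L) return(numeric(0))
  lens <- nchar(windows)
  if (any(lens != L)) {
    i <- which(lens != L)[1L]
    stop("window length ", lens[i], " does not match matrix window length ",
         L, " (window ", i, ")")
  }
  flank <- (L - 1L) %/% 2L
  cols <- setdiff(seq_len(L), flank + 1L)
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(windows), ncol = L, byrow = TRUE)
  scores <- numeric(length(windows))
  for (j in seq_along(cols)) {
    row <- match(chars[, cols[j]], rownames(matrix))
    hit <- !is.na(row)
    scores[hit] <- scores[hit] + matrix[row[hit], j]
  }
  scores
}

#' Default prediction thresholds
#'
#' Score cutoffs for calling a site positive at increasing stringency.
#' Defaults are the calibrated low/medium/high cutoffs 123, 148 and 160; a
#' site is called at a threshold when its score is greater than or equal to
#' it. High cutoffs trade sensitivity for precision, appropriate when only
#' a small minority of S/T residues are truly modified.
#'
#' @param low,medium,high Numeric cutoffs, `low <= medium <= high`.
#' @return An object of class `prediction_thresholds`.
#' @export
prediction_thresholds <- function(low = 123, medium = 148, high = 160) {
  stopifnot(is.numeric(low), is.numeric(medium), is.numeric(high))
  if (!(low <= medium && medium <= high)) {
    stop("thresholds must satisfy low <= medium <= high; got ",
         low, ", ", medium, ", ", high)
  }
  structure(list(low = low, medium = medium, high = high),
            class = "prediction_thresholds")
}

#' Predict glycosylation sites in a protein
#'
#' Extracts every S/T-centered window at the matrix's length, scores it,
#' and calls it positive at each threshold where score >= cutoff. Calls are
#' monotone by construction: every high-threshold call is also a medium and
#' low call.
#'
#' @param matrix A [scoring_matrix()].
#' @param protein A [protein_record()].
#' @param thresholds A [prediction_thresholds()] object.
#' @return A data frame of class `site_predictions` with columns
#'   `parent_id`, `center_position`, `center_residue`, `score`,
#'   `call_low`, `call_medium`, `call_high`.
#' @export
predict_sites <- function(matrix, protein,
                          thresholds = prediction_thresholds()) {
  stopifnot(inherits(thresholds, "prediction_thresholds"))
  windows <- extract_windows(protein, matrix_length(matrix))
  scores <- score_window_strings(matrix, windows$window)
  out <- data.frame(
    parent_id = windows$parent_id,
    center_position = windows$center_position,
    center_residue = windows$center_residue,
    score = scores,
    call_low = scores >= thresholds$low,
    call_medium = scores >= thresholds$medium,
    call_high = scores >= thresholds$high,
    stringsAsFactors = FALSE
  )
  structure(out, thresholds = thresholds,
            class = c("site_predictions", "data.frame"))
}

#' Write site predictions to TSV
#'
#' Scores are printed with 6 decimal places; logical calls as TRUE/FALSE.
#'
#' @param predictions A `site_predictions` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  d <- as.data.frame(predictions)
  d$score <- sprintf("%.6f", d$score)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read site predictions from TSV
#' @param path Input path.
#' @return A `site_predictions` data frame.
#' @export
read_predictions_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("parent_id", "center_position", "center_residue", "score",
            "call_low", "call_medium", "call_high")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("prediction file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  structure(d[, need], class = c("site_predictions", "data.frame"))
}

#' Write a scoring matrix to TSV
#'
#' One header row of signed integer offsets, then 18 amino-acid-labeled
#' rows in fixed alphabetical order. Values are written with full double
#' precision so that write-then-read is the identity.
#'
#' @param matrix A [scoring_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  header <- paste(c("aa", colnames(matrix)), collapse = "\t")
  rows <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i], sprintf("%.17g", matrix[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a scoring matrix from TSV
#'
#' Accepts rows in any order; an offset-0 column, if present, is dropped
#' with a warning (the center residue is not scored). Missing or duplicated
#' amino-acid rows and non-numeric cells are format errors.
#'
#' @param path Input path.
#' @param name Matrix name (defaults to the file name).
#' @return A [scoring_matrix()].
#' @export
read_matrix <- function(path, name = basename(path)) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (names(d)[1L] != "aa") {
    stop("matrix file ", path, ": first column must be named 'aa'")
  }
  aa <- d$aa
  dup <- unique(aa[duplicated(aa)])
  if (length(dup) > 0L) {
    stop("matrix file ", path, ": duplicated amino-acid row(s): ",
         paste(dup, collapse = ", "))
  }
  missing <- setdiff(AA_MATRIX, aa)
  if (length(missing) > 0L) {
    stop("matrix file ", path, ": missing amino-acid row(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(aa, AA_MATRIX)
  if (length(extra) > 0L) {
    stop("matrix file ", path, ": unexpected row(s): ",
         paste(extra, collapse = ", "))
  }
  off_names <- names(d)[-1L]
  offsets <- suppressWarnings(as.integer(off_names))
  if (anyNA(offsets)) {
    stop("matrix file ", path, ": non-integer offset column(s): ",
         paste(off_names[is.na(offsets)], collapse = ", "))
  }
  if (0L %in% offsets) {
    warning("matrix file ", path,
            ": offset-0 column present; ignored (center is not scored)")
    keep <- offsets != 0L
    d <- d[, c(TRUE, keep)]
    offsets <- offsets[keep]
  }
  L <- length(offsets) + 1L
  expected <- matrix_offsets(L)
  if (!setequal(offsets, expected) || anyDuplicated(offsets)) {
    stop("matrix file ", path, ": offsets do not form a contiguous ",
         "symmetric range; got ", paste(sort(offsets), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = length(AA_MATRIX), ncol = length(offsets),
                 dimnames = list(AA_MATRIX, as.character(expected)))
  ord <- match(as.character(expected), names(d)[-1L])
  for (i in seq_along(aa)) {
    row <- suppressWarnings(as.numeric(unlist(d[i, -1L])[ord]))
    if (anyNA(row)) {
      j <- which(is.na(row))[1L]
      stop("matrix file ", path, ": non-numeric cell at row '", aa[i],
           "', offset ", expected[j])
    }
    vals[aa[i], ] <- row
  }
  scoring_matrix(L, values = vals, name = name)
}
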