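#' Extract S/T-centered peptide windows from a protein
#'
#' Every serine and threonine in the sequence yields exactly one window of
#' odd length `length`, centered on the site. Positions beyond either
#' terminus are padded with `-`, which scores zero downstream, so no site is
#' dropped near the ends. Window centers are reported in the parent
#' protein's numbering when the record carries region metadata.
#'
#' @param protein A [protein_record()].
#' @param length Odd window length, >= 3. Default 39 (19 flanking residues
#'   per side), the length at which compositional trends around OGT sites
#'   remain visible end to end.
#' @return A data frame of class `peptide_windows` with columns
#'   `parent_id`, `center_position`, `center_residue`, `window`, and
#'   attribute `window_length`.
#' @examples
#' extract_windows(protein_record("p", "GGSGG"), length = 5)
#' @export
extract_windows <- function(protein, length = 39L) {
  stopifnot(inherits(protein, "protein_record"))
  length <- check_window_length(length)
  flank <- (length - 1L) %/% 2L
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  centers <- which(chars == "S" | chars == "T")
  build_windows(protein, centers, chars, length, flank)
}

#' Build windows around a list of known modification sites
#'
#' Like [extract_windows()], but only around the given positions — used to
#' rebuild long windows around database-listed glycosylation sites. Every
#' listed position must hold an S or T.
#'
#' @param protein A [protein_record()].
#' @param sites Integer vector of 1-based site positions, in the parent
#'   numbering when the record has region metadata.
#' @param length Odd window length, >= 3.
#' @return A `peptide_windows` data frame (empty for an empty site list).
#' @export
windows_from_site_list <- function(protein, sites, length = 39L) {
  stopifnot(inherits(protein, "protein_record"))
  length <- check_window_length(length)
  flank <- (length - 1L) %/% 2L
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  offset <- if (!is.null(protein$region_start)) protein$region_start - 1L else 0L
  local <- as.integer(sites) - offset
  if (any(local < 1L | local > length(chars))) {
    bad <- sites[local < 1L | local > length(chars)]
    stop("site position(s) outside the sequence: ",
         paste(bad, collapse = ", "))
  }
  res <- chars[local]
  bad <- res != "S" & res != "T"
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("site at position ", sites[i], " is '", res[i],
         "', not S or T")
  }
  build_windows(protein, local, chars, length, flank)
}

check_window_length <- function(length) {
  length <- as.integer(length)
  if (is.na(length) || length < 3L || length %% 2L == 0L) {
    stop("window length must be an odd integer >= 3, got ", length)
  }
  length
}

build_windows <- function(protein, centers, chars, length, flank) {
  offset <- if (!is.null(protein$region_start)) protein$region_start - 1L else 0L
  padded <- c(rep(PAD_CHAR, flank), chars, rep(PAD_CHAR, flank))
  windows <- vapply(centers, function(i) {
    paste(padded[i:(i + 2L * flank)], collapse = "")
  }, character(1))
  out <- data.frame(
    parent_id = rep(protein$id, length(centers)),
    center_position = as.integer(centers + offset),
    center_residue = chars[centers],
    window = windows,
    stringsAsFactors = FALSE
  )
  structure(out, window_length = length,
            class = c("peptide_windows", "data.frame"))
}

#' Assemble a labeled peptide set
#'
#' A labeled set is the unit of training data: a named collection of
#' equal-length S/T-centered windows tagged positive (known glycosylation
#' sites) or negative (experimentally unglycosylated peptides). Duplicate
#' and overlapping windows are retained, matching how redundant database
#' peptides are used.
#'
#' @param windows A `peptide_windows` data frame (several may be combined
#'   with `rbind` first), or any data frame with a `window` column.
#' @param name Free-text set name.
#' @param label `"positive"` or `"negative"`.
#' @return An object of class `peptide_set`.
#' @export
peptide_set <- function(windows, name, label = c("positive", "negative")) {
  label <- match.arg(label)
  stopifnot(is.data.frame(windows), "window" %in% names(windows))
  lens <- unique(nchar(windows$window))
  if (nrow(windows) > 0L && length(lens) != 1L) {
    stop("all windows in a set must share one length; found lengths ",
         paste(sort(lens), collapse = ", "))
  }
  L <- if (nrow(windows) > 0L) lens else attr(windows, "window_length")
  if (is.null(L)) {
    stop("cannot determine window length of an empty set; ",
         "build windows with extract_windows()")
  }
  check_window_length(L)
  flank <- (L - 1L) %/% 2L
  if (nrow(windows) > 0L) {
    centers <- substr(windows$window, flank + 1L, flank + 1L)
    bad <- !(centers %in% c("S", "T"))
    if (any(bad)) {
      stop("window(s) not centered on S/T: row(s) ",
           paste(head(which(bad), 5L), collapse = ", "))
    }
  }
  structure(
    list(name = name, label = label,
         windows = as.data.frame(windows)[,
           intersect(c("parent_id", "center_position", "center_residue",
                       "window"), names(windows)), drop = FALSE],
         window_length = as.integer(L)),
    class = "peptide_set"
  )
}

#' @export
print.peptide_set <- function(x, ...) {
  cat("<peptide_set> '", x$name, "' (", x$label, "): ",
      nrow(x$windows), " windows of length ", x$window_length, "\n",
      sep = "")
  invisible(x)
}

#' Number of windows in a peptide set
#' @param x A `peptide_set`.
#' @return Integer count.
#' @export
set_size <- function(x) {
  stopifnot(inherits(x, "peptide_set"))
  nrow(x$windows)
}

#' Write peptide windows or a labeled set to TSV
#'
#' Sets gain a `label` column; plain window tables are written as-is.
#' Output is deterministic (no timestamps) and re-readable with
#' [read_windows_tsv()].
#'
#' @param x A `peptide_windows` data frame or a `peptide_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(x, path) {
  if (inherits(x, "peptide_set")) {
    d <- x$windows
    d$label <- x$label
  } else {
    d <- as.data.frame(x)
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read peptide windows from TSV
#'
#' Accepts any tab-separated file with a `window` column; `parent_id`,
#' `center_position`, `center_residue` and `label` are used when present.
#'
#' @param path Input path.
#' @param name Set name for labeled output (defaults to the file name).
#' @return A `peptide_set` when the file has a single-valued `label`
#'   column, otherwise a `peptide_windows` data frame.
#' @export
read_windows_tsv <- function(path, name = basename(path)) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!"window" %in% names(d)) {
    stop("no 'window' column in ", path)
  }
  L <- unique(nchar(d$window))
  if (length(L) != 1L) {
    stop("windows in ", path, " have mixed lengths: ",
         paste(sort(L), collapse = ", "))
  }
  flank <- (L - 1L) %/% 2L
  if (!"center_residue" %in% names(d)) {
    d$center_residue <- substr(d$window, flank + 1L, flank + 1L)
  }
  if (!"center_position" %in% names(d)) {
    d$center_position <- NA_integer_
  } else {
    d$center_position <- as.integer(d$center_position)
  }
  if (!"parent_id" %in% names(d)) d$parent_id <- NA_character_
  windows <- structure(
    d[, c("parent_id", "center_position", "center_residue", "window")],
    window_length = as.integer(L),
    class = c("peptide_windows", "data.frame")
  )
  if ("label" %in% names(d) && length(unique(d$label)) == 1L &&
      d$label[1L] %in% c("positive", "negative")) {
    peptide_set(windows, name = name, label = d$label[1L])
  } else {
    windows
  }
}
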