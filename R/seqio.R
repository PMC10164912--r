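#' Create a protein record
#'
#' A protein record holds an identifier and a one-letter amino-acid sequence,
#' optionally annotated as a subregion of a parent protein (1-based inclusive
#' residue coordinates in the parent's numbering, as in "FUS aa 1-214").
#'
#' @param id Free-text identifier.
#' @param sequence Uppercase string over the 20 canonical one-letter codes
#'   plus `X` (unknown residue). Any other character is rejected.
#' @param parent_id Optional identifier of the parent protein.
#' @param region_start,region_end Optional 1-based inclusive coordinates of
#'   this sequence within the parent. When given, the span length must equal
#'   `nchar(sequence)`.
#' @return An object of class `protein_record`.
#' @examples
#' protein_record("FUS_LCR", "MASNDYTQQATQSYGAYPTQ")
#' @export
protein_record <- function(id, sequence, parent_id = NULL,
                           region_start = NULL, region_end = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) {
    stop("protein record '", id, "': sequence is empty")
  }
  if (sequence != toupper(sequence)) {
    stop("protein record '", id, "': sequence must be uppercase")
  }
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]), AA_INPUT)
  if (length(bad) > 0L) {
    stop("protein record '", id, "': illegal residue character(s) ",
         paste0("'", bad, "'", collapse = ", "),
         " (allowed: 20 canonical amino acids plus 'X')")
  }
  if (xor(is.null(region_start), is.null(region_end))) {
    stop("region_start and region_end must be given together")
  }
  if (!is.null(region_start)) {
    region_start <- as.integer(region_start)
    region_end <- as.integer(region_end)
    if (region_start < 1L) {
      stop("region_start must be >= 1, got ", region_start)
    }
    span <- region_end - region_start + 1L
    if (span != nchar(sequence)) {
      stop("region ", region_start, "-", region_end, " spans ", span,
           " residues but sequence has ", nchar(sequence))
    }
  }
  structure(
    list(id = id, sequence = sequence, parent_id = parent_id,
         region_start = region_start, region_end = region_end),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, sep = "")
  if (!is.null(x$parent_id)) {
    cat(" [", x$parent_id, " aa ", x$region_start, "-", x$region_end, "]",
        sep = "")
  }
  cat("\n  ", nchar(x$sequence), " aa: ",
      if (nchar(x$sequence) > 60) {
        paste0(substr(x$sequence, 1, 57), "...")
      } else {
        x$sequence
      },
      "\n", sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Each entry becomes one [protein_record()]; the header token before the
#' first whitespace is the id. Sequences are uppercased and trailing `*` stop
#' characters are stripped. Residues outside the 21-letter input alphabet
#' (20 canonical plus `X`) are a parse error.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A list of `protein_record` objects, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0L) {
    stop("FASTA file is empty: ", path)
  }
  first <- meaningful[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA at line ", first,
         ": sequence data before any '>' header")
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- toupper(as.character(seqs[[i]]))
    s <- sub("\\*+$", "", s)
    rec <- tryCatch(
      protein_record(ids[i], s),
      error = function(e) {
        stop("FASTA record ", i, " ('", ids[i], "'): ", conditionMessage(e))
      }
    )
    out[[i]] <- rec
  }
  out
}

#' Write protein records to a FASTA file
#'
#' The inverse of [read_fasta()]: ids become headers, sequences are written
#' unwrapped at width 60. Region metadata, when present, is appended to the
#' header as `parent:start-end` after a space (ignored on re-read, which
#' keeps only the first token).
#'
#' @param records A list of `protein_record` objects (a single record is
#'   also accepted).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "protein_record")) records <- list(records)
  stopifnot(length(records) > 0L)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  hdrs <- vapply(records, function(r) {
    if (!is.null(r$parent_id)) {
      paste0(r$id, " ", r$parent_id, ":", r$region_start, "-", r$region_end)
    } else {
      r$id
    }
  }, character(1))
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- hdrs
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Extract a residue span from a protein record
#'
#' Coordinates are 1-based inclusive in the record's own sequence. The
#' returned record carries region metadata so that window centers and
#' mutation positions can be reported in the parent protein's numbering.
#' Slicing an already-sliced region composes: coordinates chain back to the
#' original parent.
#'
#' @param protein A `protein_record`.
#' @param start,end 1-based inclusive slice coordinates,
#'   `1 <= start <= end <= nchar(sequence)`.
#' @return A `protein_record` of length `end - start + 1`.
#' @examples
#' p <- protein_record("x", "MKTAYS")
#' slice_region(p, 2, 4)  # "KTA", region 2-4 of "x"
#' @export
slice_region <- function(protein, start, end) {
  stopifnot(inherits(protein, "protein_record"))
  start <- as.integer(start)
  end <- as.integer(end)
  n <- nchar(protein$sequence)
  if (start < 1L || end < start || end > n) {
    stop("slice ", start, "-", end, " out of range for '", protein$id,
         "' (sequence length ", n, ")")
  }
  if (!is.null(protein$region_start)) {
    parent <- protein$parent_id
    new_start <- protein$region_start + start - 1L
    new_end <- protein$region_start + end - 1L
  } else {
    parent <- protein$id
    new_start <- start
    new_end <- end
  }
  protein_record(
    id = paste0(protein$id, "_", new_start, "-", new_end),
    sequence = substr(protein$sequence, start, end),
    parent_id = parent, region_start = new_start, region_end = new_end
  )
}

#' Parse point mutations from compact "G34A" notation
#'
#' Each token is wild-type residue, 1-based position, mutant residue, e.g.
#' `"Q31T"`. Tokens may be supplied as a character vector or as one string
#' separated by commas and/or whitespace.
#'
#' @param x Character vector of mutation tokens, or a single string of
#'   comma/whitespace-separated tokens.
#' @return A data frame of class `point_mutations` with columns `wt`
#'   (character), `position` (integer), `mut` (character).
#' @examples
#' parse_mutations("Q31T, G34A Q36A")
#' @export
parse_mutations <- function(x) {
  stopifnot(is.character(x))
  tokens <- unlist(strsplit(x, "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    return(structure(
      data.frame(wt = character(), position = integer(), mut = character(),
                 stringsAsFactors = FALSE),
      class = c("point_mutations", "data.frame")
    ))
  }
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Z])$", tokens))
  bad <- tokens[vapply(m, length, integer(1)) == 0L]
  if (length(bad) > 0L) {
    stop("cannot parse mutation token(s): ",
         paste0("'", bad, "'", collapse = ", "),
         " (expected e.g. 'G34A')")
  }
  wt <- vapply(m, `[`, character(1), 2L)
  pos <- as.integer(vapply(m, `[`, character(1), 3L))
  mut <- vapply(m, `[`, character(1), 4L)
  bad_aa <- setdiff(unique(c(wt, mut)), AA_CANONICAL)
  if (length(bad_aa) > 0L) {
    stop("mutation residue(s) outside the canonical alphabet: ",
         paste(bad_aa, collapse = ", "))
  }
  same <- wt == mut
  if (any(same)) {
    stop("wild-type and mutant residue identical in: ",
         paste(tokens[same], collapse = ", "))
  }
  structure(
    data.frame(wt = wt, position = pos, mut = mut, stringsAsFactors = FALSE),
    class = c("point_mutations", "data.frame")
  )
}

#' Format point mutations back to compact notation
#'
#' @param mutations A `point_mutations` data frame from [parse_mutations()].
#' @return Character vector of tokens like `"G34A"`.
#' @export
format_mutations <- function(mutations) {
  paste0(mutations$wt, mutations$position, mutations$mut)
}

#' Apply point mutations to a protein record
#'
#' Positions are interpreted in the record's own numbering; when region
#' metadata is present they are interpreted in the parent's numbering (so
#' published mutation names like "G34A" apply directly to a sliced region).
#' The wild-type residue at each position must match, duplicated positions
#' are rejected, and the input record is never modified.
#'
#' @param protein A `protein_record`.
#' @param mutations A `point_mutations` data frame (or something
#'   [parse_mutations()] accepts).
#' @return A new `protein_record` with all substitutions applied and
#'   `_mut` appended to the id (empty mutation lists return an identical
#'   sequence under the original id).
#' @examples
#' p <- protein_record("p", "GQG")
#' apply_mutations(p, parse_mutations(c("G1A", "Q2T")))$sequence  # "ATG"
#' @export
apply_mutations <- function(protein, mutations) {
  stopifnot(inherits(protein, "protein_record"))
  if (!inherits(mutations, "point_mutations")) {
    mutations <- parse_mutations(mutations)
  }
  if (nrow(mutations) == 0L) {
    return(protein)
  }
  if (anyDuplicated(mutations$position)) {
    dup <- unique(mutations$position[duplicated(mutations$position)])
    stop("duplicate mutation position(s): ", paste(dup, collapse = ", "))
  }
  offset <- if (!is.null(protein$region_start)) protein$region_start - 1L else 0L
  local <- mutations$position - offset
  n <- nchar(protein$sequence)
  out_of_range <- local < 1L | local > n
  if (any(out_of_range)) {
    stop("mutation position(s) outside the record: ",
         paste(format_mutations(mutations[out_of_range, , drop = FALSE]),
               collapse = ", "))
  }
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  found <- chars[local]
  mismatch <- found != mutations$wt
  if (any(mismatch)) {
    i <- which(mismatch)[1L]
    stop("wild-type mismatch at position ", mutations$position[i],
         ": expected '", mutations$wt[i], "', found '", found[i], "'")
  }
  chars[local] <- mutations$mut
  protein_record(
    id = paste0(protein$id, "_mut"),
    sequence = paste(chars, collapse = ""),
    parent_id = protein$parent_id,
    region_start = protein$region_start,
    region_end = protein$region_end
  )
}

#' Published compositional mutation sets for the FUS low-complexity region
#'
#' Six glycosylation-enhancing mutant constructs of the FUS N-terminal
#' low-complexity region (aa 1-214), designed purely on amino-acid
#' composition: glycines to alanine/threonine/proline, glutamines to
#' threonine/proline, serines to threonine, one aspartate to threonine.
#' Mut-D combines A+B, Mut-E combines B+C, and Mut-F combines A+B+C
#' (23 substitutions). Positions are in FUS full-length numbering.
#'
#' @return A named list of `point_mutations` data frames
#'   (`mut_A` ... `mut_F`).
#' @export
fus_mutation_sets <- function() {
  a <- parse_mutations(c("Q31T", "G34A", "Q36A", "G40T", "Q43P", "D46T",
                         "G49A"))
  b <- parse_mutations(c("G67A", "Q69T", "G74A", "G76P", "G79A", "G80P",
                         "G82A", "S83T", "Q85P"))
  c_ <- parse_mutations(c("G99A", "G101T", "S107T", "S108T", "G111A",
                          "G114A", "S115T"))
  combine <- function(...) {
    d <- do.call(rbind, list(...))
    d <- d[order(d$position), , drop = FALSE]
    rownames(d) <- NULL
    structure(d, class = c("point_mutations", "data.frame"))
  }
  list(
    mut_A = a, mut_B = b, mut_C = c_,
    mut_D = combine(a, b),
    mut_E = combine(b, c_),
    mut_F = combine(a, b, c_)
  )
}

#' Registry of named IDR regions used in training and evaluation
#'
#' The regions whose S/T-centered peptides form the experimentally verified
#' negative set (TAF15, CFTR, DDX4, FMRP, SARA), the FET low-complexity
#' regions, the four CBP intrinsically disordered test segments, Lamin A and
#' the RNA Pol II RPB1 C-terminal region. Only the accessions and residue
#' spans are bundled; sequences must be supplied by the user (e.g. from a
#' UniProt FASTA via [registry_sequences()]) — operations needing a sequence
#' fail cleanly when it is absent. Lamin A's span is recorded as full length;
#' the isoform numbering used by published site lists is not resolved here.
#'
#' @return A data frame with columns `name`, `parent_id` (UniProt
#'   accession), `organism`, `region_start`, `region_end` (NA = full
#'   length), `sequence` (NA until attached).
#' @export
fixture_regions <- function() {
  data.frame(
    name = c("EWS", "FUS", "TAF15", "SARA", "DDX4", "CFTR", "FMRP",
             "CBP_ID1", "CBP_ID3", "CBP_ID4", "CBP_ID5", "LaminA",
             "RPB1_CTD"),
    parent_id = c("Q01844", "P35637", "Q92804", "O95405", "Q61496",
                  "P13569", "Q06787", "Q92793", "Q92793", "Q92793",
                  "Q92793", "P02545", "P24928"),
    organism = c("human", "human", "human", "human", "mouse", "human",
                 "human", "human", "human", "human", "human", "human",
                 "human"),
    region_start = c(1L, 1L, 1L, 766L, 1L, 654L, 445L, 1L, 676L, 1851L,
                     2124L, 1L, 1586L),
    region_end = c(264L, 214L, 210L, 822L, 236L, 838L, 632L, 344L, 1080L,
                   2057L, 2442L, NA, 1970L),
    sequence = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Attach full-length sequences to the fixture registry
#'
#' Matches FASTA records to registry rows by accession (the FASTA id must
#' contain the accession, as UniProt headers do) and stores the sliced
#' region sequence in the `sequence` column.
#'
#' @param registry A data frame from [fixture_regions()].
#' @param records A list of `protein_record`s holding full-length parent
#'   sequences.
#' @return The registry with `sequence` filled in where a parent was found.
#' @export
registry_sequences <- function(registry, records) {
  ids <- vapply(records, function(r) r$id, character(1))
  for (i in seq_len(nrow(registry))) {
    hit <- which(grepl(registry$parent_id[i], ids, fixed = TRUE))
    if (length(hit) == 0L) next
    rec <- records[[hit[1L]]]
    end <- registry$region_end[i]
    if (is.na(end)) end <- nchar(rec$sequence)
    if (end > nchar(rec$sequence)) {
      warning("registry region '", registry$name[i],
              "' extends past the supplied sequence; skipped")
      next
    }
    registry$sequence[i] <-
      substr(rec$sequence, registry$region_start[i], end)
  }
  registry
}

#' Turn a registry row into a protein record
#'
#' @param registry A data frame from [fixture_regions()], with sequences
#'   attached.
#' @param name Region name (e.g. `"TAF15"`).
#' @return A `protein_record` with parent/region metadata.
#' @export
registry_record <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) {
    stop("unknown registry region: '", name, "'")
  }
  if (is.na(registry$sequence[i])) {
    stop("registry region '", name, "' has no sequence attached; ",
         "supply one with registry_sequences()")
  }
  end <- registry$region_end[i]
  if (is.na(end)) {
    end <- registry$region_start[i] + nchar(registry$sequence[i]) - 1L
  }
  protein_record(
    id = registry$name[i],
    sequence = registry$sequence[i],
    parent_id = registry$parent_id[i],
    region_start = registry$region_start[i],
    region_end = end
  )
}
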