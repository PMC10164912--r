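# shared fixtures: built in code, no files on disk beyond tempfiles

# L=5 matrix scoring 1 for 'A' at every offset, 0 elsewhere
a_matrix <- function() {
  m <- scoring_matrix(5, name = "A-only")
  m["A", ] <- 1
  m
}

random_protein <- function(n, seed, id = "rnd") {
  set.seed(seed)
  protein_record(id, paste(sample(c(AA_CANONICAL(), "X"), n, replace = TRUE),
                           collapse = ""))
}

# the package keeps these internal; re-derive them here so tests stay
# independent of the implementation's constants
AA_CANONICAL <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

count_st <- function(seq) {
  sum(strsplit(seq, "")[[1]] %in% c("S", "T"))
}

write_temp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(mapply(function(id, s) c(paste0(">", id), s),
                         ids, seqs, SIMPLIFY = FALSE))
  writeLines(lines, path)
  path
}

# small planted-bias training sets for optimizer tests
small_training_sets <- function(n = 60, length = 9, seed = 42) {
  specs <- planted_specs(0.5)
  list(
    positive = generate_set(specs$positive, n, length, seed = seed,
                            label = "positive"),
    negative = generate_set(specs$negative, n, length, seed = seed + 1,
                            label = "negative")
  )
}
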