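test_that("FASTA reading preserves order, ids and sequences", {
  path <- write_temp_fasta(c(p = "GGSGG"))
  recs <- read_fasta(path)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$id, "p")
  expect_equal(recs[[1]]$sequence, "GGSGG")

  path2 <- write_temp_fasta(c(one = "GGS", two = "GGSGG"))
  recs2 <- read_fasta(path2)
  expect_length(recs2, 2)
  expect_equal(vapply(recs2, `[[`, "", "id"), c("one", "two"))
  expect_equal(nchar(vapply(recs2, `[[`, "", "sequence")), c(3L, 5L))
})

test_that("FASTA reading lowercases, strips stops, keeps first header token", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|NAME some description", "ggsG", "Gtt*"), path)
  recs <- read_fasta(path)
  expect_equal(recs[[1]]$id, "sp|P1|NAME")
  expect_equal(recs[[1]]$sequence, "GGSGGTT")
})

test_that("malformed FASTA and illegal residues are parse errors", {
  bad <- tempfile(fileext = ".fasta")
  writeLines(c("GGSGG", ">p", "GGS"), bad)
  expect_error(read_fasta(bad), "line 1")

  badres <- write_temp_fasta(c(p = "GGBSG"))
  expect_error(read_fasta(badres), "B")

  expect_error(protein_record("p", ""), "empty")
  expect_error(protein_record("p", "ggs"), "uppercase")
  # X is accepted as an unknown residue
  expect_silent(protein_record("p", "GXS"))
})

test_that("FASTA write-then-read round-trips ids and sequences exactly", {
  set.seed(11)
  recs <- lapply(1:4, function(i) {
    protein_record(paste0("seq", i),
                   paste(sample(AA_CANONICAL(), 50 + i * 37, replace = TRUE),
                         collapse = ""))
  })
  path <- tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(vapply(back, `[[`, "", "id"),
               vapply(recs, `[[`, "", "id"))
  expect_equal(vapply(back, `[[`, "", "sequence"),
               vapply(recs, `[[`, "", "sequence"))
})

test_that("slice_region slices inclusively and records provenance", {
  p <- protein_record("x", "MKYDE")
  s <- slice_region(p, 2, 4)
  expect_equal(s$sequence, "KYD")
  expect_equal(s$parent_id, "x")
  expect_equal(s$region_start, 2L)
  expect_equal(s$region_end, 4L)

  ident <- slice_region(p, 1, nchar(p$sequence))
  expect_equal(ident$sequence, p$sequence)
  expect_equal(ident$region_start, 1L)

  expect_error(slice_region(p, 3, 9), "out of range")
})

test_that("nested slices compose back to original coordinates", {
  set.seed(3)
  p <- protein_record("parent",
                      paste(sample(AA_CANONICAL(), 80, replace = TRUE),
                            collapse = ""))
  outer <- slice_region(p, 11, 60)
  inner <- slice_region(outer, 5, 20)
  direct <- slice_region(p, 11 + 5 - 1, 11 + 20 - 1)
  expect_equal(inner$sequence, direct$sequence)
  expect_equal(inner$region_start, direct$region_start)
  expect_equal(inner$region_end, direct$region_end)
  expect_equal(inner$parent_id, "parent")
})

test_that("mutation notation parses and serializes", {
  m <- parse_mutations("Q31T, G34A  Q36A")
  expect_equal(nrow(m), 3)
  expect_equal(m$wt, c("Q", "G", "Q"))
  expect_equal(m$position, c(31L, 34L, 36L))
  expect_equal(format_mutations(m), c("Q31T", "G34A", "Q36A"))
  expect_error(parse_mutations("G34G"), "identical")
  expect_error(parse_mutations("34A"), "parse")
  expect_equal(nrow(parse_mutations(character())), 0)
})

test_that("apply_mutations substitutes, validates and leaves input intact", {
  p <- protein_record("p", "GQG")
  out <- apply_mutations(p, parse_mutations(c("G1A", "Q2T")))
  expect_equal(out$sequence, "ATG")
  expect_equal(p$sequence, "GQG")

  expect_identical(apply_mutations(p, parse_mutations(character()))$sequence,
                   "GQG")
  expect_error(apply_mutations(p, parse_mutations("G2A")),
               "position 2.*expected 'G'.*found 'Q'")
  expect_error(apply_mutations(p, parse_mutations(c("G1A", "G1T"))),
               "duplicate")
})

test_that("apply_mutations is order-independent for distinct positions", {
  set.seed(7)
  p <- protein_record("p", paste(rep("G", 30), collapse = ""))
  muts <- parse_mutations(c("G3A", "G10T", "G17P", "G25V"))
  for (i in 1:5) {
    perm <- muts[sample(nrow(muts)), , drop = FALSE]
    class(perm) <- class(muts)
    expect_equal(apply_mutations(p, perm)$sequence,
                 apply_mutations(p, muts)$sequence)
  }
})

test_that("mutations use parent numbering on sliced regions", {
  p <- protein_record("p", "AAAGQGAAA")
  region <- slice_region(p, 4, 6)  # "GQG", parent positions 4-6
  out <- apply_mutations(region, parse_mutations("Q5T"))
  expect_equal(out$sequence, "GTG")
  expect_error(apply_mutations(region, parse_mutations("Q2T")),
               "outside")
})

test_that("combined FUS mutant lists have the published sizes", {
  sets <- fus_mutation_sets()
  expect_equal(nrow(sets$mut_A), 7)
  expect_equal(nrow(sets$mut_B), 9)
  expect_equal(nrow(sets$mut_C), 7)
  expect_equal(nrow(sets$mut_D), 16)
  expect_equal(nrow(sets$mut_E), 16)
  expect_equal(nrow(sets$mut_F), 23)

  # applying the combined list to a compatible synthetic parent changes
  # exactly 23 positions
  chars <- rep("Y", 214)
  chars[sets$mut_F$position] <- sets$mut_F$wt
  parent <- protein_record("synthetic_fus_stand_in",
                           paste(chars, collapse = ""))
  mutated <- apply_mutations(parent, sets$mut_F)
  diffs <- sum(strsplit(parent$sequence, "")[[1]] !=
                 strsplit(mutated$sequence, "")[[1]])
  expect_equal(diffs, 23)
})

test_that("fixture registry records regions but not fabricated sequences", {
  reg <- fixture_regions()
  expect_true(all(c("TAF15", "CFTR", "DDX4", "FMRP", "SARA",
                    "CBP_ID1", "LaminA") %in% reg$name))
  expect_true(all(is.na(reg$sequence)))
  expect_equal(reg$region_start[reg$name == "SARA"], 766L)
  expect_equal(reg$region_end[reg$name == "DDX4"], 236L)
  expect_error(registry_record(reg, "TAF15"), "no sequence attached")
  expect_error(registry_record(reg, "nope"), "unknown")
})

test_that("registry_sequences attaches and slices parent sequences", {
  reg <- fixture_regions()
  set.seed(5)
  full <- protein_record("sp|Q92804|TAF15_HUMAN",
                         paste(sample(AA_CANONICAL(), 592, replace = TRUE),
                               collapse = ""))
  reg <- registry_sequences(reg, list(full))
  expect_false(is.na(reg$sequence[reg$name == "TAF15"]))
  rec <- registry_record(reg, "TAF15")
  expect_equal(nchar(rec$sequence), 210)
  expect_equal(rec$sequence, substr(full$sequence, 1, 210))
  expect_equal(rec$region_start, 1L)
})
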