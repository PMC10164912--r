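test_that("positional frequencies are one-hot for a single window", {
  f <- positional_frequency(data.frame(window = "AST"))
  expect_equal(f["A", "-1"], 1)
  expect_equal(f["S", "0"], 1)
  expect_equal(f["T", "1"], 1)
  expect_equal(sum(f[, "-1"]), 1)
})

test_that("positional frequencies count scorable residues per offset", {
  f <- positional_frequency(data.frame(window = c("AST", "GTV")))
  expect_equal(f["A", "-1"], 0.5)
  expect_equal(f["G", "-1"], 0.5)
  # the center column is all S/T by construction
  expect_equal(f["S", "0"] + f["T", "0"], 1)
})

test_that("frequency columns normalize and ignore pads and X", {
  set.seed(33)
  s <- generate_set(planted_specs()$positive, 200, 11, seed = 9,
                    label = "positive")
  f <- positional_frequency(s)
  expect_true(all(abs(colSums(f) - 1) < 1e-9))

  # duplicating the set leaves frequencies unchanged
  dup <- peptide_set(rbind(s$windows, s$windows), "dup", "positive")
  expect_equal(unclass(positional_frequency(dup))[, ],
               unclass(f)[, ])

  # pads and X are excluded from numerator and denominator
  fx <- positional_frequency(data.frame(window = c("-XSAA", "AGSAA")))
  expect_equal(fx["A", "-2"], 1)     # only one scorable residue there
  expect_equal(fx["G", "-1"], 1)
  expect_equal(attr(fx, "counts")[1], 1)

  expect_error(positional_frequency(data.frame(window = character())),
               "empty")
})

test_that("background frequencies pool counts and normalize", {
  expect_equal(background_from_sequences(
    list(protein_record("a", "AAAA")))[["A"]], 1)
  bg <- background_from_sequences(list(protein_record("a", "AG"),
                                       protein_record("b", "GA")))
  expect_equal(bg[["A"]], 0.5)
  expect_equal(bg[["G"]], 0.5)

  set.seed(12)
  seqs <- lapply(1:3, function(i) {
    protein_record(paste0("s", i),
                   paste(sample(AA_CANONICAL(), 100, replace = TRUE),
                         collapse = ""))
  })
  expect_lt(abs(sum(background_from_sequences(seqs)) - 1), 1e-12)
  expect_error(background_from_sequences(list()), "at least one")
})

test_that("composition reports per-residue fractions", {
  expect_equal(composition(protein_record("p", "GGS")),
               c(G = 2 / 3, S = 1 / 3))
  expect_equal(composition(protein_record("p", "M")), c(M = 1))
  a <- composition(protein_record("p", "GASGT"))
  b <- composition(protein_record("p", "TGSAG"))
  expect_equal(a[sort(names(a))], b[sort(names(b))])
})

test_that("compositional bias equals the exact binomial upper tail", {
  bg <- stats::setNames(rep(1 / 20, 20), AA_CANONICAL())

  # brute-force oracle: direct summation of the binomial mass
  seqs <- list(protein_record("p", "GGGGGAAAAA"))
  bias <- compositional_bias(seqs, bg)
  g <- bias[bias$residue == "G", ]
  expect_equal(g$observed_count, 5)
  expect_equal(g$total_residues, 10)
  expect_equal(g$p_bias, sum(dbinom(5:10, 10, 1 / 20)), tolerance = 1e-12)

  # a residue observed zero times has p_bias exactly 1
  expect_equal(bias$p_bias[bias$residue == "W"], 1)

  # oracle with the uneven background from the worked 5-G example
  bg2 <- bg
  bg2[] <- (1 - 0.1) / 19
  bg2["G"] <- 0.1
  b2 <- compositional_bias(seqs, bg2)
  expect_equal(b2$p_bias[b2$residue == "G"],
               sum(dbinom(5:10, 10, 0.1)), tolerance = 1e-12)
})

test_that("log-space tails agree with direct summation to 1e-10 relative", {
  bg <- stats::setNames(rep(1 / 20, 20), AA_CANONICAL())
  set.seed(40)
  for (rep in 1:10) {
    n <- sample(20:400, 1)
    seqs <- list(protein_record("p", paste(
      sample(AA_CANONICAL(), n, replace = TRUE,
             prob = c(rep(1, 10), rep(3, 10))), collapse = "")))
    bias <- compositional_bias(seqs, bg)
    direct <- vapply(seq_len(nrow(bias)), function(i) {
      k <- bias$observed_count[i]
      sum(dbinom(k:bias$total_residues[i], bias$total_residues[i],
                 bias$background_frequency[i]))
    }, numeric(1))
    ok <- direct > 0
    expect_true(all(abs(bias$p_bias[ok] - direct[ok]) <=
                      1e-10 * direct[ok]))
  }
})

test_that("bias p-values decrease as the observed count grows", {
  bg <- stats::setNames(rep(1 / 20, 20), AA_CANONICAL())
  p_at <- vapply(c(2, 5, 8, 10), function(k) {
    s <- paste(c(rep("G", k), rep("A", 10 - k)), collapse = "")
    b <- compositional_bias(list(protein_record("p", s)), bg)
    b$p_bias[b$residue == "G"]
  }, numeric(1))
  expect_true(all(diff(p_at) < 0))
})

test_that("extreme enrichment yields representable tiny p-values", {
  bg <- stats::setNames(rep(1 / 20, 20), AA_CANONICAL())
  s <- paste(rep("G", 2000), collapse = "")
  b <- compositional_bias(list(protein_record("p", s)), bg)
  g <- b[b$residue == "G", ]
  expect_true(g$p_bias >= 0 && g$p_bias < 1e-200)
  expect_lt(g$log10_p, -260)
})

test_that("invalid backgrounds are rejected", {
  seqs <- list(protein_record("p", "GA"))
  bad <- stats::setNames(rep(1 / 20, 19), AA_CANONICAL()[-1])
  expect_error(compositional_bias(seqs, bad), "named over the 20")
  unnorm <- stats::setNames(rep(1 / 10, 20), AA_CANONICAL())
  expect_error(compositional_bias(seqs, unnorm), "sum to 1")
  zero <- stats::setNames(c(0, rep(1 / 19, 19)), AA_CANONICAL())
  expect_error(compositional_bias(seqs, zero), "positive")
})

test_that("confusion metrics match hand-built tables", {
  perfect <- evaluate_predictions(1:4, 1:4, 1:4)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, NA_real_)  # no negatives exist
  expect_equal(perfect$accuracy, 1)

  cs <- evaluate_predictions(c(2, 3), 2, 1:4)
  expect_equal(c(cs$tp, cs$fp, cs$fn, cs$tn), c(1, 1, 0, 2))
  expect_equal(cs$sensitivity, 1)
  expect_equal(cs$specificity, 2 / 3)
  expect_equal(cs$accuracy, 3 / 4)
  expect_equal(cs$precision, 1 / 2)
  d <- as.data.frame(cs)
  expect_equal(d$specificity_pct, 67)

  expect_error(evaluate_predictions(c(2, 9), 2, 1:4), "9")
})

test_that("confusion counts always partition the site set", {
  set.seed(50)
  for (rep in 1:10) {
    all_sites <- sort(sample(1:100, 30))
    known <- sample(all_sites, 8)
    predicted <- sample(all_sites, 12)
    cs <- evaluate_predictions(predicted, known, all_sites)
    expect_equal(cs$tp + cs$fp + cs$tn + cs$fn, length(all_sites))
    expect_true(all(c(cs$tp, cs$fp, cs$tn, cs$fn) >= 0))
  }
})

test_that("pearson matches the textbook formula", {
  expect_equal(pearson(1:5, 1:5)$r, 1)
  expect_equal(pearson(1:5, -(1:5))$r, -1)

  x <- c(1, 2, 3, 4)
  y <- c(2, 4, 5, 4)
  # textbook oracle
  r0 <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t0 <- r0 * sqrt(2) / sqrt(1 - r0^2)
  p0 <- 2 * stats::pt(-abs(t0), df = 2)
  got <- pearson(x, y)
  expect_equal(got$r, r0, tolerance = 1e-12)
  expect_equal(got$p, p0, tolerance = 1e-12)

  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(c(1, 1, 1), 1:3), "variance")
  expect_error(pearson(1:3, 1:4), "equal length")
})
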