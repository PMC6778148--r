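test_that("degenerate codon expansion enumerates equal-weight codons", {
  nnk <- expandDegenerateCodon("NNK")
  expect_equal(nrow(nnk), 32)
  expect_true(all(abs(nnk$probability - 1 / 32) < 1e-15))
  expect_equal(sum(nnk$probability), 1)
  expect_true(all(substr(nnk$codon, 3, 3) %in% c("G", "T")))

  expect_equal(expandDegenerateCodon("ATG"),
               data.frame(codon = "ATG", probability = 1))
  expect_equal(nrow(expandDegenerateCodon("NNN")), 64)
  expect_error(expandDegenerateCodon("NXK"), "IUPAC")
  expect_error(expandDegenerateCodon("NN"), "three")

  # expansion size = product of per-position degeneracies, probs sum to 1
  degen <- c(A = 1, C = 1, G = 1, T = 1, R = 2, Y = 2, S = 2, W = 2, K = 2,
             M = 2, B = 3, D = 3, H = 3, V = 3, N = 4)
  set.seed(11)
  for (i in 1:20) {
    cd <- paste(sample(names(degen), 3, replace = TRUE), collapse = "")
    e <- expandDegenerateCodon(cd)
    expect_equal(nrow(e), prod(degen[strsplit(cd, "")[[1]]]))
    expect_equal(sum(e$probability), 1, tolerance = 1e-12)
  }
})

test_that("NNK amino-acid distribution matches a direct genetic-code tally", {
  d <- aaDistribution("NNK")
  expect_equal(sum(d), 1, tolerance = 1e-12)
  # oracle: tally the 32 codons against the standard code lookup table
  gc <- Biostrings::GENETIC_CODE
  codons <- expandDegenerateCodon("NNK")$codon
  oracle <- table(unname(gc[codons])) / length(codons)
  expect_equal(unname(d["*"]), 1 / 32)          # amber TAG only
  expect_equal(unname(d["W"]), 1 / 32)          # TGG only
  for (aa in names(oracle))
    expect_equal(unname(d[aa]), unname(as.numeric(oracle[aa])))
  expect_equal(aaDistribution("TGG"), c(W = 1))
  # amber suppression reassigns the stop mass to Gln
  ds <- aaDistribution("NNK", suppressAmber = TRUE)
  expect_false("*" %in% names(ds))
  expect_equal(unname(ds["Q"]), 2 / 32)
  # marginals sum to 1 for arbitrary IUPAC codons
  set.seed(7)
  for (i in 1:15) {
    cd <- paste(sample(c("N", "K", "R", "Y", "B", "A", "C", "G", "T"), 3,
                       replace = TRUE), collapse = "")
    expect_equal(sum(aaDistribution(cd)), 1, tolerance = 1e-12)
  }
})

test_that("oligo sets carry one oligo per loop length with intact flanks", {
  sc <- SCAFFOLD
  bc <- designLoopOligos(loopDesign("BC", 25, c(5, 9)), sc)
  fg <- designLoopOligos(loopDesign("FG", 75, c(7, 13)), sc)
  expect_equal(nrow(bc), 5)   # published BC oligo count
  expect_equal(nrow(fg), 7)   # published FG oligo count
  expect_equal(nrow(designLoopOligos(loopDesign("BC", 25, c(3, 3)), sc)), 1)
  # each oligo is flank5 + L degenerate codons + flank3, in frame
  for (k in seq_len(nrow(bc))) {
    L <- bc$n_random_codons[k]
    expect_equal(nchar(bc$oligo[k]), 6 * 3 + 3 * L + 6 * 3)
    core <- substr(bc$oligo[k], 19, 18 + 3 * L)
    expect_equal(core, strrep("NNK", L))
    expect_true(grepl(substr(bc$oligo[k], 1, 18), sc@dna, fixed = TRUE))
  }
  # property: count = max - min + 1 over random ranges
  set.seed(3)
  for (i in 1:10) {
    lo <- sample(1:6, 1); hi <- lo + sample(0:6, 1)
    n <- nrow(designLoopOligos(loopDesign("BC", 25, c(lo, hi)), sc))
    expect_equal(n, hi - lo + 1)
  }
  expect_error(designLoopOligos(loopDesign("BC", 25, c(5, 9)), sc,
                                flankLen = 40), "outside")
})

test_that("theoretical diversity matches exact combinatorics", {
  sc <- SCAFFOLD
  one <- libraryDesign(sc, list(loopDesign("BC", 25, c(1, 1), "NNK")))
  expect_equal(theoreticalDiversity(one, "protein", stopFree = TRUE)$count,
               "20")
  two <- libraryDesign(sc, list(loopDesign("BC", 25, c(2, 2), "NNK")))
  expect_equal(theoreticalDiversity(two, "dna")$count, "1024")

  full <- fn3LibraryDesign(sc)
  div <- theoreticalDiversity(full, "dna")
  # oracle (a): log10 of sum(32^5..9) * sum(32^7..13) in log space
  log_oracle <- log10(sum(32^(5:9))) + log10(sum(32^(7:13)))
  expect_equal(div$log10, log_oracle, tolerance = 1e-12)
  # oracle (b): exact residue check of the decimal string via modular
  # arithmetic under two primes
  str_mod <- function(s, p) {
    r <- 0
    for (ch in strsplit(s, "")[[1]]) r <- (r * 10 + as.integer(ch)) %% p
    r
  }
  pow_mod <- function(b, e, p) {
    r <- 1; b <- b %% p
    while (e > 0) {
      if (e %% 2 == 1) r <- (r * b) %% p
      b <- (b * b) %% p
      e <- e %/% 2
    }
    r
  }
  for (p in c(32749, 65521)) {
    oracle <- (sum(vapply(5:9, function(l) pow_mod(32, l, p), numeric(1))) %%
                 p) *
      (sum(vapply(7:13, function(l) pow_mod(32, l, p), numeric(1))) %% p) %% p
    expect_equal(str_mod(div$count, p), oracle %% p)
  }
  # protein-level stop-free diversity never exceeds DNA diversity
  for (d in list(one, two, full)) {
    expect_lte(theoreticalDiversity(d, "protein", stopFree = TRUE)$log10,
               theoreticalDiversity(d, "dna")$log10)
  }
  expect_error(libraryDesign(sc, list()), "at least one")
})

test_that("stop-free fraction multiplies per-codon amber survival", {
  sc <- SCAFFOLD
  one <- libraryDesign(sc, list(loopDesign("BC", 25, c(1, 1), "NNK")))
  expect_equal(stopFreeFraction(one), 31 / 32)
  fixed <- libraryDesign(sc, list(loopDesign("BC", 25, c(5, 5), "NNK"),
                                  loopDesign("FG", 75, c(7, 7), "NNK")))
  expect_equal(stopFreeFraction(fixed), (31 / 32)^12)
  nostop <- libraryDesign(sc, list(loopDesign("BC", 25, c(4, 4), "ATG")))
  expect_equal(stopFreeFraction(nostop), 1.0)
  # equal-weight length averaging: explicit enumeration oracle
  rng <- libraryDesign(sc, list(loopDesign("BC", 25, c(5, 9), "NNK")))
  expect_equal(stopFreeFraction(rng), mean((31 / 32)^(5:9)),
               tolerance = 1e-15)
})

test_that("collision bound solves the exact birthday product", {
  expect_equal(collisionDiversityBound(2, 0, 0.5), 2)
  expect_equal(collisionDiversityBound(96, 96 * 95 / 2, 0.95), 1)
  expect_error(collisionDiversityBound(96, 0, 1.5), "confidence")

  D <- collisionDiversityBound(96, 0, 0.95)
  p_no_collision <- function(D) exp(sum(log1p(-(0:95) / D)))
  expect_gte(p_no_collision(D), 0.05)       # bound is attained
  expect_lt(p_no_collision(D - 1), 0.05)    # and is the smallest such D
  # monotone non-decreasing in the sample size at zero collisions
  bounds <- vapply(c(10, 30, 96, 200), collisionDiversityBound,
                   numeric(1), nCollisions = 0, confidence = 0.95)
  expect_true(all(diff(bounds) >= 0))
  # collisions shrink the bound
  expect_lt(collisionDiversityBound(96, 5, 0.95),
            collisionDiversityBound(96, 0, 0.95))
})

test_that("design and oligo serialization round-trip standard formats", {
  tmp <- withr::local_tempdir()
  sc <- SCAFFOLD
  path <- file.path(tmp, "scaffold.json")
  writeScaffoldTemplate(sc, path)
  back <- readScaffoldTemplate(path)
  expect_equal(back@dna, sc@dna)
  expect_equal(back@loops, sc@loops)
  oligos <- designLoopOligos(loopDesign("BC", 25, c(5, 9)), sc)
  fa <- file.path(tmp, "oligos.fasta")
  writeOligoFasta(oligos, fa)
  rt <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(rt[[1]]), oligos$oligo[1])  # IUPAC preserved
  writeLibraryDesign(fn3LibraryDesign(sc), file.path(tmp, "design.json"))
  js <- jsonlite::read_json(file.path(tmp, "design.json"),
                            simplifyVector = TRUE)
  expect_equal(js$loops$codon, c("NNK", "NNK"))
})
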