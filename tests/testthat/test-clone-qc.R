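test_that("exact scaffold fragments orient and frame on both strands", {
  sc <- SCAFFOLD
  of <- orientAndFrame(sc@dna, sc)
  expect_true(of$ok)
  expect_equal(of$orientation, "forward")
  expect_equal(of$frameOffset, sc@frameOffset %% 3L)

  rc <- orientAndFrame(revcomp(sc@dna), sc)
  expect_true(rc$ok)
  expect_equal(rc$orientation, "reverse")
  expect_equal(rc$frameOffset, sc@frameOffset %% 3L)

  # a 5'-truncated fragment changes the frame offset consistently
  frag <- substr(sc@dna, 8, nchar(sc@dna))
  off <- orientAndFrame(frag, sc)
  expect_true(off$ok)
  expect_equal(off$frameOffset, (sc@frameOffset - 7L) %% 3L)

  expect_false(orientAndFrame(strrep("ACGT", 40), sc)$ok)
})

test_that("frame recovery under truncation and errors matches a six-frame oracle", {
  sc <- SCAFFOLD
  set.seed(7)
  for (i in 1:10) {
    read <- make_clone(bc = strrep("GCT", 6), fg = strrep("ACC", 9))
    read <- substr(read, sample(1:5, 1), nchar(read))     # 5' truncation
    v <- strsplit(read, "")[[1]]
    hit <- which(runif(length(v)) < 0.01)                 # ~1% substitutions
    for (k in hit) v[k] <- sample(setdiff(c("A", "C", "G", "T"), v[k]), 1)
    read <- paste(v, collapse = "")
    if (runif(1) < 0.5) read <- revcomp(read)
    of <- orientAndFrame(read, sc)
    expect_true(of$ok)
    # oracle: translate all six frames, score against the scaffold protein
    # with an independent aligner, take the best
    frames <- expand.grid(strand = c("forward", "reverse"), frame = 0:2,
                          stringsAsFactors = FALSE)
    scores <- mapply(function(strand, frame) {
      s <- if (strand == "forward") read else revcomp(read)
      n <- nchar(s) - frame
      if (n < 3) return(-Inf)
      p <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, frame + 1, frame + 3 * (n %/% 3))),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(gsub("\\*", "X", p)),
        Biostrings::AAString(sc@protein),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 4, scoreOnly = TRUE)
    }, frames$strand, frames$frame)
    k <- which.max(scores)
    expect_equal(of$orientation, frames$strand[k])
    expect_equal(of$frameOffset, frames$frame[k])
  }
})

test_that("clone validation applies the site and stop-codon filter rules", {
  sc <- SCAFFOLD
  intact <- validateClone(make_clone(bc = "GTTAGCTGGACCGCT"), sc, "ok")
  expect_true(isValid(intact))
  expect_length(intact@failureReasons, 0)

  # TAA planted inside the BC loop
  stopcl <- validateClone(make_clone(bc = "GTTTAATGGACCGCT"), sc, "stop")
  expect_equal(stopcl@status, "invalid")
  expect_true(any(grepl("stop codon in variable region",
                        stopcl@failureReasons)))

  # NotI recognition sequence destroyed
  broken <- sub("GCGGCCGC", "GCGGACGC", make_clone(bc = "GTTAGCTGG"),
                fixed = TRUE)
  nocut <- validateClone(broken, sc, "nosite")
  expect_equal(nocut@status, "invalid")
  expect_true("missing required site NotI" %in% nocut@failureReasons)

  # ambiguous base inside a loop
  amb <- validateClone(make_clone(bc = "GTTANCTGGACCGCT"), sc, "amb")
  expect_true(any(grepl("ambiguous base in variable region",
                        amb@failureReasons)))

  # checks accumulate rather than short-circuit
  multi <- validateClone(sub("GCGGCCGC", "GCGGACGC",
                             make_clone(bc = "GTTTAATGG"), fixed = TRUE),
                         sc, "multi")
  expect_gte(length(multi@failureReasons), 2)

  # whole-ORF stop screening is opt-in
  orf <- make_clone(bc = "GTTAGCTGG")
  orf_taa <- sub("AAACCGGGT", "TAACCGGGT", orf, fixed = TRUE)  # codons 63-65
  expect_true(isValid(validateClone(orf_taa, sc)))
  expect_false(isValid(validateClone(orf_taa, sc, wholeOrf = TRUE)))
})

test_that("loop extraction returns the planted peptides", {
  sc <- SCAFFOLD
  # BC loop VSWTA: GTT AGC TGG ACC GCT
  cl <- validateClone(make_clone(bc = "GTTAGCTGGACCGCT"), sc)
  expect_equal(cl@loops$BC$peptide, "VSWTA")
  # 13-codon FG loop
  cl13 <- validateClone(make_clone(fg = strrep("GCT", 13)), sc)
  expect_equal(nchar(cl13@loops$FG$peptide), 13)
  expect_equal(cl13@loops$FG$peptide, strrep("A", 13))
  # generator round trip: error-free reads reproduce the planted loops
  g <- genLibraryReads(nReads = 60, nFamilies = 6, seed = 21, errorRate = 0)
  clones <- validateClones(g$reads, sc)
  expect_true(all(vapply(clones, isValid, logical(1))))
  for (i in seq_along(clones)) {
    fam <- g$truth$families[[g$truth$assignment[i]]]
    expect_equal(clones[[i]]@loops$BC$peptide, fam$BC$peptide)
    expect_equal(clones[[i]]@loops$FG$peptide, fam$FG$peptide)
  }
})

test_that("validation is strand- and order-invariant", {
  sc <- SCAFFOLD
  g <- genLibraryReads(nReads = 24, nFamilies = 4, seed = 9,
                       errorRate = 0.002, stopRate = 0.2)
  clones <- validateClones(g$reads, sc)
  # reverse-complementing any read leaves protein, loops and status fixed
  for (i in seq_along(g$reads)) {
    a <- clones[[i]]
    b <- validateClone(revcomp(g$reads[[i]]), sc, a@readId)
    expect_equal(b@status, a@status)
    expect_equal(b@protein, a@protein)
    expect_equal(b@loops, a@loops)
  }
  # permuting read order never changes the valid/invalid partition
  perm <- sample(seq_along(g$reads))
  shuffled <- validateClones(g$reads[perm], sc)
  expect_equal(vapply(shuffled, function(x) x@status, character(1)),
               vapply(clones[perm], function(x) x@status, character(1)))
})

test_that("clone tables and FASTA IO round-trip", {
  tmp <- withr::local_tempdir()
  sc <- SCAFFOLD
  fa <- file.path(tmp, "reads.fasta")
  g <- genLibraryReads(nReads = 12, nFamilies = 3, seed = 2, fasta = fa)
  reads <- readReads(fa)
  expect_equal(reads, g$reads)
  clones <- validateClones(reads, sc)
  tab <- cloneTable(clones)
  expect_equal(nrow(tab), 12)
  expect_true(all(c("read_id", "status", "BC", "FG") %in% names(tab)))
  tsv <- file.path(tmp, "clones.tsv")
  writeCloneTable(clones, tsv)
  back <- read.delim(tsv)
  expect_equal(back$read_id, tab$read_id)
  # unalignable reads are excluded from clustering input
  junk <- c(g$reads, junk_read = strrep("ACGT", 40))
  all_cl <- validateClones(junk, sc)
  expect_false(isValid(all_cl$junk_read))
  expect_false("junk_read" %in% names(validLoopPeptides(all_cl)))
})
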