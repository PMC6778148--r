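test_that("global alignment matches the exhaustive-alignment oracle", {
  expect_equal(nwAlign("VSWTA", "VSWTA")$identity, 1.0)
  expect_equal(nwAlign("AAAA", "CCCC")$score, -4)   # forced all-mismatch

  alphabet <- c("A", "B", "C")
  seqs <- unlist(lapply(1:3, function(L) {
    apply(expand.grid(rep(list(alphabet), L)), 1, paste, collapse = "")
  }))
  # every pair of lengths <= 3 ...
  for (i in seq_along(seqs)) for (j in i:length(seqs)) {
    expect_equal(nwAlign(seqs[i], seqs[j])$score,
                 brute_nw_score(seqs[i], seqs[j]))
  }
  # ... plus sampled longer pairs up to length 6
  set.seed(17)
  for (k in 1:60) {
    a <- paste(sample(alphabet, sample(4:6, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(alphabet, sample(4:6, 1), replace = TRUE),
               collapse = "")
    expect_equal(nwAlign(a, b)$score, brute_nw_score(a, b))
  }
  expect_error(nwAlign("", "A"), "non-empty")
})

test_that("alignment scores agree with an independent aligner", {
  # cross-check against Biostrings under the same scoring scheme
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- matrix(-1, 20, 20, dimnames = list(aas, aas))
  diag(mat) <- 1
  for (k in 1:10) {
    a <- paste(sample(aas, 8, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 10, replace = TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2,
      scoreOnly = TRUE)
    expect_equal(nwAlign(a, b)$score, ref)
  }
})

test_that("similarity matrices separate planted families", {
  expect_equal(unname(similarityMatrix(c(x = "VSWTA"))@matrix),
               matrix(1, 1, 1))
  two <- similarityMatrix(c(a = "VSWTAGG", b = "VSWTAGG"))
  expect_equal(unname(two@matrix[1, 2]), 1.0)

  g <- genLibraryReads(nReads = 30, nFamilies = 3, seed = 4, errorRate = 0)
  clones <- validateClones(g$reads, SCAFFOLD)
  gr <- similarityMatrix(clones)
  expect_s4_class(gr, "SimilarityGraph")
  expect_equal(max(abs(gr@matrix - t(gr@matrix))), 0)
  fam <- g$truth$assignment
  names(fam) <- names(g$reads)
  fam <- fam[gr@labels]
  within <- gr@matrix[outer(fam, fam, "==") & upper.tri(gr@matrix)]
  between <- gr@matrix[outer(fam, fam, "!=") & upper.tri(gr@matrix)]
  expect_gt(min(within), max(between))
  expect_error(similarityMatrix(list()), "valid clones")
})

test_that("MCL recovers planted structure and matches components oracle", {
  # two disconnected cliques
  m <- matrix(0, 6, 6)
  m[1:3, 1:3] <- 0.9; m[4:6, 4:6] <- 0.9
  diag(m) <- 1
  cl <- mcl(new("SimilarityGraph", labels = letters[1:6], matrix = m,
                edgeThreshold = 0.5))
  expect_equal(nClusters(cl), 2)
  expect_true(same_partition(clusterAssignments(cl), rep(1:2, each = 3)))

  single <- mcl(new("SimilarityGraph", labels = "x",
                    matrix = matrix(1, 1, 1), edgeThreshold = 0.5))
  expect_equal(nClusters(single), 1)

  # planted-partition graphs: strong within-block, weak between-block
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 12; blocks <- rep(1:3, each = 4)
    m <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      w <- if (blocks[i] == blocks[j]) {
        if (runif(1) < 0.9) runif(1, 0.8, 1) else 0
      } else {
        if (runif(1) < 0.2) runif(1, 0.05, 0.2) else 0
      }
      m[i, j] <- m[j, i] <- w
    }
    diag(m) <- 1
    gr <- new("SimilarityGraph", labels = sprintf("n%02d", 1:n), matrix = m,
              edgeThreshold = 0.5)
    part <- clusterAssignments(mcl(gr))
    mm <- m; mm[mm < 0.5] <- 0
    oracle <- components_oracle(mm, 1e-12)
    if (same_partition(part, oracle)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("MCL output is a label-permutation-invariant partition", {
  g <- genLibraryReads(nReads = 30, nFamilies = 4, seed = 8, errorRate = 0)
  clones <- validateClones(g$reads, SCAFFOLD)
  gr <- similarityMatrix(clones)
  cl <- mcl(gr)
  # partition covers every valid clone exactly once
  expect_setequal(names(clusterAssignments(cl)), gr@labels)
  expect_equal(sum(table(clusterAssignments(cl))),
               sum(vapply(clones, isValid, logical(1))))
  # permuting the input labels relabels but does not reshape the partition
  set.seed(1)
  perm <- sample(length(gr@labels))
  gp <- new("SimilarityGraph", labels = gr@labels[perm],
            matrix = gr@matrix[perm, perm], edgeThreshold = gr@edgeThreshold)
  clp <- mcl(gp)
  a <- clusterAssignments(cl)
  b <- clusterAssignments(clp)[names(a)]
  expect_true(same_partition(a, b))
})

test_that("large inflation collapses MCL to thresholded components", {
  # on graphs whose supra-threshold components are dense blocks, raising
  # the inflation drives MCL to exactly those components
  for (seed in 1:5) {
    set.seed(100 + seed)
    n <- 10
    sizes <- c(4, 3, 3)
    blocks <- rep(seq_along(sizes), sizes)
    m <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- if (blocks[i] == blocks[j])
        runif(1, 0.8, 1) else runif(1, 0, 0.2)
    }
    diag(m) <- 1
    gr <- new("SimilarityGraph", labels = sprintf("n%02d", 1:n), matrix = m,
              edgeThreshold = 0.5)
    for (infl in c(4, 8)) {
      part <- clusterAssignments(mcl(gr, inflation = infl))
      mm <- m; mm[mm < 0.5] <- 0
      expect_true(same_partition(part, components_oracle(mm, 1e-12)))
    }
  }
})

test_that("cluster reports carry medoids, consensus and loop lengths", {
  peps <- c(a = "VSWTA", b = "VSWTA", c = "VSWTA")
  gr <- similarityMatrix(peps)
  cl <- mcl(gr)
  rep <- clusterReport(cl, gr, peptides = peps)
  expect_equal(rep$table$consensus, "VSWTA")
  expect_equal(rep$table$size, 3)

  # singleton: representative is the clone itself
  solo <- similarityMatrix(c(only = "AAAA"))
  rsolo <- clusterReport(mcl(solo), solo, peptides = c(only = "AAAA"))
  expect_equal(rsolo$table$representative, "only")

  # consensus ties break alphabetically
  tie <- c(x = "AB", y = "CB")
  gtie <- similarityMatrix(tie, edgeThreshold = 0)
  ctie <- mcl(gtie)
  if (nClusters(ctie) == 1) {
    rtie <- clusterReport(ctie, gtie, peptides = tie)
    expect_equal(substr(rtie$table$consensus, 1, 1), "A")
  }

  g <- genLibraryReads(nReads = 30, nFamilies = 3, seed = 4, errorRate = 0)
  clones <- validateClones(g$reads, SCAFFOLD)
  gr2 <- similarityMatrix(clones)
  rep2 <- clusterReport(mcl(gr2), gr2, clones = clones)
  expect_equal(nrow(rep2$table), 3)
  expect_true(all(c("len_BC", "len_FG") %in% names(rep2$table)))
  tmp <- withr::local_tempdir()
  writeClusterReport(rep2, tsv = file.path(tmp, "cl.tsv"),
                     fasta = file.path(tmp, "cons.fasta"))
  expect_equal(nrow(read.delim(file.path(tmp, "cl.tsv"))), 3)
  expect_length(Biostrings::readAAStringSet(file.path(tmp, "cons.fasta")), 3)
})
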