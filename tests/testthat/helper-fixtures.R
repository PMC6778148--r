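# Shared test helpers: clone construction on the synthetic cassette,
# a brute-force alignment oracle, and a union-find components oracle.

SCAFFOLD <- fn3Scaffold()

# build a clone read with the given loop DNA planted between the anchors
make_clone <- function(bc = NULL, fg = NULL, scaffold = SCAFFOLD) {
  dna <- scaffold@dna
  loops <- list(BC = bc, FG = fg)
  for (id in names(loops)) {
    if (is.null(loops[[id]])) next
    lp <- scaffold@loops[[id]]
    i5 <- regexpr(lp$anchor5, dna, fixed = TRUE)
    i3 <- regexpr(lp$anchor3, dna, fixed = TRUE)
    dna <- paste0(substr(dna, 1, i5 + attr(i5, "match.length") - 1),
                  loops[[id]],
                  substr(dna, i3, nchar(dna)))
  }
  dna
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# exhaustive global-alignment score by plain recursion over all alignments
brute_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, (if (av[i] == bv[j]) match else mismatch) +
                    rec(i + 1, j + 1))
    if (i <= length(av)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# connected components of a thresholded weight matrix (union-find)
components_oracle <- function(m, threshold) {
  n <- nrow(m)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (m[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# partitions as canonical sets of member index sets
partition_sets <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))
}
same_partition <- function(a, b) {
  sa <- partition_sets(a); sb <- partition_sets(b)
  length(sa) == length(sb) &&
    all(vapply(sa, function(s) any(vapply(sb, identical, logical(1), s)),
               logical(1)))
}
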