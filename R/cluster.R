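#' Pairwise similarity graph of valid clones
#'
#' Symmetric matrix of Needleman-Wunsch fraction identities between clone
#' peptides (diagonal 1), with entries below `edgeThreshold` zeroed for graph
#' construction.
#'
#' @slot labels clone identifiers.
#' @slot matrix symmetric similarity matrix in `[0, 1]`.
#' @slot edgeThreshold identity threshold below which edges are dropped.
#' @name SimilarityGraph-class
#' @aliases SimilarityGraph
#' @exportClass SimilarityGraph
setClass("SimilarityGraph", representation(
  labels = "character", matrix = "matrix", edgeThreshold = "numeric"))

setValidity("SimilarityGraph", function(object) {
  m <- object@matrix
  if (nrow(m) != length(object@labels)) return("matrix/labels size mismatch")
  if (any(m < 0)) return("similarities must be non-negative")
  if (max(abs(m - t(m))) > 1e-12) return("matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-12)) return("diagonal must be 1")
  TRUE
})

setMethod("show", "SimilarityGraph", function(object) {
  off <- object@matrix[upper.tri(object@matrix)]
  cat(sprintf("SimilarityGraph: %d clones, %d edges >= %.2f\n",
              length(object@labels), sum(off >= object@edgeThreshold),
              object@edgeThreshold))
})

#' Clone partition from Markov clustering
#'
#' @slot partition named integer vector: clone id -> cluster id (1-based,
#'   numbered by decreasing cluster size).
#' @slot attractors named list: cluster id -> attractor clone ids.
#' @slot consensus named character: cluster id -> consensus peptide (filled
#'   by [clusterReport()]).
#' @slot converged logical convergence flag from the MCL iteration.
#' @name ClusterSet-class
#' @aliases ClusterSet
#' @exportClass ClusterSet
setClass("ClusterSet", representation(
  partition = "integer", attractors = "list", consensus = "character",
  converged = "logical"))

setValidity("ClusterSet", function(object) {
  if (is.null(names(object@partition))) return("partition must be named")
  if (anyDuplicated(names(object@partition)))
    return("each clone appears exactly once")
  TRUE
})

setMethod("show", "ClusterSet", function(object) {
  sizes <- table(object@partition)
  cat(sprintf("ClusterSet: %d clones in %d cluster(s)%s; sizes: %s\n",
              length(object@partition), length(sizes),
              if (object@converged) "" else " [not converged]",
              paste(sort(as.integer(sizes), decreasing = TRUE),
                    collapse = ", ")))
})

#' @describeIn ClusterSet-class the clone -> cluster assignment.
#' @param x a `ClusterSet`.
#' @export
clusterAssignments <- function(x) x@partition

#' @describeIn ClusterSet-class number of clusters.
#' @export
nClusters <- function(x) length(unique(x@partition))

#' Similarity matrix over valid clones
#'
#' Computes all pairwise global-alignment fraction identities between clone
#' peptides: by default the concatenated loop peptides (`mode = "loops"`,
#' the diversified positions carry the signal), or the full translated
#' insert. Entries below `edgeThreshold` are zeroed when the graph is used
#' for clustering; the stored matrix keeps raw identities.
#'
#' @param clones list of [CloneRecord-class] (invalid clones are dropped) or
#'   a named character vector of peptides.
#' @param mode `"loops"` or `"full_protein"`.
#' @param edgeThreshold identity below which edges are dropped (default 0.5).
#' @param ... passed to [nwAlign()].
#' @return A [SimilarityGraph-class].
#' @export
similarityMatrix <- function(clones, mode = c("loops", "full_protein"),
                             edgeThreshold = 0.5, ...) {
  mode <- match.arg(mode)
  if (is.character(clones)) {
    peps <- clones
    if (is.null(names(peps)))
      names(peps) <- sprintf("clone_%03d", seq_along(peps))
  } else {
    keep <- Filter(isValid, clones)
    if (length(keep) == 0) stop("no valid clones", call. = FALSE)
    peps <- if (mode == "loops") validLoopPeptides(keep) else
      setNames(vapply(keep, function(cl) cl@protein, character(1)),
               vapply(keep, function(cl) cl@readId, character(1)))
  }
  n <- length(peps)
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- nwAlign(peps[[i]], peps[[j]], ...)$identity
      }
    }
  }
  dimnames(m) <- list(names(peps), names(peps))
  new("SimilarityGraph", labels = names(peps), matrix = m,
      edgeThreshold = edgeThreshold)
}

#' Markov clustering (MCL)
#'
#' Clusters the similarity graph by the Markov Cluster algorithm: self-loops
#' are added, columns normalized to a stochastic matrix, then expansion
#' (matrix power) and inflation (entrywise power followed by column
#' renormalization) alternate, pruning entries below `prune`, until the
#' largest entry change drops below 1e-8 or `maxIter` is reached. Clusters
#' are read from attractor rows of the limit matrix; overlapping attractor
#' sets are merged so the result is a partition. Cluster ids are assigned by
#' decreasing size (ties by first member) so the labelling is deterministic.
#'
#' @param graph a [SimilarityGraph-class] (entries below its `edgeThreshold`
#'   are dropped) or a non-negative matrix.
#' @param inflation inflation exponent (> 1, default 2).
#' @param expansion expansion power (integer >= 2, default 2).
#' @param prune entries below this are set to 0 each iteration.
#' @param maxIter iteration cap; non-convergence yields a warning flag on
#'   the returned object, not an error.
#' @param selfLoop weight added on the diagonal before normalization.
#' @return A [ClusterSet-class].
#' @export
mcl <- function(graph, inflation = 2, expansion = 2L, prune = 1e-5,
                maxIter = 100L, selfLoop = 1) {
  if (is(graph, "SimilarityGraph")) {
    m <- graph@matrix
    m[m < graph@edgeThreshold] <- 0
    labels <- graph@labels
  } else {
    m <- as.matrix(graph)
    labels <- rownames(m)
    if (is.null(labels)) labels <- sprintf("node_%03d", seq_len(nrow(m)))
  }
  stopifnot(all(m >= 0), inflation > 1, expansion >= 2)
  n <- nrow(m)
  diag(m) <- pmax(diag(m), selfLoop)
  norm_cols <- function(x) sweep(x, 2, pmax(colSums(x), .Machine$double.xmin),
                                 "/")
  M <- norm_cols(m)
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    prev <- M
    P <- M
    for (k in seq_len(expansion - 1L)) P <- P %*% M
    P <- P^inflation
    P[P < prune] <- 0
    M <- norm_cols(P)
    if (max(abs(M - prev)) < 1e-8) { converged <- TRUE; break }
  }
  # attractors: nodes with positive diagonal mass in the limit matrix
  attr_idx <- which(diag(M) > prune)
  if (length(attr_idx) == 0) attr_idx <- seq_len(n)
  members <- lapply(attr_idx, function(i) which(M[i, ] > prune))
  # merge attractor rows sharing members (overlapping attractor systems)
  clusters <- list()
  for (mem in members) {
    hit <- which(vapply(clusters, function(cl) length(intersect(cl, mem)) > 0,
                        logical(1)))
    if (length(hit)) {
      merged <- sort(unique(c(unlist(clusters[hit]), mem)))
      clusters <- clusters[-hit]
      clusters <- c(clusters, list(merged))
    } else clusters <- c(clusters, list(sort(mem)))
  }
  # sweep up nodes not claimed by any attractor row (numerical corner case):
  # each joins the cluster holding its largest column mass
  claimed <- unlist(clusters)
  for (j in setdiff(seq_len(n), claimed)) {
    owner <- which.max(vapply(clusters, function(cl) sum(M[cl, j]),
                              numeric(1)))
    clusters[[owner]] <- sort(c(clusters[[owner]], j))
  }
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, min, integer(1)))
  clusters <- clusters[ord]
  part <- integer(n)
  for (k in seq_along(clusters)) part[clusters[[k]]] <- k
  attractors <- lapply(seq_along(clusters), function(k)
    labels[intersect(attr_idx, clusters[[k]])])
  names(attractors) <- as.character(seq_along(clusters))
  new("ClusterSet", partition = setNames(part, labels),
      attractors = attractors, consensus = character(0),
      converged = converged)
}

# consensus over peptides aligned to the medoid: per medoid column the most
# frequent residue, ties broken alphabetically; gaps ignored unless majority
.consensus_to_medoid <- function(peps, medoid, ...) {
  cols <- lapply(peps, function(p) {
    al <- nwAlign(medoid, p, ...)
    a <- strsplit(al$alignment[1], "")[[1]]
    b <- strsplit(al$alignment[2], "")[[1]]
    b[a != "-"]  # residues of p at medoid positions
  })
  L <- nchar(medoid)
  out <- vapply(seq_len(L), function(i) {
    col <- vapply(cols, `[`, character(1), i)
    col <- col[col != "-"]
    if (length(col) == 0) return("-")
    tab <- table(col)
    names(tab)[order(-tab, names(tab))][1]
  }, character(1))
  paste(out, collapse = "")
}

#' Per-cluster report
#'
#' Summarizes a [ClusterSet-class]: cluster size, representative clone
#' (medoid, the member with the highest mean identity to its cluster, ties
#' by label order), consensus peptide built from pairwise alignments of the
#' members to the medoid (per position the most frequent residue, ties
#' alphabetical), and the loop-length composition when clone records are
#' supplied.
#'
#' @param clusters a [ClusterSet-class].
#' @param graph the [SimilarityGraph-class] the clustering was computed from.
#' @param peptides named character vector of the clustered peptides
#'   (defaults to being recovered from `clones`).
#' @param clones optional list of [CloneRecord-class] for loop-length
#'   summaries.
#' @return list with `table` (one row per cluster: cluster, size, members,
#'   representative, consensus, loop-length columns) and `clusters` (the
#'   input with consensus filled in).
#' @export
clusterReport <- function(clusters, graph, peptides = NULL, clones = NULL) {
  stopifnot(is(clusters, "ClusterSet"), is(graph, "SimilarityGraph"))
  if (is.null(peptides) && !is.null(clones))
    peptides <- validLoopPeptides(clones)
  part <- clusters@partition
  ids <- sort(unique(part))
  loop_len <- NULL
  if (!is.null(clones)) {
    keep <- Filter(isValid, clones)
    loop_ids <- unique(unlist(lapply(keep, function(cl) names(cl@loops))))
    loop_len <- lapply(setNames(loop_ids, loop_ids), function(L)
      setNames(vapply(keep, function(cl)
        if (!is.null(cl@loops[[L]])) as.numeric(nchar(cl@loops[[L]]$peptide))
        else NA_real_, numeric(1)),
        vapply(keep, function(cl) cl@readId, character(1))))
  }
  rows <- lapply(ids, function(k) {
    mem <- names(part)[part == k]
    sub <- graph@matrix[mem, mem, drop = FALSE]
    medoid <- mem[order(-rowMeans(sub), mem)][1]
    cons <- if (!is.null(peptides) && all(mem %in% names(peptides))) {
      .consensus_to_medoid(peptides[mem], peptides[[medoid]])
    } else NA_character_
    row <- data.frame(cluster = k, size = length(mem),
                      representative = medoid,
                      consensus = cons,
                      members = paste(mem, collapse = ","),
                      stringsAsFactors = FALSE)
    if (!is.null(loop_len)) {
      for (L in names(loop_len)) {
        lens <- loop_len[[L]][mem]
        row[[paste0("len_", L)]] <- paste(
          sort(unique(lens[!is.na(lens)])), collapse = "/")
      }
    }
    row
  })
  tab <- do.call(rbind, rows)
  cons <- setNames(tab$consensus, as.character(tab$cluster))
  clusters@consensus <- cons[!is.na(cons)]
  list(table = tab, clusters = clusters)
}

#' Write cluster assignments and consensus sequences
#'
#' @param report result of [clusterReport()].
#' @param tsv,fasta output paths (either may be `NULL` to skip).
#' @return invisible list of written paths.
#' @export
writeClusterReport <- function(report, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv))
    write.table(report$table, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(fasta)) {
    cons <- report$table$consensus
    keep <- !is.na(cons)
    set <- Biostrings::AAStringSet(cons[keep])
    names(set) <- sprintf("cluster_%d_consensus", report$table$cluster[keep])
    Biostrings::writeXStringSet(set, fasta)
  }
  invisible(list(tsv = tsv, fasta = fasta))
}
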