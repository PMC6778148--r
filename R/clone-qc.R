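#' One validated sequencing clone
#'
#' A Sanger-derived colony read after orientation and reading-frame
#' resolution: the oriented DNA, its translation, the extracted loop
#' sequences and a validity verdict. A clone is `valid` only if every
#' required restriction site is present, every loop was extracted in frame,
#' and no loop contains a stop codon or ambiguous base; all checks run and
#' every failure is recorded (no short-circuit).
#'
#' @slot readId read identifier.
#' @slot dna oriented (forward-strand) DNA.
#' @slot orientation `"forward"` or `"reverse"` (strand of the raw read).
#' @slot frameOffset 0-based offset of the reading frame in `dna`.
#' @slot protein translation of the oriented read.
#' @slot loops named list of `list(dna, peptide)` per extracted loop.
#' @slot status `"valid"` or `"invalid"`.
#' @slot failureReasons character vector of accumulated failure reasons.
#' @name CloneRecord-class
#' @aliases CloneRecord
#' @exportClass CloneRecord
setClass("CloneRecord", representation(
  readId = "character", dna = "character", orientation = "character",
  frameOffset = "integer", protein = "character", loops = "list",
  status = "character", failureReasons = "character"))

setMethod("show", "CloneRecord", function(object) {
  cat(sprintf("CloneRecord %s [%s, frame %d, %s]%s\n", object@readId,
              object@orientation, object@frameOffset, object@status,
              if (length(object@failureReasons))
                paste0(": ", paste(object@failureReasons, collapse = "; "))
              else ""))
})

#' @describeIn CloneRecord-class `TRUE` for a valid clone.
#' @param x a `CloneRecord`.
#' @export
isValid <- function(x) x@status == "valid"

#' @describeIn CloneRecord-class extracted loops.
#' @export
cloneLoops <- function(x) x@loops

.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

.translate_from <- function(s, frame) {
  n <- nchar(s) - frame
  if (n < 3L) return("")
  cds <- substr(s, frame + 1L, frame + 3L * (n %/% 3L))
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# leftmost minimum-mismatch hit of `pattern` in `subject` (DNAString),
# searching mismatch counts 0..max_mm; NULL when absent
.best_hit <- function(pattern, subject, max_mm) {
  for (mm in 0:max_mm) {
    h <- Biostrings::matchPattern(pattern, subject, max.mismatch = mm,
                                  with.indels = FALSE)
    if (length(h) > 0)
      return(list(start = Biostrings::start(h)[1], mismatch = mm,
                  end = Biostrings::end(h)[1]))
  }
  NULL
}

#' Resolve read orientation and reading frame
#'
#' Searches both strands of a read for the scaffold's fixed loop-flank
#' anchors, allowing up to `maxAnchorMismatch` substitutions per anchor.
#' The strand of the best anchor hit (fewest mismatches, then leftmost, then
#' forward on ties) gives the orientation; the reading frame follows from the
#' anchor's codon coordinate on the scaffold modulo 3 (loop-length variation
#' shifts positions by whole codons, so the frame is strand-wide). When no
#' anchor is found, a six-frame translation of the read is globally aligned
#' to the scaffold protein as a fallback; a read failing both routes is an
#' "unalignable read".
#'
#' @param read DNA sequence (character).
#' @param scaffold a [ScaffoldTemplate-class].
#' @param maxAnchorMismatch per-anchor substitution tolerance (default 2).
#' @return list with `ok`; when `ok`, also `orientation` (`"forward"` /
#'   `"reverse"`), `frameOffset` (0-2) and `method`; otherwise `reason`.
#' @export
orientAndFrame <- function(read, scaffold, maxAnchorMismatch = 2L) {
  stopifnot(is(scaffold, "ScaffoldTemplate"))
  read <- toupper(as.character(read))
  anchors <- unlist(lapply(scaffold@loops, function(lp)
    c(lp$anchor5, lp$anchor3)), use.names = FALSE)
  if (nchar(read) < min(nchar(anchors)))
    return(list(ok = FALSE, reason = "unalignable read"))
  subjects <- list(forward = Biostrings::DNAString(read),
                   reverse = Biostrings::DNAString(.revcomp(read)))
  best <- NULL
  for (strand in c("forward", "reverse")) {
    for (a in anchors) {
      h <- .best_hit(a, subjects[[strand]], maxAnchorMismatch)
      if (is.null(h)) next
      cand <- list(strand = strand, anchor = a, start = h$start,
                   mismatch = h$mismatch)
      # lexicographic tie-break: fewest mismatches, then leftmost hit,
      # then forward strand
      key <- function(x) x$mismatch * 1e8 + x$start * 10 +
        (x$strand == "reverse")
      if (is.null(best) || key(cand) < key(best)) best <- cand
    }
  }
  if (!is.null(best)) {
    s0 <- regexpr(best$anchor, scaffold@dna, fixed = TRUE)[1] - 1L
    o <- (s0 - scaffold@frameOffset) %% 3L
    f <- (best$start - 1L - o) %% 3L
    return(list(ok = TRUE, orientation = best$strand,
                frameOffset = as.integer(f), method = "anchor"))
  }
  # fallback: six-frame protein alignment against the scaffold translation
  cand <- expand.grid(strand = c("forward", "reverse"), frame = 0:2,
                      stringsAsFactors = FALSE)
  ident <- mapply(function(strand, frame) {
    s <- if (strand == "forward") read else .revcomp(read)
    p <- .translate_from(s, frame)
    if (nchar(p) < 5L) return(0)
    nwAlign(p, scaffold@protein)$identity
  }, cand$strand, cand$frame)
  k <- which.max(ident)
  if (ident[k] >= 0.5)
    return(list(ok = TRUE, orientation = cand$strand[k],
                frameOffset = as.integer(cand$frame[k]),
                method = "six-frame"))
  list(ok = FALSE, reason = "unalignable read")
}

# extract all loops from an oriented, framed read; returns
# list(loops = named list, reasons = character)
.extract_loops <- function(oriented, frame, scaffold, max_mm) {
  subj <- Biostrings::DNAString(oriented)
  loops <- list()
  reasons <- character(0)
  for (id in names(scaffold@loops)) {
    lp <- scaffold@loops[[id]]
    h5 <- .best_hit(lp$anchor5, subj, max_mm)
    h3 <- .best_hit(lp$anchor3, subj, max_mm)
    if (is.null(h5) || is.null(h3) || h3$start <= h5$end) {
      reasons <- c(reasons, sprintf("loop %s anchors not found", id))
      next
    }
    loop_dna <- substr(oriented, h5$end + 1L, h3$start - 1L)
    if ((h5$end - frame) %% 3L != 0L || nchar(loop_dna) %% 3L != 0L) {
      reasons <- c(reasons, sprintf("loop %s out of frame", id))
      next
    }
    if (grepl("[^ACGT]", loop_dna)) {
      reasons <- c(reasons,
                   sprintf("ambiguous base in variable region (%s)", id))
      next
    }
    pep <- if (nzchar(loop_dna)) .translate_from(loop_dna, 0L) else ""
    if (grepl("\\*", pep))
      reasons <- c(reasons,
                   sprintf("stop codon in variable region (%s)", id))
    loops[[id]] <- list(dna = loop_dna, peptide = pep)
  }
  list(loops = loops, reasons = reasons)
}

#' Validate a sequencing clone against the scaffold
#'
#' Runs the full clone triage: orientation/frame resolution, translation,
#' presence of every required restriction site (exact match on the oriented
#' read), loop extraction between the fixed flanks, and in-loop stop-codon /
#' ambiguous-base screening. All checks run; failures accumulate in
#' `failureReasons` and the clone is `valid` only when none occur. Content
#' problems never raise errors.
#'
#' @param read DNA sequence (character).
#' @param scaffold a [ScaffoldTemplate-class].
#' @param readId identifier stored on the record.
#' @param maxAnchorMismatch per-anchor substitution tolerance.
#' @param wholeOrf also screen the whole translated insert for stop codons
#'   (default `FALSE`: loops only).
#' @return A [CloneRecord-class].
#' @export
validateClone <- function(read, scaffold, readId = "read",
                          maxAnchorMismatch = 2L, wholeOrf = FALSE) {
  read <- toupper(as.character(read))
  of <- orientAndFrame(read, scaffold, maxAnchorMismatch)
  if (!of$ok)
    return(new("CloneRecord", readId = readId, dna = read,
               orientation = "unknown", frameOffset = NA_integer_,
               protein = "", loops = list(), status = "invalid",
               failureReasons = of$reason))
  oriented <- if (of$orientation == "forward") read else .revcomp(read)
  reasons <- character(0)
  for (nm in names(scaffold@requiredSites)) {
    if (Biostrings::countPattern(scaffold@requiredSites[[nm]],
                                 Biostrings::DNAString(oriented)) < 1L)
      reasons <- c(reasons, sprintf("missing required site %s", nm))
  }
  protein <- .translate_from(oriented, of$frameOffset)
  ex <- .extract_loops(oriented, of$frameOffset, scaffold, maxAnchorMismatch)
  reasons <- c(reasons, ex$reasons)
  if (wholeOrf && grepl("\\*", protein))
    reasons <- c(reasons, "stop codon in open reading frame")
  new("CloneRecord", readId = readId, dna = oriented,
      orientation = of$orientation, frameOffset = of$frameOffset,
      protein = protein, loops = ex$loops,
      status = if (length(reasons)) "invalid" else "valid",
      failureReasons = reasons)
}

#' Validate a set of reads
#'
#' @param reads named character vector or `DNAStringSet` of reads.
#' @inheritParams validateClone
#' @return list of [CloneRecord-class], one per read.
#' @export
validateClones <- function(reads, scaffold, maxAnchorMismatch = 2L,
                           wholeOrf = FALSE) {
  if (is(reads, "DNAStringSet")) reads <- setNames(as.character(reads),
                                                   names(reads))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%03d", seq_along(reads))
  mapply(function(r, id) validateClone(r, scaffold, id, maxAnchorMismatch,
                                       wholeOrf),
         reads, ids, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Extract loop sequences from a validated clone
#'
#' Returns the in-frame codons strictly between each loop's 5' and 3'
#' anchors, with their translations. Loops were located during
#' [validateClone()]; this accessor re-runs extraction when given a raw
#' oriented record.
#'
#' @param clone a [CloneRecord-class].
#' @param scaffold a [ScaffoldTemplate-class].
#' @return named list of `list(dna, peptide)`.
#' @export
extractLoops <- function(clone, scaffold) {
  stopifnot(is(clone, "CloneRecord"))
  if (length(clone@loops)) return(clone@loops)
  if (is.na(clone@frameOffset))
    stop("clone is not oriented/framed", call. = FALSE)
  .extract_loops(clone@dna, clone@frameOffset, scaffold, 2L)$loops
}

#' Tabulate clone records
#'
#' @param clones list of [CloneRecord-class].
#' @return data.frame with one row per read: id, orientation, frame, status,
#'   reasons, and one peptide column per loop.
#' @export
cloneTable <- function(clones) {
  loop_ids <- unique(unlist(lapply(clones, function(cl) names(cl@loops))))
  base <- data.frame(
    read_id = vapply(clones, function(cl) cl@readId, character(1)),
    orientation = vapply(clones, function(cl) cl@orientation, character(1)),
    frame = vapply(clones, function(cl) cl@frameOffset, integer(1)),
    status = vapply(clones, function(cl) cl@status, character(1)),
    reasons = vapply(clones, function(cl)
      paste(cl@failureReasons, collapse = "; "), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  for (id in loop_ids)
    base[[id]] <- vapply(clones, function(cl)
      if (!is.null(cl@loops[[id]])) cl@loops[[id]]$peptide else NA_character_,
      character(1))
  base
}

#' @rdname cloneTable
#' @param path output TSV path.
#' @export
writeCloneTable <- function(clones, path) {
  write.table(cloneTable(clones), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Concatenated loop peptides of the valid clones
#'
#' @param clones list of [CloneRecord-class].
#' @return named character vector (one entry per valid clone).
#' @export
validLoopPeptides <- function(clones) {
  keep <- Filter(isValid, clones)
  setNames(vapply(keep, function(cl)
    paste(vapply(cl@loops, function(l) l$peptide, character(1)),
          collapse = ""), character(1)),
    vapply(keep, function(cl) cl@readId, character(1)))
}

#' Read a multi-FASTA of clone reads
#'
#' @param path FASTA path.
#' @return named character vector of DNA reads.
#' @export
readReads <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
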