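#' Needleman-Wunsch global alignment
#'
#' Optimal global alignment of two sequences under match/mismatch scoring and
#' a linear gap penalty, with deterministic traceback (on ties the diagonal
#' move is preferred, then the vertical move consuming a residue of `a`, then
#' the horizontal move). Fraction identity is the number of aligned identical
#' pairs divided by the alignment length (gap columns included). A BLOSUM62
#' substitution matrix can be selected for protein inputs.
#'
#' @param a,b non-empty sequences (character strings).
#' @param match,mismatch,gap scores (defaults 1 / -1 / -2).
#' @param substitution optional substitution matrix (e.g. `"BLOSUM62"`);
#'   overrides `match`/`mismatch`.
#' @return list with `alignment` (two padded strings), `score`, `identity`.
#' @examples
#' nwAlign("VSWTA", "VSWTA")$identity  # 1
#' @export
nwAlign <- function(a, b, match = 1, mismatch = -1, gap = -2,
                    substitution = NULL) {
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  submat <- NULL
  if (!is.null(substitution)) {
    submat <- if (is.matrix(substitution)) substitution else
      get(substitution, envir = asNamespace("Biostrings"))
  }
  sub_score <- function(x, y) {
    if (is.null(submat)) {
      if (x == y) match else mismatch
    } else submat[x, y]
  }
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  # traceback codes: 1 diagonal, 2 up (gap in b), 3 left (gap in a)
  P <- matrix(0L, n + 1L, m + 1L)
  P[, 1] <- 2L; P[1, ] <- 3L; P[1, 1] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + sub_score(av[i], bv[j])
      u <- S[i, j + 1L] + gap
      l <- S[i + 1L, j] + gap
      best <- max(d, u, l)
      S[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }
  ra <- character(0); rb <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- P[i, j]
    if (mv == 1L) {
      ra <- c(av[i - 1L], ra); rb <- c(bv[j - 1L], rb)
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      ra <- c(av[i - 1L], ra); rb <- c("-", rb)
      i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j - 1L], rb)
      j <- j - 1L
    }
  }
  ident <- sum(ra == rb & ra != "-") / length(ra)
  list(alignment = c(paste(ra, collapse = ""), paste(rb, collapse = "")),
       score = S[n + 1L, m + 1L], identity = ident)
}
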