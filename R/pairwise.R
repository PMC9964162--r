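# Global pairwise alignment (Needleman-Wunsch with affine gaps) and percent
# identity, the stand-in for web-service pairwise identity figures. The
# identity denominator defaults to columns where both rows hold residues
# (ClustalW-like); the shorter-sequence denominator is exposed as an
# alternative since the convention is rarely stated with published numbers.

#' Fetch a named substitution matrix
#'
#' Currently `BLOSUM62` and `BLOSUM50`, taken from the Biostrings data
#' objects at run time.
#'
#' @param name matrix name.
#' @return Numeric substitution matrix with residue dimnames.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  if (!name %in% c("BLOSUM62", "BLOSUM50"))
    stop("unknown substitution matrix: ", name)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with affine gap penalties: a gap of length g costs
#' `gap_open + (g - 1) * gap_extend`. Traceback ties prefer match/mismatch
#' over a gap in `a` over a gap in `b`, making the reported alignment
#' deterministic.
#'
#' @param a,b single-record [protein_set()]s or residue strings (non-empty).
#' @param matrix substitution matrix name (see [substitution_matrix()]).
#' @param gap_open,gap_extend positive gap penalties (defaults 10 and 0.5,
#'   the common protein defaults).
#' @return A `pairwise_alignment`: gapped rows `a` and `b` of equal length
#'   with no all-gap column, `score`, ids and parameters.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  get_seq <- function(x) {
    if (inherits(x, "protein_set")) {
      stopifnot(length(x) == 1L)
      c(x$id[[1L]], x$seq[[1L]])
    } else c("", toupper(as.character(x)))
  }
  A <- get_seq(a); B <- get_seq(b)
  stopifnot(nzchar(A[[2L]]), nzchar(B[[2L]]))
  sub <- substitution_matrix(matrix)
  alphabet <- paste(rownames(sub), collapse = "")
  res <- .nw_align_cpp(A[[2L]], B[[2L]], unname(sub), alphabet,
                       gap_open, gap_extend)
  structure(list(id_a = A[[1L]], id_b = B[[1L]],
                 a = res$a, b = res$b, score = res$score,
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise_alignment (", x$matrix, ", open ", x$gap_open, ", extend ",
      x$gap_extend, "): score ", x$score, "\n", sep = "")
  w <- 60L
  for (s in seq(1L, nchar(x$a), by = w)) {
    cat(substr(x$a, s, s + w - 1L), "\n")
    cat(substr(x$b, s, s + w - 1L), "\n\n")
  }
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' @param aln a [global_align()] result.
#' @param mode denominator: `"aligned_columns"` (columns where both rows
#'   hold residues; default) or `"shorter_seq"` (length of the shorter
#'   input).
#' @return Identity percentage, half-up to 1 decimal.
#' @export
percent_identity <- function(aln, mode = c("aligned_columns", "shorter_seq")) {
  mode <- match.arg(mode)
  ca <- strsplit(aln$a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$b, "", fixed = TRUE)[[1L]]
  both <- ca != "-" & cb != "-"
  ident <- sum(ca[both] == cb[both])
  denom <- if (mode == "aligned_columns") sum(both) else
    min(sum(ca != "-"), sum(cb != "-"))
  if (denom == 0L) stop("zero denominator: no aligned columns")
  percent(ident, denom)
}

#' Write a pairwise alignment as aligned FASTA
#' @param aln a [global_align()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairwise <- function(aln, path) {
  ids <- c(if (nzchar(aln$id_a)) aln$id_a else "seq_a",
           if (nzchar(aln$id_b)) aln$id_b else "seq_b")
  writeLines(c(paste0(">", ids[[1L]]), aln$a,
               paste0(">", ids[[2L]]), aln$b), path)
  invisible(path)
}

#' All-pairs identity report
#'
#' @param records a [protein_set()].
#' @param ... passed to [global_align()] / [percent_identity()].
#' @param mode identity denominator mode.
#' @return A data.frame `id_a`, `id_b`, `score`, `identity` for every
#'   unordered pair.
#' @export
identity_report <- function(records, mode = "aligned_columns", ...) {
  n <- length(records)
  rows <- list()
  for (i in seq_len(max(0L, n - 1L))) for (j in (i + 1L):n) {
    aln <- global_align(records[i], records[j], ...)
    rows[[length(rows) + 1L]] <-
      data.frame(id_a = records$id[[i]], id_b = records$id[[j]],
                 score = aln$score,
                 identity = percent_identity(aln, mode = mode),
                 stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(id_a = character(), id_b = character(),
                                       score = numeric(), identity = numeric()))
  do.call(rbind, rows)
}
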