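# Gblocks-style removal of ambiguous alignment regions with the stated
# parameter set: maximum run of contiguous nonconserved positions 15,
# minimum block length 2, gap rule "half" (a column with >= 50% gaps is a
# gap position). This is a documented simplification of Gblocks 0.91b: the
# majority (b1) and 0.85 (b2) conservation thresholds and the b3/b4/gap
# parameters are implemented; Gblocks' flank-refinement sub-steps are not,
# and short internal gap-position runs inside a kept block survive (real
# Gblocks removes every gap position).

#' Classify alignment columns for block trimming
#'
#' Each column gets exactly one label: `gap_position` when its gap fraction
#' is at least 0.5 (gap rule "half"); otherwise `highly_conserved` when the
#' modal residue's fraction of all rows is at least `b2`; otherwise
#' `conserved` when the modal count exceeds half the rows (strict majority,
#' b1); otherwise `nonconserved`.
#'
#' @param x an [msa()].
#' @param b2 highly-conserved threshold as a fraction of rows (default
#'   0.85).
#' @return Character vector of per-column labels.
#' @export
classify_columns <- function(x, b2 = 0.85) {
  mat <- msa_matrix(x)
  n <- nrow(mat)
  vapply(seq_len(ncol(mat)), function(c) {
    col <- mat[, c]
    if (sum(col == "-") / n >= 0.5) return("gap_position")
    res <- col[col != "-"]
    modal <- max(table(res))
    if (modal / n >= b2) return("highly_conserved")
    if (modal > n / 2) return("conserved")
    "nonconserved"
  }, "")
}

#' Trim ambiguous blocks from an alignment
#'
#' Procedure: (1) classify columns; (2) remove every maximal run of more
#' than `max_noncons` contiguous nonconserved/gap columns; (3) trim each
#' surviving run of columns at both ends back to the nearest
#' conserved-or-better column; (4) drop surviving blocks shorter than
#' `min_block`. Output column order is preserved.
#'
#' @param x an [msa()].
#' @param max_noncons maximum tolerated run of contiguous nonconserved or
#'   gap columns (default 15).
#' @param min_block minimum surviving block length (default 2).
#' @param b2 passed to [classify_columns()].
#' @return A list: `msa` (trimmed alignment; may have zero columns, in
#'   which case `NULL`), `kept_cols` (0-based original column indices),
#'   `labels` (the column classification).
#' @export
trim_blocks <- function(x, max_noncons = 15L, min_block = 2L, b2 = 0.85) {
  labels <- classify_columns(x, b2 = b2)
  bad <- labels %in% c("nonconserved", "gap_position")
  n <- length(labels)
  keep <- rep(TRUE, n)

  # (2) long bad runs
  r <- rle(bad)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values))
    if (r$values[[j]] && r$lengths[[j]] > max_noncons)
      keep[starts[[j]]:ends[[j]]] <- FALSE

  # (3) trim ends of each surviving run back to conserved-or-better
  r <- rle(keep)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[[j]]) next
    run <- starts[[j]]:ends[[j]]
    good <- which(!bad[run])
    if (!length(good)) { keep[run] <- FALSE; next }
    keep[run[seq_len(min(good) - 1L)]] <- FALSE
    if (max(good) < length(run))
      keep[run[(max(good) + 1L):length(run)]] <- FALSE
  }

  # (4) minimum block length
  r <- rle(keep)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values))
    if (r$values[[j]] && r$lengths[[j]] < min_block)
      keep[starts[[j]]:ends[[j]]] <- FALSE

  kept <- which(keep) - 1L
  list(msa = if (length(kept)) msa_slice(x, kept) else NULL,
       kept_cols = kept, labels = labels)
}

#' Write the kept-column map TSV (kept column -> original column, 0-based)
#' @param trim a [trim_blocks()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_column_map <- function(trim, path) {
  df <- data.frame(kept = seq_along(trim$kept_cols) - 1L,
                   original = trim$kept_cols)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
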