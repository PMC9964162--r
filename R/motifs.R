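# Degenerate motif compilation and scanning; GH51 family validation by the
# two catalytic-region motifs; classification of the catalytic acid/base
# position (canonical G-N-E vs G-N-Q / G-N-D substitutions and the G-S-N
# variant).
#
# Motif syntax: dash-separated tokens; a token is one uppercase residue, a
# '/'-joined alternation (E/Q), or the wildcard 'x'. The wildcard matches
# any residue including X; fixed and alternation tokens never match X
# (conservative on ambiguous residues).

MOTIF_GNEQ  <- "G-N-E/Q"
MOTIF_SEYXV <- "S-E-Y-x-V"
MOTIF_LXVD  <- "L-x-V-D"
MOTIF_SXXP  <- "S-x-x-P"
MOTIF_CBM4_CORE <- "G-x-x-F-E-x-I-x-x-x-G-x-G-G"

#' Compile a degenerate motif pattern
#'
#' @param text motif string such as `"G-N-E/Q"`, `"S-E-Y-x-V"`, `"L-x-V-D"`,
#'   `"S-x-x-P"` or `"G-x-x-F-E-x-I-x-x-x-G-x-G-G"`.
#' @param name optional pattern name; defaults to `text`.
#' @return A `motif_pattern`: list of per-position allowed-residue sets
#'   (`NULL` marks a wildcard), with `length` = token count.
#' @export
compile_pattern <- function(text, name = text) {
  tokens <- strsplit(text, "-", fixed = TRUE)[[1L]]
  if (!length(tokens) || any(!nzchar(tokens)))
    stop("malformed motif '", text, "': empty token")
  if (length(tokens) < 2L) stop("motif must have at least 2 positions")
  sets <- lapply(tokens, function(tok) {
    if (tok == "x") return(NULL)
    res <- strsplit(tok, "/", fixed = TRUE)[[1L]]
    if (any(!res %in% AA20))
      stop("illegal motif token '", tok, "' in '", text, "'")
    res
  })
  structure(list(name = name, text = text, sets = sets,
                 length = length(sets)), class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern", x$name, "(", x$length, "positions )\n")
  invisible(x)
}

#' @export
format.motif_pattern <- function(x, ...) {
  paste(vapply(x$sets, function(s) {
    if (is.null(s)) "x" else paste(s, collapse = "/")
  }, ""), collapse = "-")
}

match_window <- function(pattern, chars, start) {
  # start is a 0-based residue index; chars a character vector
  for (k in seq_len(pattern$length)) {
    s <- pattern$sets[[k]]
    if (!is.null(s) && !(chars[start + k] %in% s)) return(FALSE)
  }
  TRUE
}

#' Scan one sequence for a motif
#'
#' Reports all occurrences, leftmost first; overlaps allowed.
#'
#' @param pattern a [compile_pattern()] result.
#' @param record a single-record [protein_set()] or a plain residue string.
#' @param seq_id id to report (taken from `record` when it is a
#'   `protein_set`).
#' @return A data.frame of hits: `pattern_name`, `seq_id`, `start` (0-based),
#'   `matched`, `resolved` ('|'-joined residues matched at non-fixed
#'   positions). Zero rows when there is no match.
#' @export
scan_sequence <- function(pattern, record, seq_id = NULL) {
  if (inherits(record, "protein_set")) {
    stopifnot(length(record) == 1L)
    seq_id <- seq_id %||% record$id[[1L]]
    s <- record$seq[[1L]]
  } else {
    s <- toupper(as.character(record))
    seq_id <- seq_id %||% ""
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(chars); m <- pattern$length
  starts <- integer(); matched <- character(); resolved <- character()
  free <- which(vapply(pattern$sets, function(s)
    is.null(s) || length(s) > 1L, TRUE))
  if (L >= m) {
    for (i in 0:(L - m)) {
      if (match_window(pattern, chars, i)) {
        starts <- c(starts, i)
        win <- chars[(i + 1L):(i + m)]
        matched <- c(matched, paste(win, collapse = ""))
        resolved <- c(resolved, paste(win[free], collapse = "|"))
      }
    }
  }
  data.frame(pattern_name = rep(pattern$name, length(starts)),
             seq_id = rep(seq_id, length(starts)),
             start = starts, matched = matched, resolved = resolved,
             stringsAsFactors = FALSE)
}

#' Validate GH51 family membership of one sequence
#'
#' A sequence passes when it is at least `min_len` residues long and carries
#' at least one occurrence of each of the two conserved catalytic-region
#' motifs, G-N-E/Q (acid/base) and S-E-Y-x-V (nucleophile). Sequences
#' shorter than 350 residues or missing either motif are excluded from the
#' family. `relaxed = TRUE` additionally accepts G-N-D and G-S-N at the
#' acid/base motif (variants that occur in some monocot sequences).
#'
#' @param record single-record [protein_set()].
#' @param min_len minimum residue count (default 350).
#' @param relaxed accept G-N-D / G-S-N in place of G-N-E/Q.
#' @return A list: `seq_id`, `passed`, `reasons` (character vector drawn from
#'   `too_short`, `missing_GNEQ`, `missing_SEYxV`).
#' @export
validate_gh51 <- function(record, min_len = 350L, relaxed = FALSE) {
  stopifnot(inherits(record, "protein_set"), length(record) == 1L)
  reasons <- character()
  if (nchar(record$seq[[1L]]) < min_len) reasons <- c(reasons, "too_short")
  acid_base <- if (relaxed) "G-N/S-E/Q/D/N" else MOTIF_GNEQ
  if (!nrow(scan_sequence(compile_pattern(acid_base, "GNEQ"), record)))
    reasons <- c(reasons, "missing_GNEQ")
  if (!nrow(scan_sequence(compile_pattern(MOTIF_SEYXV), record)))
    reasons <- c(reasons, "missing_SEYxV")
  list(seq_id = record$id[[1L]], passed = !length(reasons), reasons = reasons)
}

#' Partition a sequence set by the GH51 validation filter
#'
#' @param records a [protein_set()] with unique ids.
#' @param min_len,relaxed passed to [validate_gh51()].
#' @return A list with `kept` (a `protein_set`, input order preserved) and
#'   `excluded` (data.frame `seq_id`, `length`, `reasons` with ';'-joined
#'   reason codes), plus `report`: one row per input sequence.
#' @export
filter_set <- function(records, min_len = 350L, relaxed = FALSE) {
  n <- length(records)
  passed <- logical(n); reasons <- character(n)
  for (i in seq_len(n)) {
    v <- validate_gh51(records[i], min_len = min_len, relaxed = relaxed)
    passed[i] <- v$passed
    reasons[i] <- paste(v$reasons, collapse = ";")
  }
  report <- data.frame(seq_id = records$id, length = nchar(records$seq),
                       passed = passed, reasons = reasons,
                       stringsAsFactors = FALSE)
  list(kept = records[which(passed)],
       excluded = report[!passed, , drop = FALSE],
       report = report)
}

#' Locate a conserved motif in an alignment
#'
#' Slides the pattern over column windows. A window "matches" a row when the
#' row's residues at the window's columns (gaps disqualify) satisfy the
#' pattern. Among windows matching at least `min_fraction` of rows, the one
#' with the highest match fraction wins; ties break leftmost.
#'
#' @param x an [msa()].
#' @param pattern a [compile_pattern()] result.
#' @param min_fraction minimum fraction of rows that must match (default
#'   0.5; "conserved" has no stated threshold so a majority is required).
#' @return A list `c_start`, `c_end` (0-based half-open column interval) and
#'   `fraction`, or `NULL` when no window reaches `min_fraction`.
#' @export
locate_conserved_motif <- function(x, pattern, min_fraction = 0.5) {
  m <- pattern$length
  if (m > x$n_cols) stop("pattern longer than alignment (", x$n_cols, " cols)")
  mat <- msa_matrix(x)
  n <- nrow(mat)
  best_frac <- -1; best_start <- NA_integer_
  for (c0 in 0:(x$n_cols - m)) {
    cols <- (c0 + 1L):(c0 + m)
    ok <- 0L
    for (r in seq_len(n)) {
      win <- mat[r, cols]
      if (any(win == "-")) next
      hit <- TRUE
      for (k in seq_len(m)) {
        s <- pattern$sets[[k]]
        if (!is.null(s) && !(win[[k]] %in% s)) { hit <- FALSE; break }
      }
      if (hit) ok <- ok + 1L
    }
    frac <- ok / n
    if (frac > best_frac + 1e-12) { best_frac <- frac; best_start <- c0 }
  }
  if (best_frac < min_fraction) return(NULL)
  list(c_start = best_start, c_end = best_start + m, fraction = best_frac)
}

#' Classify the catalytic acid/base position of one sequence
#'
#' Direct-scan path: the sequence is searched for G-N-E (canonical), then
#' G-N-Q, then G-N-D, then G-S-N. When an alignment and a reference
#' acid/base column are supplied, the call is made from the residue in that
#' column instead (E/Q/D; anything else is `undetermined`) with
#' `evidence = "alignment_column"`; with several direct matches the one whose
#' motif spans the reference column wins, otherwise the leftmost (flagged
#' `ambiguous`).
#'
#' @param record single-record [protein_set()].
#' @param msa optional [msa()] containing the record's row.
#' @param ref_column optional 0-based alignment column of the acid/base
#'   residue (the E of G-N-E).
#' @return A list: `seq_id`, `status` (one of `canonical_E`,
#'   `substituted_Q`, `substituted_D`, `variant_GSN`, `undetermined`),
#'   `motif_start` (0-based, `NA` for alignment evidence), `evidence`
#'   (`direct_scan` or `alignment_column`), `ambiguous` flag.
#' @export
classify_catalytic <- function(record, msa = NULL, ref_column = NULL) {
  stopifnot(inherits(record, "protein_set"), length(record) == 1L)
  id <- record$id[[1L]]
  use_column <- !is.null(msa) && !is.null(ref_column)

  if (!use_column) {
    variants <- list(canonical_E = "G-N-E", substituted_Q = "G-N-Q",
                     substituted_D = "G-N-D", variant_GSN = "G-S-N")
    for (st in names(variants)) {
      hits <- scan_sequence(compile_pattern(variants[[st]]), record)
      if (nrow(hits)) {
        return(list(seq_id = id, status = st,
                    motif_start = hits$start[[1L]], evidence = "direct_scan",
                    ambiguous = nrow(hits) > 1L))
      }
    }
    return(list(seq_id = id, status = "undetermined", motif_start = NA_integer_,
                evidence = "direct_scan", ambiguous = FALSE))
  }

  maps <- msa_maps(msa, id)
  res_idx <- maps$col_to_res[[ref_column + 1L]]
  aa <- if (is.na(res_idx)) NA_character_ else
    substr(record$seq[[1L]], res_idx + 1L, res_idx + 1L)
  status <- switch(aa %||na% "",
                   E = "canonical_E", Q = "substituted_Q", D = "substituted_D",
                   "undetermined")
  # prefer a direct motif hit spanning the reference column for motif_start
  motif_start <- NA_integer_; ambiguous <- FALSE
  pat_txt <- switch(status, canonical_E = "G-N-E", substituted_Q = "G-N-Q",
                    substituted_D = "G-N-D", NA_character_)
  if (!is.na(pat_txt)) {
    hits <- scan_sequence(compile_pattern(pat_txt), record)
    if (nrow(hits)) {
      at_ref <- which(hits$start + 2L == res_idx)
      motif_start <- if (length(at_ref)) hits$start[[at_ref[[1L]]]]
                     else hits$start[[1L]]
      ambiguous <- nrow(hits) > 1L && !length(at_ref)
    }
  }
  list(seq_id = id, status = status, motif_start = motif_start,
       evidence = "alignment_column", ambiguous = ambiguous)
}

`%||na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Classify the catalytic status of every sequence in a set
#'
#' @param records a [protein_set()].
#' @param msa,ref_column optional alignment evidence (see
#'   [classify_catalytic()]).
#' @return A data.frame with one row per sequence: `seq_id`, `status`,
#'   `motif_start`, `evidence`, `ambiguous`.
#' @export
classify_catalytic_set <- function(records, msa = NULL, ref_column = NULL) {
  rows <- lapply(seq_along(records$id), function(i) {
    cc <- classify_catalytic(records[i], msa = msa, ref_column = ref_column)
    data.frame(seq_id = cc$seq_id, status = cc$status,
               motif_start = cc$motif_start, evidence = cc$evidence,
               ambiguous = cc$ambiguous, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the validation report TSV
#' @param report the `report` element of [filter_set()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the catalytic classification report TSV (1-based motif starts)
#' @param calls a [classify_catalytic_set()] data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalytic_report <- function(calls, path) {
  out <- calls
  out$motif_start <- ifelse(is.na(out$motif_start), NA, out$motif_start + 1L)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
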