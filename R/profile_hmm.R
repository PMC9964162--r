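# Profile HMM construction from a (domain) alignment and sequence scanning:
# a native stand-in for hmmbuild/hmmscan. Match columns are chosen by a
# maximum-gap-fraction rule; emissions and transitions are estimated from
# the observed match/insert/delete paths with Laplace-style pseudocounts
# mixed with the background; scoring is log-odds in bits against an i.i.d.
# background null with a geometric length term matched to the local-mode
# flank transitions. Sequence weighting is uniform (no Henikoff weighting),
# a documented deviation from hmmbuild defaults.

PHMM_R_NULL <- 350 / 351   # geometric null / flank-loop parameter
PHMM_TAU <- 0.1            # local-mode per-match-state exit probability

#' Select match columns of an alignment
#'
#' A column is a match column when its gap fraction is at most
#' `max_gap_fraction`.
#'
#' @param x an [msa()].
#' @param max_gap_fraction maximum tolerated gap fraction (default 0.5).
#' @return Logical vector, one flag per column.
#' @export
select_match_columns <- function(x, max_gap_fraction = 0.5) {
  mat <- msa_matrix(x)
  gap_frac <- colMeans(mat == "-")
  flags <- gap_frac <= max_gap_fraction
  if (!any(flags)) stop("no match columns at max_gap_fraction = ",
                        max_gap_fraction)
  flags
}

#' Build a profile HMM from an alignment
#'
#' @param x an [msa()] (typically the excised CBM4-like domain alignment).
#' @param pseudocount Laplace-style pseudocount weight alpha mixed with the
#'   background (default 1.0).
#' @param background `"uniform"` (1/20 each) or `"from_alignment"` (smoothed
#'   residue frequencies over the alignment).
#' @param max_gap_fraction match-column rule, see [select_match_columns()].
#' @return A `profile_hmm`: match-state count `M`, `match_emis` (M x 20
#'   probability matrix), `insert_emis` (= background), `trans`
#'   ((M+1) x 3 x 3 array over from/to {M,I,D}; row M at position 0 is the
#'   begin state, target M at position M is the end state), `bg`, and build
#'   metadata. All distributions sum to 1 after pseudocounting (asserted).
#' @export
build_profile <- function(x, pseudocount = 1.0,
                          background = c("uniform", "from_alignment"),
                          max_gap_fraction = 0.5) {
  background <- match.arg(background)
  stopifnot(inherits(x, "msa"), length(x$id) >= 1L)
  flags <- select_match_columns(x, max_gap_fraction)
  M <- sum(flags)
  mat <- msa_matrix(x)
  n <- nrow(mat)

  bg <- if (background == "uniform") rep(1 / 20, 20) else {
    res <- mat[mat != "-" & mat != "X"]
    cnt <- table(factor(res, levels = AA20))
    as.numeric(cnt + 1) / (sum(cnt) + 20)
  }
  names(bg) <- AA20

  # emission counts at match columns (X not counted)
  ecounts <- matrix(0, nrow = M, ncol = 20, dimnames = list(NULL, AA20))
  mcols <- which(flags)
  for (k in seq_len(M)) {
    col <- mat[, mcols[[k]]]
    col <- col[col != "-" & col != "X"]
    if (length(col)) {
      tb <- table(factor(col, levels = AA20))
      ecounts[k, ] <- as.numeric(tb)
    }
  }
  a <- pseudocount
  match_emis <- (ecounts + a * matrix(bg, M, 20, byrow = TRUE)) /
    (rowSums(ecounts) + a)

  # transition counts from per-row state paths through the architecture
  tcounts <- array(0, dim = c(M + 1, 3, 3),
                   dimnames = list(NULL, c("M", "I", "D"), c("M", "I", "D")))
  is_match <- flags
  for (r in seq_len(n)) {
    k <- 0L; prev <- c(0L, 1L)             # (k, type); type 1=M/B, 2=I, 3=D
    for (c in seq_len(ncol(mat))) {
      ch <- mat[r, c]
      if (is_match[[c]]) {
        k <- k + 1L
        typ <- if (ch == "-") 3L else 1L
        tcounts[prev[[1L]] + 1L, prev[[2L]], typ] <-
          tcounts[prev[[1L]] + 1L, prev[[2L]], typ] + 1
        prev <- c(k, typ)
      } else if (ch != "-") {
        tcounts[prev[[1L]] + 1L, prev[[2L]], 2L] <-
          tcounts[prev[[1L]] + 1L, prev[[2L]], 2L] + 1
        prev <- c(k, 2L)
      }
    }
    tcounts[prev[[1L]] + 1L, prev[[2L]], 1L] <-   # -> E
      tcounts[prev[[1L]] + 1L, prev[[2L]], 1L] + 1
  }

  # +pseudocount smoothing over the valid targets of each from-state
  trans <- array(0, dim = dim(tcounts), dimnames = dimnames(tcounts))
  for (k in 0:M) {
    for (from in 1:3) {
      if (k == 0L && from == 3L) next                 # no D0
      valid <- if (k == M) c(1L, 2L) else 1:3          # no D(M+1)
      v <- tcounts[k + 1L, from, valid] + a
      trans[k + 1L, from, valid] <- v / sum(v)
    }
  }

  prof <- structure(list(M = M, match_emis = match_emis, insert_emis = bg,
                         trans = trans, bg = bg, pseudocount = a,
                         background = background,
                         max_gap_fraction = max_gap_fraction,
                         match_cols = mcols - 1L,
                         n_seqs = n, tau = PHMM_TAU, r = PHMM_R_NULL),
                    class = "profile_hmm")
  check_profile(prof)
  prof
}

check_profile <- function(p, tol = 1e-9) {
  stopifnot(p$M >= 1L)
  if (any(abs(rowSums(p$match_emis) - 1) > tol))
    stop("match emission distribution does not sum to 1")
  if (abs(sum(p$bg) - 1) > tol) stop("background does not sum to 1")
  for (k in 0:p$M) for (from in 1:3) {
    if (k == 0L && from == 3L) next
    s <- sum(p$trans[k + 1L, from, ])
    if (abs(s - 1) > tol)
      stop("transition distribution (k=", k, ", from=", from,
           ") sums to ", s)
  }
  invisible(p)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm with", x$M, "match states (built from", x$n_seqs,
      "sequences,", x$background, "background)\n")
  invisible(x)
}

encode_seq <- function(s) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1L]], c(AA20, "X")) - 1L
  if (anyNA(idx)) stop("illegal residue in sequence")
  idx
}

trans_flat <- function(p) as.numeric(aperm(p$trans, c(3L, 2L, 1L)))

emission_odds <- function(p) {
  lo <- log2(p$match_emis) - matrix(log2(p$bg), p$M, 20, byrow = TRUE)
  cbind(lo, 0)  # X column
}

#' Forward log-odds score of a sequence against a profile
#'
#' Returns `log2 P(seq | profile) / P(seq | null)` in bits, summed over all
#' state paths, computed in log space. Local mode allows the domain to sit
#' anywhere in the sequence (uniform entry/exit across match states);
#' glocal mode requires traversing the whole model.
#'
#' @param profile a [build_profile()] result.
#' @param record single-record [protein_set()] or residue string.
#' @param mode `"local"` or `"glocal"`.
#' @return Forward score in bits (finite).
#' @export
forward_bits <- function(profile, record, mode = c("local", "glocal")) {
  mode <- match.arg(mode)
  s <- if (inherits(record, "protein_set")) record$seq[[1L]] else
    toupper(as.character(record))
  stopifnot(nzchar(s))
  .phmm_forward_cpp(emission_odds(profile), trans_flat(profile),
                    encode_seq(s), mode == "local", profile$tau, profile$r)
}

#' Viterbi best path of a sequence against a profile
#'
#' @inheritParams forward_bits
#' @return A list: `bits` (best single-path log-odds; always at most the
#'   Forward score), `path` (state labels), `start`, `end` (0-based
#'   half-open residue interval consumed by the core model).
#' @export
viterbi <- function(profile, record, mode = c("local", "glocal")) {
  mode <- match.arg(mode)
  s <- if (inherits(record, "protein_set")) record$seq[[1L]] else
    toupper(as.character(record))
  stopifnot(nzchar(s))
  .phmm_viterbi_cpp(emission_odds(profile), trans_flat(profile),
                    encode_seq(s), mode == "local", profile$tau, profile$r)
}

#' Scan a sequence collection with a profile
#'
#' Sequences of length at most `min_len` are skipped (recorded, not scored):
#' only sequences longer than 200 residues take part in the domain search by
#' default. Each remaining record is Forward-scored and passes when its bit
#' score reaches `threshold`.
#'
#' @param profile a [build_profile()] result.
#' @param records a [protein_set()].
#' @param threshold bit-score acceptance threshold in bits (default 25).
#' @param min_len skip rule: scan only sequences with `length > min_len`
#'   (default 200).
#' @param mode `"local"` or `"glocal"`.
#' @return A data.frame in input order: `seq_id`, `group`, `length`,
#'   `bit_score` (`NA` when skipped), `status` (`passed`, `failed`,
#'   `skipped`), and the Viterbi `start`/`end` interval for scored records.
#' @export
scan_profile <- function(profile, records, threshold = 25, min_len = 200L,
                         mode = c("local", "glocal")) {
  mode <- match.arg(mode)
  n <- length(records)
  out <- data.frame(seq_id = records$id, group = records$group,
                    length = if (n) nchar(records$seq) else integer(),
                    bit_score = rep(NA_real_, n),
                    status = rep("skipped", n),
                    start = rep(NA_integer_, n), end = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (out$length[[i]] <= min_len) next
    bits <- forward_bits(profile, records[i], mode = mode)
    vit <- viterbi(profile, records[i], mode = mode)
    out$bit_score[[i]] <- bits
    out$status[[i]] <- if (bits >= threshold) "passed" else "failed"
    out$start[[i]] <- vit$start; out$end[[i]] <- vit$end
  }
  out
}

#' Write a scan report TSV
#' @param hits a [scan_profile()] data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a profile HMM to plain text
#'
#' A documented HMMER3-like layout: a header, the background line, one
#' MATCH line per state and one TRANS line per position (probabilities,
#' full precision).
#'
#' @param profile a `profile_hmm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w"); on.exit(close(con))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  writeLines(c("GH51KIT-PHMM 1",
               paste("M", profile$M),
               paste("NSEQ", profile$n_seqs),
               paste("PSEUDOCOUNT", sprintf("%.17g", profile$pseudocount)),
               paste("BACKGROUND_MODE", profile$background),
               paste("TAU", sprintf("%.17g", profile$tau)),
               paste("RNULL", sprintf("%.17g", profile$r)),
               paste("MATCH_COLS", paste(profile$match_cols, collapse = " ")),
               paste("ALPHABET", paste(AA20, collapse = "")),
               paste("BG", num(profile$bg))), con)
  for (k in seq_len(profile$M))
    writeLines(paste("MATCH", k, num(profile$match_emis[k, ])), con)
  for (k in 0:profile$M)
    writeLines(paste("TRANS", k, num(as.numeric(profile$trans[k + 1L, , ]))), con)
  writeLines("END", con)
  invisible(path)
}

#' Read a serialized profile HMM
#' @param path path written by [write_profile()].
#' @return A `profile_hmm`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[[1L]], "GH51KIT-PHMM"))
    stop("not a gh51kit profile file: ", path)
  fields <- function(tag) {
    ln <- grep(paste0("^", tag, " "), lines, value = TRUE)[[1L]]
    strsplit(sub(paste0("^", tag, " "), "", ln), " ", fixed = TRUE)[[1L]]
  }
  M <- as.integer(fields("M")[[1L]])
  bg <- as.numeric(fields("BG")); names(bg) <- AA20
  match_emis <- matrix(0, M, 20, dimnames = list(NULL, AA20))
  for (ln in grep("^MATCH ", lines, value = TRUE)) {
    parts <- strsplit(ln, " ", fixed = TRUE)[[1L]]
    match_emis[as.integer(parts[[2L]]), ] <- as.numeric(parts[-(1:2)])
  }
  trans <- array(0, dim = c(M + 1, 3, 3),
                 dimnames = list(NULL, c("M", "I", "D"), c("M", "I", "D")))
  for (ln in grep("^TRANS ", lines, value = TRUE)) {
    parts <- strsplit(ln, " ", fixed = TRUE)[[1L]]
    trans[as.integer(parts[[2L]]) + 1L, , ] <- as.numeric(parts[-(1:2)])
  }
  prof <- structure(list(M = M, match_emis = match_emis, insert_emis = bg,
                         trans = trans, bg = bg,
                         pseudocount = as.numeric(fields("PSEUDOCOUNT")[[1L]]),
                         background = fields("BACKGROUND_MODE")[[1L]],
                         max_gap_fraction = NA_real_,
                         match_cols = as.integer(fields("MATCH_COLS")),
                         n_seqs = as.integer(fields("NSEQ")[[1L]]),
                         tau = as.numeric(fields("TAU")[[1L]]),
                         r = as.numeric(fields("RNULL")[[1L]])),
                    class = "profile_hmm")
  check_profile(prof)
  prof
}
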