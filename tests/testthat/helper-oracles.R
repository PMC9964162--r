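# Independent oracles used by the property and acceptance tests. Each one
# avoids the code path it checks: motif scanning via the regex engine,
# profile-HMM scores via explicit path enumeration, global alignment via
# exhaustive recursion, NJ via additive matrices built from known trees.

## ---- motif scanning: regex with lookahead (overlapping matches) ----

pattern_to_regex <- function(text) {
  toks <- strsplit(text, "-", fixed = TRUE)[[1L]]
  body <- paste(vapply(toks, function(tok) {
    if (tok == "x") "[A-Z]"
    else {
      res <- strsplit(tok, "/", fixed = TRUE)[[1L]]
      if (length(res) == 1L) res else paste0("[", paste(res, collapse = ""), "]")
    }
  }, ""), collapse = "")
  paste0("(?=", body, ")")
}

oracle_scan_starts <- function(text, seq) {
  m <- gregexpr(pattern_to_regex(text), seq, perl = TRUE)[[1L]]
  if (m[[1L]] == -1L) integer() else as.integer(m) - 1L
}

random_seq <- function(len, alphabet = c(AA20_T, "X")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## ---- profile HMM: exhaustive path enumeration ----

# random profile parameters with the package's architecture (valid
# distributions; not built from an alignment)
random_profile <- function(M, seed = NULL) {
  emis <- matrix(NA_real_, M, 20, dimnames = list(NULL, AA20_T))
  for (k in seq_len(M)) {
    v <- rgamma(20, shape = 0.5) + 1e-6
    emis[k, ] <- v / sum(v)
  }
  bg <- rep(1 / 20, 20); names(bg) <- AA20_T
  trans <- array(0, dim = c(M + 1, 3, 3),
                 dimnames = list(NULL, c("M", "I", "D"), c("M", "I", "D")))
  for (k in 0:M) for (from in 1:3) {
    if (k == 0 && from == 3) next
    valid <- if (k == M) 1:2 else 1:3
    v <- rgamma(length(valid), shape = 1) + 0.05
    trans[k + 1, from, valid] <- v / sum(v)
  }
  structure(list(M = M, match_emis = emis, insert_emis = bg, trans = trans,
                 bg = bg, pseudocount = 1, background = "uniform",
                 max_gap_fraction = 0.5, match_cols = seq_len(M) - 1L,
                 n_seqs = 1L, tau = 0.1, r = 350 / 351),
            class = "profile_hmm")
}

# enumerate every state path; returns list(forward_bits, viterbi_bits)
oracle_phmm <- function(prof, seq, local = TRUE) {
  M <- prof$M; tau <- prof$tau; r <- prof$r
  a <- match(strsplit(seq, "", fixed = TRUE)[[1L]], c(AA20_T, "X"))
  L <- length(a)
  odds <- function(k, ai) if (ai == 21L) 1 else
    prof$match_emis[k, ai] / prof$bg[[ai]]
  tr <- function(k, from, to) prof$trans[k + 1L, from, to]
  total <- 0; best <- -Inf; best_path <- character()

  # scale applied to continuing moves out of a match state (local exits)
  cscale <- function(k, from) if (local && from == 1L && k >= 1L) 1 - tau else 1
  exit_w <- function(k, from) {
    if (local) {
      if (from == 1L) {
        if (k == M) tau + (1 - tau) * tr(M, 1L, 1L) else tau
      } else if (k == M) tr(M, from, 1L) else 0
    } else if (k == M) tr(M, from, 1L) else 0
  }

  walk <- function(k, from, i, w, path) {
    ew <- exit_w(k, from)
    if (ew > 0) {
      total <<- total + w * ew
      if (w * ew > best) { best <<- w * ew; best_path <<- path }
    }
    s <- cscale(k, from)
    if (k < M && i < L)                     # -> M_{k+1}
      walk(k + 1L, 1L, i + 1L, w * s * tr(k, from, 1L) *
             odds(k + 1L, a[[i + 1L]]) / r,
           c(path, paste0("M", k + 1L)))
    if (i < L)                              # -> I_k
      walk(k, 2L, i + 1L, w * s * tr(k, from, 2L) / r,
           c(path, paste0("I", k)))
    if (k < M)                              # -> D_{k+1}
      walk(k + 1L, 3L, i, w * s * tr(k, from, 3L),
           c(path, paste0("D", k + 1L)))
  }

  if (local) {
    for (j in seq_len(M)) for (i in seq_len(L))
      walk(j, 1L, i, (1 / M) * odds(j, a[[i]]) / r, paste0("M", j))
  } else {
    for (i0 in 0:L) {
      if (i0 < L) {
        walk(1L, 1L, i0 + 1L, tr(0L, 1L, 1L) * odds(1L, a[[i0 + 1L]]) / r, "M1")
        walk(0L, 2L, i0 + 1L, tr(0L, 1L, 2L) / r, "I0")
      }
      walk(1L, 3L, i0, tr(0L, 1L, 3L), "D1")
    }
  }
  list(forward = unname(log2(total)), viterbi = unname(log2(best)),
       path = best_path)
}

## ---- global alignment: exhaustive recursion over all alignments ----

oracle_align_score <- function(a, b, sub, gap_open, gap_extend) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, last) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m)
      best <- max(best, sub[ca[[i + 1L]], cb[[j + 1L]]] + rec(i + 1L, j + 1L, "M"))
    if (i < n)  # gap in b
      best <- max(best, -(if (last == "X") gap_extend else gap_open) +
                    rec(i + 1L, j, "X"))
    if (j < m)  # gap in a
      best <- max(best, -(if (last == "Y") gap_extend else gap_open) +
                    rec(i, j + 1L, "Y"))
    best
  }
  rec(0L, 0L, "start")
}

## ---- NJ: additive matrices from random trees ----

random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(n) runif(n, 0.05, 0.5))
  tr <- ape::unroot(tr)
  dm <- cophenetic(tr)
  dm <- dm[order(rownames(dm)), order(colnames(dm))]
  list(tree = tr, dm = dm)
}

## ---- shared fixtures ----

# small gap-free family alignment with planted domain anchors
anchored_msa <- function() {
  mid <- strrep("A", 20)
  rows <- c(
    paste0("MKV", "LAVD", mid, "SQKP", "WYFE"),
    paste0("MKV", "LTVD", mid, "SARP", "WYFE"),
    paste0("MKV", "LSVD", mid, "SGGP", "WYFE"),
    paste0("MKV", "LAVD", mid, "SQKP", "WYFE"))
  msa(paste0("s", 1:4), rows)
}
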