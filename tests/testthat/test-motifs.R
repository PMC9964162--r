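test_that("compile_pattern parses fixed, alternation and wildcard tokens", {
  p <- compile_pattern("G-N-E/Q")
  expect_equal(p$length, 3L)
  expect_equal(p$sets[[1L]], "G")
  expect_equal(sort(p$sets[[3L]]), c("E", "Q"))
  expect_null(compile_pattern("S-x-x-P")$sets[[2L]])
  expect_equal(format(compile_pattern("G-x-x-F-E-x-I-x-x-x-G-x-G-G")),
               "G-x-x-F-E-x-I-x-x-x-G-x-G-G")
  expect_error(compile_pattern("G--N"), "empty token")
  expect_error(compile_pattern("G-N-1"), "illegal motif token")
  expect_error(compile_pattern("G"), "at least 2")
})

test_that("scan_sequence reports all occurrences leftmost-first", {
  hits <- scan_sequence(compile_pattern("S-E-Y-x-V"), "ASEYKVA")
  expect_equal(hits$start, 1L)
  expect_equal(hits$matched, "SEYKV")

  hits <- scan_sequence(compile_pattern("G-N-E/Q"), "GNQGNE")
  expect_equal(hits$start, c(0L, 3L))
  expect_equal(hits$resolved, c("Q", "E"))

  expect_equal(nrow(scan_sequence(compile_pattern("G-N-E"), "AAAA")), 0L)
})

test_that("wildcards match X but fixed tokens never do", {
  expect_equal(nrow(scan_sequence(compile_pattern("S-x-x-P"), "SXXP")), 1L)
  expect_equal(nrow(scan_sequence(compile_pattern("G-N-E"), "XNE")), 0L)
  expect_equal(nrow(scan_sequence(compile_pattern("G-N-E/Q"), "GNX")), 0L)
})

test_that("scan_sequence equals the regex window oracle on random input", {
  set.seed(101)
  pats <- c("G-N-E/Q", "S-E-Y-x-V", "L-x-V-D", "S-x-x-P",
            "G-x-x-F-E-x-I-x-x-x-G-x-G-G", "A-C/D/E-x-x-W")
  for (rep in 1:200) {
    s <- random_seq(sample(5:60, 1))
    pat <- sample(pats, 1)
    got <- scan_sequence(compile_pattern(pat), s)$start
    expect_identical(got, oracle_scan_starts(pat, s),
                     info = paste(pat, s))
  }
})

test_that("validate_gh51 applies the 350-residue boundary and motif rules", {
  core <- "GNEAAASEYKV"
  pad <- function(n) paste0(core, strrep("A", n - nchar(core)))
  v349 <- validate_gh51(protein_set("a", pad(349)))
  expect_false(v349$passed)
  expect_equal(v349$reasons, "too_short")

  v350 <- validate_gh51(protein_set("a", pad(350)))
  expect_true(v350$passed)
  expect_length(v350$reasons, 0L)

  no_sey <- protein_set("a", paste0("GNE", strrep("A", 400)))
  v <- validate_gh51(no_sey)
  expect_false(v$passed)
  expect_equal(v$reasons, "missing_SEYxV")

  neither <- validate_gh51(protein_set("a", strrep("A", 100)))
  expect_setequal(neither$reasons,
                  c("too_short", "missing_GNEQ", "missing_SEYxV"))
})

test_that("validate_gh51 is monotone in min_len", {
  set.seed(7)
  core <- "GNEAAASEYKV"
  for (rep in 1:25) {
    n <- sample(300:420, 1)
    ps <- protein_set("a", paste0(core, strrep("A", n)))
    hi <- validate_gh51(ps, min_len = 380L)
    lo <- validate_gh51(ps, min_len = 320L)
    if (hi$passed) expect_true(lo$passed)
  }
})

test_that("relaxed validation admits G-N-D and G-S-N acid/base variants", {
  gsd <- protein_set("a", paste0("GND", strrep("A", 342), "SEYKV"))
  expect_false(validate_gh51(gsd)$passed)
  expect_true(validate_gh51(gsd, relaxed = TRUE)$passed)
})

test_that("filter_set partitions without loss and matches planted truth", {
  # 156 synthetic sequences, exactly 17 planted violations (mirrors the
  # published 139/156 survival count at synthetic scale)
  set.seed(42)
  core <- "GNEAAASEYKV"
  good <- function() paste0(core, paste(sample(AA20_T, 389, TRUE),
                                        collapse = ""))
  seqs <- vapply(1:156, function(i) good(), "")
  bad_idx <- sample(156, 17)
  kinds <- rep(c("short", "no_gne", "no_sey"), length.out = 17)
  for (k in seq_along(bad_idx)) {
    i <- bad_idx[[k]]
    seqs[[i]] <- switch(kinds[[k]],
      short = substr(seqs[[i]], 1, 349),
      no_gne = gsub("GN[EQ]", "AAA", gsub("E", "A", seqs[[i]])),
      no_sey = gsub("SEY.V", "AAAAA",
                    gsub("E", "A", sub("^GNE", "GNE", seqs[[i]]))))
  }
  # re-plant what the blunt substitutions may have removed
  for (k in seq_along(bad_idx)) {
    i <- bad_idx[[k]]
    if (kinds[[k]] == "no_gne")
      seqs[[i]] <- paste0(substr(seqs[[i]], 1, 389), "SEYKV",
                          strrep("A", 6))
    if (kinds[[k]] == "no_sey")
      seqs[[i]] <- paste0("GNE", substr(seqs[[i]], 4, 400))
  }
  ps <- protein_set(sprintf("s%03d", 1:156), seqs)
  res <- filter_set(ps)
  truth_bad <- !vapply(seqs, function(s)
    nchar(s) >= 350 && length(oracle_scan_starts("G-N-E/Q", s)) > 0 &&
      length(oracle_scan_starts("S-E-Y-x-V", s)) > 0, TRUE)
  expect_equal(nrow(res$excluded), sum(truth_bad))
  expect_equal(length(res$kept), 156L - sum(truth_bad))
  expect_setequal(c(res$kept$id, res$excluded$seq_id), ps$id)
  expect_equal(sum(truth_bad), 17L)

  empty <- filter_set(protein_set(character(), character()))
  expect_length(empty$kept, 0L)
  expect_equal(nrow(empty$excluded), 0L)
})

test_that("locate_conserved_motif finds the best-supported window", {
  m <- anchored_msa()
  hit <- locate_conserved_motif(m, compile_pattern("L-x-V-D"))
  expect_equal(hit$c_start, 3L)
  expect_equal(hit$c_end, 7L)
  expect_equal(hit$fraction, 1.0)

  none <- locate_conserved_motif(m, compile_pattern("W-W-W-W"))
  expect_null(none)
  expect_error(locate_conserved_motif(msa("a", "ACD"),
                                      compile_pattern("S-E-Y-x-V")),
               "longer than alignment")
})

test_that("locate_conserved_motif agrees with a brute-force window oracle", {
  set.seed(31)
  pat_txt <- "L-x-V-D"
  for (rep in 1:50) {
    n_rows <- sample(3:6, 1); n_cols <- sample(8:20, 1)
    rows <- vapply(seq_len(n_rows), function(i)
      paste(sample(c("L", "V", "D", "A", "-"), n_cols, TRUE), collapse = ""),
      "")
    rows[1] <- gsub("-", "A", rows[1])  # keep at least one ungapped row
    m <- msa(paste0("r", seq_len(n_rows)), rows)
    # oracle: evaluate every window by regex on the window strings
    mat <- msa_matrix(m)
    best <- NULL
    for (c0 in 0:(n_cols - 4L)) {
      win <- apply(mat[, (c0 + 1L):(c0 + 4L), drop = FALSE], 1, paste,
                   collapse = "")
      ok <- !grepl("-", win, fixed = TRUE) & grepl("^L[A-Z]VD$", win)
      frac <- mean(ok)
      if (is.null(best) || frac > best$fraction + 1e-12)
        best <- list(c_start = c0, fraction = frac)
    }
    got <- locate_conserved_motif(m, compile_pattern(pat_txt),
                                  min_fraction = 0.5)
    if (best$fraction >= 0.5) {
      expect_equal(got$c_start, best$c_start)
      expect_equal(got$fraction, best$fraction)
    } else expect_null(got)
  }
})

test_that("classify_catalytic follows the scan precedence E > Q > D > GSN", {
  mk <- function(s) protein_set("a", paste0("AAA", s, "AAA"))
  expect_equal(classify_catalytic(mk("GNE"))$status, "canonical_E")
  expect_equal(classify_catalytic(mk("GNQ"))$status, "substituted_Q")
  expect_equal(classify_catalytic(mk("GND"))$status, "substituted_D")
  expect_equal(classify_catalytic(mk("GSN"))$status, "variant_GSN")
  expect_equal(classify_catalytic(mk("AAA"))$status, "undetermined")
  # E precedes Q regardless of position
  both <- classify_catalytic(mk("GNQAAAGNE"))
  expect_equal(both$status, "canonical_E")
  expect_equal(both$motif_start, 9L)
})

test_that("classify_catalytic can call from an alignment column", {
  m <- msa(c("a", "b"), c("AGNE-A", "AGND-A"))
  ps_b <- protein_set("b", "AGNDA")
  cc <- classify_catalytic(ps_b, msa = m, ref_column = 3L)
  expect_equal(cc$status, "substituted_D")
  expect_equal(cc$evidence, "alignment_column")
  expect_equal(cc$motif_start, 1L)

  # gap in the reference column -> undetermined
  m2 <- msa(c("a", "b"), c("AGNE-A", "A---GA"))
  cc2 <- classify_catalytic(protein_set("b", "AGA"), msa = m2, ref_column = 3L)
  expect_equal(cc2$status, "undetermined")
})

test_that("classification agrees 100% with generator truth at zero noise", {
  fam <- generate_family(sim_params(
    n_per_group = c(plant = 40), sub_rate = 0, indel_rate = 0,
    decoy_fraction = 0, seed = 909,
    catalytic_composition = c(canonical_E = 0.5, substituted_Q = 0.3,
                              substituted_D = 0.1, variant_GSN = 0.1)))
  calls <- classify_catalytic_set(fam$records)
  expect_identical(calls$status, fam$truth$catalytic_status)
})
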