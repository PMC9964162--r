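# Synthetic GH51-like protein families with ground truth, so every pipeline
# stage is testable without downloads. A single ancestor carrying the two
# catalytic-region motifs (G-N-E, S-E-Y-x-V) and, per sequence with
# probability p, an N-terminal CBM4-like domain bracketed by L-x-V-D and
# S-x-x-P (with the internal G-x-x-F-E-x-I-x-x-x-G-x-G-G motif) is evolved
# by a star-like process: point substitutions from a flat non-identity
# model outside protected motif spans, and geometric-length indels (mean 2)
# never inside motifs, so truth labels stay exact. Decoys are
# residue-shuffled family sequences. A true alignment is emitted from the
# known indel history; everything is reproducible from the seed.

#' Simulation parameters for [generate_family()]
#'
#' @param n_per_group named integer vector of family-member counts per
#'   group.
#' @param len_range ancestor length range (residues); domain-less rows stay
#'   at or above 350 residues by construction.
#' @param domain_prevalence probability that a family member carries the
#'   N-terminal domain; scalar or named per group.
#' @param catalytic_composition named fractions over `canonical_E`,
#'   `substituted_Q`, `substituted_D`, `variant_GSN`; must sum to 1.
#' @param sub_rate per-residue substitution probability outside protected
#'   motif spans.
#' @param indel_rate per-residue indel event rate (events split evenly
#'   between insertions and deletions; lengths 1 + Geometric, mean 2).
#' @param decoy_fraction decoys emitted as a fraction of the family size
#'   (residue-shuffled, no domain, no catalytic truth).
#' @param seed integer seed (mandatory).
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(n_per_group = c(plant = 50),
                       len_range = c(350L, 700L),
                       domain_prevalence = 0.9,
                       catalytic_composition = c(canonical_E = 0.70,
                                                 substituted_Q = 0.25,
                                                 substituted_D = 0.03,
                                                 variant_GSN = 0.02),
                       sub_rate = 0.05,
                       indel_rate = 0.01,
                       decoy_fraction = 0.1,
                       seed) {
  if (missing(seed) || is.null(seed) || length(seed) != 1L ||
      is.na(suppressWarnings(as.integer(seed))))
    stop("seed is mandatory and must be a single integer")
  stopifnot(length(n_per_group) >= 1L, !is.null(names(n_per_group)),
            all(names(n_per_group) %in% GROUP_LEVELS),
            all(n_per_group >= 0))
  stopifnot(length(len_range) == 2L, len_range[[1L]] >= 350,
            len_range[[2L]] >= len_range[[1L]])
  stopifnot(all(domain_prevalence >= 0), all(domain_prevalence <= 1))
  comp <- catalytic_composition
  stopifnot(setequal(names(comp), c("canonical_E", "substituted_Q",
                                    "substituted_D", "variant_GSN")),
            all(comp >= 0), abs(sum(comp) - 1) < 1e-9)
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1)
  structure(list(n_per_group = n_per_group, len_range = len_range,
                 domain_prevalence = domain_prevalence,
                 catalytic_composition = comp, sub_rate = sub_rate,
                 indel_rate = indel_rate, decoy_fraction = decoy_fraction,
                 seed = as.integer(seed)),
            class = "sim_params")
}

rand_res <- function(n) sample(AA20, n, replace = TRUE)

# Rewrite accidental occurrences of the planted motif vocabulary so truth
# labels are exact: any match that is not one of the planted copies loses a
# fixed-token residue. `hard` marks the fixed-token positions of planted
# motifs (immutable); wildcard positions inside planted spans may be
# rewritten freely (the planted motif still matches by definition).
scrub_motifs <- function(anc, hard, planted_starts) {
  pats <- lapply(c(MOTIF_LXVD, MOTIF_SXXP, MOTIF_SEYXV,
                   "G-N-E", "G-N-Q", "G-N-D", "G-S-N"), compile_pattern)
  for (iter in 1:25) {
    dirty <- FALSE
    s <- paste(anc, collapse = "")
    for (pat in pats) {
      hits <- scan_sequence(pat, s)
      for (h in hits$start) {
        if (h %in% planted_starts) next          # a planted copy
        win <- (h + 1L):(h + pat$length)
        fixed <- win[!vapply(pat$sets, is.null, TRUE)]
        fixed <- fixed[!hard[fixed]]
        if (!length(fixed)) next                 # fully inside hard residues
        pos <- fixed[[1L]]
        tok <- pat$sets[[match(pos, win)]]
        anc[[pos]] <- sample(setdiff(AA20, c(tok, anc[[pos]])), 1L)
        dirty <- TRUE
      }
    }
    if (!dirty) return(anc)
  }
  stop("could not scrub spurious motifs from the ancestor")
}

# fill the wildcard positions of a motif text with random residues,
# returning (chars, protected-flag per char)
instantiate_motif <- function(text) {
  toks <- strsplit(text, "-", fixed = TRUE)[[1L]]
  chars <- character(length(toks)); fixed <- logical(length(toks))
  for (i in seq_along(toks)) {
    if (toks[[i]] == "x") { chars[[i]] <- rand_res(1L); fixed[[i]] <- FALSE }
    else {
      res <- strsplit(toks[[i]], "/", fixed = TRUE)[[1L]]
      chars[[i]] <- res[[1L]]; fixed[[i]] <- TRUE
    }
  }
  list(chars = chars, fixed = fixed)
}

#' Generate a labeled synthetic protein family
#'
#' @param params a [sim_params()] object.
#' @return A list:
#'   * `records`: [protein_set()] of family members plus decoys;
#'   * `msa`: the true alignment of the family members (decoys excluded;
#'     ungapping any row reproduces its sequence exactly);
#'   * `truth`: data.frame per sequence: `seq_id`, `group`, `is_decoy`,
#'     `has_domain`, `domain_start`/`domain_end` (0-based half-open, final
#'     coordinates), `catalytic_status` (planted; `undetermined` for
#'     decoys), `acid_base_start` (0-based start of the planted acid/base
#'     motif), `passes_filter` (computed by running the validation filter
#'     on the emitted sequence);
#'   * `params`: the parameter echo.
#'
#' With zero substitution noise the generator re-scans every family member
#' and asserts that direct-scan catalytic classification and domain-anchor
#' presence agree with the planted truth.
#' @export
generate_family <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, generate_family_impl(params))
}

generate_family_impl <- function(p) {
  # ---- ancestor architecture (0-based spans, fixed for the family) ----
  dom_pre <- 5L
  lxvd <- instantiate_motif(MOTIF_LXVD)
  core <- instantiate_motif(MOTIF_CBM4_CORE)
  sxxp <- instantiate_motif(MOTIF_SXXP)
  sp1 <- 40L; sp2 <- 60L
  dom_len <- 4L + sp1 + 14L + sp2 + 4L           # 122
  min_anc <- 350L + dom_len + 8L                  # domain-less rows >= ~350
  L_anc <- sample(seq(max(min_anc, p$len_range[[1L]]), p$len_range[[2L]]), 1L)
  gne <- instantiate_motif("G-N-E")
  seyxv <- instantiate_motif(MOTIF_SEYXV)

  dom_start <- dom_pre
  dom_end <- dom_start + dom_len                 # half-open
  gne_start <- dom_end + 190L
  sey_start <- gne_start + 3L + 60L
  stopifnot(sey_start + 5L <= L_anc)

  anc <- rand_res(L_anc)
  # proline linker ahead of the domain: no planted motif starts with P, so
  # removing the domain cannot splice a spurious motif across the junction
  anc[1:dom_pre] <- "P"
  put <- function(anc, start, m) { anc[start + seq_along(m$chars)] <- m$chars; anc }
  anc <- put(anc, dom_start, lxvd)
  anc <- put(anc, dom_start + 4L + sp1, core)
  anc <- put(anc, dom_end - 4L, sxxp)
  anc <- put(anc, gne_start, gne)
  anc <- put(anc, sey_start, seyxv)

  spans <- list(lxvd = c(dom_start, dom_start + 4L),
                core = c(dom_start + 4L + sp1, dom_start + 4L + sp1 + 14L),
                sxxp = c(dom_end - 4L, dom_end),
                gne = c(gne_start, gne_start + 3L),
                seyxv = c(sey_start, sey_start + 5L))
  protected <- rep(FALSE, L_anc)
  for (s in spans) protected[(s[[1L]] + 1L):s[[2L]]] <- TRUE
  hard <- rep(FALSE, L_anc)
  mark_hard <- function(hard, start, m) {
    hard[start + which(m$fixed)] <- TRUE
    hard
  }
  hard <- mark_hard(hard, dom_start, lxvd)
  hard <- mark_hard(hard, dom_start + 4L + sp1, core)
  hard <- mark_hard(hard, dom_end - 4L, sxxp)
  hard <- mark_hard(hard, gne_start, gne)
  hard <- mark_hard(hard, sey_start, seyxv)
  planted_starts <- c(dom_start, dom_end - 4L, gne_start, sey_start)
  anc <- scrub_motifs(anc, hard, planted_starts)
  in_motif_boundary <- rep(FALSE, L_anc + 1L)    # boundary p strictly inside a motif
  for (s in spans) if (s[[2L]] - s[[1L]] > 1L)
    in_motif_boundary[(s[[1L]] + 2L):s[[2L]]] <- TRUE

  # ---- per-sequence evolution ----
  groups <- rep(names(p$n_per_group), p$n_per_group)
  n_fam <- length(groups)
  prev <- p$domain_prevalence
  prev_for <- function(g) if (length(prev) == 1L && is.null(names(prev)))
    prev else unname(prev[[g]])
  statuses <- names(p$catalytic_composition)

  rows <- vector("list", n_fam)
  for (i in seq_len(n_fam)) {
    g <- groups[[i]]
    has_domain <- runif(1) < prev_for(g)
    status <- sample(statuses, 1L, prob = p$catalytic_composition)

    chars <- anc
    keep <- rep(TRUE, L_anc)
    if (!has_domain) keep[(dom_start + 1L):dom_end] <- FALSE

    # plant the catalytic acid/base variant (G-N-E -> G-N-Q / G-N-D / G-S-N)
    ab <- gne_start
    if (status == "substituted_Q") chars[[ab + 3L]] <- "Q"
    if (status == "substituted_D") chars[[ab + 3L]] <- "D"
    if (status == "variant_GSN") { chars[[ab + 2L]] <- "S"; chars[[ab + 3L]] <- "N" }

    # point substitutions outside protected spans
    if (p$sub_rate > 0) {
      at <- which(!protected & keep & runif(L_anc) < p$sub_rate)
      for (j in at) chars[[j]] <- sample(setdiff(AA20, chars[[j]]), 1L)
    }

    # indels
    ins <- vector("list", L_anc + 1L)             # boundary p: before anc pos p
    if (p$indel_rate > 0) {
      n_ev <- rbinom(1L, L_anc, p$indel_rate)
      for (ev in seq_len(n_ev)) {
        len <- 1L + rgeom(1L, 0.5)
        if (runif(1) < 0.5) {                      # insertion
          ok <- which(!in_motif_boundary) - 1L
          if (!has_domain) ok <- ok[!(ok > dom_start & ok < dom_end)]
          b <- sample(ok, 1L)
          ins[[b + 1L]] <- c(ins[[b + 1L]], list(rand_res(len)))
        } else {                                    # deletion
          starts <- which(!protected & keep) - 1L
          if (!length(starts)) next
          s0 <- sample(starts, 1L)
          run <- s0:(min(s0 + len - 1L, L_anc - 1L))
          run <- run[!protected[run + 1L] & keep[run + 1L]]
          if (length(run)) {
            stop_at <- which(diff(run) != 1L)
            if (length(stop_at)) run <- run[seq_len(stop_at[[1L]])]
            keep[run + 1L] <- FALSE
          }
        }
      }
    }
    ins_str <- vapply(ins, function(v)
      if (is.null(v)) "" else paste(unlist(v), collapse = ""), "")
    rows[[i]] <- list(group = g, has_domain = has_domain, status = status,
                      chars = chars, keep = keep, ins = ins_str)
  }

  # ---- assemble sequences, truth coordinates and the true alignment ----
  ins_max <- if (n_fam) apply(do.call(rbind, lapply(rows, function(r)
    nchar(r$ins))), 2L, max) else integer(L_anc + 1L)
  ids <- sprintf("%s_%03d", groups,
                 as.integer(stats::ave(seq_len(n_fam), groups,
                                       FUN = seq_along)))
  seqs <- character(n_fam); aln_rows <- character(n_fam)
  dom_iv <- matrix(NA_integer_, n_fam, 2L)
  ab_start <- integer(n_fam)
  for (i in seq_len(n_fam)) {
    r <- rows[[i]]
    pieces <- character(0); aln_pieces <- character(0)
    final_pos <- 0L
    pos_of <- rep(NA_integer_, L_anc)             # anc pos -> final 0-based
    for (pb in 0:L_anc) {
      s <- r$ins[[pb + 1L]]
      pieces <- c(pieces, s)
      aln_pieces <- c(aln_pieces,
                      paste0(s, strrep("-", ins_max[[pb + 1L]] - nchar(s))))
      final_pos <- final_pos + nchar(s)
      if (pb < L_anc) {
        if (r$keep[[pb + 1L]]) {
          pieces <- c(pieces, r$chars[[pb + 1L]])
          aln_pieces <- c(aln_pieces, r$chars[[pb + 1L]])
          pos_of[[pb + 1L]] <- final_pos
          final_pos <- final_pos + 1L
        } else aln_pieces <- c(aln_pieces, "-")
      }
    }
    seqs[[i]] <- paste(pieces, collapse = "")
    aln_rows[[i]] <- paste(aln_pieces, collapse = "")
    if (r$has_domain) {
      kept_dom <- which(!is.na(pos_of[(dom_start + 1L):dom_end])) + dom_start
      dom_iv[i, ] <- c(pos_of[[kept_dom[[1L]]]],
                       pos_of[[kept_dom[[length(kept_dom)]]]] + 1L)
    }
    ab_start[[i]] <- pos_of[[gne_start + 1L]]
  }

  # ---- decoys: residue-shuffled family sequences ----
  n_dec <- round(p$decoy_fraction * n_fam)
  dec_ids <- character(0); dec_seqs <- character(0); dec_groups <- character(0)
  if (n_dec > 0) {
    src <- sample(seq_len(n_fam), n_dec, replace = n_dec > n_fam)
    for (d in seq_len(n_dec)) {
      dec_ids[[d]] <- sprintf("decoy_%03d", d)
      dec_seqs[[d]] <- paste(sample(strsplit(seqs[[src[[d]]]], "",
                                             fixed = TRUE)[[1L]]),
                             collapse = "")
      dec_groups[[d]] <- rows[[src[[d]]]]$group
    }
  }

  records <- protein_set(c(ids, dec_ids), c(seqs, dec_seqs),
                         group = c(groups, dec_groups))
  truth <- data.frame(
    seq_id = c(ids, dec_ids),
    group = c(groups, dec_groups),
    is_decoy = c(rep(FALSE, n_fam), rep(TRUE, n_dec)),
    has_domain = c(vapply(rows, `[[`, TRUE, "has_domain"), rep(FALSE, n_dec)),
    domain_start = c(dom_iv[, 1L], rep(NA_integer_, n_dec)),
    domain_end = c(dom_iv[, 2L], rep(NA_integer_, n_dec)),
    catalytic_status = c(vapply(rows, `[[`, "", "status"),
                         rep("undetermined", n_dec)),
    acid_base_start = c(ab_start, rep(NA_integer_, n_dec)),
    stringsAsFactors = FALSE)
  truth$passes_filter <- vapply(seq_len(nrow(truth)), function(i)
    validate_gh51(records[i])$passed, TRUE)

  # zero-noise consistency audit against the planted truth
  if (p$sub_rate == 0 && n_fam) {
    for (i in seq_len(n_fam)) {
      cc <- classify_catalytic(records[i])
      stopifnot(cc$status == truth$catalytic_status[[i]])
      has_anchor <- nrow(scan_sequence(compile_pattern(MOTIF_LXVD),
                                       records[i])) > 0 &&
        nrow(scan_sequence(compile_pattern(MOTIF_SXXP), records[i])) > 0
      stopifnot(!truth$has_domain[[i]] || has_anchor)
    }
  }

  list(records = records,
       msa = if (n_fam) msa(ids, aln_rows) else NULL,
       truth = truth, params = p)
}

#' Write a generated family bundle to a directory
#'
#' Emits `family.fasta` (all records), `true_alignment.afa` (family
#' members), `truth.tsv` and `params.json`.
#'
#' @param fam a [generate_family()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fam$records, file.path(dir, "family.fasta"))
  if (!is.null(fam$msa))
    write_alignment(fam$msa, file.path(dir, "true_alignment.afa"))
  write.table(fam$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pj <- fam$params; class(pj) <- NULL
  jsonlite::write_json(pj, file.path(dir, "params.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}
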