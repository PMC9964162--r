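# Sequence and alignment I/O with coordinate maps and group metadata.
#
# Conventions: 0-based, half-open intervals everywhere internally; 1-based
# inclusive only in human-readable reports. Residue alphabet is the 20
# canonical amino acids plus X; B/Z/U/O are normalized to X with a warning.
# '.' and '-' are both accepted as gaps on input; '-' is emitted on output.

LEGAL_RESIDUES <- c(AA20, "X")
AMBIG_MAP <- c(B = "X", Z = "X", U = "X", O = "X")

#' Construct a protein record set
#'
#' A `protein_set` is the package's container for identified protein
#' sequences: parallel vectors of unique ids, free-text descriptions, group
#' labels and residue strings over the 20-letter amino-acid alphabet plus X.
#'
#' @param id character vector of unique sequence identifiers.
#' @param seq character vector of residue strings (no gap characters).
#' @param desc optional descriptions (recycled from "").
#' @param group group labels, one of `plant`, `bacteria`, `fungi`, `insect`,
#'   `unknown` (recycled from "unknown").
#' @return An object of class `protein_set`.
#' @export
protein_set <- function(id, seq, desc = "", group = "unknown") {
  id <- as.character(id); seq <- toupper(as.character(seq))
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id))
    stop("duplicate id: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(seq))) stop("empty sequence for id: ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  if (any(grepl("[-.]", seq))) stop("gap characters are not allowed in a protein_set")
  seq <- normalize_residues(seq, id)
  desc <- rep_len(as.character(desc), length(id))
  group <- rep_len(as.character(group), length(id))
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  structure(list(id = id, desc = desc, group = group, seq = seq),
            class = "protein_set")
}

normalize_residues <- function(seq, id) {
  has_ambig <- grepl("[BZUO]", seq)
  if (any(has_ambig)) {
    warning("mapped ambiguous residues B/Z/U/O to X in: ",
            paste(id[has_ambig], collapse = ", "))
    seq <- chartr("BZUO", "XXXX", seq)
  }
  bad <- grepl(paste0("[^", paste(LEGAL_RESIDUES, collapse = ""), "]"), seq)
  if (any(bad)) stop("illegal residue character in: ",
                     paste(id[bad], collapse = ", "))
  seq
}

#' @export
length.protein_set <- function(x) length(x$id)

#' @export
print.protein_set <- function(x, ...) {
  cat("protein_set with", length(x), "sequence(s)\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %s [%s] %d aa\n", x$id[i], x$group[i], nchar(x$seq[i])))
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Subset a protein set
#' @param x a `protein_set`.
#' @param i index vector (integer, logical, or ids).
#' @param ... unused.
#' @export
`[.protein_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  structure(list(id = x$id[i], desc = x$desc[i], group = x$group[i],
                 seq = x$seq[i]), class = "protein_set")
}

#' Read a protein FASTA file
#'
#' Parses a (multi-record) FASTA file into a [protein_set()]. `*` stop
#' characters are stripped, lowercase residues are uppercased, B/Z/U/O are
#' mapped to X with a warning, and record order is preserved. Malformed
#' headers or illegal residue characters raise an error naming the offending
#' line number; duplicate ids are rejected.
#'
#' @param path path to a FASTA file.
#' @param group_table optional [read_group_table()] result used to attach
#'   group labels by id.
#' @return A [protein_set()].
#' @export
read_fasta <- function(path, group_table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  ids <- character(); descs <- character(); seqs <- character()
  cur <- NULL
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      header <- sub("^>\\s*", "", line)
      id <- sub("\\s.*$", "", header)
      if (!nzchar(id)) stop("malformed header at line ", ln, ": empty id")
      desc <- sub("^\\S+\\s*", "", header)
      ids <- c(ids, id); descs <- c(descs, desc); seqs <- c(seqs, "")
      cur <- length(ids)
    } else {
      if (is.null(cur)) stop("sequence data before first header at line ", ln)
      chunk <- toupper(gsub("[\\s*]", "", line, perl = TRUE))
      if (grepl("[^A-Z]", chunk))
        stop("illegal residue character at line ", ln)
      if (grepl(paste0("[^", paste(LEGAL_RESIDUES, collapse = ""), "BZUO]"), chunk))
        stop("illegal residue character at line ", ln)
      seqs[cur] <- paste0(seqs[cur], chunk)
    }
  }
  if (!length(ids)) {
    return(protein_set(character(), character()))
  }
  if (anyDuplicated(ids))
    stop("duplicate id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  group <- "unknown"
  if (!is.null(group_table)) {
    group <- unname(group_table$group[match(ids, group_table$id)])
    group[is.na(group)] <- "unknown"
  }
  protein_set(ids, seqs, descs, group)
}

#' Write a protein set to FASTA
#'
#' @param x a [protein_set()].
#' @param path output path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(x$id)) {
    hdr <- if (nzchar(x$desc[i])) paste(x$id[i], x$desc[i]) else x$id[i]
    writeLines(paste0(">", hdr), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' An `msa` stores ordered aligned rows of identical length with '-' gaps,
#' plus lazily computed column/residue coordinate maps (see [msa_maps()]).
#'
#' @param id character vector of unique row ids.
#' @param aln character vector of aligned strings (gaps '-' or '.').
#' @return An object of class `msa` with fields `id`, `aln`, `n_cols`.
#' @export
msa <- function(id, aln) {
  id <- as.character(id); aln <- toupper(as.character(aln))
  stopifnot(length(id) == length(aln), length(id) >= 1L)
  if (anyDuplicated(id))
    stop("duplicate id: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  aln <- gsub(".", "-", aln, fixed = TRUE)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment rows: ",
         paste(id[lens != lens[1L]], collapse = ", "))
  ung <- gsub("-", "", aln, fixed = TRUE)
  normalize_residues(ung, id)
  aln <- chartr("BZUO", "XXXX", aln)
  structure(list(id = id, aln = aln, n_cols = lens[[1L]]), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$id), "rows x", x$n_cols, "columns\n")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA (`afa`) or Stockholm 1.0 (`stockholm`; sequence lines
#' only, `#=GC`/`#=GR` annotations ignored). Gap characters '-' and '.' are
#' normalized to '-'. Ragged rows raise an error listing the offending ids.
#'
#' @param path input path.
#' @param format `"afa"` or `"stockholm"`.
#' @return An [msa()].
#' @export
read_alignment <- function(path, format = c("afa", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "afa") {
    lines <- readLines(path)
    ids <- character(); rows <- character(); cur <- NULL
    for (ln in seq_along(lines)) {
      line <- lines[[ln]]
      if (!nzchar(trimws(line))) next
      if (startsWith(line, ">")) {
        id <- sub("\\s.*$", "", sub("^>\\s*", "", line))
        if (!nzchar(id)) stop("malformed header at line ", ln, ": empty id")
        ids <- c(ids, id); rows <- c(rows, ""); cur <- length(ids)
      } else {
        if (is.null(cur)) stop("alignment data before first header at line ", ln)
        rows[cur] <- paste0(rows[cur], gsub("\\s", "", line))
      }
    }
    if (!length(ids)) stop("empty alignment file: ", path)
    msa(ids, rows)
  } else {
    lines <- readLines(path)
    rows <- list()
    for (line in lines) {
      if (startsWith(line, "#") || startsWith(line, "//") ||
          !nzchar(trimws(line))) next
      parts <- strsplit(trimws(line), "\\s+")[[1L]]
      if (length(parts) != 2L)
        stop("malformed Stockholm sequence line: ", line)
      rows[[parts[[1L]]]] <- paste0(rows[[parts[[1L]]]] %||% "", parts[[2L]])
    }
    if (!length(rows)) stop("no sequence lines in Stockholm file: ", path)
    msa(names(rows), unlist(rows, use.names = FALSE))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an alignment
#'
#' @param x an [msa()].
#' @param path output path.
#' @param format `"afa"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path, format = c("afa", "stockholm")) {
  format <- match.arg(format)
  con <- file(path, "w"); on.exit(close(con))
  if (format == "afa") {
    for (i in seq_along(x$id))
      writeLines(c(paste0(">", x$id[i]), x$aln[i]), con)
  } else {
    writeLines("# STOCKHOLM 1.0", con)
    w <- max(nchar(x$id))
    writeLines(sprintf("%-*s %s", w, x$id, x$aln), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Remove gaps from one alignment row
#'
#' @param x an [msa()].
#' @param id row id.
#' @return The ungapped residue string.
#' @export
ungap <- function(x, id) {
  i <- match(id, x$id)
  if (is.na(i)) stop("unknown id: ", id)
  gsub("-", "", x$aln[[i]], fixed = TRUE)
}

#' Column/residue coordinate maps for one alignment row
#'
#' For row `id`, returns mutually inverse maps between 0-based alignment
#' columns and 0-based residue indices of the ungapped sequence.
#'
#' @param x an [msa()].
#' @param id row id.
#' @return A list with `col_to_res` (length `n_cols`, `NA` at gap columns)
#'   and `res_to_col` (length = ungapped sequence length).
#' @export
msa_maps <- function(x, id) {
  i <- match(id, x$id)
  if (is.na(i)) stop("unknown id: ", id)
  chars <- strsplit(x$aln[[i]], "", fixed = TRUE)[[1L]]
  is_res <- chars != "-"
  col_to_res <- rep(NA_integer_, x$n_cols)
  col_to_res[is_res] <- seq_len(sum(is_res)) - 1L
  res_to_col <- which(is_res) - 1L
  list(col_to_res = col_to_res, res_to_col = res_to_col)
}

#' Extract a column slice of an alignment
#'
#' @param x an [msa()].
#' @param cols integer vector of 0-based column indices to keep (ordered).
#' @return An [msa()] restricted to `cols`.
#' @export
msa_slice <- function(x, cols) {
  stopifnot(all(cols >= 0L), all(cols < x$n_cols))
  rows <- vapply(strsplit(x$aln, "", fixed = TRUE),
                 function(ch) paste(ch[cols + 1L], collapse = ""), "")
  out <- x
  out$aln <- rows
  out$n_cols <- length(cols)
  out
}

#' Per-row character matrix view of an alignment
#' @param x an [msa()].
#' @return A character matrix, rows = sequences, columns = alignment columns.
#' @export
msa_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$aln, "", fixed = TRUE))
  rownames(m) <- x$id
  m
}

#' Convert an alignment's rows to a protein set (ungapped)
#' @param x an [msa()].
#' @param group_table optional group table for labels.
#' @return A [protein_set()].
#' @export
msa_to_protein_set <- function(x, group_table = NULL) {
  seqs <- gsub("-", "", x$aln, fixed = TRUE)
  keep <- nzchar(seqs)
  group <- "unknown"
  if (!is.null(group_table)) {
    group <- unname(group_table$group[match(x$id[keep], group_table$id)])
    group[is.na(group)] <- "unknown"
  }
  protein_set(x$id[keep], seqs[keep], group = group)
}

#' Read a TSV group table
#'
#' Expects a header line `id<TAB>group`; an optional third column is kept as
#' a free-text provenance note. Every id must resolve to exactly one group.
#'
#' @param path TSV path.
#' @return A data.frame with columns `id`, `group`, `note`.
#' @export
read_group_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(df)))
    stop("group table must have columns 'id' and 'group'")
  if (anyDuplicated(df$id))
    stop("duplicate id in group table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (is.null(df$note)) df$note <- ""
  df[c("id", "group", "note")]
}

#' Write a group table
#' @param df data.frame with columns `id`, `group` (and optionally `note`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(df, path) {
  if (is.null(df$note)) df$note <- ""
  write.table(df[c("id", "group", "note")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
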