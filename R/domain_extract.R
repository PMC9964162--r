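# Excision of the N-terminal CBM4-like domain region from an alignment,
# anchored on the conserved L-x-V-D (start) and S-x-x-P (end) motifs. The
# anchors are included in the excised region: the end motif sits on the loop
# separating the CBM4-like domain from the catalytic barrel, so it bounds
# the domain inclusively.

#' Excise the CBM4-like domain region from an alignment
#'
#' Locates the two conserved anchor motifs with [locate_conserved_motif()]
#' and returns the alignment columns from the first column of the start
#' anchor through the last column of the end anchor (inclusive of both
#' motifs). Columns after the end anchor are always removed; columns before
#' the start anchor are removed by default (`keep_left = TRUE` preserves
#' them, i.e. only trims the tail).
#'
#' @param x an [msa()].
#' @param start_pattern,end_pattern anchor motifs ([compile_pattern()]
#'   results); defaults are the L-x-V-D and S-x-x-P domain anchors.
#' @param min_fraction conservation threshold for anchor location.
#' @param keep_left keep columns left of the start anchor.
#' @return A list with `msa` (the excised alignment), `segments` (data.frame
#'   `seq_id`, `start`, `end` in 0-based half-open ungapped coordinates;
#'   all-gap rows get `NA` and are flagged), `anchors` (located column
#'   intervals), and `all_gap_ids` (rows excluded from downstream profile
#'   building).
#' @export
excise_domain_alignment <- function(x,
                                    start_pattern = compile_pattern(MOTIF_LXVD),
                                    end_pattern = compile_pattern(MOTIF_SXXP),
                                    min_fraction = 0.5,
                                    keep_left = FALSE) {
  a1 <- locate_conserved_motif(x, start_pattern, min_fraction)
  if (is.null(a1)) stop("start anchor '", start_pattern$name, "' not found")
  a2 <- locate_conserved_motif(x, end_pattern, min_fraction)
  if (is.null(a2)) stop("end anchor '", end_pattern$name, "' not found")
  if (a1$c_start >= a2$c_start)
    stop("anchors out of order: start anchor at column ", a1$c_start,
         " is not left of end anchor at column ", a2$c_start)
  c_from <- if (keep_left) 0L else a1$c_start
  c_to <- a2$c_end                      # half-open
  cols <- c_from:(c_to - 1L)
  out <- msa_slice(x, cols)

  segs <- lapply(x$id, function(id) {
    maps <- msa_maps(x, id)
    res_in <- maps$col_to_res[cols + 1L]
    res_in <- res_in[!is.na(res_in)]
    if (!length(res_in))
      return(data.frame(seq_id = id, start = NA_integer_, end = NA_integer_,
                        all_gap = TRUE, stringsAsFactors = FALSE))
    data.frame(seq_id = id, start = res_in[[1L]], end = res_in[[length(res_in)]] + 1L,
               all_gap = FALSE, stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  list(msa = out, segments = segs,
       anchors = list(start = a1, end = a2),
       all_gap_ids = segs$seq_id[segs$all_gap])
}

#' Write domain segments as BED-like TSV (0-based half-open)
#' @param segments the `segments` data.frame of [excise_domain_alignment()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  write.table(segments[c("seq_id", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
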