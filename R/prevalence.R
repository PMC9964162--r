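# Per-group domain-prevalence statistics aggregated from profile-scan
# results: hit counts, totals, percentages (half-up, one decimal — the
# reporting style of the source counts) and Wilson 95% confidence
# intervals. Sequences skipped by the 200-residue scan rule are not part of
# any denominator: only sequences actually used for search are counted.

#' Percentage, rounded half-up to one decimal
#'
#' @param n_hit hit count.
#' @param n_total total count (> 0).
#' @return `100 * n_hit / n_total`, rounded half-up to 1 decimal, e.g.
#'   `percent(119, 133)` is `89.5`.
#' @export
percent <- function(n_hit, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  stopifnot(all(n_hit >= 0), all(n_hit <= n_total))
  round_half_up(100 * n_hit / n_total, 1)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k successes.
#' @param n trials (> 0).
#' @param conf confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)` on the proportion scale, inside
#'   `[0, 1]`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Per-group prevalence table from scan hits
#'
#' @param hits a [scan_profile()] data.frame (`seq_id`, `group`, `status`).
#' @param groups optional group table (data.frame `id`, `group`) overriding
#'   the group labels carried in `hits`; unmatched ids become `unknown`.
#' @param conf confidence level for the Wilson interval.
#' @return A data.frame with one row per group present among scanned
#'   (non-skipped) sequences: `group`, `n_total`, `n_hit`, `percent`,
#'   `ci_lower`, `ci_upper` (percent scale). Zero rows when everything was
#'   skipped.
#' @export
prevalence_table <- function(hits, groups = NULL, conf = 0.95) {
  stopifnot(all(c("seq_id", "status") %in% names(hits)))
  grp <- hits$group
  if (!is.null(groups)) {
    grp <- unname(groups$group[match(hits$seq_id, groups$id)])
    grp[is.na(grp)] <- "unknown"
  }
  scanned <- hits$status != "skipped"
  grp <- grp[scanned]
  passed <- hits$status[scanned] == "passed"
  if (!length(grp)) {
    return(data.frame(group = character(), n_total = integer(),
                      n_hit = integer(), percent = numeric(),
                      ci_lower = numeric(), ci_upper = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(intersect(GROUP_LEVELS, unique(grp)), function(g) {
    n <- sum(grp == g); k <- sum(passed & grp == g)
    ci <- wilson_ci(k, n, conf)
    data.frame(group = g, n_total = n, n_hit = k, percent = percent(k, n),
               ci_lower = round_half_up(100 * ci[["lower"]], 1),
               ci_upper = round_half_up(100 * ci[["upper"]], 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a prevalence table as TSV and/or JSON
#' @param tab a [prevalence_table()] data.frame.
#' @param path output path; `.json` extension selects JSON, anything else
#'   TSV.
#' @return `path`, invisibly.
#' @export
write_prevalence <- function(tab, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  } else {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
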