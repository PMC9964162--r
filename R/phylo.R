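# Distance-based phylogeny: p-distance matrices, neighbor-joining trees
# (backed by ape, the field-standard implementation), column-resampling
# bootstrap support, and congruence between clade membership and the
# catalytic acid/base status. NJ with p-distances is an explicit
# methodological stand-in for maximum-likelihood inference with ultrafast
# bootstrap; congruence conclusions are qualitative.

#' p-distance matrix of an alignment
#'
#' `d(i, j)` = mismatches / columns where both rows hold residues. X
#' residues are excluded from the comparable set (their identity is
#' unknown), as are gap columns.
#'
#' @param x an [msa()] with at least 3 rows.
#' @return A symmetric `dist`-convertible matrix with zero diagonal and
#'   entries in `[0, 1]`, taxa in row order.
#' @export
p_distance_matrix <- function(x) {
  stopifnot(length(x$id) >= 3L)
  mat <- msa_matrix(x)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(x$id, x$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-" & mat[i, ] != "X" & mat[j, ] != "X"
      nc <- sum(ok)
      if (nc == 0L)
        stop("zero comparable columns between ", x$id[i], " and ", x$id[j])
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / nc
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei neighbor joining (via `ape::nj`). Negative branch
#' length estimates are clamped to 0 with a warning. The result is an
#' unrooted `ape::phylo` tree, newick-serializable.
#'
#' @param dm symmetric non-negative distance matrix with zero diagonal and
#'   unique taxon names.
#' @return An `ape` `phylo` object.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop("non-symmetric distance matrix")
  if (is.null(rownames(dm))) stop("distance matrix must carry taxon names")
  tr <- ape::nj(as.dist(dm))
  if (any(tr$edge.length < 0)) {
    warning("clamped ", sum(tr$edge.length < 0),
            " negative NJ branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Column-resampling bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree from the p-distances of each replicate, and annotates each
#' internal bipartition of the full-data tree with the percentage of
#' replicates containing it. A classical NJ bootstrap, the declared
#' stand-in for ultrafast bootstrap on an ML tree.
#'
#' @param x an [msa()].
#' @param n_reps bootstrap replicates (>= 1).
#' @param seed integer seed; results are deterministic given the seed.
#' @return The NJ tree (`phylo`) with `node.label` holding integer percent
#'   supports on internal nodes (root label empty) and an attribute
#'   `supports`.
#' @export
bootstrap_support <- function(x, n_reps, seed) {
  stopifnot(n_reps >= 1L)
  main <- nj_tree(p_distance_matrix(x))
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      cols <- sample.int(x$n_cols, x$n_cols, replace = TRUE) - 1L
      bx <- msa_slice(x, cols)
      tryCatch(suppressWarnings(nj_tree(p_distance_matrix(bx))),
               error = function(e) NULL)
    })
  })
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- round_half_up(100 * counts / n_reps, 0)
  main$node.label <- as.character(supp)
  # the root "bipartition" of an unrooted tree is not a real split
  main$node.label[[1L]] <- ""
  attr(main, "supports") <- supp
  main
}

#' Write a tree with support labels as newick
#' @param tree a `phylo` (optionally with `node.label` supports).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Clade membership vs catalytic-status congruence
#'
#' Roots the tree at the declared outgroup, finds the smallest clade
#' containing all `clade_seed_taxa`, and cross-tabulates the catalytic
#' acid/base status of taxa inside versus outside that clade (outgroup taxa
#' excluded from "outside"). Exceptions — members whose status differs from
#' the clade's majority status, and outside taxa carrying it — are listed.
#'
#' @param tree a `phylo` tree whose tip labels match `calls$seq_id`.
#' @param calls a [classify_catalytic_set()] data.frame.
#' @param clade_seed_taxa non-empty character vector of tip labels defining
#'   the clade of interest.
#' @param outgroup non-empty character vector of outgroup tip labels used
#'   to root the tree.
#' @return A list: `clade_members`, `inside` / `outside` (status count
#'   tables), `inside_fraction` / `outside_fraction` (named fractions per
#'   status), `exceptions` (data.frame `seq_id`, `status`, `where`).
#' @export
clade_catalysis_congruence <- function(tree, calls, clade_seed_taxa,
                                       outgroup) {
  if (!length(clade_seed_taxa)) stop("empty clade seed set")
  if (!length(outgroup)) stop("empty outgroup")
  missing_seed <- setdiff(clade_seed_taxa, tree$tip.label)
  if (length(missing_seed))
    stop("seed taxon absent from tree: ", paste(missing_seed, collapse = ", "))
  missing_og <- setdiff(outgroup, tree$tip.label)
  if (length(missing_og))
    stop("outgroup taxon absent from tree: ", paste(missing_og, collapse = ", "))

  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  members <- if (length(clade_seed_taxa) == 1L) clade_seed_taxa else {
    node <- ape::getMRCA(rooted, clade_seed_taxa)
    ape::extract.clade(rooted, node)$tip.label
  }
  status <- setNames(calls$status, calls$seq_id)
  inside <- status[intersect(members, names(status))]
  out_taxa <- setdiff(tree$tip.label, c(members, outgroup))
  outside <- status[intersect(out_taxa, names(status))]

  frac <- function(s) {
    if (!length(s)) return(numeric())
    tb <- table(s)
    setNames(as.numeric(tb) / length(s), names(tb))
  }
  major <- if (length(inside)) names(which.max(table(inside))) else NA_character_
  exc_df <- function(v, keep, where) {
    if (!length(v) || !any(keep)) return(NULL)
    data.frame(seq_id = names(v)[keep], status = unname(v[keep]),
               where = where, stringsAsFactors = FALSE)
  }
  exc <- rbind(exc_df(inside, inside != major, "inside"),
               exc_df(outside, outside == major, "outside"))
  list(clade_members = members,
       inside = table(inside), outside = table(outside),
       inside_fraction = frac(inside), outside_fraction = frac(outside),
       majority_status = major,
       exceptions = exc %||% data.frame(seq_id = character(),
                                        status = character(),
                                        where = character()))
}

#' Collapse weakly supported branches
#'
#' Report-level filter mirroring the removal of branches with bootstrap
#' support below a cutoff (default 90).
#'
#' @param tree a `phylo` with numeric-like `node.label` supports.
#' @param cutoff minimum support to keep an internal branch.
#' @return A `phylo` with low-support internal branches collapsed into
#'   polytomies.
#' @export
collapse_low_support <- function(tree, cutoff = 90) {
  if (is.null(tree$node.label)) stop("tree has no support labels")
  supp <- suppressWarnings(as.numeric(tree$node.label))
  keep_thresh <- function(s) !is.na(s) & s < cutoff
  n_tip <- length(tree$tip.label)
  drop_nodes <- which(keep_thresh(supp)) + n_tip
  if (!length(drop_nodes)) return(tree)
  # contract each low-support internal edge
  edge_drop <- tree$edge[, 2] %in% drop_nodes
  if (!any(edge_drop)) return(tree)
  tr <- tree
  tr$edge.length[edge_drop] <- 0
  ape::di2multi(tr, tol = 1e-12)
}
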