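# Distance trees with bootstrap as the in-repo route to supported lineages.
# Neighbor-joining and bipartition counting are delegated to ape; midpoint
# rooting to phangorn. Externally computed support values (e.g. from
# likelihood or Bayesian analyses) can be imported instead of the in-repo
# bootstrap via import_supports().

#' Uncorrected p-distance matrix of an alignment
#'
#' Proportion of differing sites over the pairwise comparable columns (both
#' bases unambiguous A/C/G/U; gaps and ambiguity codes are excluded per
#' pair).
#'
#' @param alignment aligned sequences (named character vector or data.frame
#'   with `id`/`sequence`); at least 3 sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  m <- as_char_matrix(alignment)
  if (nrow(m) < 3) stop("at least 3 sequences are required")
  ok <- matrix(m %in% UNAMBIGUOUS, nrow = nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0)
      stop(sprintf("no comparable columns between '%s' and '%s'",
                   rownames(m)[i], rownames(m)[j]), call. = FALSE)
    d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via `ape::nj`); deterministic
#' given the input order. Recovers additive matrices exactly.
#'
#' @param d symmetric, non-negative distance matrix over at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (nrow(d) < 3) stop("at least 3 taxa are required")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  ape::nj(d)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the neighbor-joining tree of the alignment's p-distances, then
#' resamples alignment columns with replacement `n_replicates` times and
#' records, for each internal edge of the original tree, the percentage of
#' replicates containing the same bipartition. Reproducible given `seed`.
#'
#' @param alignment aligned sequences.
#' @param n_replicates number of bootstrap replicates (default 100).
#' @param seed integer seed for the column resampling.
#' @return a `phylo` tree whose `node.label` holds the support percentages
#'   (the root node label is empty).
#' @export
bootstrap_supports <- function(alignment, n_replicates = 100, seed = 1) {
  stopifnot(n_replicates >= 1)
  m <- as_char_matrix(alignment)
  pd <- function(mm) {
    seqs <- setNames(apply(mm, 1, paste, collapse = ""), rownames(mm))
    p_distance_matrix(seqs)
  }
  tree <- nj_tree(pd(m))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  boot_trees <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boot_trees[[r]] <- nj_tree(pd(m[, cols, drop = FALSE]))
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  pct <- round(100 * counts / n_replicates, 1)
  lab <- as.character(pct)
  lab[1] <- ""  # root of the unrooted representation carries no support
  tree$node.label <- lab
  attr(tree, "n_replicates") <- n_replicates
  tree
}

#' Import externally computed support values onto a tree
#'
#' Reads a TSV with columns `bipartition` (comma-separated taxon names of one
#' side of the split) and `support`, and writes the values into the tree's
#' node labels, matching each bipartition against the tree's clades on
#' either side of each internal edge. Unmatched internal nodes get support 0.
#'
#' @param tree a `phylo` tree.
#' @param path TSV file with columns `bipartition`, `support`.
#' @return the tree with `node.label` set to the imported supports.
#' @export
import_supports <- function(tree, path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("bipartition", "support") %in% names(tab)))
  tips <- tree$tip.label
  keyify <- function(x) paste(sort(x), collapse = "|")
  keys <- vapply(strsplit(tab$bipartition, ",", fixed = TRUE), function(s) {
    s <- trimws(s)
    unknown <- setdiff(s, tips)
    if (length(unknown) > 0)
      stop("bipartition names unknown taxa: ", paste(unknown, collapse = ", "))
    keyify(s)
  }, character(1))
  comp_keys <- vapply(strsplit(tab$bipartition, ",", fixed = TRUE), function(s)
    keyify(setdiff(tips, trimws(s))), character(1))
  nnode <- tree$Nnode
  ntip <- length(tips)
  lab <- rep("0", nnode)
  for (nd in seq_len(nnode)) {
    clade <- tips[phangorn::Descendants(tree, ntip + nd, "tips")[[1]]]
    k <- keyify(clade)
    hit <- which(keys == k | comp_keys == k)
    if (length(hit) > 0) lab[nd] <- as.character(tab$support[hit[1]])
  }
  lab[1] <- ""
  tree$node.label <- lab
  tree
}

#' Extract supported lineages from a tree
#'
#' Each internal edge with support at or above
#' `config$bootstrap_support_min` defines a bipartition; the clade is the
#' side not containing the declared outgroup, or — without an outgroup — the
#' smaller side (ties broken towards the side holding the lexicographically
#' smallest strain). Maximal supported clades become lineages; strains not
#' contained in any become singletons, so the lineages always partition the
#' strain set.
#'
#' @param tree a `phylo` tree with supports in `node.label` (e.g. from
#'   [bootstrap_supports()] or [import_supports()]).
#' @param config an [analysis_config()].
#' @param outgroup optional tip name(s) declaring the root side; clades
#'   containing outgroup taxa are never returned as lineages.
#' @return named list of character vectors (strain sets), names `lineage_1`,
#'   `lineage_2`, ..., with an attribute `support` (named numeric vector):
#'   the support of each lineage's subtending edge, 100 for singletons
#'   (terminal splits are present in every replicate). The attribute can be
#'   passed directly to [delimit_species()] as `supports`.
#' @export
supported_lineages <- function(tree, config = analysis_config(),
                               outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label))
    stop("tree carries no support values; run bootstrap_supports() or import_supports()")
  tips <- tree$tip.label
  if (!is.null(outgroup) && !all(outgroup %in% tips))
    stop("outgroup taxa not in the tree: ",
         paste(setdiff(outgroup, tips), collapse = ", "))
  ntip <- length(tips)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  cand <- list(); cand_sup <- numeric(0)
  for (nd in seq_len(tree$Nnode)) {
    s <- sup[nd]
    if (is.na(s) || s < config$bootstrap_support_min) next
    side <- sort(tips[phangorn::Descendants(tree, ntip + nd, "tips")[[1]]])
    other <- sort(setdiff(tips, side))
    if (length(other) == 0) next  # trivial split at the basal node
    clade <- if (!is.null(outgroup)) {
      if (any(outgroup %in% side)) other else side
    } else if (length(side) != length(other)) {
      if (length(side) < length(other)) side else other
    } else {
      if (min(side) < min(other)) side else other
    }
    if (!is.null(outgroup)) {
      if (any(outgroup %in% clade)) next
      if (setequal(clade, setdiff(tips, outgroup))) next  # trivial outgroup split
    }
    cand[[length(cand) + 1]] <- clade
    cand_sup <- c(cand_sup, s)
  }
  # keep maximal clades (drop any candidate contained in a larger one);
  # candidates from one tree are nested or disjoint
  keep <- rep(TRUE, length(cand))
  if (length(cand) > 1) {
    for (a in seq_along(cand)) for (b in seq_along(cand)) {
      if (a != b && keep[a] &&
          length(cand[[a]]) < length(cand[[b]]) &&
          all(cand[[a]] %in% cand[[b]]))
        keep[a] <- FALSE
    }
    # identical candidate sets (same bipartition seen from both ends): keep one
    key <- vapply(cand, paste, character(1), collapse = "|")
    keep <- keep & !duplicated(key)
  }
  lineages <- cand[keep]
  lin_support <- cand_sup[keep]
  grouped <- unlist(lineages, use.names = FALSE)
  singles <- setdiff(tips, grouped)
  lineages <- c(lineages, as.list(sort(singles)))
  lin_support <- c(lin_support, rep(100, length(singles)))
  ord2 <- order(vapply(lineages, `[`, character(1), 1))
  lineages <- lineages[ord2]
  lin_support <- lin_support[ord2]
  names(lineages) <- paste0("lineage_", seq_along(lineages))
  attr(lineages, "support") <- setNames(lin_support, names(lineages))
  lineages
}
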