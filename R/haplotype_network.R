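# Statistical-parsimony (TCS-style) haplotype networks for the V4 region:
# collapse identical sequences into haplotypes carrying sample metadata,
# estimate the 95% parsimony connection limit, connect haplotypes by unit
# mutational steps through inferred median nodes, and assign environmental
# query sequences by identity/coverage thresholds.

#' Collapse sequences into haplotypes
#'
#' Identical sequences are merged into one haplotype that carries all member
#' samples and their metadata. Alignment columns that are gaps in every
#' sequence are removed first; remaining gaps are kept as characters (they
#' enter the distance as a fifth state). Haplotype ids are `H1`, `H2`, ...
#' in order of decreasing multiplicity, ties broken by sequence.
#'
#' @param seqs sequences (named character vector or data.frame with
#'   `id`/`sequence`), one per sample; equal lengths after removing all-gap
#'   columns.
#' @param metadata optional data.frame as from [read_metadata()]; matched to
#'   samples via its `strain` column.
#' @return list of class `haplotype_set`: `haplotypes` (data.frame `id`,
#'   `sequence`, `multiplicity`) and `members` (data.frame `sample`,
#'   `haplotype`, plus metadata columns).
#' @export
collapse_haplotypes <- function(seqs, metadata = NULL) {
  v <- as_seq_vector(seqs)
  lens <- nchar(v)
  if (length(unique(lens)) != 1)
    stop("sequences have unequal lengths after degapping; align them first")
  m <- as_char_matrix(v)
  allgap <- apply(m == "-", 2, all)
  if (any(allgap)) m <- m[, !allgap, drop = FALSE]
  v <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  groups <- split(names(v), unname(v))
  mult <- lengths(groups)
  ord <- order(-mult, names(groups))
  groups <- groups[ord]
  haps <- data.frame(id = paste0("H", seq_along(groups)),
                     sequence = names(groups),
                     multiplicity = unname(lengths(groups)),
                     stringsAsFactors = FALSE)
  members <- data.frame(
    sample = unlist(groups, use.names = FALSE),
    haplotype = rep(haps$id, haps$multiplicity),
    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    stopifnot("strain" %in% names(metadata))
    idx <- match(members$sample, metadata$strain)
    for (col in setdiff(names(metadata), "strain"))
      members[[col]] <- metadata[[col]][idx]
  }
  members <- members[order(members$sample), ]
  rownames(members) <- NULL
  structure(list(haplotypes = haps, members = members),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes from %d samples\n",
              nrow(x$haplotypes), nrow(x$members)))
  invisible(x)
}

#' Mutational steps between two equal-length sequences
#'
#' Hamming distance with indels treated as a fifth state, one step per
#' contiguous run of gap-vs-base positions (a multi-nucleotide indel is a
#' single event).
#'
#' @param a,b equal-length sequence strings.
#' @return integer step count.
#' @export
hamming_steps <- function(a, b) {
  ca <- strsplit(normalize_rna(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(normalize_rna(b), "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("sequences have unequal lengths")
  gap_a <- ca == "-"; gap_b <- cb == "-"
  indel <- xor(gap_a, gap_b)
  subs <- sum(ca != cb & !indel)
  # count maximal runs of indel positions
  runs <- rle(indel)
  subs + sum(runs$values)
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps `j` for which the estimated probability
#' that `j` observed differences arose without homoplasy (each difference by
#' a single substitution) is at least `confidence`. Per-site mutation counts
#' are modelled as Poisson with rate `lambda = -log(1 - j/L)` (the rate under
#' which the expected fraction of visibly changed sites equals the observed
#' `j/L`), giving
#' `P(j) = (lambda * exp(-lambda) / (1 - exp(-lambda)))^j`,
#' the probability that every observed difference received exactly one hit,
#' given it received at least one. A single step is always connectable, so
#' the limit is at least 1.
#'
#' @param seq_length number of sites `L` (> 0).
#' @param confidence connection confidence (default 0.95).
#' @return integer step limit (>= 1).
#' @export
parsimony_limit <- function(seq_length, confidence = 0.95) {
  stopifnot(seq_length > 0, confidence > 0, confidence <= 1)
  limit <- 1L
  j <- 2
  while (j < seq_length) {
    lambda <- -log(1 - j / seq_length)
    p <- (lambda * exp(-lambda) / (1 - exp(-lambda)))^j
    if (p < confidence) break
    limit <- as.integer(j)
    j <- j + 1
  }
  limit
}

# deterministic mutational path between two sequences: change differing
# positions one at a time in ascending column order; returns intermediate
# sequences (excluding the endpoints)
mutation_path <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  diff_pos <- which(ca != cb)
  # group contiguous indel runs into single events
  gap_a <- ca == "-"; gap_b <- cb == "-"
  indel <- xor(gap_a, gap_b)
  events <- list()
  k <- 1
  while (k <= length(diff_pos)) {
    pos <- diff_pos[k]
    if (indel[pos]) {
      run <- pos
      while (k + 1 <= length(diff_pos) && diff_pos[k + 1] == diff_pos[k] + 1 &&
             indel[diff_pos[k + 1]]) {
        k <- k + 1
        run <- c(run, diff_pos[k])
      }
      events[[length(events) + 1]] <- run
    } else {
      events[[length(events) + 1]] <- pos
    }
    k <- k + 1
  }
  out <- character(0)
  cur <- ca
  if (length(events) > 1) {
    for (e in events[-length(events)]) {
      cur[e] <- cb[e]
      out <- c(out, paste(cur, collapse = ""))
    }
  }
  out
}

#' Build a statistical-parsimony haplotype network
#'
#' Haplotype pairs are connected in order of increasing mutational distance
#' up to `limit` (ties broken by higher multiplicity, then lexicographic
#' ids), skipping pairs already connected — a minimum-spanning construction,
#' so the total number of unit steps per component is minimal. Distances
#' greater than 1 are realized through inferred median nodes (multiplicity
#' 0) so that every edge is a single mutational step. Pairs farther apart
#' than `limit` are never connected directly; haplotypes beyond the limit
#' from every network member remain in separate components.
#'
#' @param haps a `haplotype_set` from [collapse_haplotypes()].
#' @param limit connection limit in steps; default
#'   `parsimony_limit(sequence length)`.
#' @return object of class `haplotype_network`: list with `graph` (igraph,
#'   unit-step edges), `nodes` (data.frame `id`, `sequence`, `multiplicity`,
#'   `type` observed/median), `connections` (data.frame of realized
#'   observed-pair connections with their step counts), `members`, `limit`.
#' @export
build_network <- function(haps, limit = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  h <- haps$haplotypes
  if (is.null(limit)) limit <- parsimony_limit(nchar(h$sequence[1]))
  stopifnot(limit >= 1)
  n <- nrow(h)
  # candidate pairs sorted by (distance, -max multiplicity, -min multiplicity, ids)
  cand <- NULL
  if (n > 1) {
    idx <- t(combn(n, 2))
    d <- apply(idx, 1, function(r) hamming_steps(h$sequence[r[1]], h$sequence[r[2]]))
    keep <- d <= limit & d > 0
    idx <- idx[keep, , drop = FALSE]; d <- d[keep]
    if (nrow(idx) > 0) {
      mx <- pmax(h$multiplicity[idx[, 1]], h$multiplicity[idx[, 2]])
      mn <- pmin(h$multiplicity[idx[, 1]], h$multiplicity[idx[, 2]])
      ord <- order(d, -mx, -mn, h$id[idx[, 1]], h$id[idx[, 2]])
      cand <- data.frame(a = idx[ord, 1], b = idx[ord, 2], d = d[ord])
    }
  }
  nodes <- data.frame(id = h$id, sequence = h$sequence,
                      multiplicity = h$multiplicity, type = "observed",
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  connections <- data.frame(from = character(0), to = character(0),
                            steps = integer(0), stringsAsFactors = FALSE)
  # union-find over observed haplotypes
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  n_median <- 0
  if (!is.null(cand)) {
    for (r in seq_len(nrow(cand))) {
      ra <- find(cand$a[r]); rb <- find(cand$b[r])
      if (ra == rb) next
      parent[ra] <- rb
      a_id <- h$id[cand$a[r]]; b_id <- h$id[cand$b[r]]
      path <- mutation_path(h$sequence[cand$a[r]], h$sequence[cand$b[r]])
      chain <- a_id
      for (s in path) {
        hit <- match(s, nodes$sequence)
        if (!is.na(hit)) {
          node_id <- nodes$id[hit]
        } else {
          n_median <- n_median + 1
          node_id <- paste0("m", n_median)
          nodes <- rbind(nodes, data.frame(id = node_id, sequence = s,
                                           multiplicity = 0L, type = "median",
                                           stringsAsFactors = FALSE))
        }
        chain <- c(chain, node_id)
      }
      chain <- c(chain, b_id)
      for (k in seq_len(length(chain) - 1)) {
        e <- sort(c(chain[k], chain[k + 1]))
        if (!any(edges$from == e[1] & edges$to == e[2]))
          edges <- rbind(edges, data.frame(from = e[1], to = e[2],
                                           stringsAsFactors = FALSE))
      }
      connections <- rbind(connections,
                           data.frame(from = a_id, to = b_id,
                                      steps = cand$d[r],
                                      stringsAsFactors = FALSE))
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, nodes = nodes, connections = connections,
                 members = haps$members, limit = limit),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  comp <- igraph::components(x$graph)$no
  cat(sprintf("<haplotype_network> %d observed haplotypes, %d median nodes, %d components (limit %d steps)\n",
              sum(x$nodes$type == "observed"), sum(x$nodes$type == "median"),
              comp, x$limit))
  invisible(x)
}

#' Number of connected components of a haplotype network
#'
#' @param network a `haplotype_network`.
#' @return integer component count.
#' @export
network_components <- function(network) {
  stopifnot(inherits(network, "haplotype_network"))
  igraph::components(network$graph)$no
}

#' Node table of a haplotype network with habitat/geography tallies
#'
#' @param network a `haplotype_network`.
#' @return data.frame with one row per node: id, multiplicity, type, and for
#'   observed haplotypes the member counts per habitat, the geographies, and
#'   the species labels seen among members.
#' @export
network_node_table <- function(network) {
  stopifnot(inherits(network, "haplotype_network"))
  nodes <- network$nodes
  mem <- network$members
  tally <- function(hid, col) {
    if (is.null(mem[[col]])) return("")
    v <- mem[[col]][mem$haplotype == hid]
    v <- v[!is.na(v) & nzchar(as.character(v))]
    if (length(v) == 0) return("")
    tb <- table(as.character(v))
    paste(sprintf("%s:%d", names(tb), as.integer(tb)), collapse = ",")
  }
  nodes$habitat <- vapply(nodes$id, tally, character(1), col = "habitat")
  nodes$geography <- vapply(nodes$id, tally, character(1), col = "geography")
  nodes$species <- vapply(nodes$id, tally, character(1), col = "species_label")
  nodes
}

#' Export a haplotype network
#'
#' Writes the unit-step edge list as TSV (`node1`, `node2`), the node table
#' as TSV, or the full graph as GraphML for visualization.
#'
#' @param network a `haplotype_network`.
#' @param path output file path.
#' @param format one of `"edges"`, `"nodes"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("edges", "nodes", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "haplotype_network"))
  if (format == "edges") {
    el <- igraph::as_edgelist(network$graph)
    write.table(data.frame(node1 = el[, 1], node2 = el[, 2]), path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "nodes") {
    write.table(network_node_table(network), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    g <- network$graph
    nt <- network_node_table(network)
    for (col in c("habitat", "geography", "species"))
      g <- igraph::set_vertex_attr(g, col, value = nt[[col]])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Assign a query sequence to a reference haplotype by identity and coverage
#'
#' The query is compared against every reference; it is assigned to the
#' species of the best-matching haplotype only when it covers the required
#' fraction of the reference region and exceeds the identity threshold
#' (defaults: 100% coverage, identity strictly greater than 97%).
#' Equal-length comparisons are positional; a shorter query is slid along
#' the reference and scored at its best offset, its coverage being the
#' fraction of the reference it spans.
#'
#' @param query a sequence string (or 1-row data.frame with `sequence`).
#' @param references data.frame with columns `id`, `sequence` and `species`.
#' @param config an [analysis_config()].
#' @return list with `assigned` (logical), `species` (label or `NA`),
#'   `haplotype`, `identity`, `coverage`.
#' @export
assign_query <- function(query, references, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.data.frame(query)) query <- query$sequence[1]
  query <- gsub("-", "", normalize_rna(query), fixed = TRUE)
  stopifnot(is.data.frame(references),
            all(c("id", "sequence", "species") %in% names(references)),
            nrow(references) > 0)
  best <- list(identity = -1, coverage = 0, haplotype = NA_character_,
               species = NA_character_)
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  for (r in seq_len(nrow(references))) {
    ref <- gsub("-", "", normalize_rna(references$sequence[r]), fixed = TRUE)
    rc <- strsplit(ref, "", fixed = TRUE)[[1]]
    if (length(qc) == length(rc)) {
      identity <- sum(qc == rc) / length(rc)
      coverage <- 1
    } else if (length(qc) < length(rc)) {
      # best ungapped offset of the query within the reference
      hits <- vapply(0:(length(rc) - length(qc)), function(off)
        sum(qc == rc[(off + 1):(off + length(qc))]), numeric(1))
      identity <- max(hits) / length(qc)
      coverage <- length(qc) / length(rc)
    } else {
      hits <- vapply(0:(length(qc) - length(rc)), function(off)
        sum(rc == qc[(off + 1):(off + length(rc))]), numeric(1))
      identity <- max(hits) / length(qc)
      coverage <- 1
    }
    if (identity > best$identity) {
      best <- list(identity = identity, coverage = coverage,
                   haplotype = references$id[r],
                   species = references$species[r])
    }
  }
  ok <- best$coverage >= config$coverage_required &&
    best$identity > config$identity_min
  list(assigned = ok,
       species = if (ok) best$species else NA_character_,
       haplotype = best$haplotype,
       identity = best$identity, coverage = best$coverage)
}
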