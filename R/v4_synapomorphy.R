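# The hypervariable V4 region of the SSU rRNA: extraction against an E23
# helix template, per-column helix/spacer annotation, and detection of
# clade-diagnostic characters — non-homoplasious synapomorphies (NHSs) at
# single columns and CBCs/hemi-CBCs at paired columns.

#' Read a V4 helix template
#'
#' Template TSV with columns `helix`, `start`, `end`, `partner_helix`
#' (1-based inclusive coordinates on the ungapped reference). Each helix name
#' appears twice — the 5' strand span first, the 3' strand span second — and
#' `partner_helix` names the helix it pairs with (itself for a simple
#' hairpin). Spans must be non-overlapping, partner spans equal length, and
#' the resulting pairing nested.
#'
#' @param path template TSV path.
#' @param reference_id identifier of the reference strain the coordinates
#'   refer to.
#' @return object of class `v4_template`: list with `reference_id`, `spans`
#'   (data.frame), `pairing` (two-column matrix on ungapped reference
#'   positions), `region` (c(start, end)).
#' @export
read_v4_template <- function(path, reference_id = "reference") {
  spans <- read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, comment.char = "#")
  v4_template(spans, reference_id)
}

#' Construct a V4 helix template from a span table
#'
#' @param spans data.frame with columns `helix`, `start`, `end`,
#'   `partner_helix`.
#' @param reference_id identifier of the reference strain.
#' @return a `v4_template` (see [read_v4_template()]).
#' @export
v4_template <- function(spans, reference_id = "reference") {
  stopifnot(all(c("helix", "start", "end", "partner_helix") %in% names(spans)))
  spans$start <- as.integer(spans$start)
  spans$end <- as.integer(spans$end)
  if (any(spans$end < spans$start)) stop("template span with end < start")
  spans <- spans[order(spans$start), ]
  rownames(spans) <- NULL
  if (any(spans$start[-1] <= spans$end[-nrow(spans)]))
    stop("template spans overlap")
  pairing <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (hx in unique(spans$helix)) {
    rows <- which(spans$helix == hx)
    if (length(rows) != 2)
      stop("helix '", hx, "' must have exactly two spans (5' and 3' strand)")
    a <- spans[rows[1], ]; b <- spans[rows[2], ]
    if (!identical(a$partner_helix, hx) || !identical(b$partner_helix, hx))
      stop("partner_helix of '", hx, "' spans must name the paired helix")
    la <- a$end - a$start + 1; lb <- b$end - b$start + 1
    if (la != lb)
      stop("paired spans of helix '", hx, "' have unequal lengths")
    pairing <- rbind(pairing,
                     cbind(a$start:a$end, b$end:b$start))
  }
  pairing <- pairing[order(pairing[, 1]), , drop = FALSE]
  # nestedness check
  if (nrow(pairing) > 1) {
    for (r in 2:nrow(pairing)) {
      cross <- pairing[1:(r - 1), 1] < pairing[r, 1] &
        pairing[r, 1] < pairing[1:(r - 1), 2] &
        pairing[1:(r - 1), 2] < pairing[r, 2]
      if (any(cross)) stop("template pairing is not nested (pseudoknot)")
    }
  }
  structure(list(reference_id = reference_id, spans = spans,
                 pairing = pairing,
                 region = c(min(spans$start), max(spans$end))),
            class = "v4_template")
}

#' Write a V4 helix template to TSV
#'
#' @param template a `v4_template`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_v4_template <- function(template, path) {
  stopifnot(inherits(template, "v4_template"))
  write.table(template$spans, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.v4_template <- function(x, ...) {
  cat(sprintf("<v4_template> reference '%s', %d helices, region %d-%d\n",
              x$reference_id, length(unique(x$spans$helix)),
              x$region[1], x$region[2]))
  invisible(x)
}

#' Synthetic example V4/E23 helix template
#'
#' A constructed stand-in template with helices E23_1 to E23_14 (E23_10 and
#' E23_11 nested inside E23_9, so the spacer between the E23_11 hairpin and
#' the closing strand of E23_9 exists as in the E23 model). It is synthetic:
#' span coordinates do not come from any real SSU sequence. A matching
#' random reference sequence with complementary strands can be generated
#' with [synthetic_v4_reference()]. The same template ships as
#' `inst/extdata/v4_template_synthetic.tsv`.
#'
#' @return a `v4_template` with `reference_id = "SYNTH_REF"`.
#' @export
v4_template_synthetic <- function() {
  rows <- list()
  pos <- 6  # 5 nt leading spacer
  add <- function(helix, len5, inner, len3 = len5) {
    # hairpin: 5' span, `inner` unpaired nt, 3' span
    r5 <- c(pos, pos + len5 - 1)
    r3 <- c(pos + len5 + inner, pos + len5 + inner + len3 - 1)
    pos <<- r3[2] + 4  # 3 nt spacer after
    rows[[length(rows) + 1]] <<- data.frame(
      helix = helix, start = r5[1], end = r5[2], partner_helix = helix,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <<- data.frame(
      helix = helix, start = r3[1], end = r3[2], partner_helix = helix,
      stringsAsFactors = FALSE)
  }
  for (h in 1:8) add(paste0("E23_", h), 4, 4)
  # E23_9 encloses E23_10 and E23_11
  e9_5p <- c(pos, pos + 4)  # 5 bp
  pos <- pos + 5 + 2
  rows[[length(rows) + 1]] <- data.frame(helix = "E23_9", start = e9_5p[1],
                                         end = e9_5p[2],
                                         partner_helix = "E23_9",
                                         stringsAsFactors = FALSE)
  add("E23_10", 4, 4)
  add("E23_11", 4, 4)
  # spacer between E23_11 and the closing strand of E23_9
  pos <- pos + 2
  rows[[length(rows) + 1]] <- data.frame(helix = "E23_9", start = pos,
                                         end = pos + 4,
                                         partner_helix = "E23_9",
                                         stringsAsFactors = FALSE)
  pos <- pos + 5 + 3
  for (h in 12:14) add(paste0("E23_", h), 4, 4)
  v4_template(do.call(rbind, rows), reference_id = "SYNTH_REF")
}

#' Random reference sequence consistent with a V4 template
#'
#' Draws a random sequence whose paired template positions are Watson-Crick
#' complementary, so the template pairing is realized.
#'
#' @param template a `v4_template`.
#' @param length total sequence length (default: template region end plus a
#'   short 3' tail).
#' @param seed integer seed.
#' @return a sequence string.
#' @export
synthetic_v4_reference <- function(template, length = template$region[2] + 4,
                                   seed = 1) {
  stopifnot(inherits(template, "v4_template"), length >= template$region[2])
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  with_seed(seed, {
    chars <- sample(UNAMBIGUOUS, length, replace = TRUE)
    chars[template$pairing[, 2]] <- comp[chars[template$pairing[, 1]]]
    paste(chars, collapse = "")
  })
}

#' Extract the V4 region from an SSU alignment
#'
#' Maps the template's region boundaries from ungapped reference coordinates
#' through the reference row's gaps to alignment columns and slices every
#' strain identically.
#'
#' @param ssu_alignment aligned SSU sequences (named character vector or
#'   data.frame with `id`/`sequence`); must contain the template's reference.
#' @param template a `v4_template`.
#' @return object of class `v4_slice`: list with `seqs` (named character
#'   vector of slices), `columns` (original alignment columns), `ref_pos`
#'   (ungapped reference position per slice column, `NA` where the reference
#'   has a gap), `template`.
#' @export
extract_v4 <- function(ssu_alignment, template) {
  stopifnot(inherits(template, "v4_template"))
  seqs <- as_seq_vector(ssu_alignment)
  if (!template$reference_id %in% names(seqs))
    stop("reference '", template$reference_id, "' not found in the alignment")
  ref_row <- strsplit(seqs[[template$reference_id]], "", fixed = TRUE)[[1]]
  ungapped <- which(ref_row != "-")
  if (template$region[2] > length(ungapped))
    stop("template region extends past the ungapped reference length")
  cols <- ungapped[template$region[1]]:ungapped[template$region[2]]
  ref_pos <- rep(NA_integer_, length(cols))
  ref_pos[match(ungapped[template$region[1]:template$region[2]], cols)] <-
    template$region[1]:template$region[2]
  slices <- vapply(seqs, function(s)
    paste(strsplit(s, "", fixed = TRUE)[[1]][cols], collapse = ""),
    character(1))
  structure(list(seqs = slices, columns = cols, ref_pos = ref_pos,
                 template = template),
            class = "v4_slice")
}

#' Annotate a V4 slice with helix and spacer labels
#'
#' Every slice column receives a label: the helix name when the reference
#' position falls inside a template span, otherwise
#' `spacer(X-Y)` where X and Y are the helices flanking the position in
#' sequence order (`5'` / `3'` at the region edges). Columns where the
#' reference has a gap inherit the label of the nearest reference position
#' to their left. The template pairing is mapped to slice columns.
#'
#' @param v4_slice a `v4_slice` from [extract_v4()].
#' @return the slice with elements `labels` (character per column) and
#'   `pairing` (two-column matrix of slice columns) added.
#' @export
annotate_v4 <- function(v4_slice) {
  stopifnot(inherits(v4_slice, "v4_slice"))
  tpl <- v4_slice$template
  maxpos <- tpl$region[2]
  pos_label <- rep(NA_character_, maxpos)
  for (r in seq_len(nrow(tpl$spans)))
    pos_label[tpl$spans$start[r]:tpl$spans$end[r]] <- tpl$spans$helix[r]
  # spacer labels between flanking spans
  span_order <- tpl$spans[order(tpl$spans$start), ]
  for (p in which(is.na(pos_label))) {
    prev <- span_order$helix[span_order$end < p]
    nxt <- span_order$helix[span_order$start > p]
    left <- if (length(prev) > 0) prev[length(prev)] else "5'"
    right <- if (length(nxt) > 0) nxt[1] else "3'"
    pos_label[p] <- sprintf("spacer(%s-%s)", left, right)
  }
  labels <- character(length(v4_slice$ref_pos))
  last <- tpl$region[1]
  for (k in seq_along(labels)) {
    if (!is.na(v4_slice$ref_pos[k])) last <- v4_slice$ref_pos[k]
    labels[k] <- pos_label[last]
  }
  pairing <- tpl$pairing
  keep <- pairing[, 1] >= tpl$region[1] & pairing[, 2] <= tpl$region[2]
  pairing <- pairing[keep, , drop = FALSE]
  slice_col <- match(pairing, v4_slice$ref_pos)
  pairing_slice <- matrix(slice_col, ncol = 2,
                          dimnames = list(NULL, c("i", "j")))
  v4_slice$labels <- labels
  v4_slice$pairing <- pairing_slice
  v4_slice
}

# normalize alignment input for the diagnostic finders: accepts a v4_slice
# (labels/pairing available) or plain aligned sequences
diag_input <- function(alignment) {
  if (inherits(alignment, "v4_slice")) {
    if (is.null(alignment$labels)) alignment <- annotate_v4(alignment)
    list(m = as_char_matrix(alignment$seqs), labels = alignment$labels,
         pairing = alignment$pairing)
  } else {
    list(m = as_char_matrix(alignment), labels = NULL, pairing = NULL)
  }
}

#' Find non-homoplasious synapomorphies of a clade
#'
#' Columns where all clade members share one unambiguous non-gap state that
#' occurs in no strain outside the clade. When a tree is supplied, single
#' origin is additionally verified: the presence/absence character of the
#' state must have parsimony score 1 on the tree (one originating branch).
#' A clade of size one yields autapomorphies, flagged as such. When the
#' alignment carries a pairing (a `v4_slice`), template-paired columns are
#' excluded by default — diagnostic changes at paired columns belong to
#' [find_pair_synapomorphies()], which classifies them as CBC or hemi-CBC.
#'
#' @param alignment a `v4_slice` or aligned sequences.
#' @param clade character vector of strain ids (non-empty proper subset of
#'   the alignment).
#' @param tree optional `phylo` tree over the alignment's strains.
#' @param exclude_paired drop columns that are base-paired in the template.
#' @return data.frame with columns `kind` ("NHS"), `column`, `label` (helix
#'   or spacer when available), `clade_state`, `outside_states`,
#'   `autapomorphy`.
#' @export
find_nhs <- function(alignment, clade, tree = NULL, exclude_paired = TRUE) {
  inp <- diag_input(alignment)
  m <- inp$m
  paired_cols <- if (exclude_paired && !is.null(inp$pairing))
    c(inp$pairing) else integer(0)
  strains <- rownames(m)
  if (length(clade) == 0) stop("clade is empty")
  if (!all(clade %in% strains))
    stop("clade members missing from the alignment: ",
         paste(setdiff(clade, strains), collapse = ", "))
  if (setequal(clade, strains))
    stop("clade equals the full strain set; synapomorphies are undefined")
  inside <- m[clade, , drop = FALSE]
  outside <- m[setdiff(strains, clade), , drop = FALSE]
  hits <- list()
  for (col in seq_len(ncol(m))) {
    if (col %in% paired_cols) next
    st <- unique(inside[, col])
    if (length(st) != 1 || !st %in% UNAMBIGUOUS) next
    if (st %in% outside[, col]) next
    if (!is.null(tree)) {
      present <- matrix(as.integer(m[, col] == st), ncol = 1,
                        dimnames = list(strains, NULL))
      dat <- phangorn::phyDat(present, type = "USER", levels = c(0L, 1L))
      if (phangorn::parsimony(tree, dat) != 1) next
    }
    hits[[length(hits) + 1]] <- data.frame(
      kind = "NHS", column = col,
      label = if (!is.null(inp$labels)) inp$labels[col] else NA_character_,
      clade_state = st,
      outside_states = paste(sort(unique(outside[, col])), collapse = ","),
      autapomorphy = length(clade) == 1,
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(kind = character(0), column = integer(0),
                      label = character(0), clade_state = character(0),
                      outside_states = character(0),
                      autapomorphy = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Find clade-diagnostic base-pair changes (CBC / hemi-CBC)
#'
#' At each template-paired column pair, reports the pairs where the clade's
#' (uniform) base pair differs from the base pair of every outside strain,
#' classified against the outside majority pair with the same rules as the
#' barcode comparison: CBC when both strands differ, HCBC when one does;
#' changes involving gaps or mismatch pairs are reported with kind "NHS"
#' (paired-column synapomorphy without retained pairing). A polymorphic
#' outside pair set is flagged, not silently classified.
#'
#' @param alignment a `v4_slice` (annotated) or aligned sequences plus
#'   `pairing`.
#' @param clade character vector of strain ids.
#' @param pairing optional two-column matrix of paired columns (required
#'   when `alignment` is not a `v4_slice`).
#' @return data.frame with columns `kind`, `column5`, `column3`, `label`,
#'   `clade_state`, `outside_state`, `outside_polymorphic`.
#' @export
find_pair_synapomorphies <- function(alignment, clade, pairing = NULL) {
  inp <- diag_input(alignment)
  m <- inp$m
  if (is.null(pairing)) pairing <- inp$pairing
  if (is.null(pairing)) stop("no pairing available: supply a v4_slice or a pairing matrix")
  strains <- rownames(m)
  stopifnot(all(clade %in% strains), !setequal(clade, strains),
            length(clade) > 0)
  outside_ids <- setdiff(strains, clade)
  hits <- list()
  for (r in seq_len(nrow(pairing))) {
    i <- pairing[r, 1]; j <- pairing[r, 2]
    if (is.na(i) || is.na(j)) next
    in5 <- unique(m[clade, i]); in3 <- unique(m[clade, j])
    if (length(in5) != 1 || length(in3) != 1) next
    if (!in5 %in% c(UNAMBIGUOUS, "-") || !in3 %in% c(UNAMBIGUOUS, "-")) next
    out_pairs <- paste(m[outside_ids, i], m[outside_ids, j])
    clade_pair <- paste(in5, in3)
    if (clade_pair %in% out_pairs) next
    tb <- sort(table(out_pairs), decreasing = TRUE)
    maj <- strsplit(names(tb)[1], " ", fixed = TRUE)[[1]]
    cl <- as.character(classify_change(encode_pair(in5, in3),
                                       encode_pair(maj[1], maj[2])))
    kind <- switch(cl, CBC = "CBC", HCBC = "HCBC", "NHS")
    if (cl == "IDENTICAL") next
    hits[[length(hits) + 1]] <- data.frame(
      kind = kind, column5 = i, column3 = j,
      label = if (!is.null(inp$labels)) inp$labels[i] else NA_character_,
      clade_state = paste0(in5, "-", in3),
      outside_state = paste0(maj[1], "-", maj[2]),
      outside_polymorphic = length(tb) > 1,
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(kind = character(0), column5 = integer(0),
                      column3 = integer(0), label = character(0),
                      clade_state = character(0), outside_state = character(0),
                      outside_polymorphic = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}
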