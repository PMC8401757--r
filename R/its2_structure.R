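# Base-paired ITS-2 structures: dot-bracket parsing, helix annotation under
# the three-helix model (helices I-III; helix IV absent in these taxa), and
# selection of the conserved barcode columns across an aligned strain set.
#
# Coordinates are 1-based throughout, following R convention; the same
# coordinates appear in reports.

#' Build a structured sequence from a dot-bracket string
#'
#' Parses a nested dot-bracket structure into a base-pairing map. `-` and `.`
#' are both treated as unpaired (so aligned structures can carry gaps).
#'
#' @param sequence nucleotide string (same length as `structure`).
#' @param structure dot-bracket string using `(`, `)`, `.`, `-`.
#' @param id identifier for the strain/record.
#' @param annotate if `TRUE`, helix labels are assigned via
#'   [annotate_helices()].
#' @return an object of class `structured_sequence`: a list with elements
#'   `id`, `sequence`, `structure`, `pairing` (two-column integer matrix of
#'   1-based position pairs, i < j) and `helix` (per-position labels, `NA`
#'   until annotated).
#' @export
#' @examples
#' ss <- pairing_from_dotbracket("GGAACC", "((..))")
#' ss$pairing  # pairs (1,6) and (2,5)
pairing_from_dotbracket <- function(sequence, structure, id = "seq",
                                    annotate = FALSE) {
  sequence <- normalize_rna(sequence)
  if (nchar(sequence) != nchar(structure))
    stop(sprintf("record '%s': structure length (%d) differs from sequence length (%d)",
                 id, nchar(structure), nchar(sequence)), call. = FALSE)
  validate_alphabet(sequence, id)
  validate_dotbracket(structure, id)
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs <- rbind(pairs, c(i, k))
    }
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(id = id, sequence = sequence, structure = structure,
                 pairing = pairs,
                 helix = rep(NA_character_, nchar(sequence))),
            class = "structured_sequence")
}

#' @export
print.structured_sequence <- function(x, ...) {
  cat(sprintf("<structured_sequence> %s (%d nt, %d base pairs)\n",
              x$id, nchar(x$sequence), nrow(x$pairing)))
  helices <- unique(x$helix[!is.na(x$helix) & x$helix %in% c("I", "II", "III")])
  if (length(helices) > 0)
    cat("  helices:", paste(helices, collapse = ", "), "\n")
  invisible(x)
}

# Decompose a pairing map into stems. Consecutive pairs (sorted by opening
# position) belong to one stem when both strands continue with at most
# `max_bulge` unpaired nucleotides on either side.
stem_decomposition <- function(pairing, max_bulge = 3) {
  if (nrow(pairing) == 0) return(list())
  p <- pairing[order(pairing[, 1]), , drop = FALSE]
  stems <- list()
  cur <- p[1, , drop = FALSE]
  if (nrow(p) > 1) {
    for (r in 2:nrow(p)) {
      prev <- cur[nrow(cur), ]
      gap5 <- p[r, 1] - prev[1] - 1
      gap3 <- prev[2] - p[r, 2] - 1
      nested <- p[r, 1] > prev[1] && p[r, 2] < prev[2]
      if (nested && gap5 <= max_bulge && gap3 <= max_bulge) {
        cur <- rbind(cur, p[r, ])
      } else {
        stems[[length(stems) + 1]] <- cur
        cur <- p[r, , drop = FALSE]
      }
    }
  }
  stems[[length(stems) + 1]] <- cur
  stems
}

#' Annotate the helices of an ITS-2 structure
#'
#' Maximal stacked stems (interior bulges up to `max_bulge` nucleotides do
#' not split a stem) with at least `min_stem_len` base pairs are numbered
#' I, II, III in 5'-to-3' order of their opening strands. Terminal-loop
#' positions of each helix are labelled `loop_I`, `loop_II`, `loop_III`; all
#' other positions are `spacer`. Helix IV is never assigned: more than
#' `max_helices` qualifying stems is an error (override the template), fewer
#' produces a warning and labels only the stems present.
#'
#' @param ss a `structured_sequence`.
#' @param min_stem_len minimum number of stacked pairs for a stem to count as
#'   a helix (default 2).
#' @param max_bulge largest interior bulge (nt per side) that does not split
#'   a helix (default 3).
#' @param max_helices maximum number of helices expected (default 3).
#' @param warn warn when fewer than `max_helices` helices are found.
#' @return the `structured_sequence` with its `helix` labels filled in.
#' @export
annotate_helices <- function(ss, min_stem_len = 2, max_bulge = 3,
                             max_helices = 3, warn = TRUE) {
  stopifnot(inherits(ss, "structured_sequence"))
  n <- nchar(ss$sequence)
  labels <- rep("spacer", n)
  stems <- stem_decomposition(ss$pairing, max_bulge = max_bulge)
  stems <- Filter(function(s) nrow(s) >= min_stem_len, stems)
  if (length(stems) > max_helices)
    stop(sprintf("found %d stems of >= %d pairs but at most %d helices are expected; supply a structure template or adjust min_stem_len",
                 length(stems), min_stem_len, max_helices), call. = FALSE)
  if (length(stems) < max_helices && warn)
    warning(sprintf("found %d helices (expected %d); labelling those present",
                    length(stems), max_helices), call. = FALSE)
  # order by opening strand position
  if (length(stems) > 0) {
    ord <- order(vapply(stems, function(s) min(s[, 1]), numeric(1)))
    stems <- stems[ord]
    for (h in seq_along(stems)) {
      roman <- as.character(utils::as.roman(h))
      s <- stems[[h]]
      labels[c(s[, 1], s[, 2])] <- roman
      # terminal loop: positions strictly inside the innermost pair of this
      # stem that contain no further pairs
      inner <- s[which.max(s[, 1]), ]
      if (inner[2] - inner[1] > 1) {
        span <- (inner[1] + 1):(inner[2] - 1)
        has_pairs <- any(ss$pairing[, 1] %in% span | ss$pairing[, 2] %in% span)
        if (!has_pairs) labels[span] <- paste0("loop_", roman)
      }
    }
  }
  ss$helix <- labels
  ss
}

#' Transfer a reference secondary structure to aligned strains
#'
#' Homology transfer: the pairing (and helix labels) of one reference
#' structure are applied column-by-column to every strain of an alignment,
#' giving all strains one shared coordinate system. The reference structure
#' may be given on the aligned reference row (same length as the alignment)
#' or on the ungapped reference sequence, in which case it is mapped through
#' the reference row's gaps.
#'
#' @param reference a `structured_sequence` for the reference strain.
#' @param alignment aligned sequences (named character vector or
#'   `data.frame` with `id`/`sequence`); must contain `reference$id` unless
#'   the reference structure is already in alignment coordinates and
#'   `require_reference = FALSE`.
#' @param annotate annotate helices on the transferred structure.
#' @param require_reference error when the reference id is missing from the
#'   alignment.
#' @return named list of `structured_sequence` objects, one per strain, all
#'   sharing the reference pairing.
#' @export
transfer_structure <- function(reference, alignment, annotate = TRUE,
                               require_reference = TRUE) {
  stopifnot(inherits(reference, "structured_sequence"))
  seqs <- as_seq_vector(alignment)
  width <- unique(nchar(seqs))
  if (length(width) != 1) stop("alignment rows have unequal lengths")
  if (nchar(reference$sequence) == width) {
    pairing <- reference$pairing
    struct_aln <- reference$structure
  } else {
    if (!reference$id %in% names(seqs)) {
      stop("reference '", reference$id, "' not found in the alignment")
    }
    ref_row <- strsplit(seqs[[reference$id]], "", fixed = TRUE)[[1]]
    ungapped_pos <- which(ref_row != "-")
    if (length(ungapped_pos) != nchar(reference$sequence))
      stop("ungapped reference row length does not match the reference structure length")
    pairing <- reference$pairing
    pairing[, 1] <- ungapped_pos[pairing[, 1]]
    pairing[, 2] <- ungapped_pos[pairing[, 2]]
    sc <- rep(".", width)
    sc[pairing[, 1]] <- "("
    sc[pairing[, 2]] <- ")"
    struct_aln <- paste(sc, collapse = "")
  }
  if (require_reference && !reference$id %in% names(seqs))
    stop("reference '", reference$id, "' not found in the alignment")
  out <- lapply(names(seqs), function(id) {
    ss <- structure(list(id = id, sequence = seqs[[id]], structure = struct_aln,
                         pairing = pairing,
                         helix = rep(NA_character_, width)),
                    class = "structured_sequence")
    if (annotate) ss <- annotate_helices(ss, warn = FALSE)
    ss
  })
  names(out) <- names(seqs)
  out
}

#' Select the conserved barcode columns of an aligned strain set
#'
#' Returns exactly the alignment columns that are base-paired in every strain
#' with a consistent partner column, minus the terminal-loop columns of
#' helices I and II (the variable loops are not part of the barcode). The
#' partner map is an involution; each pair is reported once, keyed by its
#' opening (5') column.
#'
#' @param strains list of `structured_sequence` objects sharing one alignment
#'   coordinate system.
#' @param exclude_loops helices whose terminal-loop columns are excluded
#'   (default `c("I", "II")`).
#' @return data.frame of class `conserved_columns` with columns `column`
#'   (opening strand), `partner` (closing strand) and `helix`.
#' @export
conserved_columns <- function(strains, exclude_loops = c("I", "II")) {
  stopifnot(length(strains) >= 1,
            all(vapply(strains, inherits, logical(1), "structured_sequence")))
  widths <- vapply(strains, function(s) nchar(s$sequence), numeric(1))
  if (length(unique(widths)) != 1)
    stop("strains do not share one alignment coordinate system")
  width <- widths[1]
  strains <- lapply(strains, function(s) {
    if (all(is.na(s$helix))) annotate_helices(s, warn = FALSE) else s
  })
  # partner vector per strain: 0 = unpaired
  partner_of <- function(s) {
    p <- integer(width)
    p[s$pairing[, 1]] <- s$pairing[, 2]
    p[s$pairing[, 2]] <- s$pairing[, 1]
    p
  }
  partners <- vapply(strains, partner_of, integer(width))
  paired_everywhere <- apply(partners > 0, 1, all)
  consistent <- apply(partners, 1, function(r) length(unique(r)) == 1)
  conflict <- which(paired_everywhere & !consistent)
  if (length(conflict) > 0)
    stop("inconsistent partner columns across strains at column(s): ",
         paste(conflict, collapse = ", "), call. = FALSE)
  keep <- which(paired_everywhere & consistent)
  # drop terminal-loop columns of the excluded helices (in any strain)
  loop_labels <- paste0("loop_", exclude_loops)
  in_loop <- rep(FALSE, width)
  for (s in strains) in_loop <- in_loop | s$helix %in% loop_labels
  keep <- keep[!in_loop[keep]]
  part <- partners[, 1]
  opening <- keep[keep < part[keep]]
  opening <- opening[part[opening] %in% keep]
  helix <- strains[[1]]$helix[opening]
  out <- data.frame(column = opening, partner = part[opening], helix = helix,
                    stringsAsFactors = FALSE)
  out <- out[order(out$column), ]
  rownames(out) <- NULL
  class(out) <- c("conserved_columns", "data.frame")
  out
}

#' Write a conserved-column report
#'
#' @param cols a `conserved_columns` object.
#' @param path output TSV path (columns: column, partner, helix; 1-based
#'   inclusive coordinates).
#' @return `path`, invisibly.
#' @export
write_conserved_columns <- function(cols, path) {
  write.table(as.data.frame(cols), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
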