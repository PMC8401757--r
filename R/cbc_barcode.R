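# The eight-state base-pair number code and the CBC/hemi-CBC machinery:
# encode conserved base pairs as codes 1-8, compare barcodes column by
# column, classify the changes, count variable positions, and delimit
# species from barcode evidence plus lineage support.
#
# Number code: 1 = A-U; 2 = U-A; 3 = G-C; 4 = C-G; 5 = G.U; 6 = U.G;
# 7 = mismatch (any other two non-gap bases at a paired column);
# 8 = deletion, single or unpaired bases.

# the six pairing-retaining types, indexed by code
PAIR_TYPES <- matrix(c("A", "U",
                       "U", "A",
                       "G", "C",
                       "C", "G",
                       "G", "U",
                       "U", "G"),
                     ncol = 2, byrow = TRUE,
                     dimnames = list(NULL, c("base5", "base3")))

CHANGE_LEVELS <- c("IDENTICAL", "CBC", "HCBC", "MISMATCH_CHANGE",
                   "INDEL_CHANGE", "AMBIGUOUS")

# vectorized code assignment; b5/b3 normalized single characters
pair_code <- function(b5, b3, paired) {
  code <- integer(length(b5))
  gap <- b5 == "-" | b3 == "-"
  code[gap | !paired] <- 8L
  todo <- which(code == 0L)
  if (length(todo) > 0) {
    key <- paste0(b5[todo], b3[todo])
    pkey <- paste0(PAIR_TYPES[, 1], PAIR_TYPES[, 2])
    m <- match(key, pkey)
    code[todo] <- ifelse(is.na(m), 7L, m)
  }
  code
}

#' Encode one base pair into the eight-state number code
#'
#' @param base5 5' nucleotide (IUPAC) or `-`.
#' @param base3 3' nucleotide (IUPAC) or `-`.
#' @param paired whether the column is base-paired in this strain; `FALSE`
#'   forces code 8.
#' @return a list of class `barcode_column` with elements `code`, `base5`,
#'   `base3`.
#' @export
#' @examples
#' encode_pair("A", "U")$code  # 1
#' encode_pair("U", "G")$code  # 6
#' encode_pair("C", "C")$code  # 7 (mismatch)
#' encode_pair("A", "-")$code  # 8 (deletion)
encode_pair <- function(base5, base3, paired = TRUE) {
  base5 <- normalize_rna(base5)
  base3 <- normalize_rna(base3)
  for (b in c(base5, base3)) {
    if (!b %in% IUPAC_CHARS)
      stop("not an IUPAC nucleotide or gap: '", b, "'", call. = FALSE)
  }
  structure(list(code = pair_code(base5, base3, paired),
                 base5 = base5, base3 = base3),
            class = "barcode_column")
}

#' Encode a strain's barcode over the conserved columns
#'
#' One number-code state per conserved column, ordered 5' to 3' by the
#' opening strand. A gap on either side of a pair yields code 8.
#'
#' @param ss a `structured_sequence` in the alignment coordinates underlying
#'   `cols`.
#' @param cols a `conserved_columns` object.
#' @return object of class `its2_barcode`: list with `strain`, `code`
#'   (integer vector), `base5`, `base3`, `column`, `partner`.
#' @export
encode_barcode <- function(ss, cols) {
  stopifnot(inherits(ss, "structured_sequence"),
            inherits(cols, "conserved_columns"))
  n <- nchar(ss$sequence)
  if (any(cols$column > n) || any(cols$partner > n))
    stop("strain '", ss$id, "' is shorter than the conserved column set; ",
         "it does not belong to the underlying alignment", call. = FALSE)
  chars <- strsplit(ss$sequence, "", fixed = TRUE)[[1]]
  pairset <- paste(ss$pairing[, 1], ss$pairing[, 2])
  paired <- paste(cols$column, cols$partner) %in% pairset
  b5 <- chars[cols$column]
  b3 <- chars[cols$partner]
  structure(list(strain = ss$id,
                 code = pair_code(b5, b3, paired),
                 base5 = b5, base3 = b3,
                 column = cols$column, partner = cols$partner),
            class = "its2_barcode")
}

#' Render a barcode as a digit string
#'
#' Concatenated codes 1-8, e.g. `"341256"`, the form in which barcodes are
#' reported and compared by eye.
#'
#' @param barcode an `its2_barcode`.
#' @return a single string of digits.
#' @export
barcode_string <- function(barcode) {
  stopifnot(inherits(barcode, "its2_barcode"))
  paste(barcode$code, collapse = "")
}

#' @export
print.its2_barcode <- function(x, ...) {
  cat(sprintf("<its2_barcode> %s: %s\n", x$strain, barcode_string(x)))
  invisible(x)
}

# vectorized change classification over parallel code/base vectors
classify_change_vec <- function(code_a, b5a, b3a, code_b, b5b, b3b) {
  n <- length(code_a)
  out <- character(n)
  amb <- !(b5a %in% c(UNAMBIGUOUS, "-")) | !(b3a %in% c(UNAMBIGUOUS, "-")) |
         !(b5b %in% c(UNAMBIGUOUS, "-")) | !(b3b %in% c(UNAMBIGUOUS, "-"))
  same <- b5a == b5b & b3a == b3b
  out[amb] <- "AMBIGUOUS"
  out[!amb & same] <- "IDENTICAL"
  rest <- !amb & !same
  indel <- rest & (code_a == 8L | code_b == 8L)
  out[indel] <- "INDEL_CHANGE"
  mism <- rest & !indel & (code_a == 7L | code_b == 7L)
  out[mism] <- "MISMATCH_CHANGE"
  canon <- rest & !indel & !mism  # both codes in 1..6
  both <- canon & b5a != b5b & b3a != b3b
  out[both] <- "CBC"
  out[canon & !both] <- "HCBC"
  factor(out, levels = CHANGE_LEVELS)
}

#' Classify the change between two barcode columns
#'
#' `IDENTICAL` when the bases match on both sides (gap vs gap included);
#' `CBC` when both columns keep pairing (codes 1-6) and both strands differ;
#' `HCBC` when pairing is kept and exactly one strand differs;
#' `INDEL_CHANGE` when code 8 is involved; `MISMATCH_CHANGE` when code 7 is
#' involved; `AMBIGUOUS` when any base is an IUPAC ambiguity code. The
#' classification is symmetric in its arguments.
#'
#' @param a,b `barcode_column` objects from [encode_pair()].
#' @return factor of length 1 with levels
#'   `IDENTICAL, CBC, HCBC, MISMATCH_CHANGE, INDEL_CHANGE, AMBIGUOUS`.
#' @export
#' @examples
#' classify_change(encode_pair("A", "U"), encode_pair("G", "C"))  # CBC
#' classify_change(encode_pair("A", "U"), encode_pair("G", "U"))  # HCBC
classify_change <- function(a, b) {
  stopifnot(inherits(a, "barcode_column"), inherits(b, "barcode_column"))
  classify_change_vec(a$code, a$base5, a$base3, b$code, b$base5, b$base3)
}

#' Compare two barcodes column by column
#'
#' @param a,b `its2_barcode` objects of equal length.
#' @return object of class `barcode_comparison`: list with `strain_a`,
#'   `strain_b`, `per_column` (factor of change classes), and the counts
#'   `n_cbc`, `n_hcbc`, `n_other` (mismatch + indel changes), `n_ambiguous`.
#' @export
compare_barcodes <- function(a, b) {
  stopifnot(inherits(a, "its2_barcode"), inherits(b, "its2_barcode"))
  if (length(a$code) != length(b$code))
    stop(sprintf("barcode lengths differ: %s has %d columns, %s has %d",
                 a$strain, length(a$code), b$strain, length(b$code)),
         call. = FALSE)
  cl <- classify_change_vec(a$code, a$base5, a$base3, b$code, b$base5, b$base3)
  structure(list(strain_a = a$strain, strain_b = b$strain,
                 per_column = cl,
                 n_cbc = sum(cl == "CBC"),
                 n_hcbc = sum(cl == "HCBC"),
                 n_other = sum(cl %in% c("MISMATCH_CHANGE", "INDEL_CHANGE")),
                 n_ambiguous = sum(cl == "AMBIGUOUS")),
            class = "barcode_comparison")
}

#' @export
print.barcode_comparison <- function(x, ...) {
  cat(sprintf("<barcode_comparison> %s vs %s: %d CBC, %d HCBC, %d other, %d ambiguous\n",
              x$strain_a, x$strain_b, x$n_cbc, x$n_hcbc, x$n_other,
              x$n_ambiguous))
  invisible(x)
}

#' Count variable base-pair positions across a set of barcodes
#'
#' A column is variable when not all barcodes carry the same (5', 3') bases
#' there. Counting uses base identity rather than code identity (two distinct
#' mismatches both code 7 but still count as variable). Columns containing an
#' IUPAC ambiguity code in any barcode are excluded.
#'
#' @param barcodes list of at least two `its2_barcode` objects of equal
#'   length.
#' @return integer count of variable positions.
#' @export
count_variable_positions <- function(barcodes) {
  if (length(barcodes) < 2)
    stop("at least two barcodes are required", call. = FALSE)
  stopifnot(all(vapply(barcodes, inherits, logical(1), "its2_barcode")))
  lens <- vapply(barcodes, function(b) length(b$code), integer(1))
  if (length(unique(lens)) != 1) stop("barcode lengths differ", call. = FALSE)
  m5 <- vapply(barcodes, function(b) b$base5, character(lens[1]))
  m3 <- vapply(barcodes, function(b) b$base3, character(lens[1]))
  if (lens[1] == 0) return(0L)
  m5 <- matrix(m5, nrow = lens[1])
  m3 <- matrix(m3, nrow = lens[1])
  amb <- apply(m5, 1, function(r) any(!r %in% c(UNAMBIGUOUS, "-"))) |
         apply(m3, 1, function(r) any(!r %in% c(UNAMBIGUOUS, "-")))
  varies <- apply(m5, 1, function(r) length(unique(r)) > 1) |
            apply(m3, 1, function(r) length(unique(r)) > 1)
  sum(varies & !amb)
}

# minimum CBC/HCBC counts over all cross-lineage strain pairs: a change only
# counts as separating evidence when it is seen in every member pair
lineage_separation <- function(strains_a, strains_b, barcodes) {
  min_cbc <- Inf; min_hcbc <- Inf
  identical_all <- TRUE
  for (sa in strains_a) for (sb in strains_b) {
    cmp <- compare_barcodes(barcodes[[sa]], barcodes[[sb]])
    min_cbc <- min(min_cbc, cmp$n_cbc)
    min_hcbc <- min(min_hcbc, cmp$n_hcbc)
    if (cmp$n_cbc + cmp$n_hcbc + cmp$n_other > 0) identical_all <- FALSE
  }
  list(min_cbc = min_cbc, min_hcbc = min_hcbc, identical = identical_all)
}

#' Delimit species from lineages, barcodes and support values
#'
#' Lineages are kept distinct when separated by at least one CBC (regardless
#' of support), or by at least one hemi-CBC when both lineages are supported
#' (bootstrap at or above `config$bootstrap_support_min`, or posterior at or
#' above `config$posterior_min` when posteriors are supplied). Lineages that
#' are not separable — identical barcodes, or hemi-CBC-only splits without
#' support — are merged by transitive closure. Output is invariant to strain
#' ordering; species are numbered by the lexicographically smallest strain
#' they contain.
#'
#' @param lineages named list of character vectors of strain ids (disjoint),
#'   or a data.frame with columns `lineage` and `strain`.
#' @param supports data.frame with columns `lineage`, `bootstrap` (percent)
#'   and optionally `posterior`, or a named numeric vector of bootstrap
#'   percentages.
#' @param barcodes list of `its2_barcode` objects covering every strain
#'   (named by strain, or names are taken from the `strain` fields).
#' @param config an [analysis_config()].
#' @return object of class `species_partition`: list with `groups` (named
#'   list of strain sets), `assignment` (data.frame strain/lineage/species),
#'   `evidence` (one row per retained between-species lineage split) and
#'   `config`.
#' @export
delimit_species <- function(lineages, supports, barcodes,
                            config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.data.frame(lineages)) {
    stopifnot(all(c("lineage", "strain") %in% names(lineages)))
    lineages <- split(as.character(lineages$strain),
                      as.character(lineages$lineage))
  }
  if (is.null(names(lineages)) || any(!nzchar(names(lineages))))
    stop("lineages must be named")
  all_strains <- unlist(lineages, use.names = FALSE)
  if (anyDuplicated(all_strains))
    stop("lineages are not disjoint: ",
         paste(unique(all_strains[duplicated(all_strains)]), collapse = ", "))
  # barcode lookup by strain
  bc_names <- names(barcodes)
  if (is.null(bc_names))
    bc_names <- vapply(barcodes, function(b) b$strain, character(1))
  names(barcodes) <- bc_names
  missing <- setdiff(all_strains, bc_names)
  if (length(missing) > 0)
    stop("strain(s) without barcode: ", paste(missing, collapse = ", "))
  # supports
  if (is.numeric(supports) && !is.null(names(supports)))
    supports <- data.frame(lineage = names(supports), bootstrap = supports,
                           stringsAsFactors = FALSE)
  stopifnot(is.data.frame(supports),
            all(c("lineage", "bootstrap") %in% names(supports)))
  if (!"posterior" %in% names(supports)) supports$posterior <- NA_real_
  miss_sup <- setdiff(names(lineages), supports$lineage)
  if (length(miss_sup) > 0)
    stop("lineage(s) without support value: ", paste(miss_sup, collapse = ", "))
  sup_row <- function(l) supports[match(l, supports$lineage), ]
  is_supported <- function(l) {
    r <- sup_row(l)
    (!is.na(r$bootstrap) && r$bootstrap >= config$bootstrap_support_min) ||
      (!is.na(r$posterior) && r$posterior >= config$posterior_min)
  }

  ln <- sort(names(lineages))
  k <- length(ln)
  sep_evidence <- list()
  merge_from <- character(0); merge_to <- character(0)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      sep <- lineage_separation(lineages[[ln[i]]], lineages[[ln[j]]], barcodes)
      if (sep$min_cbc >= 1) {
        ev <- "CBC"
      } else if (sep$min_hcbc >= 1 && is_supported(ln[i]) && is_supported(ln[j])) {
        ev <- "HCBC+support"
      } else {
        ev <- NA_character_
      }
      if (is.na(ev)) {
        merge_from <- c(merge_from, ln[i]); merge_to <- c(merge_to, ln[j])
      } else {
        sep_evidence[[length(sep_evidence) + 1]] <- data.frame(
          lineage_a = ln[i], lineage_b = ln[j], evidence = ev,
          n_cbc = sep$min_cbc, n_hcbc = sep$min_hcbc,
          stringsAsFactors = FALSE)
      }
    }
  }
  # transitive closure of "not separable"
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ln)
  if (length(merge_from) > 0)
    g <- igraph::add_edges(g, c(rbind(merge_from, merge_to)))
  comp <- igraph::components(g)$membership
  groups <- lapply(split(ln, comp), function(ls)
    sort(unlist(lineages[ls], use.names = FALSE)))
  # deterministic naming by smallest member strain
  groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  names(groups) <- paste0("species_", seq_along(groups))
  lineage_species <- setNames(rep(NA_character_, k), ln)
  for (sp in names(groups)) {
    for (l in ln) if (all(lineages[[l]] %in% groups[[sp]]))
      lineage_species[l] <- sp
  }
  assignment <- data.frame(
    strain = unlist(lineages, use.names = FALSE),
    lineage = rep(names(lineages), lengths(lineages)),
    stringsAsFactors = FALSE)
  assignment$species <- lineage_species[assignment$lineage]
  assignment <- assignment[order(assignment$strain), ]
  rownames(assignment) <- NULL
  evidence <- if (length(sep_evidence) > 0) do.call(rbind, sep_evidence) else
    data.frame(lineage_a = character(0), lineage_b = character(0),
               evidence = character(0), n_cbc = numeric(0),
               n_hcbc = numeric(0), stringsAsFactors = FALSE)
  # keep only splits between lineages that ended up in different species
  evidence <- evidence[lineage_species[evidence$lineage_a] !=
                         lineage_species[evidence$lineage_b], , drop = FALSE]
  rownames(evidence) <- NULL
  structure(list(groups = groups, assignment = assignment,
                 evidence = evidence, config = config),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("<species_partition> %d species\n", length(x$groups)))
  for (sp in names(x$groups))
    cat(sprintf("  %s: %s\n", sp, paste(x$groups[[sp]], collapse = ", ")))
  invisible(x)
}
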