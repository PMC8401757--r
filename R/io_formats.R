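# Readers and writers for the external formats of the pipeline: FASTA,
# Vienna dot-bracket triplets, strain metadata TSV, and network exports.
# The internal alphabet is RNA (T is converted to U on ingest) because the
# base-pair number code is defined on RNA pairs.

HABITAT_LEVELS <- c("marine", "terrestrial", "saline-soil", "unknown")

#' Read a multi-record FASTA file
#'
#' Sequences are normalized to upper-case RNA (T becomes U); IUPAC ambiguity
#' codes and '-' gaps are permitted. Duplicate identifiers, an empty file, or
#' characters outside the IUPAC alphabet raise an error.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `sequence`, `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       whole.header = TRUE),
    error = function(e) stop("could not parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(recs) == 0) stop("empty FASTA file: ", path)
  headers <- names(recs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- normalize_rna(vapply(recs, as.character, character(1)))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for record '", ids[which(nchar(seqs) == 0)[1]], "'")
  }
  for (k in seq_along(seqs)) validate_alphabet(seqs[k], ids[k])
  data.frame(id = ids, sequence = unname(seqs), description = desc,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences, or a data.frame with
#'   columns `id`, `sequence` and optionally `description`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  desc <- NULL
  if (is.data.frame(seqs) && "description" %in% names(seqs))
    desc <- seqs$description
  v <- as_seq_vector(seqs)
  nm <- names(v)
  if (!is.null(desc)) {
    nm <- ifelse(nzchar(desc), paste(nm, desc), nm)
  }
  seqinr::write.fasta(as.list(unname(v)), names = nm, file.out = path,
                      nbchar = 80)
  invisible(path)
}

# Shared dot-bracket sanity check: only ().- characters, balanced, nested.
# Extra bracket tiers ([], {}, <>) denote pseudoknots and are rejected:
# the ITS-2 and V4 models used here are nested.
validate_dotbracket <- function(struct, id = "structure") {
  chars <- strsplit(struct, "", fixed = TRUE)[[1]]
  if (any(chars %in% c("[", "]", "{", "}", "<", ">")))
    stop(sprintf("record '%s': pseudoknotted dot-bracket (extra bracket tiers) is not supported", id),
         call. = FALSE)
  bad <- which(!chars %in% c("(", ")", ".", "-"))
  if (length(bad) > 0)
    stop(sprintf("record '%s': invalid structure character '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  stack <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (length(stack) == 0)
        stop(sprintf("record '%s': unbalanced structure, unmatched ')' at position %d",
                     id, k), call. = FALSE)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0)
    stop(sprintf("record '%s': unbalanced structure, unmatched '(' at position %d",
                 id, stack[1]), call. = FALSE)
  invisible(TRUE)
}

#' Read a Vienna dot-bracket file
#'
#' Expects triplets per record: a `>` header line, the sequence line, and the
#' dot-bracket structure line. Structures must match the sequence length and
#' be balanced and nested (no pseudoknot bracket tiers).
#'
#' @param path path to a Vienna file.
#' @return data.frame with columns `id`, `sequence`, `structure`,
#'   `description`.
#' @export
read_vienna <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty Vienna file: ", path)
  if (length(lines) %% 3 != 0 || !all(startsWith(lines[seq(1, length(lines), 3)], ">")))
    stop("malformed Vienna file (expected header/sequence/structure triplets): ", path)
  idx <- seq(1, length(lines), by = 3)
  headers <- sub("^>", "", lines[idx])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- normalize_rna(trimws(lines[idx + 1]))
  structs <- trimws(lines[idx + 2])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  for (k in seq_along(ids)) {
    validate_alphabet(seqs[k], ids[k])
    if (nchar(structs[k]) != nchar(seqs[k]))
      stop(sprintf("record '%s': structure length (%d) differs from sequence length (%d)",
                   ids[k], nchar(structs[k]), nchar(seqs[k])), call. = FALSE)
    validate_dotbracket(structs[k], ids[k])
  }
  data.frame(id = ids, sequence = seqs, structure = structs,
             description = desc, stringsAsFactors = FALSE)
}

#' Write Vienna dot-bracket records
#'
#' @param records data.frame with columns `id`, `sequence`, `structure` and
#'   optionally `description`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(records, path) {
  stopifnot(all(c("id", "sequence", "structure") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  out <- as.vector(rbind(paste0(">", hdr), records$sequence, records$structure))
  writeLines(out, path)
  invisible(path)
}

#' Read a strain metadata table
#'
#' Tab-delimited with a header row. The `strain` column is required; the
#' columns `species_label`, `origin`, `habitat`, `geography`, `accession` are
#' filled with empty strings when absent. Habitat values outside the closed
#' set marine / terrestrial / saline-soil are mapped to "unknown".
#'
#' @param path path to a TSV file.
#' @return data.frame, one row per strain/sample; `habitat` is a factor over
#'   the closed habitat set.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  if (!"strain" %in% names(df))
    stop("metadata file is missing the required 'strain' column: ", path)
  for (col in c("species_label", "origin", "habitat", "geography", "accession")) {
    if (!col %in% names(df)) df[[col]] <- rep("", nrow(df))
  }
  if (nrow(df) > 0 && any(!nzchar(trimws(df$strain))))
    stop("metadata contains rows with an empty 'strain' field")
  hab <- trimws(tolower(df$habitat))
  hab[!hab %in% setdiff(HABITAT_LEVELS, "unknown")] <- "unknown"
  df$habitat <- factor(hab, levels = HABITAT_LEVELS)
  df
}

#' Write a strain metadata table
#'
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
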