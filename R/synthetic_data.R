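# Synthetic datasets with planted ground truth: ITS-2 structure sets whose
# species carry known CBC/hemi-CBC differences inside the conserved core,
# V4 sample sets whose haplotypes form known mutational chains with habitat
# and geography labels, and V4 alignments with planted clade-diagnostic
# characters. The generators plant exact counts rather than sampling them,
# so every downstream recovery is exact, and a single integer seed governs
# all draws.

# evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# codes reachable from `code` by a compensatory (both strands) or
# hemi (one strand) change, staying within the six pairing types
cbc_targets <- function(code) {
  which(PAIR_TYPES[, 1] != PAIR_TYPES[code, 1] &
          PAIR_TYPES[, 2] != PAIR_TYPES[code, 2])
}
hcbc_targets <- function(code) {
  which(xor(PAIR_TYPES[, 1] != PAIR_TYPES[code, 1],
            PAIR_TYPES[, 2] != PAIR_TYPES[code, 2]))
}

#' Generate an ITS-2 structure set with planted species differences
#'
#' Builds a three-helix ITS-2-like molecule whose stems hold `core_width`
#' conserved base pairs. An ancestor barcode is drawn from codes 1-6; each
#' species then receives its own private compensatory changes (both strands
#' substituted, pairing kept) and hemi-compensatory changes (one strand,
#' pairing kept) at fresh core columns, so between species i and j the
#' planted CBC/HCBC counts are exactly the sums of the two species' counts.
#' Free sequence variation occurs only in the terminal loops of helices I
#' and II, at `loop_noise_rate` per strain and position, and never touches
#' paired columns — planted core counts are exact, not statistical. Lineage
#' support values emulating strongly supported clades are drawn uniformly
#' from 90-100.
#'
#' @param n_species number of species (>= 1).
#' @param strains_per_species strains per species (scalar or vector).
#' @param core_width total number of conserved base pairs across the three
#'   helices (>= 6; must be at least the total number of planted changes).
#' @param cbc_per_split compensatory changes planted on each species' own
#'   branch (scalar or per-species vector).
#' @param hcbc_per_split hemi-compensatory changes per species branch
#'   (scalar or per-species vector).
#' @param loop_noise_rate per-position substitution probability in the
#'   helix I/II terminal loops (default 0.1).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return list with `structures` (named list of annotated
#'   `structured_sequence`), `sequences` (data.frame `id`, `sequence`,
#'   `description`), `structure` (shared dot-bracket string), `metadata`
#'   (strain table) and `truth` (planted partition, per-pair CBC/HCBC
#'   counts, variable-position count, lineage supports, changed columns,
#'   seed and parameters).
#' @export
generate_its2_dataset <- function(n_species = 3, strains_per_species = 2,
                                  core_width = 40, cbc_per_split = 1,
                                  hcbc_per_split = 2, loop_noise_rate = 0.1,
                                  seed = 1) {
  stopifnot(n_species >= 1, core_width >= 6,
            loop_noise_rate >= 0, loop_noise_rate <= 1)
  n_strains <- rep_len(strains_per_species, n_species)
  cbc <- rep_len(cbc_per_split, n_species)
  hcbc <- rep_len(hcbc_per_split, n_species)
  if (any(cbc < 0) || any(hcbc < 0)) stop("planted counts must be >= 0")
  total_changes <- sum(cbc + hcbc)
  if (total_changes > core_width)
    stop(sprintf("infeasible parameters: %d planted changes exceed core_width = %d",
                 total_changes, core_width))
  if (core_width < max(cbc + hcbc))
    stop("core_width must be at least cbc_per_split + hcbc_per_split")

  # layout: spacer2 | helix I (k1 bp, loop 6) | spacer3 |
  #         helix II (k2 bp, loop 6) | spacer3 | helix III (k3 bp, loop 4) | spacer2
  k <- c(core_width %/% 3, core_width %/% 3,
         core_width - 2 * (core_width %/% 3))
  loops <- c(6, 6, 4)
  struct_parts <- character(0)
  pair5 <- integer(0); pair3 <- integer(0)
  pos <- 0
  spacers <- c(2, 3, 3, 2)
  for (hh in 1:3) {
    struct_parts <- c(struct_parts, strrep(".", spacers[hh]))
    pos <- pos + spacers[hh]
    open <- (pos + 1):(pos + k[hh])
    pos <- pos + k[hh] + loops[hh]
    close <- (pos + k[hh]):(pos + 1)
    struct_parts <- c(struct_parts, strrep("(", k[hh]), strrep(".", loops[hh]),
                      strrep(")", k[hh]))
    pos <- pos + k[hh]
    pair5 <- c(pair5, open); pair3 <- c(pair3, close)
  }
  struct_parts <- c(struct_parts, strrep(".", spacers[4]))
  pos <- pos + spacers[4]
  dotbracket <- paste(struct_parts, collapse = "")
  total_len <- pos

  with_seed(seed, {
    anc_codes <- sample(1:6, core_width, replace = TRUE)
    chars <- sample(UNAMBIGUOUS, total_len, replace = TRUE)
    chars[pair5] <- PAIR_TYPES[anc_codes, 1]
    chars[pair3] <- PAIR_TYPES[anc_codes, 2]

    # assign disjoint planted columns per species
    pool <- sample(core_width)
    changed <- vector("list", n_species)
    species_codes <- matrix(rep(anc_codes, n_species), ncol = n_species)
    taken <- 0
    for (i in seq_len(n_species)) {
      cols_i <- if (cbc[i] + hcbc[i] > 0)
        pool[(taken + 1):(taken + cbc[i] + hcbc[i])] else integer(0)
      taken <- taken + cbc[i] + hcbc[i]
      kinds <- c(rep("CBC", cbc[i]), rep("HCBC", hcbc[i]))
      for (q in seq_along(cols_i)) {
        cur <- anc_codes[cols_i[q]]
        cand <- if (kinds[q] == "CBC") cbc_targets(cur) else hcbc_targets(cur)
        species_codes[cols_i[q], i] <-
          if (length(cand) == 1) cand else sample(cand, 1)
      }
      changed[[i]] <- data.frame(core_column = cols_i, kind = kinds,
                                 stringsAsFactors = FALSE)
    }

    loop_pos <- integer(0)
    # recover loop positions of helices I and II from the layout
    lp1 <- spacers[1] + k[1]
    loop_pos <- c((lp1 + 1):(lp1 + loops[1]))
    lp2 <- spacers[1] + 2 * k[1] + loops[1] + spacers[2] + k[2]
    loop_pos <- c(loop_pos, (lp2 + 1):(lp2 + loops[2]))

    structures <- list()
    seq_rows <- list()
    meta_rows <- list()
    for (i in seq_len(n_species)) {
      sp_chars <- chars
      sp_chars[pair5] <- PAIR_TYPES[species_codes[, i], 1]
      sp_chars[pair3] <- PAIR_TYPES[species_codes[, i], 2]
      for (s in seq_len(n_strains[i])) {
        st_chars <- sp_chars
        mut <- loop_pos[stats::runif(length(loop_pos)) < loop_noise_rate]
        for (p in mut)
          st_chars[p] <- sample(setdiff(UNAMBIGUOUS, st_chars[p]), 1)
        id <- sprintf("SP%d_S%d", i, s)
        ss <- pairing_from_dotbracket(paste(st_chars, collapse = ""),
                                      dotbracket, id = id)
        structures[[id]] <- annotate_helices(ss, warn = FALSE)
        seq_rows[[id]] <- data.frame(id = id,
                                     sequence = ss$sequence,
                                     description = sprintf("species_%d", i),
                                     stringsAsFactors = FALSE)
        meta_rows[[id]] <- data.frame(strain = id,
                                      species_label = sprintf("species_%d", i),
                                      origin = "synthetic", habitat = "unknown",
                                      geography = "synthetic", accession = "",
                                      stringsAsFactors = FALSE)
      }
    }
    supports <- stats::runif(n_species, 90, 100)
  })

  partition <- lapply(seq_len(n_species), function(i)
    sprintf("SP%d_S%d", i, seq_len(n_strains[i])))
  names(partition) <- sprintf("species_%d", seq_len(n_species))
  pairs <- if (n_species > 1) t(combn(n_species, 2)) else
    matrix(integer(0), ncol = 2)
  pair_counts <- data.frame(
    species_a = sprintf("species_%d", pairs[, 1]),
    species_b = sprintf("species_%d", pairs[, 2]),
    n_cbc = cbc[pairs[, 1]] + cbc[pairs[, 2]],
    n_hcbc = hcbc[pairs[, 1]] + hcbc[pairs[, 2]],
    stringsAsFactors = FALSE)
  truth <- list(partition = partition,
                supports = setNames(supports, names(partition)),
                pair_counts = pair_counts,
                n_variable = total_changes,
                core_width = core_width,
                changed_columns = changed,
                seed = seed,
                params = list(n_species = n_species, strains = n_strains,
                              cbc = cbc, hcbc = hcbc,
                              loop_noise_rate = loop_noise_rate))
  list(structures = structures,
       sequences = do.call(rbind, unname(seq_rows)),
       structure = dotbracket,
       metadata = do.call(rbind, unname(meta_rows)),
       truth = truth)
}

#' Generate a V4 sample set with a planted haplotype graph
#'
#' Each species descends from a common random reference through its own
#' block of private substitutions wide enough that between-species distances
#' exceed the statistical-parsimony limit; within a species, haplotypes form
#' a chain in which neighbours differ by exactly `steps_between`
#' substitutions at fresh positions. Every haplotype is observed in
#' `samples_per_haplotype` samples whose habitat is drawn from `habitat_mix`
#' and whose geography is drawn from a small fixed pool.
#'
#' @param n_species number of species.
#' @param haplotypes_per_species haplotypes per species (scalar or vector).
#' @param steps_between substitutions between chain neighbours (>= 1).
#' @param samples_per_haplotype samples observing each haplotype (>= 1).
#' @param habitat_mix named probability vector over habitats (default
#'   `c(marine = 0.6, terrestrial = 0.3, "saline-soil" = 0.1)`).
#' @param seq_length V4 sequence length in nt (default 360).
#' @param seed integer seed.
#' @return list with `sequences` (data.frame, one row per sample),
#'   `metadata` (strain table) and `truth` (haplotype table with species,
#'   planted chain edges, sample-to-haplotype map, connection limit,
#'   expected component count, seed and parameters).
#' @export
generate_v4_dataset <- function(n_species = 3, haplotypes_per_species = 2,
                                steps_between = 1, samples_per_haplotype = 2,
                                habitat_mix = c(marine = 0.6, terrestrial = 0.3,
                                                "saline-soil" = 0.1),
                                seq_length = 360, seed = 1) {
  stopifnot(n_species >= 1, steps_between >= 1, samples_per_haplotype >= 1,
            !is.null(names(habitat_mix)), all(habitat_mix >= 0),
            sum(habitat_mix) > 0)
  n_haps <- rep_len(haplotypes_per_species, n_species)
  stopifnot(all(n_haps >= 1))
  limit <- parsimony_limit(seq_length)
  block <- limit + 1  # private substitutions per species branch
  need <- n_species * block + sum((n_haps - 1) * steps_between)
  if (need > seq_length)
    stop(sprintf("infeasible parameters: %d planted substitutions exceed seq_length = %d",
                 need, seq_length))
  geos <- c("North Sea", "Baltic Sea", "Atlantic", "Pacific", "Black Sea",
            "Antarctica")
  with_seed(seed, {
    ref <- sample(UNAMBIGUOUS, seq_length, replace = TRUE)
    pool <- sample(seq_length)  # fresh positions for every planted change
    taken <- 0
    take <- function(nn) {
      out <- pool[(taken + 1):(taken + nn)]
      taken <<- taken + nn
      out
    }
    hap_rows <- list(); seq_rows <- list(); meta_rows <- list()
    edges <- list(); hap_of_sample <- character(0)
    for (i in seq_len(n_species)) {
      sp <- ref
      for (p in take(block)) sp[p] <- sample(setdiff(UNAMBIGUOUS, sp[p]), 1)
      cur <- sp
      for (hk in seq_len(n_haps[i])) {
        if (hk > 1) {
          for (p in take(steps_between))
            cur[p] <- sample(setdiff(UNAMBIGUOUS, cur[p]), 1)
          edges[[length(edges) + 1]] <-
            data.frame(from = sprintf("sp%d_h%d", i, hk - 1),
                       to = sprintf("sp%d_h%d", i, hk),
                       steps = steps_between, stringsAsFactors = FALSE)
        }
        hap_key <- sprintf("sp%d_h%d", i, hk)
        hap_rows[[hap_key]] <- data.frame(
          hap = hap_key, sequence = paste(cur, collapse = ""),
          species = sprintf("species_%d", i), stringsAsFactors = FALSE)
        for (s in seq_len(samples_per_haplotype)) {
          sid <- sprintf("sp%d_h%d_s%d", i, hk, s)
          seq_rows[[sid]] <- data.frame(id = sid,
                                        sequence = paste(cur, collapse = ""),
                                        description = sprintf("species_%d", i),
                                        stringsAsFactors = FALSE)
          meta_rows[[sid]] <- data.frame(
            strain = sid, species_label = sprintf("species_%d", i),
            origin = "synthetic",
            habitat = sample(names(habitat_mix), 1,
                             prob = habitat_mix / sum(habitat_mix)),
            geography = sample(geos, 1), accession = "",
            stringsAsFactors = FALSE)
          hap_of_sample[sid] <- hap_key
        }
      }
    }
  })
  truth <- list(
    haplotypes = do.call(rbind, unname(hap_rows)),
    chain_edges = if (length(edges) > 0) do.call(rbind, edges) else
      data.frame(from = character(0), to = character(0), steps = integer(0)),
    hap_of_sample = hap_of_sample,
    limit = limit,
    expected_components = if (steps_between <= limit) n_species else NA_integer_,
    seed = seed,
    params = list(n_species = n_species, haplotypes = n_haps,
                  steps_between = steps_between,
                  samples_per_haplotype = samples_per_haplotype,
                  seq_length = seq_length))
  list(sequences = do.call(rbind, unname(seq_rows)),
       metadata = do.call(rbind, unname(meta_rows)),
       truth = truth)
}

#' Generate a V4 alignment with planted clade-diagnostic characters
#'
#' Builds a reference sequence realizing a V4 helix template, a clade whose
#' members carry exactly the requested diagnostic changes, and outside
#' strains identical to the reference: `n_cbc` compensatory and `n_hcbc`
#' hemi-compensatory changes at template-paired columns, and `n_nhs`
#' single-column synapomorphies at unpaired (spacer) positions. The NHS
#' positions can be restricted to a named spacer (e.g.
#' `"spacer(E23_11-E23_9)"`).
#'
#' @param n_clade clade size (>= 1).
#' @param n_out number of non-clade strains (>= 1; the reference row counts
#'   in addition).
#' @param n_cbc,n_hcbc,n_nhs planted diagnostic counts.
#' @param nhs_spacer optional spacer label restricting where NHSs are
#'   planted.
#' @param template a `v4_template` (default [v4_template_synthetic()]).
#' @param seed integer seed.
#' @return list with `alignment` (named character vector including the
#'   template reference row), `clade` (strain ids) and `truth` (planted
#'   slice columns and kinds, seed, parameters).
#' @export
generate_v4_diagnostics_dataset <- function(n_clade = 4, n_out = 4,
                                            n_cbc = 2, n_hcbc = 4, n_nhs = 2,
                                            nhs_spacer = NULL,
                                            template = v4_template_synthetic(),
                                            seed = 1) {
  stopifnot(n_clade >= 1, n_out >= 1, n_cbc >= 0, n_hcbc >= 0, n_nhs >= 0)
  ref <- synthetic_v4_reference(template, seed = seed)
  # labels on ungapped reference positions via a self-alignment slice
  slice <- annotate_v4(extract_v4(setNames(ref, template$reference_id),
                                  template))
  region_start <- template$region[1]
  with_seed(seed + 1, {
    chars <- strsplit(ref, "", fixed = TRUE)[[1]]
    clade_chars <- chars
    n_pairs_needed <- n_cbc + n_hcbc
    if (n_pairs_needed > nrow(template$pairing))
      stop("not enough template pairs for the requested CBC/HCBC counts")
    pick_pairs <- sample(nrow(template$pairing), n_pairs_needed)
    kinds <- c(rep("CBC", n_cbc), rep("HCBC", n_hcbc))
    planted <- list()
    for (q in seq_along(pick_pairs)) {
      i <- template$pairing[pick_pairs[q], 1]
      j <- template$pairing[pick_pairs[q], 2]
      cur <- pair_code(chars[i], chars[j], TRUE)
      cand <- if (kinds[q] == "CBC") cbc_targets(cur) else hcbc_targets(cur)
      newcode <- if (length(cand) == 1) cand else sample(cand, 1)
      clade_chars[i] <- PAIR_TYPES[newcode, 1]
      clade_chars[j] <- PAIR_TYPES[newcode, 2]
      planted[[length(planted) + 1]] <- data.frame(
        kind = kinds[q],
        column5 = i - region_start + 1, column3 = j - region_start + 1,
        stringsAsFactors = FALSE)
    }
    unpaired <- setdiff(region_start:template$region[2],
                        c(template$pairing))
    if (!is.null(nhs_spacer)) {
      lab <- slice$labels[unpaired - region_start + 1]
      unpaired <- unpaired[lab == nhs_spacer]
    }
    if (n_nhs > length(unpaired))
      stop("not enough unpaired positions for the requested NHS count")
    nhs_pos <- if (n_nhs > 0) sample(unpaired, n_nhs) else integer(0)
    for (p in nhs_pos) {
      clade_chars[p] <- sample(setdiff(UNAMBIGUOUS, clade_chars[p]), 1)
      planted[[length(planted) + 1]] <- data.frame(
        kind = "NHS", column5 = p - region_start + 1, column3 = NA_integer_,
        stringsAsFactors = FALSE)
    }
  })
  clade_ids <- sprintf("clade_%02d", seq_len(n_clade))
  out_ids <- sprintf("out_%02d", seq_len(n_out))
  alignment <- c(setNames(ref, template$reference_id),
                 setNames(rep(paste(clade_chars, collapse = ""), n_clade),
                          clade_ids),
                 setNames(rep(ref, n_out), out_ids))
  list(alignment = alignment, clade = clade_ids,
       truth = list(planted = do.call(rbind, planted), seed = seed,
                    params = list(n_clade = n_clade, n_out = n_out,
                                  n_cbc = n_cbc, n_hcbc = n_hcbc,
                                  n_nhs = n_nhs, nhs_spacer = nhs_spacer)))
}
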