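tpl <- v4_template_synthetic()

test_that("template validation catches malformed span tables", {
  expect_s3_class(tpl, "v4_template")
  expect_equal(length(unique(tpl$spans$helix)), 14)
  bad <- tpl$spans
  bad$end[1] <- bad$start[2] + 1  # overlap
  expect_error(v4_template(bad), "overlap")
  bad2 <- tpl$spans
  bad2$end[2] <- bad2$end[2] + 1  # unequal strand lengths
  expect_error(v4_template(bad2), "unequal")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_v4_template(tpl, f)
  tpl2 <- read_v4_template(f, reference_id = "SYNTH_REF")
  expect_equal(tpl2$spans, tpl$spans)
  expect_equal(tpl2$pairing, tpl$pairing)
})

test_that("V4 extraction slices all strains identically through reference gaps", {
  ref <- synthetic_v4_reference(tpl, seed = 2)
  # ungapped reference: fixed-width slice
  aln <- c(setNames(ref, tpl$reference_id), s1 = ref)
  sl <- extract_v4(aln, tpl)
  expect_equal(unique(nchar(sl$seqs)), tpl$region[2] - tpl$region[1] + 1)

  # insert a gap column before the region and one inside it
  ins <- function(s, pos, ch) paste0(substr(s, 1, pos - 1), ch,
                                     substr(s, pos, nchar(s)))
  gap_outside <- 2
  gap_inside <- tpl$region[1] + 10
  aln2 <- vapply(aln, function(s) ins(ins(s, gap_inside, "A"), gap_outside, "A"),
                 character(1))
  aln2[tpl$reference_id] <- ins(ins(aln[[1]], gap_inside, "-"), gap_outside, "-")
  sl2 <- extract_v4(aln2, tpl)
  # a strain keeps its inserted state at the reference-gap column
  expect_equal(sum(is.na(sl2$ref_pos)), 1)
  expect_equal(nchar(sl2$seqs[["s1"]]), nchar(sl2$seqs[[tpl$reference_id]]))
  # ungapped reference content of the slice is unchanged
  expect_equal(gsub("-", "", sl2$seqs[[tpl$reference_id]]),
               substr(ref, tpl$region[1], tpl$region[2]))
  expect_error(extract_v4(c(sX = ref), tpl), "not found")
})

test_that("every slice column gets a helix or spacer label", {
  ref <- synthetic_v4_reference(tpl, seed = 2)
  sl <- annotate_v4(extract_v4(setNames(ref, tpl$reference_id), tpl))
  expect_true(all(nzchar(sl$labels)))
  # span lookup: a column inside E23_9's opening strand
  e9 <- tpl$spans[tpl$spans$helix == "E23_9", ][1, ]
  expect_equal(sl$labels[e9$start - tpl$region[1] + 1], "E23_9")
  # the spacer between the E23_11 hairpin and the closing strand of E23_9
  expect_true("spacer(E23_11-E23_9)" %in% sl$labels)
  # pairing mapped into slice coordinates stays an involution
  expect_true(all(sl$pairing[, 1] < sl$pairing[, 2]))
})

test_that("planted NHSs are found exactly and leak-free", {
  d <- generate_v4_diagnostics_dataset(n_cbc = 0, n_hcbc = 0, n_nhs = 3,
                                       seed = 12)
  sl <- annotate_v4(extract_v4(d$alignment, tpl))
  nhs <- find_nhs(sl, d$clade)
  expect_equal(sort(nhs$column),
               sort(d$truth$planted$column5[d$truth$planted$kind == "NHS"]))
  expect_false(any(nhs$autapomorphy))

  # candidate state present outside the clade -> not an NHS
  leaky <- d$alignment
  col <- nhs$column[1] + tpl$region[1] - 1
  out1 <- leaky[["out_01"]]
  substr(out1, col, col) <- substr(leaky[[d$clade[1]]], col, col)
  leaky[["out_01"]] <- out1
  nhs2 <- find_nhs(annotate_v4(extract_v4(leaky, tpl)), d$clade)
  expect_false(nhs$column[1] %in% nhs2$column)
  # adding outside strains can only shrink the NHS list
  expect_true(all(nhs2$column %in% nhs$column))

  expect_error(find_nhs(sl, names(sl$seqs)), "full strain set")
  # singleton clade: private changes are flagged autapomorphies
  nhs3 <- find_nhs(sl, d$clade[1])
  expect_true(all(nhs3$autapomorphy))
})

test_that("tree-checked NHS sets are a subset of unchecked ones", {
  d <- generate_v4_diagnostics_dataset(n_cbc = 0, n_hcbc = 0, n_nhs = 2,
                                       seed = 31)
  sl <- annotate_v4(extract_v4(d$alignment, tpl))
  tr <- nj_tree(p_distance_matrix(d$alignment))
  plain <- find_nhs(sl, d$clade)
  checked <- find_nhs(sl, d$clade, tree = tr)
  expect_true(all(checked$column %in% plain$column))
  # the planted single-origin states survive the parsimony check
  expect_equal(sort(checked$column), sort(plain$column))
})

test_that("paired-column synapomorphies are classified CBC or hemi-CBC", {
  d <- generate_v4_diagnostics_dataset(n_cbc = 2, n_hcbc = 3, n_nhs = 0,
                                       seed = 18)
  sl <- annotate_v4(extract_v4(d$alignment, tpl))
  ps <- find_pair_synapomorphies(sl, d$clade)
  truth <- d$truth$planted
  expect_equal(sum(ps$kind == "CBC"), 2)
  expect_equal(sum(ps$kind == "HCBC"), 3)
  expect_setequal(ps$column5, truth$column5)
  expect_false(any(ps$outside_polymorphic))
  # every reported clade state really is carried by all clade members
  m <- do.call(rbind, strsplit(unname(sl$seqs[d$clade]), ""))
  for (r in seq_len(nrow(ps))) {
    expect_true(all(paste0(m[, ps$column5[r]], "-", m[, ps$column3[r]]) ==
                      ps$clade_state[r]))
  }
  # no planted differences -> empty result
  d0 <- generate_v4_diagnostics_dataset(n_cbc = 0, n_hcbc = 0, n_nhs = 0,
                                        seed = 19)
  sl0 <- annotate_v4(extract_v4(d0$alignment, tpl))
  expect_equal(nrow(find_pair_synapomorphies(sl0, d0$clade)), 0)
})

test_that("NHS placement can be restricted to a named spacer", {
  d <- generate_v4_diagnostics_dataset(n_cbc = 0, n_hcbc = 0, n_nhs = 1,
                                       nhs_spacer = "spacer(E23_11-E23_9)",
                                       seed = 4)
  sl <- annotate_v4(extract_v4(d$alignment, tpl))
  nhs <- find_nhs(sl, d$clade)
  expect_equal(nrow(nhs), 1)
  expect_equal(nhs$label, "spacer(E23_11-E23_9)")
})
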