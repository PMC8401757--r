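test_that("number-code encoding follows the eight-state table", {
  expect_equal(encode_pair("A", "U")$code, 1L)
  expect_equal(encode_pair("U", "A")$code, 2L)
  expect_equal(encode_pair("G", "C")$code, 3L)
  expect_equal(encode_pair("C", "G")$code, 4L)
  expect_equal(encode_pair("G", "U")$code, 5L)
  expect_equal(encode_pair("U", "G")$code, 6L)
  expect_equal(encode_pair("C", "C")$code, 7L)
  expect_equal(encode_pair("A", "G")$code, 7L)
  expect_equal(encode_pair("A", "-")$code, 8L)
  expect_equal(encode_pair("-", "-")$code, 8L)
  expect_equal(encode_pair("A", "U", paired = FALSE)$code, 8L)  # unpaired
  expect_equal(encode_pair("a", "t")$code, 1L)  # normalized on entry
  expect_error(encode_pair("A", "Z"), "IUPAC")
})

test_that("change classification matches its definition case by case", {
  cc <- function(a, b) as.character(classify_change(
    encode_pair(a[1], a[2]), encode_pair(b[1], b[2])))
  expect_equal(cc(c("A", "U"), c("G", "C")), "CBC")
  expect_equal(cc(c("A", "U"), c("G", "U")), "HCBC")
  expect_equal(cc(c("G", "C"), c("G", "U")), "HCBC")
  expect_equal(cc(c("A", "U"), c("A", "U")), "IDENTICAL")
  expect_equal(cc(c("A", "-"), c("G", "C")), "INDEL_CHANGE")
  expect_equal(cc(c("-", "-"), c("-", "-")), "IDENTICAL")  # gap vs gap
  expect_equal(cc(c("C", "C"), c("G", "C")), "MISMATCH_CHANGE")
  expect_equal(cc(c("A", "N"), c("G", "C")), "AMBIGUOUS")
})

test_that("classification is symmetric", {
  states <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"),
                 c("G", "U"), c("U", "G"), c("C", "C"), c("A", "-"),
                 c("-", "-"), c("A", "N"))
  for (a in states) for (b in states) {
    expect_identical(
      classify_change(encode_pair(a[1], a[2]), encode_pair(b[1], b[2])),
      classify_change(encode_pair(b[1], b[2]), encode_pair(a[1], a[2])))
  }
})

test_that("barcode comparison counts match a nucleotide-level tally on random pairs", {
  set.seed(42)
  states <- c("A", "C", "G", "U", "-")
  for (rep in 1:100) {
    n <- sample(5:25, 1)
    b5a <- sample(states, n, TRUE); b3a <- sample(states, n, TRUE)
    b5b <- sample(states, n, TRUE); b3b <- sample(states, n, TRUE)
    a <- barcode_from_pairs("a", b5a, b3a)
    b <- barcode_from_pairs("b", b5b, b3b)
    cmp <- compare_barcodes(a, b)
    # independent tally straight from the nucleotides
    canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
    is_pair <- function(x, y) paste0(x, y) %in% canon
    exp_cbc <- exp_hcbc <- 0
    for (k in seq_len(n)) {
      if (b5a[k] == b5b[k] && b3a[k] == b3b[k]) next
      if (!is_pair(b5a[k], b3a[k]) || !is_pair(b5b[k], b3b[k])) next
      d5 <- b5a[k] != b5b[k]; d3 <- b3a[k] != b3b[k]
      if (d5 && d3) exp_cbc <- exp_cbc + 1
      if (xor(d5, d3)) exp_hcbc <- exp_hcbc + 1
    }
    expect_equal(cmp$n_cbc, exp_cbc)
    expect_equal(cmp$n_hcbc, exp_hcbc)
    # symmetry of the whole comparison
    rev_cmp <- compare_barcodes(b, a)
    expect_equal(rev_cmp$n_cbc, cmp$n_cbc)
    expect_equal(rev_cmp$n_hcbc, cmp$n_hcbc)
    expect_equal(rev_cmp$n_other, cmp$n_other)
  }
})

test_that("comparison requires equal barcode lengths", {
  a <- barcode_from_pairs("a", c("A", "G"), c("U", "C"))
  b <- barcode_from_pairs("b", c("A"), c("U"))
  expect_error(compare_barcodes(a, b), "lengths differ")
  expect_equal(compare_barcodes(a, a)$n_cbc, 0)
  expect_equal(compare_barcodes(a, a)$n_hcbc, 0)
})

test_that("variable position count uses bases, excludes ambiguity, grows monotonically", {
  b1 <- barcode_from_pairs("a", c("A", "G", "C", "A"), c("U", "C", "C", "N"))
  b2 <- barcode_from_pairs("b", c("A", "G", "A", "G"), c("U", "C", "C", "N"))
  # column 3: two distinct mismatches, both code 7, still variable;
  # column 4 carries an ambiguity code -> excluded
  expect_equal(b1$code[3], 7L)
  expect_equal(b2$code[3], 7L)
  expect_equal(count_variable_positions(list(b1, b2)), 1L)
  expect_equal(count_variable_positions(list(b1, b1)), 0L)
  expect_error(count_variable_positions(list(b1)), "at least two")

  set.seed(7)
  states <- c("A", "C", "G", "U")
  bcs <- lapply(1:6, function(k)
    barcode_from_pairs(paste0("s", k), sample(states, 10, TRUE),
                       sample(states, 10, TRUE)))
  counts <- vapply(2:6, function(k) count_variable_positions(bcs[1:k]),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("barcodes render as digit strings", {
  b <- barcode_from_pairs("a", c("G", "A", "C"), c("C", "U", "C"))
  expect_equal(barcode_string(b), "317")
})

test_that("species delimitation applies the CBC and HCBC+support rules", {
  cfg <- analysis_config()
  bA <- barcode_from_pairs("A1", c("A", "G"), c("U", "C"))
  bB_cbc <- barcode_from_pairs("B1", c("G", "G"), c("C", "C"))   # 1 CBC vs A
  bB_hcbc <- barcode_from_pairs("B1", c("G", "G"), c("U", "C"))  # 1 HCBC vs A
  sup_low <- data.frame(lineage = c("L1", "L2"), bootstrap = c(60, 60))
  sup_high <- data.frame(lineage = c("L1", "L2"), bootstrap = c(95, 85))
  lin <- list(L1 = "A1", L2 = "B1")

  # one lineage, one strain
  p0 <- delimit_species(list(L1 = "A1"), data.frame(lineage = "L1", bootstrap = 0),
                        list(A1 = bA), cfg)
  expect_length(p0$groups, 1)

  # CBC separates regardless of support
  p1 <- delimit_species(lin, sup_low, list(A1 = bA, B1 = bB_cbc), cfg)
  expect_length(p1$groups, 2)
  expect_equal(p1$evidence$evidence, "CBC")

  # HCBC-only with low support merges
  p2 <- delimit_species(lin, sup_low, list(A1 = bA, B1 = bB_hcbc), cfg)
  expect_length(p2$groups, 1)

  # HCBC-only with support on both sides separates
  p3 <- delimit_species(lin, sup_high, list(A1 = bA, B1 = bB_hcbc), cfg)
  expect_length(p3$groups, 2)
  expect_equal(p3$evidence$evidence, "HCBC+support")

  # posterior can substitute for bootstrap when supplied
  sup_post <- data.frame(lineage = c("L1", "L2"), bootstrap = c(60, 60),
                         posterior = c(0.99, 0.97))
  p4 <- delimit_species(lin, sup_post, list(A1 = bA, B1 = bB_hcbc), cfg)
  expect_length(p4$groups, 2)

  # identical barcodes merge
  p5 <- delimit_species(lin, sup_high, list(A1 = bA, B1 = bA), cfg)
  expect_length(p5$groups, 1)

  expect_error(delimit_species(lin, sup_high, list(A1 = bA), cfg),
               "without barcode")
})

test_that("delimitation is invariant to strain and lineage ordering", {
  g <- generate_its2_dataset(n_species = 3, strains_per_species = 2,
                             cbc_per_split = 1, hcbc_per_split = 1, seed = 77)
  cols <- conserved_columns(g$structures)
  bcs <- lapply(g$structures, encode_barcode, cols = cols)
  p1 <- delimit_species(g$truth$partition, g$truth$supports, bcs)
  shuffled <- rev(lapply(g$truth$partition, rev))
  p2 <- delimit_species(shuffled, g$truth$supports, rev(bcs))
  expect_equal(p1$groups, p2$groups)
})
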