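test_that("haplotype collapsing conserves multiplicities and metadata", {
  seqs <- c(s1 = "ACGU", s2 = "ACGU", s3 = "ACGU", s4 = "ACGU", s5 = "ACGU")
  hs <- collapse_haplotypes(seqs)
  expect_equal(nrow(hs$haplotypes), 1)
  expect_equal(hs$haplotypes$multiplicity, 5)

  seqs2 <- c(s1 = "ACGU", s2 = "ACGU", s3 = "AGGU")
  hs2 <- collapse_haplotypes(seqs2)
  expect_equal(sort(hs2$haplotypes$multiplicity), c(1, 2))
  expect_equal(sum(hs2$haplotypes$multiplicity), 3)

  md <- data.frame(strain = c("s1", "s2", "s3"),
                   habitat = c("marine", "terrestrial", "marine"),
                   stringsAsFactors = FALSE)
  hs3 <- collapse_haplotypes(seqs2, md)
  h_big <- hs3$haplotypes$id[hs3$haplotypes$multiplicity == 2]
  habs <- hs3$members$habitat[hs3$members$haplotype == h_big]
  expect_setequal(habs, c("marine", "terrestrial"))  # both categories kept

  expect_error(collapse_haplotypes(c(a = "ACG", b = "ACGU")), "lengths")
})

test_that("mutational steps count substitutions plus one per gap run", {
  expect_equal(hamming_steps("ACGU", "ACGU"), 0)
  expect_equal(hamming_steps("ACGU", "ACGA"), 1)
  expect_equal(hamming_steps("AC--GU", "ACAAGU"), 1)   # one 2-nt indel
  expect_equal(hamming_steps("AC--GU", "ACAAGA"), 2)   # indel + substitution
  expect_equal(hamming_steps("A-C-G", "AUCUG"), 2)     # two separate runs
  expect_error(hamming_steps("ACG", "ACGU"), "lengths")
})

test_that("parsimony limit matches the independently evaluated estimator", {
  # frozen oracle: direct numeric evaluation of
  # P(j) = (dpois(1, lambda) / ppois(0, lambda, lower.tail = FALSE))^j,
  # lambda = -log(1 - j/L), scanning all j — computed apart from the
  # package's closed-form implementation
  oracle <- data.frame(
    L = rep(c(100, 200, 360, 500, 1000, 2000), 3),
    conf = rep(c(0.90, 0.95, 0.99), each = 6),
    limit = c(4, 6, 8, 10, 14, 20,
              3, 4, 6, 7, 10, 14,
              1, 1, 2, 3, 4, 6))
  for (r in seq_len(nrow(oracle))) {
    expect_equal(parsimony_limit(oracle$L[r], oracle$conf[r]),
                 oracle$limit[r],
                 info = sprintf("L=%d conf=%.2f", oracle$L[r], oracle$conf[r]))
  }
  # full certainty: only single steps
  expect_equal(parsimony_limit(1000, confidence = 1.0), 1L)
  # non-decreasing in sequence length at fixed confidence
  lims <- vapply(seq(50, 2000, by = 50), parsimony_limit, integer(1))
  expect_true(all(diff(lims) >= 0))
})

test_that("simple networks take their minimal shape", {
  # chain: d(A,B)=1, d(B,C)=1, d(A,C)=2 -> path A-B-C, no medians
  hs <- collapse_haplotypes(c(a = "AAAA", b = "AAAC", c = "AACC"))
  net <- build_network(hs, limit = 5)
  expect_equal(sum(net$nodes$type == "median"), 0)
  expect_equal(igraph::ecount(net$graph), 2)
  expect_equal(network_components(net), 1)

  # two haplotypes at distance 2: one median, two unit edges
  hs2 <- collapse_haplotypes(c(a = "AAAA", b = "AACC"))
  net2 <- build_network(hs2, limit = 5)
  expect_equal(sum(net2$nodes$type == "median"), 1)
  expect_equal(igraph::ecount(net2$graph), 2)

  # distance beyond the limit: separate components
  hs3 <- collapse_haplotypes(c(a = "AAAAAA", b = "CCCAAA"))
  net3 <- build_network(hs3, limit = 2)
  expect_equal(network_components(net3), 2)
  expect_equal(igraph::ecount(net3$graph), 0)
})

test_that("total steps equal the brute-force minimum on small random sets", {
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "U"), 12, TRUE),
                               collapse = ""))
    seqs <- unique(seqs)
    names(seqs) <- paste0("h", seq_along(seqs))
    if (length(seqs) < 2) next
    hs <- collapse_haplotypes(seqs)
    net <- build_network(hs, limit = 12)
    expect_equal(sum(net$connections$steps), brute_force_min_steps(seqs))
    # conservation and unit-edge invariants
    expect_equal(sum(net$nodes$multiplicity), length(seqs))
    el <- igraph::as_edgelist(net$graph)
    sq <- setNames(net$nodes$sequence, net$nodes$id)
    if (nrow(el) > 0)
      expect_true(all(apply(el, 1, function(e)
        hamming_steps(sq[[e[1]]], sq[[e[2]]])) == 1))
  }
})

test_that("network shape is invariant under input order", {
  seqs <- c(a = "AAAAA", b = "AAAAC", c = "AAACC", d = "GGAAA")
  net1 <- build_network(collapse_haplotypes(seqs), limit = 5)
  net2 <- build_network(collapse_haplotypes(rev(seqs)), limit = 5)
  key <- function(net) {
    sq <- setNames(net$nodes$sequence, net$nodes$id)
    el <- igraph::as_edgelist(net$graph)
    sort(apply(el, 1, function(e) paste(sort(c(sq[[e[1]]], sq[[e[2]]])),
                                        collapse = ">")))
  }
  expect_equal(key(net1), key(net2))
})

test_that("query assignment enforces coverage and identity thresholds", {
  ref_seq <- paste(rep(c("A", "C", "G", "U"), 50), collapse = "")  # 200 nt
  refs <- data.frame(id = "H1", sequence = ref_seq, species = "sp1",
                     stringsAsFactors = FALSE)
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    ch[k] <- ifelse(ch[k] == "A", "C", "A")
    paste(ch, collapse = "")
  }
  # identical -> assigned at identity 1
  r0 <- assign_query(ref_seq, refs)
  expect_true(r0$assigned)
  expect_equal(r0$identity, 1)
  expect_equal(r0$species, "sp1")
  # 5 mismatches: 97.5% -> accepted (> 97)
  r1 <- assign_query(mutate_at(ref_seq, 1:5), refs)
  expect_true(r1$assigned)
  expect_equal(r1$identity, 0.975)
  # 8 mismatches: 96% -> rejected
  r2 <- assign_query(mutate_at(ref_seq, 1:8), refs)
  expect_false(r2$assigned)
  expect_equal(r2$identity, 0.96)
  expect_true(is.na(r2$species))
  # exactly 97% is not strictly greater -> rejected
  r3 <- assign_query(mutate_at(ref_seq, 1:6), refs)
  expect_false(r3$assigned)
  # half-length query: rejected regardless of identity
  r4 <- assign_query(substr(ref_seq, 1, 100), refs)
  expect_false(r4$assigned)
  expect_equal(r4$coverage, 0.5)
  expect_equal(r4$identity, 1)
  # relaxed coverage admits the fragment again
  r5 <- assign_query(substr(ref_seq, 1, 100), refs,
                     analysis_config(coverage_required = 0.5))
  expect_true(r5$assigned)
})

test_that("network exports are written and re-readable", {
  v <- generate_v4_dataset(n_species = 2, haplotypes_per_species = 2, seed = 8)
  hs <- collapse_haplotypes(v$sequences, v$metadata)
  net <- build_network(hs, limit = v$truth$limit)
  f_e <- withr::local_tempfile(fileext = ".tsv")
  f_n <- withr::local_tempfile(fileext = ".tsv")
  f_g <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f_e, "edges")
  export_network(net, f_n, "nodes")
  export_network(net, f_g, "graphml")
  edges <- read.delim(f_e)
  expect_equal(nrow(edges), igraph::ecount(net$graph))
  nodes <- read.delim(f_n)
  expect_equal(nrow(nodes), nrow(net$nodes))
  g <- igraph::read_graph(f_g, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
})
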