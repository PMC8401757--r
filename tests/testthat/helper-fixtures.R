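# shared builders for small in-code fixtures

make_ss <- function(sequence, structure, id = "s1", annotate = FALSE) {
  pairing_from_dotbracket(sequence, structure, id = id, annotate = FALSE) |>
    (\(ss) if (annotate) annotate_helices(ss, warn = FALSE) else ss)()
}

# a minimal three-helix molecule: three 3-bp hairpins with 4-nt loops;
# stems are complementary so every pair is canonical
three_helix <- function(loop1 = "AAAA", loop2 = "AAAA", loop3 = "AAAA") {
  hp <- function(stem5, loop, stem3) {
    list(seq = paste0(stem5, loop, stem3),
         str = paste0(strrep("(", nchar(stem5)), strrep(".", nchar(loop)),
                      strrep(")", nchar(stem3))))
  }
  h1 <- hp("GCG", loop1, "CGC"); h2 <- hp("AUC", loop2, "GAU")
  h3 <- hp("GGC", loop3, "GCC")
  list(sequence = paste0("GA", h1$seq, "AAA", h2$seq, "AAA", h3$seq, "AG"),
       structure = paste0("..", h1$str, "...", h2$str, "...", h3$str, ".."))
}

# barcode directly from explicit base pairs (paired columns 1..n)
barcode_from_pairs <- function(strain, pairs5, pairs3) {
  n <- length(pairs5)
  structure(list(strain = strain,
                 code = its2cbc:::pair_code(pairs5, pairs3, rep(TRUE, n)),
                 base5 = pairs5, base3 = pairs3,
                 column = seq_len(n), partner = 2 * n + 1 - seq_len(n)),
            class = "its2_barcode")
}

# the six pairing-retaining pair types, as used by the number code
SIX_PAIRS <- list(c("A", "U"), c("U", "A"), c("G", "C"),
                  c("C", "G"), c("G", "U"), c("U", "G"))

# brute-force minimum spanning weight over observed haplotypes by exhaustive
# enumeration of spanning edge subsets (independent of the network builder)
brute_force_min_steps <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(0L)
  idx <- t(combn(n, 2))
  w <- apply(idx, 1, function(r) hamming_steps(seqs[r[1]], seqs[r[2]]))
  m <- nrow(idx)
  best <- Inf
  for (sub in combn(m, n - 1, simplify = FALSE)) {
    # connectivity check by label propagation
    comp <- seq_len(n)
    for (e in sub) {
      a <- comp[idx[e, 1]]; b <- comp[idx[e, 2]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1) best <- min(best, sum(w[sub]))
  }
  best
}
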