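test_that("ordered all-by-all enumeration yields n^2 constructs and n(n+1)/2 pairings", {
  reg <- default_registry()
  for (n in c(1, 2, 5, 24, 33)) {
    sub <- subset_registry(reg, sort(reg$binders$binder_id)[seq_len(n)])
    lib <- enumerate_library(sub)
    expect_equal(nrow(lib), n^2)
    expect_equal(count_unique_pairings(lib), n * (n + 1) / 2)
    # brute-force set of unordered target pairs must agree
    tgt <- sub$binders$target_receptor[match(lib$n_term_binder,
                                             sub$binders$binder_id)]
    tgt2 <- sub$binders$target_receptor[match(lib$c_term_binder,
                                              sub$binders$binder_id)]
    brute <- unique(vapply(seq_along(tgt), function(i)
      paste(sort(c(tgt[i], tgt2[i])), collapse = "|"), character(1)))
    expect_equal(count_unique_pairings(lib), length(brute))
  }
})

test_that("full and pilot libraries match their expected sizes", {
  expect_equal(nrow(enumerate_library(default_registry())), 1089)
  expect_equal(nrow(enumerate_library(pilot_registry())), 576)
  expect_gte(count_unique_pairings(enumerate_library(default_registry())), 500)
})

test_that("unordered mode collapses orientations and receptor pairs are derived", {
  reg <- toy_registry()
  lib <- enumerate_library(reg, orientations = "unordered")
  expect_equal(nrow(lib), 3 * 4 / 2)
  expect_true(all(lib$receptor_a <= lib$receptor_b))
  both <- enumerate_library(reg)
  fwd <- both[both$n_term_binder == "a_bd" & both$c_term_binder == "b_bd", ]
  rev <- both[both$n_term_binder == "b_bd" & both$c_term_binder == "a_bd", ]
  expect_equal(fwd[, c("receptor_a", "receptor_b")],
               rev[, c("receptor_a", "receptor_b")],
               ignore_attr = TRUE)
  expect_error(enumerate_library(subset_registry(reg, character(0))), "empty")
})

test_that("sequence assembly follows the N-linker-C grammar", {
  reg <- attach_sequences(toy_registry(), toy_fasta(toy_registry()))
  lib <- enumerate_library(reg, linker_spec("GGS", 2))
  row <- lib[lib$n_term_binder == "a_bd" & lib$c_term_binder == "b_bd", ]
  s <- assemble_sequence(row, reg)
  expect_equal(nchar(s), 60 + 6 + 70)
  # 5xGGS linker appears exactly once, between the domains
  lib5 <- enumerate_library(reg, linker_spec("GGS", 5))
  s5 <- assemble_sequence(lib5[lib5$n_term_binder == "a_bd" &
                                 lib5$c_term_binder == "b_bd", ], reg)
  expect_equal(lengths(gregexpr("GGSGGSGGSGGSGGS", s5, fixed = TRUE)), 1)
  expect_equal(substr(s5, 61, 75), strrep("GGS", 5))
  # direct fusion at zero repeats
  lib0 <- enumerate_library(reg, linker_spec("GGS", 0))
  s0 <- assemble_sequence(lib0[lib0$n_term_binder == "a_bd" &
                                 lib0$c_term_binder == "b_bd", ], reg)
  expect_equal(nchar(s0), 130)
  expect_error(assemble_sequence(row, toy_registry()), "sequence")
})

test_that("FASTA plus manifest round-trip the library", {
  reg <- attach_sequences(toy_registry(), toy_fasta(toy_registry()))
  lib <- enumerate_library(reg)
  fa <- tempfile(fileext = ".fasta"); mf <- tempfile(fileext = ".tsv")
  write_library(lib, reg, fa, mf)
  back <- read_manifest(mf)
  expect_equal(back, lib, ignore_attr = TRUE)
  seqs <- Biostrings::readAAStringSet(fa)
  expect_equal(names(seqs), lib$construct_id)
  expect_equal(unname(nchar(as.character(seqs[1]))),
               nchar(assemble_sequence(lib[1, ], reg)))
  # empty library: valid empty FASTA, header-only manifest
  write_library(lib[0, ], reg, fa, mf)
  expect_equal(nrow(read_manifest(mf)), 0)
})

test_that("enumeration is deterministic across runs", {
  a <- enumerate_library(default_registry())
  b <- enumerate_library(default_registry())
  expect_identical(a, b)
})
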