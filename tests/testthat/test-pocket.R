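toy_ref <- function() {
  tibble::tibble(
    id = "REF",
    sequence = strrep("ACDEFGHIKLMNPQRSTVWY", 2)
  )
}

test_that("identical sequences align without gaps at 100% identity", {
  s <- random_aa_sequence(60)
  aln <- align_global(s, s)
  expect_false(grepl("-", aln$ref_aln))
  expect_identical(aln$ref_aln, aln$cand_aln)
})

test_that("the ACDEF/ACEF alignment has length 5 and one gap", {
  aln <- align_global("ACDEF", "ACEF")
  expect_equal(nchar(aln$ref_aln), 5)
  expect_equal(sum(strsplit(aln$cand_aln, "")[[1]] == "-"), 1)
  # affine cost: 4 + 9 + 5 + 6 matches minus (10 + 0.5) gap
  expect_equal(aln$score, 13.5)
  # scoring scheme is symmetric
  expect_equal(align_global("ACEF", "ACDEF")$score, aln$score)

  expect_error(align_global("", "ACDEF"), "empty")
})

test_that("alignment scores equal brute-force enumeration over all alignments", {
  sm <- psmascreen:::blosum62()
  set.seed(61)
  for (i in 1:20) {
    a <- random_aa_sequence(sample(1:6, 1), alphabet = c("A", "C", "D", "E"))
    b <- random_aa_sequence(sample(1:6, 1), alphabet = c("A", "C", "D", "E"))
    expect_equal(
      align_global(a, b)$score,
      brute_force_align_score(a, b, sm),
      tolerance = 1e-9,
      info = paste(a, b)
    )
  }
})

test_that("pocket conservation scores per-feature identity from the alignment", {
  ref <- toy_ref()
  spec <- pocket_spec(ref, list(pair = c(`3` = "D", `5` = "F")), threshold = 60)

  cand <- ref$sequence
  substr(cand, 3, 3) <- "E"
  aln <- align_global(ref, tibble::tibble(id = "cand", sequence = cand))
  rep1 <- score_pocket_conservation(aln, spec)
  expect_equal(rep1$identity_pct, 50)
  expect_false(rep1$flagged)

  spec3 <- pocket_spec(ref, list(trio = c(`3` = "D", `5` = "F", `7` = "H")), threshold = 60)
  rep3 <- score_pocket_conservation(aln, spec3)
  expect_equal(rep3$identity_pct, 200 / 3, tolerance = 1e-9)
  expect_true(rep3$flagged)
})

test_that("the reference scores 100% against itself under the default spec", {
  spec <- default_pocket_spec()
  expect_equal(
    sum(vapply(spec$features, nrow, integer(1))), 18
  )
  expect_length(spec$features, 4)
  rep0 <- score_pocket_candidates(spec$reference, spec)
  expect_true(all(rep0$identity_pct == 100))
  expect_true(all(rep0$flagged))
})

test_that("without indels, extraction equals direct string indexing", {
  spec <- default_pocket_spec()
  set.seed(71)
  cand <- spec$reference$sequence
  # mutate 40 random positions, no indels
  pos <- sample(nchar(cand), 40)
  aa <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  for (p in pos) substr(cand, p, p) <- sample(aa, 1)
  aln <- align_global(spec$reference, tibble::tibble(id = "mut", sequence = cand))
  rep1 <- score_pocket_conservation(aln, spec)
  positions <- attr(rep1, "positions")
  direct <- vapply(positions$position, function(p) substr(cand, p, p), character(1))
  expect_identical(positions$aligned, direct)
  expect_identical(positions$match, direct == positions$expected)
})

test_that("pocket specs validate positions and expected residues", {
  ref <- toy_ref()
  expect_error(pocket_spec(ref, list(f = c(`99` = "A"))), "outside")
  expect_error(pocket_spec(ref, list(f = c(`3` = "W"))), "mismatch")
})

test_that("the YAML spec round-trips", {
  spec <- default_pocket_spec()
  path <- withr::local_tempfile(fileext = ".yaml")
  fasta <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_proteins(spec$reference, fasta)
  yaml::write_yaml(
    list(
      reference_fasta = fasta, threshold = 70,
      features = list(zinc = list(`377` = "H", `387` = "D"))
    ),
    path
  )
  spec2 <- read_pocket_spec(path)
  expect_equal(spec2$threshold, 70)
  expect_equal(spec2$features$zinc$position, c(377L, 387L))
})
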