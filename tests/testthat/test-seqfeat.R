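aa20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

test_that("amino-acid composition matches hand counts and normalizes", {
  a <- compute_aac(strrep("A", 30))
  expect_equal(unname(a["aac_A"]), 1)
  expect_equal(sum(a), 1)

  b <- compute_aac(strrep("AC", 15))
  expect_equal(unname(b[c("aac_A", "aac_C")]), c(0.5, 0.5))
  expect_equal(sum(b[!names(b) %in% c("aac_A", "aac_C")]), 0)

  u <- compute_aac(strrep(paste(aa20, collapse = ""), 2))
  expect_equal(unname(u), rep(0.05, 20))

  expect_error(compute_aac("ACXKW"), "position 3")
})

test_that("dipeptide composition enumerates adjacent pairs", {
  d <- compute_dpc("ACACA")
  expect_equal(unname(d[c("dpc_AC", "dpc_CA")]), c(0.5, 0.5))
  expect_equal(sum(d), 1)

  h <- compute_dpc(strrep("A", 30))
  expect_equal(unname(h["dpc_AA"]), 1)

  expect_error(compute_dpc("A"), "length")

  set.seed(11)
  for (i in 1:20) {
    expect_equal(sum(compute_dpc(random_aa_sequence(sample(2:200, 1)))), 1,
      tolerance = 1e-12
    )
  }
})

test_that("autocorrelation follows the homopolymer conventions and closed form", {
  props <- aa_properties()
  ac <- compute_autocorrelation(strrep("W", 50))
  expect_true(all(ac[grepl("^moran_", names(ac))] == 0))
  expect_true(all(ac[grepl("^geary_", names(ac))] == 0))
  p_w <- props$hydropathy[props$aa == "W"]
  expect_equal(unname(ac["mb_hydropathy_lag7"]), p_w^2)
  p_k <- props$volume[props$aa == "K"]
  expect_equal(unname(compute_autocorrelation(strrep("K", 40))["mb_volume_lag3"]), p_k^2)

  expect_error(compute_autocorrelation(strrep("A", 20), max_lag = 30), "max_lag")
})

test_that("vectorized Moreau-Broto equals the naive double-loop oracle", {
  props <- aa_properties()
  set.seed(21)
  for (i in 1:15) {
    s <- random_aa_sequence(sample(35:150, 1))
    pn <- sample(setdiff(names(props), "aa"), 1)
    d <- sample(1:30, 1)
    got <- compute_autocorrelation(s, props, max_lag = 30)[paste0("mb_", pn, "_lag", d)]
    expect_equal(unname(got), naive_moreau_broto(s, props[[pn]], d), tolerance = 1e-9)
  }
})

test_that("QSO components share one denominator and reduce to composition", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_aa_sequence(sample(31:200, 1))
    expect_equal(sum(compute_qso(s)), 1, tolerance = 1e-9)
    expect_equal(sum(compute_apaac(s)), 1, tolerance = 1e-9)
  }

  s <- random_aa_sequence(60)
  q0 <- compute_qso(s, weight = 0)
  expect_equal(unname(q0[1:20]), unname(compute_aac(s)))
  expect_true(all(q0[21:50] == 0))

  # homopolymer: zero self-distance collapses all coupling terms
  qh <- compute_qso(strrep("M", 45))
  expect_true(all(qh[grepl("tau", names(qh))] == 0))
  expect_equal(unname(qh["qso_f_M"]), 1)
})

test_that("featurization has fixed width, a skip log, and depends on sequence only", {
  cfg <- seqfeat_config()
  prots <- tibble::tibble(
    id = c("ok1", "ok2", "dup_of_ok1", "too_short"),
    sequence = c(
      random_aa_sequence(30), random_aa_sequence(80),
      NA, strrep("A", 29)
    )
  )
  prots$sequence[3] <- prots$sequence[1]
  fm <- featurize_proteins(prots, cfg)
  expect_equal(nrow(fm), 3)
  expect_equal(ncol(fm), length(cfg$names) + 1)
  expect_true(all(is.finite(as.matrix(fm[-1]))))
  # identical sequences give identical vectors regardless of id
  expect_equal(as.numeric(fm[1, -1]), as.numeric(fm[3, -1]))

  sk <- attr(fm, "skipped")
  expect_equal(sk$id, "too_short")
  expect_match(sk$reason, "29")

  expect_error(
    featurize_proteins(tibble::tibble(id = "x", sequence = strrep("A", 10))),
    "no featurizable"
  )
})

test_that("strict mode rejects non-standard letters; lenient mode strips them", {
  prots <- tibble::tibble(id = "u1", sequence = paste0(strrep("ACDK", 10), "X"))
  expect_error(featurize_proteins(prots), "non-standard residue")
  fm <- featurize_proteins(prots, seqfeat_config(families = "aac", lenient = TRUE))
  expect_equal(nrow(fm), 1)
  expect_equal(sum(fm[1, -1]), 1)
})
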