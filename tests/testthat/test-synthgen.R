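test_that("generators are pure functions of the config and seed", {
  cfg <- synth_config(
    n_proteins = 25, n_selective = 3, n_enriched = 3, n_ubiquitous = 8,
    seed = 91
  )
  p1 <- generate_proteins(cfg)
  p2 <- generate_proteins(cfg)
  expect_identical(p1, p2)
  e1 <- generate_energies(cfg, p1)
  e2 <- generate_energies(cfg, p1)
  expect_identical(e1$dg_bind, e2$dg_bind)
  x1 <- generate_expression(cfg, p1$id)
  x2 <- generate_expression(cfg, p1$id)
  expect_identical(x1, x2)

  p3 <- generate_proteins(synth_config(n_proteins = 25, seed = 92))
  expect_equal(nrow(p3), 25)
  expect_false(identical(p1$sequence, p3$sequence))
})

test_that("generated proteins respect the length bounds and featurize fully", {
  cfg <- synth_config(n_proteins = 50, length_range = c(30, 600), seed = 93)
  prots <- generate_proteins(cfg)
  expect_equal(nrow(prots), 50)
  expect_true(all(nchar(prots$sequence) >= 30))
  expect_true(all(nchar(prots$sequence) <= 600))
  fm <- featurize_proteins(prots, seqfeat_config(families = "aac"))
  expect_equal(nrow(fm), 50)
  expect_equal(nrow(attr(fm, "skipped")), 0)
})

test_that("synthetic energies hit the envelope exactly", {
  cfg <- synth_config(seed = 94)
  prots <- generate_proteins(cfg)
  en <- generate_energies(cfg, prots)
  expect_equal(nrow(en), 79 * 3)
  expect_equal(median(en$dg_bind), -17.935, tolerance = 1e-9)
  expect_equal(IQR(en$dg_bind), 14.62, tolerance = 1e-9)
  expect_true(all(en$dg_bind >= -46.085))
  expect_true(all(en$dg_bind <= -1.635))
})

test_that("zero-noise energies are an exact affine map of the planted columns", {
  cfg <- synth_config(noise_sd = 0, seed = 95)
  prots <- generate_proteins(cfg)
  en <- generate_energies(cfg, prots)
  # regression on the named descriptor columns + per-ligand offset recovers
  # everything except the clipped tails
  pf <- featurize_proteins(prots, seqfeat_config(families = "aac"))
  df <- dplyr::left_join(en, pf, by = c(protein_id = "id"))
  keep <- en$dg_bind > -46.085 & en$dg_bind < -1.635
  fit <- lm(
    dg_bind ~ aac_A + aac_K + aac_D + aac_E + aac_R + factor(ligand_id),
    data = df[keep, ]
  )
  expect_lt(max(abs(residuals(fit))), 1e-8)

  expect_error(
    generate_energies(
      synth_config(signal_cols = c("aac_A", "nope"), signal_beta = c(1, 1), seed = 1),
      prots
    ),
    "nope"
  )
})

test_that("planted expression classes behave as designed under the filter", {
  cfg <- synth_config(n_proteins = 40, seed = 96)
  ids <- sprintf("S%03d", 1:40)
  expr <- generate_expression(cfg, ids)
  cls <- attr(expr, "classes")
  out <- apply_salivary_filter(ids, expr)
  sel <- cls$id[cls$class == "selective"]
  ubi <- cls$id[cls$class == "ubiquitous"]
  expect_true(all(sel %in% out$id))
  expect_length(intersect(ubi, out$id), 0)
  # explicit class assignment is honored
  forced <- generate_expression(cfg, ids[1:4],
    classes = c("selective", "enriched", "ubiquitous", "background")
  )
  expect_equal(attr(forced, "classes")$class[1], "selective")
  expect_equal(sum(forced[3, -1] >= 1), ncol(forced) - 1) # ubiquitous everywhere
})

test_that("synthetic inputs round-trip through files", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(
    n_proteins = 10, n_selective = 2, n_enriched = 2, n_ubiquitous = 3,
    seed = 97
  )
  write_synthetic_inputs(cfg, dir)
  prots <- read_fasta_proteins(file.path(dir, "proteins.fasta"))
  expect_equal(nrow(prots), 10)
  expect_identical(prots, generate_proteins(cfg))
  en <- read_energy_table(file.path(dir, "energies.csv"))
  expect_equal(nrow(en), 30)
  expr <- read_expression_table(file.path(dir, "expression.tsv"))
  expect_equal(nrow(expr), 10)
  labels <- jsonlite::read_json(file.path(dir, "truth_labels.json"))
  expect_equal(labels$seed, 97)
})
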