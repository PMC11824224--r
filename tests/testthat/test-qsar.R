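tiny_pairs <- function() {
  pf <- tibble::tibble(id = c("p1", "p2"), f1 = c(0.1, 0.4), f2 = c(1, 2))
  lf <- tibble::tibble(id = "L1", g1 = 5)
  en <- tibble::tibble(
    protein_id = c("p1", "p2"), ligand_id = "L1", dg_bind = c(-10, -20)
  )
  list(pf = pf, lf = lf, en = en)
}

test_that("pair assembly concatenates protein and ligand vectors", {
  d <- tiny_pairs()
  pairs <- make_pairs(d$pf, d$lf, d$en)
  expect_equal(nrow(pairs), 2)
  expect_equal(ncol(pairs), 3 + 2 + 1)
  expect_equal(pairs$f1, c(0.1, 0.4))
  expect_equal(pairs$g1, c(5, 5))

  bad <- dplyr::mutate(d$en, protein_id = c("p1", "ghost"))
  expect_error(make_pairs(d$pf, d$lf, bad), "ghost")
})

test_that("79 proteins fully crossed with 3 ligands give 237 rows", {
  cfg <- synth_config(seed = 5)
  prots <- generate_proteins(cfg)
  en <- generate_energies(cfg, prots)
  expect_equal(nrow(en), 237)
  pf <- featurize_proteins(prots, seqfeat_config(families = "aac"))
  lf <- featurize_ligands(bait_ligands())
  pairs <- make_pairs(pf, lf, en)
  expect_equal(nrow(pairs), 237)
  expect_equal(ncol(pairs), 3 + 20 + length(ligfeat_config()$names))
})

test_that("stratified split follows the per-bin allocation rule", {
  pairs <- tibble::tibble(
    protein_id = letters[1:8], ligand_id = "L", dg_bind = as.numeric(1:8),
    f1 = rnorm(8)
  )
  sp <- stratified_split(pairs, test_fraction = 0.25, n_bins = 4, seed = 3)
  expect_equal(nrow(sp$test), 2)
  expect_equal(nrow(sp$train), 6)
  # top-up fills the first two bins in stable order: one test row from each
  expect_true(any(sp$test$dg_bind <= 2))
  expect_true(any(sp$test$dg_bind %in% 3:4))
  # partition: disjoint and exhaustive
  expect_setequal(c(sp$train$protein_id, sp$test$protein_id), pairs$protein_id)

  sp2 <- stratified_split(pairs, test_fraction = 0.25, n_bins = 4, seed = 3)
  expect_identical(sp$test$protein_id, sp2$test$protein_id)
})

test_that("the 237-pair split gives a test set of 59-60 under four bins", {
  cfg <- synth_config(seed = 5)
  prots <- generate_proteins(cfg)
  en <- generate_energies(cfg, prots)
  pf <- featurize_proteins(prots, seqfeat_config(families = "aac"))
  lf <- featurize_ligands(bait_ligands())
  pairs <- make_pairs(pf, lf, en)
  sp <- stratified_split(pairs, 0.25, 4, seed = 9)
  expect_true(nrow(sp$test) %in% 59:60)
  expect_equal(nrow(sp$test) + nrow(sp$train), 237)
})

test_that("per-bin test counts always sum to round(test_fraction * N)", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(20:300, 1)
    tf <- runif(1, 0.1, 0.5)
    nb <- sample(2:6, 1)
    pairs <- tibble::tibble(
      protein_id = as.character(seq_len(n)), ligand_id = "L",
      dg_bind = rnorm(n), f1 = rnorm(n)
    )
    sp <- stratified_split(pairs, tf, nb, seed = i)
    expect_equal(nrow(sp$test), round(tf * n))
    expect_equal(nrow(sp$train) + nrow(sp$test), n)
    expect_length(intersect(sp$train$protein_id, sp$test$protein_id), 0)
  }
})

test_that("a noiseless low-rank signal is recovered almost exactly", {
  set.seed(42)
  n <- 200
  z <- matrix(rnorm(n * 3), n, 3)
  w <- matrix(rnorm(30), 3, 10)
  x <- z %*% w
  colnames(x) <- paste0("d", 1:10)
  pairs <- dplyr::bind_cols(
    tibble::tibble(
      protein_id = as.character(seq_len(n)), ligand_id = "L",
      dg_bind = as.numeric(z %*% c(2, -1, 0.5))
    ),
    tibble::as_tibble(x)
  )
  sp <- stratified_split(pairs, seed = 1)
  m <- fit_qsar(sp$train, k_components = 3, seed = 1)
  expect_equal(m$k, 3)
  test_r2 <- evaluate_metrics(sp$test$dg_bind, predict(m, sp$test))$r2
  train_r2 <- evaluate_metrics(sp$train$dg_bind, predict(m, sp$train))$r2
  expect_gte(test_r2, 0.95)
  expect_gte(train_r2, 0.9)
})

test_that("fitting and prediction are deterministic and name-keyed", {
  cfg <- synth_config(seed = 13)
  prots <- generate_proteins(cfg)
  en <- generate_energies(cfg, prots)
  pf <- featurize_proteins(prots, seqfeat_config(families = "aac"))
  lf <- featurize_ligands(bait_ligands())
  pairs <- make_pairs(pf, lf, en)
  sp <- stratified_split(pairs, seed = 13)
  m1 <- suppressMessages(fit_qsar(sp$train, k_components = 10, seed = 13))
  m2 <- suppressMessages(fit_qsar(sp$train, k_components = 10, seed = 13))
  expect_identical(predict(m1, sp$test), predict(m2, sp$test))

  # stored metadata
  expect_equal(m1$k, 10)
  expect_true(m1$cum_variance > 0 && m1$cum_variance <= 1)
  expect_true(all(diff(m1$var_fraction) <= 1e-12))

  # duplicated row predicts identically
  two <- sp$test[c(1, 1), ]
  expect_equal(predict(m1, two)[1], predict(m1, two)[2])

  # permuted columns with matching names predict identically
  perm <- sp$test[, c(1:3, sample(4:ncol(sp$test)))]
  expect_equal(predict(m1, perm), predict(m1, sp$test))

  # predictions are row-wise: adding rows does not change the others
  aug <- dplyr::bind_rows(sp$test, sp$train[1:3, ])
  expect_equal(predict(m1, aug)[seq_len(nrow(sp$test))], predict(m1, sp$test))

  # manifest mismatch names the first missing column
  broken <- sp$test[, -5]
  expect_error(predict(m1, broken), names(sp$test)[5])
})

test_that("component selection by variance target matches the realized variance", {
  set.seed(8)
  n <- 60
  x <- matrix(rnorm(n * 12), n, 12)
  colnames(x) <- paste0("d", 1:12)
  pairs <- dplyr::bind_cols(
    tibble::tibble(
      protein_id = as.character(1:n), ligand_id = "L", dg_bind = rnorm(n)
    ),
    tibble::as_tibble(x)
  )
  m <- fit_qsar(pairs, variance_target = 0.7, seed = 1)
  expect_gte(m$cum_variance, 0.7)
  expect_lt(sum(m$var_fraction[seq_len(m$k - 1)]), 0.7)
  expect_error(fit_qsar(pairs, k_components = 3, variance_target = 0.7), "exactly one")
})

test_that("regression metrics match their definitions", {
  expect_equal(evaluate_metrics(c(1, 2, 3), c(1, 2, 3)), tibble::tibble(rmse = 0, r2 = 1))
  truth <- c(0, 2, 4, 6)
  expect_equal(evaluate_metrics(truth, rep(mean(truth), 4))$r2, 0)
  m <- evaluate_metrics(c(0, 2), c(1, 1))
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, 0)
  expect_warning(m0 <- evaluate_metrics(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_true(is.nan(m0$r2))
})

test_that("tidy and glance expose the fitted model structure", {
  set.seed(3)
  x <- matrix(rnorm(50 * 6), 50, 6)
  colnames(x) <- paste0("d", 1:6)
  pairs <- dplyr::bind_cols(
    tibble::tibble(protein_id = as.character(1:50), ligand_id = "L", dg_bind = rnorm(50)),
    tibble::as_tibble(x)
  )
  m <- fit_qsar(pairs, k_components = 4, seed = 2)
  td <- tidy(m)
  expect_equal(nrow(td), 4)
  expect_equal(td$cum_variance[4], m$cum_variance)
  gl <- glance(m)
  expect_equal(gl$k, 4)
  expect_equal(gl$ntree, 500)
})
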