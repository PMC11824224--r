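## QSAR: "Activity" (binding free energy, kJ/mol) regressed on "Structure"
## (concatenated protein + ligand descriptors) through column
## standardization, PCA reduction, and a random-forest ensemble on the
## component scores. Standardizer and PCA are fitted on the training rows
## only; the fitted objects carry everything needed for leak-free
## prediction.

pair_meta_cols <- c("protein_id", "ligand_id", "dg_bind")

pair_feature_cols <- function(pairs) setdiff(names(pairs), pair_meta_cols)

#' Read a binding-energy table
#'
#' CSV with columns `protein_id`, `ligand_id` and `dg_bind_kj_mol` (or
#' `dg_bind`); energies are free energies of binding in kJ/mol, negative
#' meaning stronger binding.
#'
#' @param path Path to the CSV file.
#' @return Tibble with columns `protein_id`, `ligand_id`, `dg_bind`.
#' @export
read_energy_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if ("dg_bind_kj_mol" %in% names(tbl)) {
    tbl <- dplyr::rename(tbl, dg_bind = "dg_bind_kj_mol")
  }
  stopifnot(all(pair_meta_cols %in% names(tbl)), all(is.finite(tbl$dg_bind)))
  tbl[pair_meta_cols]
}

#' Assemble the protein-ligand pair feature matrix
#'
#' One row per binding-energy record; the feature vector is the protein
#' descriptor vector concatenated with the ligand descriptor vector.
#'
#' @param protein_features Feature tibble from [featurize_proteins()].
#' @param ligand_features Feature tibble from [featurize_ligands()].
#' @param energies Tibble with columns `protein_id`, `ligand_id`, `dg_bind`.
#' @return A pair tibble: `protein_id`, `ligand_id`, `dg_bind`, then all
#'   feature columns. Attribute `manifest_hash` combines both feature
#'   manifests.
#' @export
make_pairs <- function(protein_features, ligand_features, energies) {
  stopifnot(all(pair_meta_cols %in% names(energies)))
  if (anyDuplicated(energies[c("protein_id", "ligand_id")])) {
    rlang::abort("duplicate (protein_id, ligand_id) pairs in energy table")
  }
  bad_p <- setdiff(energies$protein_id, protein_features$id)
  bad_l <- setdiff(energies$ligand_id, ligand_features$id)
  if (length(bad_p) || length(bad_l)) {
    rlang::abort(paste0(
      "unresolved ids in energy table",
      if (length(bad_p)) paste0("; proteins: ", paste(bad_p, collapse = ", ")),
      if (length(bad_l)) paste0("; ligands: ", paste(bad_l, collapse = ", "))
    ))
  }
  pf <- protein_features[match(energies$protein_id, protein_features$id), -1]
  lf <- ligand_features[match(energies$ligand_id, ligand_features$id), -1]
  out <- dplyr::bind_cols(tibble::as_tibble(energies[pair_meta_cols]), pf, lf)
  attr(out, "manifest_hash") <- rlang::hash(list(
    attr(protein_features, "manifest_hash"), attr(ligand_features, "manifest_hash"),
    names(out)
  ))
  out
}

#' Stratified train/test split on the binding-energy response
#'
#' Rows are binned into response quantile (equal-count) bins; each bin
#' contributes `floor(test_fraction * bin_size)` test rows, topped up by
#' largest fractional remainder (stable bin order on ties) until the total
#' reaches `round(test_fraction * N)`. Assignment within a bin is a seeded
#' shuffle. Degenerate quantile breaks (heavily tied responses) merge
#' adjacent bins with a warning.
#'
#' @param pairs Pair tibble from [make_pairs()].
#' @param test_fraction Fraction of rows for the test set (default 0.25).
#' @param n_bins Number of response bins (default 4).
#' @param seed Integer seed for the within-bin shuffle.
#' @return A list with tibbles `train` and `test`; together they partition
#'   the input rows.
#' @export
stratified_split <- function(pairs, test_fraction = 0.25, n_bins = 4L, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, n_bins >= 1, nrow(pairs) >= n_bins)
  y <- pairs$dg_bind
  n <- length(y)
  breaks <- stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1), type = 7)
  ub <- unique(breaks)
  if (length(ub) < length(breaks)) {
    rlang::warn("tied response quantiles: merging adjacent empty bins")
  }
  if (length(ub) < 2) {
    bin <- rep(1L, n)
  } else {
    bin <- as.integer(cut(y, breaks = ub, include.lowest = TRUE))
  }
  bins <- sort(unique(bin))
  sizes <- vapply(bins, function(b) sum(bin == b), integer(1))
  total_test <- round(test_fraction * n)
  base <- floor(test_fraction * sizes)
  rem <- test_fraction * sizes - base
  counts <- base
  # top up by largest fractional remainder, stable bin order on ties
  ord <- order(-rem, seq_along(bins))
  i <- 1L
  while (sum(counts) < total_test) {
    b <- ord[((i - 1L) %% length(bins)) + 1L]
    if (counts[b] < sizes[b]) counts[b] <- counts[b] + 1L
    i <- i + 1L
  }
  while (sum(counts) > total_test) {
    b <- ord[length(bins) - ((i - 1L) %% length(bins))]
    if (counts[b] > 0L) counts[b] <- counts[b] - 1L
    i <- i + 1L
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(seq_along(bins), function(j) {
      rows <- which(bin == bins[j])
      if (counts[j] == 0L) return(integer(0))
      rows[sample.int(length(rows), counts[j])]
    }))
  })
  train <- pairs[setdiff(seq_len(n), test_idx), ]
  test <- pairs[sort(test_idx), ]
  attr(train, "manifest_hash") <- attr(pairs, "manifest_hash")
  attr(test, "manifest_hash") <- attr(pairs, "manifest_hash")
  list(train = train, test = test)
}

#' Fit the PCA + random-forest QSAR
#'
#' Feature columns are centered and scaled on the training rows (constant
#' columns are dropped with a message), reduced by PCA fitted on the
#' training rows, and the retained component scores are passed to a random
#' forest regression on the binding energy.
#'
#' @param train Training pair tibble from [stratified_split()].
#' @param k_components Number of principal components to retain (default 34,
#'   capped at `n_train - 1`). Give either this or `variance_target`.
#' @param variance_target If non-`NULL`, retain the smallest number of
#'   components whose cumulative explained-variance fraction reaches this
#'   value (e.g. 0.708) instead of a fixed count.
#' @param rf_params List of random-forest hyperparameters: `ntree` (default
#'   500) and `mtry` (default `ceiling(sqrt(k))`).
#' @param seed Integer seed for the forest.
#' @return A `qsar_model` object.
#' @export
fit_qsar <- function(train, k_components = 34L, variance_target = NULL,
                     rf_params = list(), seed = 1L) {
  stopifnot(nrow(train) > 1)
  if (!is.null(variance_target) && !missing(k_components)) {
    rlang::abort("give exactly one of k_components or variance_target")
  }
  y <- train$dg_bind
  cols <- pair_feature_cols(train)
  x <- as.matrix(train[cols])
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    rlang::inform(paste0(
      "dropping ", sum(const), " constant column(s): ",
      paste(head(cols[const], 5), collapse = ", "),
      if (sum(const) > 5) ", ..."
    ))
    x <- x[, !const, drop = FALSE]
    cols <- cols[!const]
    sds <- sds[!const]
  }
  ctr <- colMeans(x)
  xs <- scale(x, center = ctr, scale = sds)
  pca <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  varfrac <- pca$sdev^2 / sum(pca$sdev^2)
  kmax <- min(nrow(train) - 1L, ncol(xs))
  k <- if (!is.null(variance_target)) {
    stopifnot(variance_target > 0, variance_target <= 1)
    min(which(cumsum(varfrac) >= variance_target)[1], kmax)
  } else {
    min(as.integer(k_components), kmax)
  }
  scores <- xs %*% pca$rotation[, seq_len(k), drop = FALSE]
  ntree <- rf_params$ntree %||% 500L
  mtry <- rf_params$mtry %||% ceiling(sqrt(k))
  set.seed(seed)
  rf <- randomForest::randomForest(x = scores, y = y, ntree = ntree, mtry = mtry)
  structure(
    list(
      columns = cols, center = ctr, scale = sds,
      rotation = pca$rotation[, seq_len(k), drop = FALSE],
      var_fraction = varfrac, k = k, cum_variance = sum(varfrac[seq_len(k)]),
      rf = rf, seed = seed, n_train = nrow(train),
      rf_params = list(ntree = ntree, mtry = mtry),
      manifest_hash = attr(train, "manifest_hash")
    ),
    class = "qsar_model"
  )
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf(
    "<qsar_model> %d PCs (%.1f%% variance), %d trees, n_train = %d, seed = %d\n",
    x$k, 100 * x$cum_variance, x$rf_params$ntree, x$n_train, x$seed
  ))
  invisible(x)
}

#' Predict binding energies with a fitted QSAR
#'
#' Columns of `newdata` are aligned to the model's manifest by name, so any
#' column order with matching names predicts identically; a missing model
#' column is an error naming the first mismatch.
#'
#' @param object A `qsar_model`.
#' @param newdata Pair tibble (or any tibble containing the model's feature
#'   columns).
#' @param ... Unused.
#' @return Numeric vector of predicted free energies of binding (kJ/mol),
#'   one per row.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$columns, names(newdata))
  if (length(missing_cols)) {
    rlang::abort(paste0("feature manifest mismatch: missing column '", missing_cols[1], "'"))
  }
  x <- as.matrix(newdata[object$columns])
  xs <- scale(x, center = object$center, scale = object$scale)
  scores <- xs %*% object$rotation
  as.numeric(stats::predict(object$rf, scores))
}

#' Regression metrics on held-out data
#'
#' @param truth Numeric vector of observed responses.
#' @param pred Numeric vector of predictions, same length.
#' @return One-row tibble with `rmse` (\eqn{\sqrt{mean((t-p)^2)}}) and `r2`
#'   (\eqn{1 - SS_{res}/SS_{tot}}); `r2` is `NaN` with a warning when the
#'   truth has zero variance.
#' @export
#' @examples
#' evaluate_metrics(c(0, 2), c(1, 1))
evaluate_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 2)
  rmse <- sqrt(mean((truth - pred)^2))
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) {
    rlang::warn("zero variance in truth: r2 undefined")
    r2 <- NaN
  } else {
    r2 <- 1 - sum((truth - pred)^2) / ss_tot
  }
  tibble::tibble(rmse = rmse, r2 = r2)
}

#' @export
tidy.qsar_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$k),
    var_fraction = x$var_fraction[seq_len(x$k)],
    cum_variance = cumsum(x$var_fraction)[seq_len(x$k)]
  )
}

#' @export
glance.qsar_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, cum_variance = x$cum_variance, n_train = x$n_train,
    ntree = x$rf_params$ntree, mtry = x$rf_params$mtry, seed = x$seed
  )
}

#' Predicted-versus-observed plot for a QSAR model
#'
#' @param object A `qsar_model`.
#' @param new_data Pair tibble with observed `dg_bind` (typically the test
#'   set).
#' @param ... Unused.
#' @return A ggplot: predictions against observed binding energies with the
#'   identity line.
#' @export
autoplot.qsar_model <- function(object, new_data, ...) {
  df <- tibble::tibble(
    observed = new_data$dg_bind,
    predicted = predict(object, new_data)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Observed ΔG_bind (kJ/mol)",
      y = "Predicted ΔG_bind (kJ/mol)"
    ) +
    ggplot2::theme_minimal()
}
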