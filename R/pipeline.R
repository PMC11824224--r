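## End-to-end orchestration: featurize -> train QSAR -> screen library ->
## salivary expression filter -> pocket conservation -> report. Stage order
## mirrors the screening procedure: candidates may only be removed from one
## stage to the next.

#' Run the full reverse-screening pipeline
#'
#' Trains (or reuses) the QSAR on the energy table, screens the protein
#' library against the screening ligand, keeps the top quartile, applies the
#' salivary expression filter, and scores binding-pocket conservation. Each
#' stage logs its in/out counts; the run report embeds the seed and a
#' configuration hash for provenance.
#'
#' @param proteins Screening library tibble (`id`, `sequence`).
#' @param energies Binding-energy tibble (`protein_id`, `ligand_id`,
#'   `dg_bind`); required unless `model` is given.
#' @param expression Optional expression tibble for the salivary filter.
#' @param pocket Optional [pocket_spec()]; default the packaged synthetic
#'   FOLH1 spec.
#' @param model Optional pre-trained `qsar_model`; skips training.
#' @param train_proteins Proteins referenced by `energies` (default: the
#'   screening library itself).
#' @param ligands Bait ligand tibble (default [bait_ligands()]).
#' @param screening_ligand One-row ligand tibble (default 2-PMPA).
#' @param select_quartile Apply the top-quartile stage (default `TRUE`).
#' @param test_fraction,n_bins,k_components,rf_params Passed to
#'   [stratified_split()] and [fit_qsar()].
#' @param seqfeat_cfg,ligfeat_cfg Featurization configurations.
#' @param seed Integer seed governing the split and the forest.
#' @return A `pipeline_run`: list with `report` (per-stage counts),
#'   `screening`, `candidates`, `expression_pass`, `pocket_report`,
#'   `final_candidates`, `model`, `metrics`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(proteins, energies = NULL, expression = NULL,
                         pocket = default_pocket_spec(), model = NULL,
                         train_proteins = NULL, ligands = bait_ligands(),
                         screening_ligand = bait_ligands()[1, ],
                         select_quartile = TRUE,
                         test_fraction = 0.25, n_bins = 4L, k_components = 34L,
                         rf_params = list(),
                         seqfeat_cfg = seqfeat_config(),
                         ligfeat_cfg = ligfeat_config(), seed = 1L) {
  config_hash <- rlang::hash(list(
    test_fraction, n_bins, k_components, rf_params, select_quartile,
    seqfeat_cfg$hash, ligfeat_cfg$hash, screening_ligand$smiles, seed
  ))
  report <- tibble::tibble(
    stage = character(), n_in = integer(), n_out = integer(), detail = character()
  )
  log_stage <- function(stage, n_in, n_out, detail = "") {
    report <<- dplyr::add_row(
      report,
      stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out),
      detail = detail
    )
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  metrics <- NULL
  if (is.null(model)) {
    if (is.null(energies)) rlang::abort("either a model or an energy table is required")
    model <- run_stage("train", {
      tp <- train_proteins %||% proteins
      pf <- featurize_proteins(tp, seqfeat_cfg)
      lf <- featurize_ligands(ligands, ligfeat_cfg)
      pairs <- make_pairs(pf, lf, energies)
      split <- stratified_split(pairs, test_fraction, n_bins, seed = seed)
      m <- fit_qsar(split$train, k_components = k_components,
                    rf_params = rf_params, seed = seed)
      # the stage block is evaluated in this function's frame, so plain
      # assignment updates the pipeline-level result
      metrics <- evaluate_metrics(split$test$dg_bind, predict(m, split$test))
      log_stage("train", nrow(pairs), nrow(split$train),
                sprintf("test R2 %.3f, RMSE %.2f kJ/mol", metrics$r2, metrics$rmse))
      m
    })
  }

  screening <- run_stage("screen", {
    s <- screen_library(proteins, model, screening_ligand, seqfeat_cfg, ligfeat_cfg)
    log_stage("screen", nrow(proteins), nrow(s),
              sprintf("%d excluded (<30 AA)", nrow(attr(s, "skipped"))))
    s
  })

  candidates <- run_stage("quartile", {
    cand <- if (select_quartile) select_top_quartile(screening) else screening
    log_stage(
      "quartile", nrow(screening), nrow(cand),
      if (select_quartile) {
        sprintf("threshold %.2f kJ/mol", attr(cand, "threshold"))
      } else {
        "disabled"
      }
    )
    cand
  })

  expression_pass <- NULL
  surviving <- candidates$protein_id
  if (!is.null(expression)) {
    expression_pass <- run_stage("expression_filter", {
      ep <- apply_salivary_filter(candidates, expression)
      log_stage("expression_filter", nrow(candidates), nrow(ep))
      ep
    })
    surviving <- expression_pass$id
  }

  pocket_report <- NULL
  final <- surviving
  if (!is.null(pocket) && length(surviving)) {
    pocket_report <- run_stage("pocket", {
      seqs <- proteins[match(surviving, proteins$id), ]
      pr <- score_pocket_candidates(seqs, pocket)
      flagged <- pr |>
        dplyr::group_by(.data$candidate) |>
        dplyr::summarise(flagged = any(.data$flagged), .groups = "drop")
      final <- flagged$candidate[flagged$flagged]
      log_stage("pocket", length(surviving), length(final),
                sprintf("threshold >%g%% identity", pocket$threshold))
      pr
    })
  }

  structure(
    list(
      report = report, screening = screening, candidates = candidates,
      expression_pass = expression_pass, pocket_report = pocket_report,
      final_candidates = final, model = model, metrics = metrics,
      seed = seed, config_hash = config_hash
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> seed %d, config %s\n", x$seed, x$config_hash))
  print(as.data.frame(x$report), row.names = FALSE)
  cat(sprintf(
    "final candidates: %d%s\n", length(x$final_candidates),
    if (length(x$final_candidates)) {
      paste0(" (", paste(head(x$final_candidates, 10), collapse = ", "), ")")
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Per-stage attrition plot for a pipeline run
#'
#' @param object A `pipeline_run`.
#' @param ... Unused.
#' @return A ggplot of candidate counts surviving each stage.
#' @export
autoplot.pipeline_run <- function(object, ...) {
  df <- dplyr::mutate(object$report, stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Candidates surviving stage") +
    ggplot2::theme_minimal()
}
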