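## Salivary-gland expression filter. A screening candidate is admitted when
## it is detected in the salivary gland and satisfies at least one of three
## selectivity rules: (a) >= 4-fold enrichment over every other tissue,
## (b) expression limited to the salivary gland, (c) detection in fewer than
## one third of all tissues.

#' Read a tissue expression table
#'
#' TSV with the protein/gene identifier in the first column and one numeric
#' column per tissue (TPM-like, non-negative).
#'
#' @param path Path to the TSV file.
#' @return Tibble: `id` plus one column per tissue.
#' @export
read_expression_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  names(tbl)[1] <- "id"
  stopifnot(
    !anyDuplicated(names(tbl)),
    all(vapply(tbl[-1], is.numeric, logical(1))),
    all(as.matrix(tbl[-1]) >= 0)
  )
  tbl
}

#' Filter candidates by salivary-gland expression
#'
#' A candidate passes when it is detected in the salivary gland
#' (value >= `tau_detect`) and meets at least one of:
#' * `fold`: salivary expression at least `fold_change` times the maximum
#'   (or, with `compare = "mean"`, the mean) non-salivary expression;
#' * `exclusive`: detected in no non-salivary tissue;
#' * `restricted`: detected in fewer than one third of all tissues
#'   (salivary included, strict `<`).
#'
#' Candidates absent from the table are dropped with a warning and recorded
#' in the `missing` attribute.
#'
#' @param candidates Character vector of candidate ids, or a tibble with a
#'   `protein_id` column (as from [select_top_quartile()]).
#' @param expression Expression tibble from [read_expression_table()] or
#'   [generate_expression()].
#' @param salivary_col Name of the salivary-gland tissue column.
#' @param tau_detect Detection threshold (default 1, TPM-like).
#' @param fold_change Enrichment factor for the fold rule (default 4,
#'   inclusive `>=`).
#' @param compare Non-salivary summary for the fold rule: `"max"`
#'   (conservative default) or `"mean"`.
#' @return Tibble `id`, `rule_fold`, `rule_exclusive`, `rule_restricted`,
#'   one row per passing candidate; attribute `missing` lists ids absent
#'   from the table.
#' @export
apply_salivary_filter <- function(candidates, expression,
                                  salivary_col = "salivary_gland",
                                  tau_detect = 1, fold_change = 4,
                                  compare = c("max", "mean")) {
  compare <- match.arg(compare)
  if (is.data.frame(candidates)) candidates <- candidates$protein_id
  stopifnot(salivary_col %in% names(expression))
  missing_ids <- setdiff(candidates, expression$id)
  if (length(missing_ids)) {
    rlang::warn(paste0(
      length(missing_ids), " candidate(s) absent from expression table: ",
      paste(head(missing_ids, 5), collapse = ", "),
      if (length(missing_ids) > 5) ", ..."
    ))
  }
  ids <- intersect(candidates, expression$id)
  rows <- expression[match(ids, expression$id), ]
  tissue_cols <- setdiff(names(expression), "id")
  n_tissues <- length(tissue_cols)
  sal <- rows[[salivary_col]]
  other <- as.matrix(rows[setdiff(tissue_cols, salivary_col)])
  other_summary <- if (compare == "max") {
    apply(other, 1, max)
  } else {
    rowMeans(other)
  }
  detected_any_other <- apply(other >= tau_detect, 1, any)
  n_detected <- rowSums(as.matrix(rows[tissue_cols]) >= tau_detect)
  detected_sal <- sal >= tau_detect
  rule_fold <- detected_sal & sal >= fold_change * other_summary
  rule_exclusive <- detected_sal & !detected_any_other
  rule_restricted <- detected_sal & n_detected < n_tissues / 3
  pass <- rule_fold | rule_exclusive | rule_restricted
  out <- tibble::tibble(
    id = ids,
    rule_fold = rule_fold,
    rule_exclusive = rule_exclusive,
    rule_restricted = rule_restricted
  )[pass, ]
  attr(out, "missing") <- missing_ids
  out
}
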