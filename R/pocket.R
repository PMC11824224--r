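## Binding-pocket conservation against FOLH1 (glutamate carboxypeptidase
## II). Candidates are globally aligned to the reference with
## Needleman-Wunsch (BLOSUM62, affine gaps, end gaps penalized) and scored
## for residue identity at the pocket positions, grouped into four
## structural features: zinc-binding, substrate-binding, structural, and
## arginine-patch residues (R463/R534/R536, which orient the glutamate
## moiety of PSMA ligands).

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties and end gaps
#' penalized. Defaults follow the EMBL-EBI needle service: BLOSUM62, gap
#' open 10, gap extend 0.5. A gap of length k costs `gap_open + k *
#' gap_extend`.
#'
#' @param a,b One-row protein tibbles (columns `id`, `sequence`), or plain
#'   sequence strings.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param submat Substitution matrix (default BLOSUM62).
#' @return A `pocket_alignment`: list with `ref_id`, `cand_id`, `score`,
#'   and the two gapped alignment strings `ref_aln`, `cand_aln`.
#' @export
#' @examples
#' align_global("ACDEF", "ACEF")
align_global <- function(a, b, gap_open = 10, gap_extend = 0.5, submat = NULL) {
  as_rec <- function(x, default_id) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1)
      list(id = x$id, sequence = toupper(x$sequence))
    } else {
      list(id = default_id, sequence = toupper(x))
    }
  }
  ra <- as_rec(a, "a")
  rb <- as_rec(b, "b")
  if (!nzchar(ra$sequence) || !nzchar(rb$sequence)) {
    rlang::abort("cannot align an empty sequence")
  }
  submat <- submat %||% blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ra$sequence), Biostrings::AAString(rb$sequence),
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  structure(
    list(
      ref_id = ra$id, cand_id = rb$id,
      score = Biostrings::score(aln),
      ref_aln = as.character(Biostrings::alignedPattern(aln)),
      cand_aln = as.character(Biostrings::alignedSubject(aln))
    ),
    class = "pocket_alignment"
  )
}

#' @export
print.pocket_alignment <- function(x, ...) {
  cat(sprintf("<pocket_alignment> %s vs %s, score %.1f\n", x$ref_id, x$cand_id, x$score))
  cat(" ", x$ref_aln, "\n ", x$cand_aln, "\n")
  invisible(x)
}

#' Construct a binding-pocket specification
#'
#' @param reference One-row protein tibble: the reference (FOLH1) sequence.
#' @param features Named list; each element a named character vector mapping
#'   1-based reference positions (names) to expected residue letters
#'   (values). Letters must match the reference sequence at those positions.
#' @param threshold Identity percentage above which (strict `>`) a feature
#'   counts as conserved (default 60).
#' @return A `pocket_spec` object.
#' @export
pocket_spec <- function(reference, features, threshold = 60) {
  stopifnot(is.data.frame(reference), nrow(reference) == 1, length(features) >= 1)
  seq_chars <- strsplit(toupper(reference$sequence), "")[[1]]
  feats <- purrr::imap(features, function(fv, fname) {
    pos <- as.integer(names(fv))
    if (any(is.na(pos)) || any(pos < 1) || any(pos > length(seq_chars))) {
      rlang::abort(sprintf("feature '%s': positions outside reference length", fname))
    }
    bad <- seq_chars[pos] != toupper(unname(fv))
    if (any(bad)) {
      rlang::abort(sprintf(
        "feature '%s': expected residue mismatch at reference position %d (%s != %s)",
        fname, pos[which(bad)[1]], seq_chars[pos[which(bad)[1]]], fv[which(bad)[1]]
      ))
    }
    tibble::tibble(position = pos, residue = toupper(unname(fv)))
  })
  structure(
    list(reference = reference, features = feats, threshold = threshold),
    class = "pocket_spec"
  )
}

#' The default FOLH1 pocket specification
#'
#' Eighteen pocket positions grouped into four structural features
#' (zinc-binding, substrate-binding, structural, arginine-patch), with the
#' five literature-named substrate/arginine-patch positions E424, R463,
#' N519, R534 and R536, at a 60% identity threshold. The packaged reference
#' is a synthetic FOLH1 stand-in sequence (see
#' `inst/extdata/folh1_synthetic.fasta`) carrying the expected residues at
#' the canonical positions; replace it (and the spec YAML) with a curated
#' reference for production use.
#'
#' @return A `pocket_spec`.
#' @export
default_pocket_spec <- function() {
  read_pocket_spec(system.file("extdata", "folh1_pocket_synthetic.yaml",
    package = "psmascreen"
  ))
}

#' Read a pocket specification from YAML
#'
#' The YAML holds `reference_fasta` (path, relative to the YAML file),
#' `threshold`, and `features` as maps of position to residue letter.
#'
#' @param path Path to the YAML file.
#' @return A `pocket_spec`.
#' @export
read_pocket_spec <- function(path) {
  y <- yaml::read_yaml(path)
  fasta <- y$reference_fasta
  if (!file.exists(fasta)) fasta <- file.path(dirname(path), fasta)
  reference <- read_fasta_proteins(fasta)[1, ]
  features <- purrr::map(y$features, function(f) {
    # YAML 1.1 reads bare N/Y as booleans; map them back to residue letters
    v <- vapply(f, function(x) {
      if (isTRUE(x)) "Y" else if (isFALSE(x)) "N" else as.character(x)
    }, character(1))
    setNames(v, names(f))
  })
  pocket_spec(reference, features, threshold = y$threshold %||% 60)
}

#' Score pocket conservation from an alignment
#'
#' For each pocket position, the candidate residue aligned to the reference
#' position is extracted (a gap counts as mismatch); each feature's identity
#' is the percentage of its positions with an identical candidate residue
#' (or, in `"similarity"` mode, a positive substitution score). A candidate
#' is flagged when any feature identity strictly exceeds the spec threshold.
#'
#' @param aln A `pocket_alignment` whose reference side is the spec
#'   reference.
#' @param spec A [pocket_spec()].
#' @param match_mode `"identity"` (default) or `"similarity"`.
#' @return Tibble `candidate`, `feature`, `n_positions`, `identity_pct`,
#'   `flagged`; attribute `positions` holds the per-position extraction
#'   (`feature`, `position`, `expected`, `aligned`, `match`).
#' @export
score_pocket_conservation <- function(aln, spec, match_mode = c("identity", "similarity")) {
  match_mode <- match.arg(match_mode)
  ref_gapped <- gsub("-", "", aln$ref_aln)
  if (ref_gapped != toupper(spec$reference$sequence)) {
    rlang::abort("alignment reference side does not match the pocket spec reference")
  }
  ref_chars <- strsplit(aln$ref_aln, "")[[1]]
  cand_chars <- strsplit(aln$cand_aln, "")[[1]]
  ref_pos <- cumsum(ref_chars != "-")
  sm <- blosum62()
  pos_tbl <- purrr::imap_dfr(spec$features, function(ft, fname) {
    cols <- vapply(ft$position, function(p) {
      w <- which(ref_pos == p & ref_chars != "-")
      stopifnot(length(w) == 1) # global alignment covers every reference position
      w
    }, integer(1))
    aligned <- cand_chars[cols]
    is_match <- if (match_mode == "identity") {
      aligned == ft$residue
    } else {
      aligned != "-" & sm[cbind(ft$residue, ifelse(aligned == "-", "A", aligned))] > 0
    }
    tibble::tibble(
      feature = fname, position = ft$position, expected = ft$residue,
      aligned = aligned, match = is_match
    )
  })
  report <- pos_tbl |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      n_positions = dplyr::n(),
      identity_pct = 100 * mean(.data$match),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      candidate = aln$cand_id,
      flagged = .data$identity_pct > spec$threshold,
      .before = 1
    )
  attr(report, "positions") <- pos_tbl
  report
}

#' Score a set of candidates against the pocket spec
#'
#' Aligns each candidate protein globally to the spec reference and scores
#' pocket-feature conservation.
#'
#' @param candidates Tibble with columns `id`, `sequence`.
#' @param spec A [pocket_spec()]; default [default_pocket_spec()].
#' @param ... Passed to [align_global()] and [score_pocket_conservation()].
#' @return Tibble with one row per candidate x feature, as
#'   [score_pocket_conservation()].
#' @export
score_pocket_candidates <- function(candidates, spec = default_pocket_spec(), ...) {
  dots <- list(...)
  aln_args <- dots[intersect(names(dots), c("gap_open", "gap_extend", "submat"))]
  score_args <- dots[intersect(names(dots), "match_mode")]
  purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    aln <- do.call(align_global, c(list(spec$reference, candidates[i, ]), aln_args))
    do.call(score_pocket_conservation, c(list(aln, spec), score_args))
  })
}

#' Heatmap of pocket-feature identity across candidates
#'
#' @param report Tibble from [score_pocket_candidates()].
#' @param ... Unused.
#' @return A ggplot tile map of identity percentages.
#' @export
plot_pocket_report <- function(report, ...) {
  ggplot2::ggplot(
    report,
    ggplot2::aes(.data$feature, .data$candidate, fill = .data$identity_pct)
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$identity_pct)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "seagreen", limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "identity %") +
    ggplot2::theme_minimal()
}
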