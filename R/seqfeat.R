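## Sequence-derived protein descriptors.
##
## Five descriptor families over the 20-letter amino-acid alphabet:
## amino-acid composition (AAC), dipeptide composition (DPC), three
## autocorrelation statistics (normalized Moreau-Broto, Moran, Geary) over
## physicochemical scales, quasi-sequence order (QSO) and amphiphilic pseudo
## amino-acid composition (APAAC). The per-sequence kernels return named
## numeric vectors; featurize_proteins() assembles the tidy feature matrix.

seq_index <- function(sequence, what = "sequence") {
  ch <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(ch, AA20)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    rlang::abort(sprintf(
      "invalid residue letter '%s' at position %d of %s", ch[p], p, what
    ))
  }
  idx
}

#' Amino-acid composition (AAC)
#'
#' Fraction of each of the 20 standard amino acids in the sequence; the 20
#' values sum to 1.
#'
#' @param sequence A single amino-acid sequence string.
#' @return Named numeric vector of length 20 (`aac_A` ... `aac_Y`).
#' @export
#' @examples
#' compute_aac(strrep("AC", 15))
compute_aac <- function(sequence) {
  idx <- seq_index(sequence)
  setNames(tabulate(idx, 20L) / length(idx), paste0("aac_", AA20))
}

#' Dipeptide composition (DPC)
#'
#' Frequency of each of the 400 ordered adjacent residue pairs, normalized by
#' the number of dipeptides (length - 1); the 400 values sum to 1.
#'
#' @inheritParams compute_aac
#' @return Named numeric vector of length 400 (`dpc_AA` ... `dpc_YY`).
#' @export
compute_dpc <- function(sequence) {
  idx <- seq_index(sequence)
  L <- length(idx)
  if (L < 2L) rlang::abort("dipeptide composition requires length >= 2")
  pair <- (idx[-L] - 1L) * 20L + idx[-1L]
  nm <- paste0("dpc_", rep(AA20, each = 20L), rep(AA20, times = 20L))
  setNames(tabulate(pair, 400L) / (L - 1L), nm)
}

#' Physicochemical autocorrelation descriptors
#'
#' Normalized Moreau-Broto, Moran and Geary autocorrelation of standardized
#' physicochemical scales along the sequence, at lags 1..`max_lag`:
#' \deqn{AC(d) = \frac{1}{L-d}\sum_i P_i P_{i+d}}
#' \deqn{I(d)  = \frac{\frac{1}{L-d}\sum_i (P_i-\bar P)(P_{i+d}-\bar P)}{\frac{1}{L}\sum_i (P_i-\bar P)^2}}
#' \deqn{C(d)  = \frac{\frac{1}{2(L-d)}\sum_i (P_i-P_{i+d})^2}{\frac{1}{L-1}\sum_i (P_i-\bar P)^2}}
#' For a zero-variance profile (e.g. a homopolymer) Moran and Geary are
#' defined as 0.
#'
#' @inheritParams compute_aac
#' @param props Property tibble as from [aa_properties()] (standardized).
#' @param max_lag Maximum lag; the sequence must be longer than `max_lag`
#'   unless `pad = TRUE`, in which case lags `>= length` are emitted as 0 to
#'   keep the vector width fixed.
#' @param pad Zero-fill out-of-range lags instead of erroring.
#' @return Named numeric vector of length `3 * n_properties * max_lag`,
#'   ordered type (mb, moran, geary), then property, then lag.
#' @export
compute_autocorrelation <- function(sequence, props = aa_properties(),
                                    max_lag = 30L, pad = FALSE) {
  idx <- seq_index(sequence)
  L <- length(idx)
  if (!pad && L <= max_lag) {
    rlang::abort(sprintf("sequence length %d must exceed max_lag %d", L, max_lag))
  }
  pnames <- setdiff(names(props), "aa")
  out <- numeric(0)
  for (type in c("mb", "moran", "geary")) {
    for (pn in pnames) {
      x <- props[[pn]][idx]
      xbar <- mean(x)
      v <- sum((x - xbar)^2)
      vals <- vapply(seq_len(max_lag), function(d) {
        if (d >= L) return(0)
        n <- L - d
        x1 <- x[seq_len(n)]
        x2 <- x[seq_len(n) + d]
        switch(type,
          mb = sum(x1 * x2) / n,
          moran = if (v == 0) 0 else (sum((x1 - xbar) * (x2 - xbar)) / n) / (v / L),
          geary = if (v == 0) 0 else (sum((x1 - x2)^2) / (2 * n)) / (v / (L - 1))
        )
      }, numeric(1))
      out <- c(out, setNames(vals, paste0(type, "_", pn, "_lag", seq_len(max_lag))))
    }
  }
  out
}

qso_tau <- function(idx, dmat, max_lag) {
  L <- length(idx)
  vapply(seq_len(max_lag), function(d) {
    if (d >= L) return(0)
    n <- L - d
    sum(dmat[cbind(idx[seq_len(n)], idx[seq_len(n) + d])]^2)
  }, numeric(1))
}

#' Quasi-sequence-order (QSO) descriptors
#'
#' Composition terms coupled with sequence-order terms derived from a
#' physicochemical distance matrix. With residue frequencies f and coupling
#' terms \eqn{\tau_d = \sum_i d(s_i, s_{i+d})^2}, the components are
#' \eqn{X_r = f_r / (\sum f + w \sum \tau)} for the 20 residues and
#' \eqn{X_{20+d} = w \tau_d / (\sum f + w \sum \tau)} for lags 1..`max_lag`;
#' all components share one denominator and sum to 1.
#'
#' @inheritParams compute_autocorrelation
#' @param dmat 20 x 20 amino-acid distance matrix, as [aa_distance_matrix()].
#' @param weight Sequence-order weight w (>= 0); `weight = 0` reduces the
#'   composition terms to [compute_aac()].
#' @return Named numeric vector of length `20 + max_lag`.
#' @export
compute_qso <- function(sequence, dmat = aa_distance_matrix(),
                        max_lag = 30L, weight = 0.1, pad = FALSE) {
  idx <- seq_index(sequence)
  L <- length(idx)
  if (!pad && L <= max_lag) {
    rlang::abort(sprintf("sequence length %d must exceed max_lag %d", L, max_lag))
  }
  stopifnot(weight >= 0)
  f <- tabulate(idx, 20L) / L
  tau <- qso_tau(idx, dmat, max_lag)
  denom <- sum(f) + weight * sum(tau)
  setNames(
    c(f / denom, weight * tau / denom),
    c(paste0("qso_f_", AA20), paste0("qso_tau_lag", seq_len(max_lag)))
  )
}

#' Amphiphilic pseudo amino-acid composition (APAAC)
#'
#' Composition terms coupled with amphiphilic correlation factors computed
#' from standardized hydropathy and hydrophilicity profiles:
#' \eqn{\tau_{2d-1} = \frac{1}{L-d}\sum_i h^{(1)}_i h^{(1)}_{i+d}} and
#' \eqn{\tau_{2d} = \frac{1}{L-d}\sum_i h^{(2)}_i h^{(2)}_{i+d}}. Components
#' share the denominator \eqn{\sum f + w \sum \tau} and sum to 1.
#'
#' @inheritParams compute_autocorrelation
#' @param weight Correlation-factor weight w (>= 0).
#' @return Named numeric vector of length `20 + 2 * max_lag`.
#' @export
compute_apaac <- function(sequence, props = aa_properties(),
                          max_lag = 30L, weight = 0.05, pad = FALSE) {
  idx <- seq_index(sequence)
  L <- length(idx)
  if (!pad && L <= max_lag) {
    rlang::abort(sprintf("sequence length %d must exceed max_lag %d", L, max_lag))
  }
  stopifnot(weight >= 0)
  h1 <- props$hydropathy[idx]
  h2 <- props$hydrophilicity[idx]
  f <- tabulate(idx, 20L) / L
  tau <- numeric(2L * max_lag)
  for (d in seq_len(max_lag)) {
    if (d >= L) next
    n <- L - d
    tau[2L * d - 1L] <- sum(h1[seq_len(n)] * h1[seq_len(n) + d]) / n
    tau[2L * d] <- sum(h2[seq_len(n)] * h2[seq_len(n) + d]) / n
  }
  denom <- sum(f) + weight * sum(tau)
  setNames(
    c(f / denom, weight * tau / denom),
    c(paste0("apaac_f_", AA20), paste0("apaac_tau", seq_len(2L * max_lag)))
  )
}

#' Protein featurization configuration
#'
#' Fixes the descriptor manifest: which families are enabled and with which
#' parameters. Every feature matrix produced under one configuration has the
#' same columns in the same order; the configuration (including the property
#' tables) is hashed so downstream consumers can verify manifest identity.
#'
#' @param families Character subset of
#'   `c("aac", "dpc", "autocorr", "qso", "apaac")`.
#' @param max_lag Maximum lag for autocorrelation/QSO/APAAC (default 30).
#' @param w_qso QSO sequence-order weight (default 0.1).
#' @param w_apaac APAAC correlation-factor weight (default 0.05).
#' @param lenient Strip non-standard residue letters instead of rejecting the
#'   record (default `FALSE`).
#' @return A `seqfeat_config` object.
#' @export
seqfeat_config <- function(families = c("aac", "dpc", "autocorr", "qso", "apaac"),
                           max_lag = 30L, w_qso = 0.1, w_apaac = 0.05,
                           lenient = FALSE) {
  families <- match.arg(families, several.ok = TRUE)
  props <- aa_properties()
  dmat <- aa_distance_matrix()
  cfg <- structure(
    list(
      families = families, max_lag = as.integer(max_lag),
      w_qso = w_qso, w_apaac = w_apaac, lenient = lenient,
      props = props, dmat = dmat
    ),
    class = "seqfeat_config"
  )
  cfg$names <- seqfeat_names(cfg)
  cfg$hash <- rlang::hash(cfg[c("families", "max_lag", "w_qso", "w_apaac", "props", "dmat", "names")])
  cfg
}

seqfeat_names <- function(cfg) {
  nprop <- length(setdiff(names(cfg$props), "aa"))
  out <- character(0)
  if ("aac" %in% cfg$families) out <- c(out, paste0("aac_", AA20))
  if ("dpc" %in% cfg$families) {
    out <- c(out, paste0("dpc_", rep(AA20, each = 20L), rep(AA20, times = 20L)))
  }
  if ("autocorr" %in% cfg$families) {
    pnames <- setdiff(names(cfg$props), "aa")
    for (type in c("mb", "moran", "geary")) {
      for (pn in pnames) {
        out <- c(out, paste0(type, "_", pn, "_lag", seq_len(cfg$max_lag)))
      }
    }
  }
  if ("qso" %in% cfg$families) {
    out <- c(out, paste0("qso_f_", AA20), paste0("qso_tau_lag", seq_len(cfg$max_lag)))
  }
  if ("apaac" %in% cfg$families) {
    out <- c(out, paste0("apaac_f_", AA20), paste0("apaac_tau", seq_len(2L * cfg$max_lag)))
  }
  out
}

featurize_one_protein <- function(sequence, cfg) {
  out <- numeric(0)
  if ("aac" %in% cfg$families) out <- c(out, compute_aac(sequence))
  if ("dpc" %in% cfg$families) out <- c(out, compute_dpc(sequence))
  if ("autocorr" %in% cfg$families) {
    out <- c(out, compute_autocorrelation(sequence, cfg$props, cfg$max_lag, pad = TRUE))
  }
  if ("qso" %in% cfg$families) {
    out <- c(out, compute_qso(sequence, cfg$dmat, cfg$max_lag, cfg$w_qso, pad = TRUE))
  }
  if ("apaac" %in% cfg$families) {
    out <- c(out, compute_apaac(sequence, cfg$props, cfg$max_lag, cfg$w_apaac, pad = TRUE))
  }
  out
}

#' Featurize a table of proteins
#'
#' Computes the configured descriptor families for every protein of at least
#' 30 residues. Shorter sequences (and, in lenient mode, records emptied by
#' stripping) are excluded and recorded in a skip log rather than aborting
#' the batch. Sequences whose length does not exceed `max_lag` have the
#' out-of-range lag terms emitted as 0 so the descriptor width is constant.
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param config A [seqfeat_config()].
#' @return A tibble with column `id` followed by one numeric column per
#'   descriptor. Attributes: `skipped` (tibble `id`, `reason`),
#'   `manifest_hash` (configuration hash).
#' @export
#' @examples
#' prots <- tibble::tibble(id = "p1", sequence = strrep("ACDK", 10))
#' dim(featurize_proteins(prots, seqfeat_config(families = "aac")))
featurize_proteins <- function(proteins, config = seqfeat_config()) {
  proteins <- validate_proteins(proteins, lenient = config$lenient)
  len <- nchar(proteins$sequence)
  keep <- len >= MIN_SEQ_LEN
  skipped <- tibble::tibble(
    id = proteins$id[!keep],
    reason = sprintf("sequence length %d < %d", len[!keep], MIN_SEQ_LEN)
  )
  kept <- proteins[keep, ]
  if (nrow(kept) == 0L) {
    rlang::abort("no featurizable proteins (all sequences shorter than 30 AA)")
  }
  mat <- t(vapply(
    kept$sequence, featurize_one_protein,
    FUN.VALUE = numeric(length(config$names)), cfg = config,
    USE.NAMES = FALSE
  ))
  colnames(mat) <- config$names
  stopifnot(all(is.finite(mat)))
  out <- dplyr::bind_cols(tibble::tibble(id = kept$id), tibble::as_tibble(mat))
  attr(out, "skipped") <- skipped
  attr(out, "manifest_hash") <- config$hash
  out
}

#' Write a feature matrix (and its skip log) to disk
#'
#' @param features Feature tibble from [featurize_proteins()] or
#'   [featurize_ligands()].
#' @param path Output CSV path; the skip log, if non-empty, is written next
#'   to it with suffix `.skipped.tsv`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_csv(features, path)
  sk <- attr(features, "skipped")
  if (!is.null(sk) && nrow(sk) > 0) {
    readr::write_tsv(sk, paste0(sub("\\.csv$", "", path), ".skipped.tsv"))
  }
  invisible(path)
}
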