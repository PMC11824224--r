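## Synthetic inputs with the statistical structure the pipeline assumes:
## random protein sequences, binding energies as a planted affine signal in
## descriptor space rescaled to the envelope of the study's MD-derived
## energy table (median -17.935 kJ/mol, IQR 14.62, range [-46.085, -1.635]),
## and expression tables with planted salivary-selective, 4-fold-enriched
## and ubiquitous proteins. All generators are pure functions of
## (config, seed).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  )
  set.seed(seed)
  force(code)
}

#' Synthetic-data configuration
#'
#' Fixes the study conditions the generator emulates: library size and
#' sequence lengths, the planted descriptor signal and its noise, the
#' binding-energy envelope, and the planted expression classes.
#'
#' @param n_proteins Number of proteins (default 79, crossed with 3 ligands
#'   for 237 pairs).
#' @param length_range Sequence length range, min >= 30 (default 30-600).
#' @param signal_cols Descriptor columns carrying the planted signal
#'   (default five amino-acid composition columns).
#' @param signal_beta Coefficient vector over `signal_cols` (standardized
#'   columns; the overall scale is set by the envelope).
#' @param ligand_beta Weight of the standardized ligand molecular-weight
#'   term (default 0.5), giving each bait ligand its own energy offset.
#' @param noise_sd Gaussian noise, kJ/mol (default 2).
#' @param envelope Target energy envelope: `median`, `iqr`, `range`
#'   (defaults emulate the MD-derived table: -17.935, 14.62,
#'   [-46.085, -1.635] kJ/mol).
#' @param n_tissues,n_selective,n_enriched,n_ubiquitous Expression-table
#'   shape: number of non-salivary tissues plus the salivary gland, and the
#'   planted class counts.
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteins = 79L, length_range = c(30L, 600L),
                         signal_cols = paste0("aac_", c("A", "K", "D", "E", "R")),
                         signal_beta = c(-1, -1, 1, 1, -0.5),
                         ligand_beta = 0.5, noise_sd = 2,
                         envelope = list(
                           median = -17.935, iqr = 14.62,
                           range = c(-46.085, -1.635)
                         ),
                         n_tissues = 40L, n_selective = 5L, n_enriched = 5L,
                         n_ubiquitous = 20L, seed = 1L) {
  stopifnot(
    n_proteins >= 1, length_range[1] >= MIN_SEQ_LEN,
    length_range[2] >= length_range[1],
    length(signal_beta) == length(signal_cols), noise_sd >= 0,
    envelope$iqr > 0, n_tissues >= 3
  )
  structure(
    list(
      n_proteins = as.integer(n_proteins), length_range = as.integer(length_range),
      signal_cols = signal_cols, signal_beta = signal_beta,
      ligand_beta = ligand_beta, noise_sd = noise_sd, envelope = envelope,
      n_tissues = as.integer(n_tissues), n_selective = as.integer(n_selective),
      n_enriched = as.integer(n_enriched), n_ubiquitous = as.integer(n_ubiquitous),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

random_sequence <- function(len, weights = NULL) {
  paste(sample(AA20, len, replace = TRUE, prob = weights), collapse = "")
}

#' Generate random protein sequences
#'
#' Sequences are uniform over the 20-letter alphabet by default; an optional
#' residue weight vector biases the composition (used to plant
#' strong-binder compositions in screening libraries).
#'
#' @param cfg A [synth_config()].
#' @param n Number of proteins (default `cfg$n_proteins`).
#' @param weights Optional named length-20 residue weight vector.
#' @param prefix Identifier prefix.
#' @return Tibble `id`, `sequence`; reproducible for a fixed config.
#' @export
generate_proteins <- function(cfg, n = cfg$n_proteins, weights = NULL,
                              prefix = "SYNP") {
  if (!is.null(weights)) weights <- weights[AA20]
  with_seed(cfg$seed, {
    lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]), n, replace = TRUE)
    tibble::tibble(
      id = sprintf("%s%04d", prefix, seq_len(n)),
      sequence = vapply(lens, random_sequence, character(1), weights = weights)
    )
  })
}

#' Generate synthetic binding energies
#'
#' Energies for the full protein x ligand cross are an affine map of the
#' planted (standardized) descriptor columns plus a per-ligand
#' molecular-weight term and Gaussian noise, affinely rescaled so the
#' sample median and IQR hit the envelope targets exactly, then clipped to
#' the envelope range (clips counted, not silently absorbed).
#'
#' @param cfg A [synth_config()].
#' @param proteins Protein tibble (`id`, `sequence`).
#' @param ligands Ligand tibble (`id`, `smiles`); default the three bait
#'   ligands.
#' @return Tibble `protein_id`, `ligand_id`, `dg_bind` (kJ/mol).
#'   Attributes: `truth` (signal spec and per-pair noiseless signal),
#'   `n_clipped`.
#' @export
generate_energies <- function(cfg, proteins, ligands = bait_ligands()) {
  pf <- featurize_proteins(proteins, seqfeat_config(families = "aac"))
  missing_cols <- setdiff(cfg$signal_cols, names(pf))
  if (length(missing_cols)) {
    rlang::abort(paste0("unknown signal column(s): ", paste(missing_cols, collapse = ", ")))
  }
  lf <- featurize_ligands(ligands)
  std <- function(v) if (stats::sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / stats::sd(v)
  zs <- as.matrix(as.data.frame(lapply(pf[cfg$signal_cols], std)))
  prot_signal <- as.numeric(zs %*% cfg$signal_beta)
  lig_signal <- cfg$ligand_beta * std(lf$lig_MW)
  grid <- tidyr::expand_grid(protein_id = pf$id, ligand_id = lf$id)
  raw <- prot_signal[match(grid$protein_id, pf$id)] +
    lig_signal[match(grid$ligand_id, lf$id)]
  env <- cfg$envelope
  sigma_total <- env$iqr / (2 * stats::qnorm(0.75))
  sigma_signal <- sqrt(max(sigma_total^2 - cfg$noise_sd^2, 0.01))
  raw_sd <- stats::sd(raw)
  scaled <- if (raw_sd == 0) rep(0, length(raw)) else (raw - mean(raw)) / raw_sd * sigma_signal
  noisy <- with_seed(cfg$seed + 1L, scaled + stats::rnorm(length(scaled), 0, cfg$noise_sd))
  # exact affine match of sample median and IQR to the envelope
  obs_iqr <- stats::IQR(noisy, type = 7)
  dg <- if (obs_iqr == 0) {
    rep(env$median, length(noisy))
  } else {
    (noisy - stats::median(noisy)) / obs_iqr * env$iqr + env$median
  }
  clipped <- dg < env$range[1] | dg > env$range[2]
  dg <- pmin(pmax(dg, env$range[1]), env$range[2])
  out <- dplyr::mutate(grid, dg_bind = dg)
  attr(out, "truth") <- list(
    signal_cols = cfg$signal_cols, signal_beta = cfg$signal_beta,
    noiseless = scaled
  )
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Generate a synthetic tissue-expression table
#'
#' Plants four classes among the supplied proteins: salivary-selective
#' (detected only in the salivary gland), 4-fold-enriched (salivary at
#' least four times every other tissue, detected broadly), ubiquitous
#' (detected everywhere, no enrichment), and background (detected in the
#' salivary gland and over a third of tissues, below 4-fold enrichment).
#' Only the selective and enriched classes satisfy the salivary filter.
#'
#' @param cfg A [synth_config()].
#' @param protein_ids Character vector of protein ids.
#' @param classes Optional character vector (same length as `protein_ids`,
#'   values in `selective`, `enriched`, `ubiquitous`, `background`) fixing
#'   the class of each protein; by default classes are assigned at random
#'   with the configured counts.
#' @return Tibble `id`, `salivary_gland`, `tissue01` ...; attribute
#'   `classes` is a tibble (`id`, `class`) of the planted truth labels.
#' @export
generate_expression <- function(cfg, protein_ids, classes = NULL) {
  n <- length(protein_ids)
  if (is.null(classes)) {
    stopifnot(cfg$n_selective + cfg$n_enriched + cfg$n_ubiquitous <= n)
  }
  nt <- cfg$n_tissues
  tissue_names <- c("salivary_gland", sprintf("tissue%02d", seq_len(nt - 1L)))
  if (!is.null(classes)) {
    stopifnot(
      length(classes) == n,
      all(classes %in% c("selective", "enriched", "ubiquitous", "background"))
    )
  }
  with_seed(cfg$seed + 2L, {
    if (is.null(classes)) {
      classes <- rep("background", n)
      planted <- sample.int(n, cfg$n_selective + cfg$n_enriched + cfg$n_ubiquitous)
      classes[planted[seq_len(cfg$n_selective)]] <- "selective"
      classes[planted[cfg$n_selective + seq_len(cfg$n_enriched)]] <- "enriched"
      classes[planted[cfg$n_selective + cfg$n_enriched + seq_len(cfg$n_ubiquitous)]] <- "ubiquitous"
    }
    mat <- matrix(0, nrow = n, ncol = nt, dimnames = list(NULL, tissue_names))
    for (i in seq_len(n)) {
      mat[i, ] <- switch(classes[i],
        selective = c(runif(1, 20, 100), rep(0, nt - 1L)),
        enriched = {
          sal <- runif(1, 40, 100)
          c(sal, runif(nt - 1L, 1, sal / 4))
        },
        ubiquitous = c(runif(1, 10, 35), runif(nt - 1L, 10, 50)),
        background = {
          others <- rep(0, nt - 1L)
          on_idx <- sample.int(nt - 1L, ceiling((nt - 1L) * 0.6))
          others[on_idx] <- runif(length(on_idx), 5, 30)
          c(runif(1, 1, 10), others)
        }
      )
    }
    out <- dplyr::bind_cols(tibble::tibble(id = protein_ids), tibble::as_tibble(mat))
    attr(out, "classes") <- tibble::tibble(id = protein_ids, class = classes)
    out
  })
}

#' Write a full set of synthetic inputs to a directory
#'
#' Emits `proteins.fasta`, `energies.csv`, `expression.tsv` and
#' `truth_labels.json` (planted classes and signal spec) so the pipeline
#' can be exercised from files alone.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  proteins <- generate_proteins(cfg)
  energies <- generate_energies(cfg, proteins)
  expr <- generate_expression(cfg, proteins$id)
  write_fasta_proteins(proteins, file.path(dir, "proteins.fasta"))
  readr::write_csv(
    dplyr::rename(energies, dg_bind_kj_mol = "dg_bind"),
    file.path(dir, "energies.csv")
  )
  readr::write_tsv(expr, file.path(dir, "expression.tsv"))
  jsonlite::write_json(
    list(
      seed = cfg$seed,
      signal_cols = cfg$signal_cols,
      signal_beta = cfg$signal_beta,
      classes = attr(expr, "classes")
    ),
    file.path(dir, "truth_labels.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
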