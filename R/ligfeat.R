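## 2D ligand descriptors.
##
## Three families, mirroring the classical ligand-side QSAR feature sets:
## physicochemical properties (OpenBabel estimates), graph-theoretical
## indices computed on the heavy-atom molecular graph, and functional-group /
## atom-type counts. All descriptors are computed on the canonicalized
## molecular graph, so they are invariant to atom-order permutations of the
## input SMILES.

#' Bait and screening ligands
#'
#' The three PSMA ligands used to build the learning set: 2-PMPA
#' (2-(phosphonomethyl)pentanedioic acid, the library-screening ligand), MUD
#' (DCMC, a urea-based inhibitor), and DCFPyL (a second-generation urea-based
#' ligand). SMILES are resolved from the ligands' chemical names; override by
#' supplying your own ligand tibble.
#'
#' @return A tibble with columns `id` and `smiles`.
#' @export
#' @examples
#' bait_ligands()
bait_ligands <- function() {
  tibble::tibble(
    id = c("2-PMPA", "MUD", "DCFPyL"),
    smiles = c(
      "OC(=O)CCC(CP(O)(O)=O)C(O)=O",
      "CSCC(NC(=O)NC(CCC(O)=O)C(O)=O)C(O)=O",
      "OC(=O)CCC(NC(=O)NC(CCCCNC(=O)c1ccc(F)nc1)C(O)=O)C(O)=O"
    )
  )
}

#' Read a SMILES file into a ligand tibble
#'
#' One record per line: identifier, whitespace, SMILES string.
#'
#' @param path Path to the SMILES file.
#' @return Tibble with columns `id`, `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(trimws(lines), "\\s+", 2L)
  if (any(!nzchar(parts[, 2]))) {
    rlang::abort("each line must be '<id> <smiles>'")
  }
  tibble::tibble(id = parts[, 1], smiles = parts[, 2])
}

#' Read ligands from an SDF file
#'
#' @param path Path to an SDF/MOL file.
#' @return Tibble with columns `id`, `smiles` (canonical SMILES of each
#'   molecule block).
#' @export
read_sdf_ligands <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  smi <- ChemmineR::sdf2smiles(sdf)
  tibble::tibble(
    id = ChemmineR::sdfid(sdf),
    smiles = as.character(smi)
  )
}

lig_elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

graph_descriptors <- function(sdf) {
  cm <- ChemmineR::conMA(sdf, exclude = "H")
  nv <- nrow(cm)
  adj <- (cm > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  ords <- cm[el]
  dmat <- igraph::distances(g)
  finite_d <- dmat[is.finite(dmat)]
  ecc <- apply(dmat, 1, function(r) max(r[is.finite(r)]))
  c(
    n_heavy = nv,
    n_bonds = nrow(el),
    n_single = sum(ords == 1),
    n_double = sum(ords == 2),
    n_triple = sum(ords == 3),
    n_rings = nrow(el) - nv + igraph::components(g)$no,
    deg1 = sum(deg == 1), deg2 = sum(deg == 2),
    deg3 = sum(deg == 3), deg4 = sum(deg >= 4),
    wiener = sum(finite_d) / 2,
    diameter = max(ecc),
    radius = min(ecc),
    randic = if (nrow(el)) sum(1 / sqrt(deg[el[, 1]] * deg[el[, 2]])) else 0,
    zagreb_m1 = sum(deg^2),
    zagreb_m2 = if (nrow(el)) sum(deg[el[, 1]] * deg[el[, 2]]) else 0,
    mean_degree = mean(deg)
  )
}

#' Ligand featurization configuration
#'
#' @return A `ligfeat_config` object fixing the descriptor manifest (names
#'   and order) with its hash.
#' @export
ligfeat_config <- function() {
  nm <- c(
    paste0("lig_", c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")),
    paste0("lig_atom_", lig_elements),
    paste0("lig_", c(
      "n_heavy", "n_bonds", "n_single", "n_double", "n_triple", "n_rings",
      "deg1", "deg2", "deg3", "deg4", "wiener", "diameter", "radius",
      "randic", "zagreb_m1", "zagreb_m2", "mean_degree"
    )),
    paste0("lig_grp_", c(
      "RNH2", "R2NH", "R3N", "ROPO3", "ROH", "RCHO", "RCOR",
      "RCOOH", "RCOOR", "ROR", "RCCH", "RCN"
    )),
    paste0("lig_", c("arom_rings", "rings_sssr"))
  )
  structure(
    list(names = nm, hash = rlang::hash(nm)),
    class = "ligfeat_config"
  )
}

parse_formula_counts <- function(formula) {
  m <- stringr::str_match_all(formula, "([A-Z][a-z]?)(\\d*)")[[1]]
  cnt <- as.numeric(ifelse(m[, 3] == "", 1, m[, 3]))
  tapply(cnt, m[, 2], sum)
}

# Syntactic sanity check: the OpenBabel SMILES parser silently repairs some
# malformed strings, so unbalanced delimiters and dangling bonds are caught
# here before parsing.
smiles_syntax_ok <- function(smiles) {
  ch <- strsplit(smiles, "")[[1]]
  if (sum(ch == "(") != sum(ch == ")")) return(FALSE)
  if (sum(ch == "[") != sum(ch == "]")) return(FALSE)
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (any(depth < 0)) return(FALSE)
  if (length(ch) && ch[length(ch)] %in% c("=", "#", "-", "/", "\\", "(", ".")) return(FALSE)
  bare <- gsub("\\[[^]]*\\]", "", smiles)
  digits <- unlist(stringr::str_extract_all(bare, "(?<=%)[0-9]{2}|[0-9]"))
  if (length(digits) && any(table(digits) %% 2 != 0)) return(FALSE)
  TRUE
}

featurize_one_ligand <- function(id, smiles, cfg) {
  reject <- function(msg) {
    rlang::abort(sprintf("ligand '%s': unparseable structure (%s)", id, msg))
  }
  if (!smiles_syntax_ok(smiles)) reject("malformed SMILES syntax")
  prop <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, ChemmineOB::prop_OB),
    error = function(e) reject(conditionMessage(e))
  )
  if (is.list(prop) && !is.data.frame(prop)) {
    if (length(prop) == 0L) reject("no molecule parsed")
    prop <- prop[[1]]
  }
  if (!nzchar(prop$formula[1])) reject("empty molecular graph")
  counts <- parse_formula_counts(prop$formula[1])
  elem <- setNames(numeric(length(lig_elements)), lig_elements)
  hit <- intersect(names(counts), lig_elements)
  elem[hit] <- counts[hit]
  n_heavy <- sum(counts[setdiff(names(counts), "H")])
  if (n_heavy == 0) reject("no heavy atoms")
  phys <- as.numeric(prop[1, c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")])
  if (n_heavy >= 2) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, id)))
    if (!ChemmineR::validSDF(sdf)[1]) reject("invalid molecule block")
    gr <- graph_descriptors(sdf[[1]])
    grp <- as.numeric(ChemmineR::groups(sdf, type = "countMA")[1, ])
    rng <- ChemmineR::rings(sdf[[1]], upper = 12, type = "count", arom = TRUE)
    arom <- as.numeric(rng["AROMATIC"])
    sssr <- as.numeric(rng["RINGS"])
  } else {
    # single heavy atom: trivial graph, no rings or functional groups
    gr <- c(
      n_heavy = 1, n_bonds = 0, n_single = 0, n_double = 0, n_triple = 0,
      n_rings = 0, deg1 = 0, deg2 = 0, deg3 = 0, deg4 = 0, wiener = 0,
      diameter = 0, radius = 0, randic = 0, zagreb_m1 = 0, zagreb_m2 = 0,
      mean_degree = 0
    )
    grp <- numeric(12L)
    arom <- 0
    sssr <- 0
  }
  vals <- c(phys, elem, gr, grp, arom, sssr)
  vals[!is.finite(vals)] <- 0
  setNames(vals, cfg$names)
}

#' Featurize a table of ligands
#'
#' Computes the fixed 2D descriptor manifest for each ligand: OpenBabel
#' physicochemical properties, element and functional-group counts, ring
#' counts, and graph-theoretical indices (Wiener, Randic, Zagreb, eccentric)
#' on the heavy-atom graph. Descriptors undefined for a molecule are imputed
#' as 0.
#'
#' @param ligands Tibble with columns `id` and `smiles`.
#' @param config A [ligfeat_config()].
#' @return A tibble with column `id` followed by one numeric column per
#'   descriptor; attribute `manifest_hash` carries the manifest hash.
#' @export
#' @examples
#' featurize_ligands(bait_ligands())[, 1:5]
featurize_ligands <- function(ligands, config = ligfeat_config()) {
  stopifnot(all(c("id", "smiles") %in% names(ligands)))
  mat <- t(vapply(
    seq_len(nrow(ligands)),
    function(i) featurize_one_ligand(ligands$id[i], ligands$smiles[i], config),
    numeric(length(config$names))
  ))
  colnames(mat) <- config$names
  out <- dplyr::bind_cols(tibble::tibble(id = ligands$id), tibble::as_tibble(mat))
  attr(out, "manifest_hash") <- config$hash
  out
}
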