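#' @title Node and edge featurization
#' @description Residue-level node features (type/charge/polarity one-hots,
#'   buried surface area, PSSM-derived columns) and the tanh-normalized
#'   distance edge feature.
#' @name features
NULL

#' Edge interaction strength from a minimal inter-residue distance
#'
#' The minimal heavy-atom distance x (Angstrom) between two residues is
#' normalized to an interaction strength e = tanh(-x/2 + 2) + 1, a smooth,
#' strictly decreasing map with e(0) = tanh(2)+1 ~ 1.96 and e -> 0 for large
#' distances. The same transform is applied to internal and external edges.
#'
#' @param x Non-negative numeric vector of distances (Angstrom).
#' @return Interaction strengths in (0, tanh(2)+1].
#' @export
edge_strength <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    grappi_stop("distances must be finite and >= 0", "grappi_usage_error")
  tanh(-x / 2 + 2) + 1
}

#' One-hot residue-type encoding over the 20 canonical amino acids
#'
#' @param resid Character vector of 3-letter residue names.
#' @return Matrix with `length(resid)` rows and 20 columns (named
#'   `type_<AA3>`); non-canonical names give an all-zero row with a warning.
#' @export
residue_type_onehot <- function(resid) {
  i <- match(toupper(resid), AA3)
  m <- matrix(0, length(resid), 20,
              dimnames = list(NULL, paste0("type_", AA3)))
  ok <- !is.na(i)
  m[cbind(which(ok), i[ok])] <- 1
  if (any(!ok))
    warning(paste0("non-canonical residue(s) encoded as zero vector: ",
                   paste(unique(resid[!ok]), collapse = ",")))
  m
}

#' Formal side-chain charge at pH 7
#'
#' ARG/LYS +1, ASP/GLU -1, HIS +0.1 (partial-protonation approximation),
#' all others (and non-canonical residues) 0.
#'
#' @param resid Character vector of 3-letter residue names.
#' @return Numeric vector of charges.
#' @export
residue_charge <- function(resid) {
  out <- .AA_CHARGE[toupper(resid)]
  out[is.na(out)] <- 0
  unname(out)
}

#' One-hot polarity class encoding
#'
#' Four classes: apolar, polar, positively charged, negatively charged
#' (standard pH-7 chemistry; 9/7/2/2 residues respectively).
#'
#' @param resid Character vector of 3-letter residue names.
#' @return Matrix with 4 columns `polarity_<class>`; non-canonical rows are
#'   all zero.
#' @export
residue_polarity_onehot <- function(resid) {
  cls <- .AA_POLARITY[toupper(resid)]
  i <- match(cls, POLARITY_CLASSES)
  m <- matrix(0, length(resid), 4,
              dimnames = list(NULL, paste0("polarity_", POLARITY_CLASSES)))
  ok <- !is.na(i)
  m[cbind(which(ok), i[ok])] <- 1
  m
}

# ---------------------------------------------------------------------------
# Solvent-accessible surface area (Shrake-Rupley)

.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# canonical (PCA) orientation of a coordinate set with deterministic sign
# fixing: returns a 3x3 rotation such that sample directions generated in
# this frame co-rotate with rigid transforms of the input. Sign ambiguity is
# resolved on the projected coordinates (rotation invariant up to sign).
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  X <- sweep(xyz, 2, colMeans(xyz))
  V <- svd(X, nu = 0)$v
  S <- X %*% V
  for (j in 1:3) if (S[which.max(abs(S[, j])), j] < 0) V[, j] <- -V[, j]
  V
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-spiral sampling with `n_points` test points per atom
#' and a probe radius of 1.4 A (water). Van der Waals radii: C 1.70, N 1.55,
#' O 1.52, S 1.80 A (others default to 1.70).
#'
#' @details Sample directions are generated in a canonical (PCA) frame of
#'   each atom's `group` (by default the whole coordinate set), so computed
#'   areas are invariant under rigid transforms of the input by construction.
#'   Grouping by chain makes the sampling of a chain's atoms identical
#'   whether the chain is evaluated in isolation or inside a complex, which
#'   in turn makes buried surface areas exactly non-negative.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param element Character vector of element symbols, length n.
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere test points per atom.
#' @param group Optional factor of length n (e.g. chain ids) controlling the
#'   sampling frame; `NULL` treats all atoms as one group.
#' @return Numeric vector of per-atom SASA (Angstrom^2).
#' @export
sasa_atoms <- function(xyz, element, probe = 1.4, n_points = 100L,
                       group = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n == 0L) return(numeric(0))
  if (is.null(group)) group <- rep(1L, n)
  r <- unname(.VDW[toupper(element)])
  r[is.na(r)] <- 1.70
  R <- r + probe
  sp <- sphere_points(n_points)
  dir_of <- lapply(split(seq_len(n), group), function(ix)
    sp %*% t(canonical_frame(xyz[ix, , drop = FALSE])))
  gid <- as.character(group)
  D <- cross_dist(xyz, xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < R[i] + R & seq_len(n) != i)
    pts <- sweep(dir_of[[gid[i]]] * R[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        acc <- acc & d2 > R[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    out[i] <- 4 * pi * R[i]^2 * frac
  }
  out
}

#' Per-residue SASA of a structure
#'
#' @param structure A `grappi_structure`.
#' @param probe,n_points Passed to [sasa_atoms()].
#' @return Named numeric vector keyed by residue key (`chain:resno:ins`).
#' @export
residue_sasa <- function(structure, probe = 1.4, n_points = 100L) {
  s <- sasa_atoms(coords(structure), structure$atoms$element, probe, n_points,
                  group = structure$atoms$chain)
  rowsum(s, residue_keys(structure))[, 1]
}

# per-residue BSA for all residues: isolated-chain SASA minus complex SASA
bsa_all <- function(structure, probe = 1.4, n_points = 100L) {
  cplx <- residue_sasa(structure, probe, n_points)
  iso <- numeric(0)
  for (ch in structure_chains(structure)) {
    sub <- new_structure(structure$id,
                         structure$atoms[structure$atoms$chain == ch, ,
                                         drop = FALSE])
    iso <- c(iso, residue_sasa(sub, probe, n_points))
  }
  pmax(iso[names(cplx)] - cplx, 0)
}

#' Buried surface area of one residue
#'
#' SASA of the residue computed on its isolated chain minus its SASA in the
#' complex; clamped at zero (burial can only reduce accessibility, small
#' negative values are sampling noise).
#'
#' @param structure A two-chain `grappi_structure`.
#' @param node Residue key string `chain:resno:ins`, or a one-row data.frame
#'   with `chain`, `resno`, `ins` columns.
#' @param probe,n_points Passed to [sasa_atoms()].
#' @return BSA in Angstrom^2.
#' @export
buried_surface_area <- function(structure, node, probe = 1.4, n_points = 100L) {
  if (is.data.frame(node)) node <- paste(node$chain, node$resno, node$ins, sep = ":")
  a <- structure$atoms
  key <- residue_keys(structure)
  if (!node %in% key)
    grappi_stop(paste0("residue not in structure: ", node), "grappi_usage_error")
  ch <- a$chain[match(node, key)]
  iso <- new_structure(structure$id, a[a$chain == ch, , drop = FALSE])
  s_iso <- residue_sasa(iso, probe, n_points)[node]
  s_cplx <- residue_sasa(structure, probe, n_points)[node]
  unname(pmax(s_iso - s_cplx, 0))
}

# ---------------------------------------------------------------------------
# PSSM profiles

#' Parse a per-chain PSSM file
#'
#' Expected format: tab-separated text with a header row, then one row per
#' residue: residue number, one-letter residue code, 20 substitution scores
#' (columns ordered as [AA1]), and the positional information content.
#'
#' @param path PSSM file path.
#' @param chain_id Chain identifier the profile belongs to (metadata, used in
#'   error messages and alignment checks).
#' @return A `grappi_pssm`: list with `chain`, `resno`, `res`, `scores`
#'   (n x 20 matrix, columns [AA1]), `ic` (length-n vector).
#' @export
parse_pssm <- function(path, chain_id) {
  if (!file.exists(path))
    grappi_stop(paste0("PSSM file not found: ", path), "grappi_io_error")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("resno", "res", AA1, "ic")
  if (!all(need %in% names(df)))
    grappi_stop(sprintf("malformed PSSM %s (chain %s): missing column(s) %s",
                        path, chain_id,
                        paste(setdiff(need, names(df)), collapse = ",")),
                "grappi_parse_error")
  scores <- as.matrix(df[, AA1])
  if (anyNA(scores) || any(!is.finite(scores)) || anyNA(df$resno))
    grappi_stop(sprintf("malformed PSSM %s (chain %s): non-numeric scores",
                        path, chain_id), "grappi_parse_error")
  structure(list(chain = chain_id, resno = as.integer(df$resno),
                 res = as.character(df$res), scores = scores,
                 ic = as.numeric(df$ic)),
            class = "grappi_pssm")
}

pssm_row <- function(profile, resno, resid) {
  i <- match(resno, profile$resno)
  if (is.na(i))
    grappi_stop(sprintf("residue %d missing from PSSM for chain %s",
                        resno, profile$chain), "grappi_pssm_error")
  code <- aa3_to_aa1(resid)
  if (code != "X" && profile$res[i] != code)
    grappi_stop(sprintf(
      "PSSM residue-code mismatch for chain %s residue %d: structure %s vs profile %s",
      profile$chain, resno, code, profile$res[i]), "grappi_pssm_error")
  i
}

#' Conservation score of a residue from its PSSM profile
#'
#' Defined as the substitution score of the residue's own amino-acid type
#' (the diagonal read-out of its PSSM row); a package convention, since
#' profile formats carry no dedicated conservation column.
#'
#' @param profile A `grappi_pssm`.
#' @param node One-row data.frame with `resno` and `resid` (3-letter) columns,
#'   or a list with those fields.
#' @return Scalar conservation score (0 with a warning for non-canonical
#'   residues).
#' @export
conservation_score <- function(profile, node) {
  code <- aa3_to_aa1(node$resid)
  if (code == "X") {
    warning(paste0("non-canonical residue ", node$resid,
                   ": conservation set to 0"))
    return(0)
  }
  i <- pssm_row(profile, node$resno, node$resid)
  unname(profile$scores[i, code])
}

# ---------------------------------------------------------------------------

#' Fill node and edge features of an interface graph
#'
#' Node feature columns appear in a fixed documented order: residue type
#' one-hot (20), charge (1), polarity one-hot (4), buried surface area (1) --
#' the default set, 26 columns -- then, when enabled, the PSSM profile (20),
#' information content (1) and conservation score (1), for 48 columns total.
#' Edge features are [edge_strength()] applied to the recorded minimal
#' distances of every internal and external edge.
#'
#' @param graph A `grappi_graph` from [build_graph()].
#' @param structure The structure the graph was built from (needed for BSA).
#' @param profiles Named list chain id -> `grappi_pssm` (required for the
#'   `pssm`, `ic` and `cons` features).
#' @param config A [graph_config()]; `config$features` selects the node
#'   feature set from `type`, `charge`, `polarity`, `bsa`, `pssm`, `ic`,
#'   `cons`.
#' @return The graph with `node_features`, `feature_names`,
#'   `internal_edge_feat` and `external_edge_feat` filled.
#' @export
featurize <- function(graph, structure = NULL, profiles = NULL,
                      config = graph_config()) {
  feats <- config$features
  known <- c("type", "charge", "polarity", "bsa", "pssm", "ic", "cons")
  bad <- setdiff(feats, known)
  if (length(bad))
    grappi_stop(paste0("unknown feature(s): ", paste(bad, collapse = ",")),
                "grappi_usage_error")
  nodes <- graph$nodes
  blocks <- list()
  if ("type" %in% feats)
    blocks$type <- suppressWarnings(residue_type_onehot(nodes$resid))
  if ("charge" %in% feats)
    blocks$charge <- matrix(residue_charge(nodes$resid),
                            dimnames = list(NULL, "charge"))
  if ("polarity" %in% feats)
    blocks$polarity <- residue_polarity_onehot(nodes$resid)
  if ("bsa" %in% feats) {
    if (is.null(structure))
      grappi_stop("BSA feature requires the source structure",
                  "grappi_usage_error")
    bsa <- bsa_all(structure)
    blocks$bsa <- matrix(unname(bsa[nodes$key]),
                         dimnames = list(NULL, "bsa"))
  }
  if (any(c("pssm", "ic", "cons") %in% feats)) {
    need <- unique(nodes$chain)
    if (is.null(profiles) || !all(need %in% names(profiles)))
      grappi_stop(paste0("PSSM profile missing for chain(s): ",
                         paste(setdiff(need, names(profiles)), collapse = ",")),
                  "grappi_pssm_error")
    rows <- mapply(function(ch, rn, rs) pssm_row(profiles[[ch]], rn, rs),
                   nodes$chain, nodes$resno, nodes$resid)
    if ("pssm" %in% feats) {
      m <- do.call(rbind, lapply(seq_len(nrow(nodes)), function(k)
        profiles[[nodes$chain[k]]]$scores[rows[k], ]))
      colnames(m) <- paste0("pssm_", AA1)
      blocks$pssm <- m
    }
    if ("ic" %in% feats)
      blocks$ic <- matrix(vapply(seq_len(nrow(nodes)), function(k)
        profiles[[nodes$chain[k]]]$ic[rows[k]], numeric(1)),
        dimnames = list(NULL, "ic"))
    if ("cons" %in% feats)
      blocks$cons <- matrix(vapply(seq_len(nrow(nodes)), function(k) {
        code <- aa3_to_aa1(nodes$resid[k])
        if (code == "X") 0 else profiles[[nodes$chain[k]]]$scores[rows[k], code]
      }, numeric(1)), dimnames = list(NULL, "cons"))
  }
  order_known <- intersect(known, feats)
  X <- do.call(cbind, blocks[order_known])
  graph$node_features <- X
  graph$feature_names <- colnames(X)
  graph$internal_edge_feat <- if (length(graph$internal_dist))
    edge_strength(graph$internal_dist) else numeric(0)
  graph$external_edge_feat <- edge_strength(graph$external_dist)
  graph
}
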