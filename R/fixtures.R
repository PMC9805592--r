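#' @title Synthetic fixtures: idealized complexes, decoy ensembles, profiles
#' @description Generates fully synthetic two-chain complexes with a designed
#'   interface, rigid-perturbation decoy ensembles of graded quality
#'   (emulating docking models), and synthetic per-chain PSSM files, so the
#'   whole pipeline can be built, tested and demonstrated without any
#'   external dataset. All geometry is idealized backbone (N, CA, C, O plus
#'   CB except glycine); one explicit seed determines every output bit.
#' @name fixtures
NULL

# rotation matrix about a unit axis (degrees), row-vector convention x %*% R
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t(R)   # transpose: column convention -> row-vector convention
}

chain_backbone <- function(n_res, chain, resid, z0, cb_dir, x0 = 0, jitter) {
  rows <- list()
  for (i in seq_len(n_res)) {
    x <- x0 + 3.8 * (i - 1)
    at <- rbind(N  = c(x - 1.00, -1.06, z0),
                CA = c(x, 0, z0),
                C  = c(x + 1.10, 1.05, z0),
                O  = c(x + 1.10, 1.05 + 1.23, z0))
    if (resid[i] != "GLY")
      at <- rbind(at, CB = c(x, 0, z0 + cb_dir * 1.54))
    el <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")[rownames(at)]
    rows[[i]] <- data.frame(chain = chain, resno = i, ins = "",
                            resid = resid[i], atom = rownames(at),
                            element = unname(el),
                            x = at[, 1], y = at[, 2], z = at[, 3],
                            canonical = TRUE, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df[, c("x", "y", "z")] <- df[, c("x", "y", "z")] +
    matrix(stats::runif(3 * nrow(df), -jitter, jitter), ncol = 3)
  rownames(df) <- NULL
  df
}

#' Generate an idealized two-chain reference complex
#'
#' Two extended poly-peptide chains (idealized backbone geometry, standard
#' bond lengths) face each other across a gap chosen so that at least five
#' cross-chain residue pairs sit within the 5 A native-contact cutoff:
#' C-beta atoms of both chains point into the interface. Residue types are
#' sampled from the 20 canonical amino acids (the first six interface
#' positions avoid glycine so their C-beta contacts always exist). A small
#' uniform coordinate jitter avoids degenerate exact ties; the seed fully
#' determines the output.
#'
#' @param n_res Residues per chain (default 10).
#' @param gap Inter-chain CA-plane separation, Angstrom (default 7: C-beta
#'   pairs then sit ~3.9 A apart).
#' @param chains Two chain ids (default A, B).
#' @param seed Integer seed.
#' @param id Structure id.
#' @param jitter Uniform coordinate jitter half-width, Angstrom.
#' @return A `grappi_structure`.
#' @export
make_reference_complex <- function(n_res = 10L, gap = 7.0,
                                   chains = c("A", "B"), seed = 1L,
                                   id = "ref", jitter = 0.12) {
  stopifnot(n_res >= 5, gap > 3.5, length(chains) == 2)
  set.seed(seed)
  pick <- function() {
    r <- sample(AA3, n_res, replace = TRUE)
    fixed <- seq_len(min(6L, n_res))
    r[fixed] <- sample(setdiff(AA3, "GLY"), length(fixed), replace = TRUE)
    r
  }
  resA <- pick(); resB <- pick()
  dfA <- chain_backbone(n_res, chains[1], resA, z0 = 0, cb_dir = +1,
                        x0 = 0, jitter = jitter)
  dfB <- chain_backbone(n_res, chains[2], resB, z0 = gap, cb_dir = -1,
                        x0 = 1.9, jitter = jitter)
  new_structure(id, rbind(dfA, dfB))
}

#' Generate a rigid-perturbation decoy ensemble from a reference complex
#'
#' Each decoy is the reference with its ligand chain (the second chain)
#' rigidly rotated about its own centroid and translated. Perturbation
#' levels grade decoy quality from near-native to fully dissociated, so
#' fnat decreases and lRMSD increases with level (statistically). The true
#' transform of every decoy is recorded in the manifest.
#'
#' @param reference A `grappi_structure` from [make_reference_complex()].
#' @param levels Numeric vector of translation magnitudes (Angstrom) per
#'   level; the rotation magnitude is `rotation_per_A * level` degrees.
#' @param n_per_level Decoys per level.
#' @param seed Integer seed.
#' @param rotation_per_A Degrees of rotation per Angstrom of translation.
#' @return List with `structures` (named list of `grappi_structure`) and
#'   `manifest` (data.frame: id, level, translation, rotation, axis, angle,
#'   translation vector and rotation center).
#' @export
make_decoys <- function(reference, levels = c(0, 1, 2, 4, 8),
                        n_per_level = 10L, seed = 7L, rotation_per_A = 4) {
  set.seed(seed)
  lig <- structure_chains(reference)[2]
  sel <- reference$atoms$chain == lig
  center <- colMeans(as.matrix(reference$atoms[sel, c("x", "y", "z")]))
  structures <- list()
  rows <- list()
  for (li in seq_along(levels)) {
    lv <- levels[li]
    for (k in seq_len(n_per_level)) {
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      tdir <- stats::rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
      angle <- rotation_per_A * lv
      tvec <- tdir * lv
      R <- rotation_matrix(axis, angle)
      id <- sprintf("%s_L%02d_d%02d", reference$id, li, k)
      dec <- transform_structure(reference, R, tvec, chain = lig,
                                 center = center)
      dec$id <- id
      structures[[id]] <- dec
      rows[[id]] <- data.frame(id = id, level = lv,
                               translation = lv, rotation = angle,
                               ax = axis[1], ay = axis[2], az = axis[3],
                               angle = angle,
                               tx = tvec[1], ty = tvec[2], tz = tvec[3],
                               cx = center[1], cy = center[2], cz = center[3],
                               stringsAsFactors = FALSE)
    }
  }
  list(structures = structures,
       manifest = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Re-apply a recorded decoy transform to the reference
#'
#' Bookkeeping check: reproduces a decoy's coordinates from the reference
#' and one manifest row.
#'
#' @param reference The reference `grappi_structure`.
#' @param manifest_row One row of a [make_decoys()] manifest.
#' @return A `grappi_structure` with the manifest row's id.
#' @export
apply_decoy_transform <- function(reference, manifest_row) {
  m <- manifest_row
  lig <- structure_chains(reference)[2]
  R <- rotation_matrix(c(m$ax, m$ay, m$az), m$angle)
  out <- transform_structure(reference, R, c(m$tx, m$ty, m$tz), chain = lig,
                             center = c(m$cx, m$cy, m$cz))
  out$id <- m$id
  out
}

#' Generate synthetic PSSM files for each chain of a structure
#'
#' Emulates iterative-search sequence profiles: per residue, 20 integer
#' substitution scores drawn around -1 with the residue's own column biased
#' strongly positive (around +6), plus a positive information-content
#' column. Files are named `<id>.<chain>.pssm` in the format read by
#' [parse_pssm()]. Deterministic for a seed.
#'
#' @param structure A `grappi_structure`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of file paths, one per chain.
#' @export
make_pssm <- function(structure, dir = tempdir(), seed = 11L) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (ch in structure_chains(structure)) {
    rt <- residue_table(structure)
    rt <- rt[rt$chain == ch, , drop = FALSE]
    n <- nrow(rt)
    scores <- matrix(round(stats::rnorm(n * 20, mean = -1, sd = 2)), n, 20,
                     dimnames = list(NULL, AA1))
    own <- match(aa3_to_aa1(rt$resid), AA1)
    ok <- !is.na(own)
    scores[cbind(which(ok), own[ok])] <- round(stats::rnorm(sum(ok), 6, 1))
    df <- data.frame(resno = rt$resno, res = aa3_to_aa1(rt$resid),
                     scores, ic = round(abs(stats::rnorm(n, 1, 0.4)), 3),
                     check.names = FALSE)
    path <- file.path(dir, sprintf("%s.%s.pssm", structure$id, ch))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    out[ch] <- path
  }
  out
}
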