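#' @title Docking-quality target values
#' @description Fraction of native contacts, interface and ligand RMSD and
#'   CAPRI quality classes of a docking model against a reference (bound)
#'   structure, plus label binarization and inverse-frequency class weights.
#'   Contact and interface cutoffs (5 and 10 Angstrom) and the class threshold
#'   table follow the CAPRI assessment convention.
#' @name targets
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Cross-chain residue contact set
#'
#' All (first chain, second chain) residue pairs whose minimal heavy-atom
#' distance is within `cutoff` (CAPRI native-contact convention: 5 A).
#'
#' @param structure A two-chain `grappi_structure`.
#' @param cutoff Contact distance, Angstrom.
#' @return Character vector of contact pairs `"keyA+keyB"` (residue keys
#'   `chain:resno:ins`), receptor-chain key first; empty if no contacts.
#' @export
contact_set <- function(structure, cutoff = 5.0) {
  M <- cross_residue_min_dist(structure)
  hit <- which(M <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(character(0))
  sort(paste(rownames(M)[hit[, 1]], colnames(M)[hit[, 2]], sep = "+"))
}

#' Fraction of native contacts (fnat)
#'
#' The fraction of the reference complex's cross-chain residue contacts that
#' the model reproduces. By construction capped between 0 and 1, which gives
#' all bad models the same weight regardless of how far they stray.
#'
#' @param model,reference Two-chain `grappi_structure`s with matching chain
#'   ids and residue numbering.
#' @param cutoff Contact distance, Angstrom (default 5, CAPRI convention).
#' @return fnat in \[0, 1\].
#' @export
fnat <- function(model, reference, cutoff = 5.0) {
  ref <- contact_set(reference, cutoff)
  if (!length(ref))
    grappi_stop("reference structure has zero cross-chain contacts",
                "grappi_usage_error")
  mod <- contact_set(model, cutoff)
  length(intersect(mod, ref)) / length(ref)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rotation and translation mapping `mobile` onto `target`;
#' the returned rotation is proper (determinant +1).
#'
#' @param mobile,target n x 3 coordinate matrices, equal n >= 3.
#' @return List with `rotation` (3 x 3, applied as `x %*% rotation`),
#'   `translation` (length 3), `rmsd`, and `fitted` (transformed mobile
#'   coordinates).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3 || ncol(target) != 3)
    grappi_stop("coordinate sets must be equal-length n x 3 matrices",
                "grappi_usage_error")
  if (nrow(mobile) < 3)
    grappi_stop("at least 3 points required for superposition",
                "grappi_usage_error")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  s <- svd(t(P) %*% Q)
  if (s$d[2] < 1e-8)
    grappi_stop("degenerate (collinear) geometry in superposition",
                "grappi_usage_error")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- sweep(P %*% R, 2, ct, "+")
  list(rotation = R, translation = as.numeric(ct - cm %*% R),
       rmsd = sqrt(mean(rowSums((fitted - target)^2))), fitted = fitted)
}

# matched backbone coordinates of model and reference over a residue key set;
# atoms present in only one of the two are dropped with a warning
matched_backbone <- function(model, reference, keys) {
  pick <- function(s) {
    a <- s$atoms
    k <- residue_keys(s)
    sel <- k %in% keys & a$atom %in% BACKBONE_ATOMS
    id <- paste(k[sel], a$atom[sel])
    list(id = id, xyz = as.matrix(a[sel, c("x", "y", "z")]))
  }
  m <- pick(model); r <- pick(reference)
  common <- intersect(m$id, r$id)
  if (length(common) < length(r$id))
    warning(sprintf("%d backbone atom(s) missing from the model dropped from RMSD",
                    length(r$id) - length(common)))
  if (length(common) < 3)
    grappi_stop("fewer than 3 matched backbone atoms", "grappi_usage_error")
  list(model = m$xyz[match(common, m$id), , drop = FALSE],
       reference = r$xyz[match(common, r$id), , drop = FALSE])
}

#' Interface RMSD (iRMSD)
#'
#' Backbone (N, CA, C, O) RMSD over the reference-defined interface residues
#' (cross-chain heavy-atom distance within `interface_cutoff`, CAPRI
#' convention 10 A) after optimal superposition of those same atoms.
#'
#' @inheritParams fnat
#' @param interface_cutoff Interface definition cutoff, Angstrom.
#' @return iRMSD in Angstrom.
#' @export
irmsd <- function(model, reference, interface_cutoff = 10.0) {
  M <- cross_residue_min_dist(reference)
  keys <- c(rownames(M)[apply(M, 1, min) <= interface_cutoff],
            colnames(M)[apply(M, 2, min) <= interface_cutoff])
  if (!length(keys))
    grappi_stop("reference has no interface at this cutoff",
                "grappi_no_interface")
  mb <- matched_backbone(model, reference, keys)
  superpose(mb$model, mb$reference)$rmsd
}

#' Ligand RMSD (lRMSD)
#'
#' The model is superposed on the reference receptor backbone (receptor = the
#' chain with more residues; ties broken by first chain id), then the backbone
#' RMSD over the ligand chain is reported without further fitting.
#'
#' @inheritParams fnat
#' @return lRMSD in Angstrom.
#' @export
lrmsd <- function(model, reference) {
  rt <- residue_table(reference)
  chs <- structure_chains(reference)
  n_res <- table(factor(rt$chain, levels = chs))
  receptor <- chs[which.max(n_res)]   # which.max takes the first on ties
  ligand <- setdiff(chs, receptor)
  rec_keys <- rt$key[rt$chain == receptor]
  lig_keys <- rt$key[rt$chain == ligand]
  rec <- matched_backbone(model, reference, rec_keys)
  sp <- superpose(rec$model, rec$reference)
  lig <- matched_backbone(model, reference, lig_keys)
  fitted <- sweep(lig$model %*% sp$rotation, 2, sp$translation, "+")
  sqrt(mean(rowSums((fitted - lig$reference)^2)))
}

#' CAPRI quality class from fnat, iRMSD and lRMSD
#'
#' high: fnat >= 0.5 and (lRMSD <= 1 or iRMSD <= 1); medium: fnat >= 0.3 and
#' (lRMSD <= 5 or iRMSD <= 2); acceptable: fnat >= 0.1 and (lRMSD <= 10 or
#' iRMSD <= 4); otherwise incorrect. Thresholds per the CAPRI assessment
#' convention.
#'
#' @param fnat,irmsd,lrmsd Numeric vectors (recycled to common length).
#' @return Character vector in
#'   `c("high", "medium", "acceptable", "incorrect")`.
#' @export
capri_class <- function(fnat, irmsd, lrmsd) {
  n <- max(length(fnat), length(irmsd), length(lrmsd))
  fnat <- rep_len(fnat, n); irmsd <- rep_len(irmsd, n); lrmsd <- rep_len(lrmsd, n)
  out <- rep("incorrect", n)
  out[fnat >= 0.1 & (lrmsd <= 10 | irmsd <= 4)] <- "acceptable"
  out[fnat >= 0.3 & (lrmsd <= 5 | irmsd <= 2)] <- "medium"
  out[fnat >= 0.5 & (lrmsd <= 1 | irmsd <= 1)] <- "high"
  out
}

#' Binarize fnat into acceptable (1) / non-acceptable (0)
#'
#' Models with fnat >= `threshold` are labelled acceptable. The default 0.3
#' is deliberately stricter than the CAPRI 0.1 "acceptable" fnat bound, which
#' is only meaningful combined with RMSD criteria; when fnat is used alone a
#' 0.3 cut avoids labelling poor models as positives.
#'
#' @param fnat Numeric vector in \[0, 1\].
#' @param threshold Inclusive threshold.
#' @return Integer vector of 0/1 labels.
#' @export
binarize_fnat <- function(fnat, threshold = 0.3) {
  as.integer(fnat >= threshold)
}

#' Inverse-frequency class weights
#'
#' Weight of class c proportional to 1/count(c), normalized to sum to 1 over
#' classes; used to balance the cross-entropy loss on imbalanced data.
#'
#' @param labels Vector of class labels (each class present at least once).
#' @return Named numeric vector of weights summing to 1.
#' @export
class_weights <- function(labels) {
  if (!length(labels))
    grappi_stop("empty label vector", "grappi_usage_error")
  cnt <- table(labels)
  if (length(cnt) < 2)
    grappi_stop("class weights require at least two classes",
                "grappi_usage_error")
  w <- 1 / as.numeric(cnt)
  w <- w / sum(w)
  names(w) <- names(cnt)
  w
}

#' Full docking-quality target record of a model against a reference
#'
#' @inheritParams fnat
#' @return List with `fnat`, `irmsd`, `lrmsd`, `capri_class`, `binary_label`.
#' @export
target_record <- function(model, reference) {
  f <- fnat(model, reference)
  ir <- irmsd(model, reference)
  lr <- lrmsd(model, reference)
  list(fnat = f, irmsd = ir, lrmsd = lr,
       capri_class = capri_class(f, ir, lr),
       binary_label = binarize_fnat(f))
}
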