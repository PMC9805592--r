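# Independent oracles and hand-built fixtures shared across the suite.
# Everything here is deliberately naive (double loops, grid searches, random
# sampling) so it stays independent of the package's implementation paths.

# -- brute-force residue-pair minimal distances -----------------------------

# all residue-pair minimal heavy-atom distances via explicit double loops
brute_pair_min <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, a$ins, sep = ":")
  keys <- unique(key)
  out <- list()
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      if (i >= j) next
      ai <- which(key == keys[i]); aj <- which(key == keys[j])
      dmin <- Inf
      for (p in ai) for (q in aj) {
        d <- sqrt((a$x[p] - a$x[q])^2 + (a$y[p] - a$y[q])^2 +
                    (a$z[p] - a$z[q])^2)
        if (d < dmin) dmin <- d
      }
      out[[paste(keys[i], keys[j], sep = "+")]] <-
        list(k1 = keys[i], k2 = keys[j],
             ch1 = a$chain[ai[1]], ch2 = a$chain[aj[1]], d = dmin)
    }
  }
  out
}

# brute-force node and edge sets at the given cutoffs
brute_graph <- function(structure, interface_cutoff = 8.5,
                        internal_cutoff = 3.0) {
  pm <- brute_pair_min(structure)
  cross <- Filter(function(p) p$ch1 != p$ch2, pm)
  contact <- sort(unique(unlist(lapply(cross, function(p)
    if (p$d <= interface_cutoff) c(p$k1, p$k2)))))
  ext <- sort(vapply(Filter(function(p)
    p$d <= interface_cutoff, cross),
    function(p) paste(p$k1, p$k2, sep = "+"), character(1)))
  internal <- Filter(function(p) {
    p$ch1 == p$ch2 && p$k1 %in% contact && p$k2 %in% contact &&
      p$d <= internal_cutoff
  }, pm)
  int <- sort(vapply(internal, function(p)
    paste(p$k1, p$k2, sep = "+"), character(1)))
  list(nodes = contact, external = unname(ext), internal = unname(int))
}

brute_contacts <- function(structure, cutoff = 5.0) {
  pm <- brute_pair_min(structure)
  cross <- Filter(function(p) p$ch1 != p$ch2 && p$d <= cutoff, pm)
  sort(unname(vapply(cross, function(p)
    paste(p$k1, p$k2, sep = "+"), character(1))))
}

# edge index matrix -> sorted "key+key" strings for comparison with the oracle
edge_strings <- function(graph, which = c("external", "internal")) {
  which <- match.arg(which)
  e <- graph[[paste0(which, "_edges")]]
  if (!nrow(e)) return(character(0))
  k <- graph$nodes$key
  sort(paste(pmin(k[e[, 1]], k[e[, 2]]), pmax(k[e[, 1]], k[e[, 2]]),
             sep = "+"))
}

# -- exhaustive-search rigid superposition oracle ---------------------------

rot_euler <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# coarse-to-fine grid search over Euler angles; translation optimal at the
# centroids for any fixed rotation
superpose_grid_oracle <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  rmsd_rot <- function(a, b, c) {
    R <- rot_euler(a, b, c)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- c(0, 0, 0); best_r <- rmsd_rot(0, 0, 0)
  step <- pi / 12
  grid <- function(ctr, half, by) {
    for (a in seq(ctr[1] - half, ctr[1] + half, by = by))
      for (b in seq(max(ctr[2] - half, 0), min(ctr[2] + half, pi), by = by))
        for (c in seq(ctr[3] - half, ctr[3] + half, by = by)) {
          r <- rmsd_rot(a, b, c)
          if (r < best_r) { best_r <<- r; best <<- c(a, b, c) }
        }
  }
  grid(c(pi, pi / 2, pi), pi, step)
  for (s in c(step, step / 5, step / 25, step / 125))
    grid(best, s, s / 5)
  best_r
}

# -- Monte-Carlo SASA oracle ------------------------------------------------

sasa_mc_oracle <- function(xyz, element, probe = 1.4, n_points = 1000L,
                           seed = 42L) {
  set.seed(seed)
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  r <- vdw[toupper(element)]; r[is.na(r)] <- 1.70
  R <- r + probe
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- matrix(rnorm(3 * n_points), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2))
    pts <- sweep(pts * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      acc <- acc & d2 > R[j]^2
    }
    out[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  out
}

# -- pair-counting AUC oracle ----------------------------------------------

auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# -- hand-written PDB fixture ----------------------------------------------

pdb_line <- function(record, serial, name, alt, resn, chain, resno, ins,
                     x, y, z, occ = 1, elem) {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resn, chain, resno, ins, x, y, z,
          occ, 0, elem)
}

# chains A (3 residues, 12 heavy atoms) and B (2 residues, 9 heavy atoms),
# plus hydrogens, an altloc pair, a water and a HETATM that must all vanish
write_fixture_pdb <- function(path) {
  bb <- function(serial, resn, chain, resno, x0, z0, ins = " ") {
    c(pdb_line("ATOM", serial, "N", " ", resn, chain, resno, ins,
               x0 - 1.0, -1.06, z0, 1, "N"),
      pdb_line("ATOM", serial + 1, "CA", " ", resn, chain, resno, ins,
               x0, 0, z0, 1, "C"),
      pdb_line("ATOM", serial + 2, "C", " ", resn, chain, resno, ins,
               x0 + 1.1, 1.05, z0, 1, "C"),
      pdb_line("ATOM", serial + 3, "O", " ", resn, chain, resno, ins,
               x0 + 1.1, 2.28, z0, 1, "O"))
  }
  lines <- c(
    bb(1, "ALA", "A", 1, 0, 0),
    pdb_line("ATOM", 5, "H", " ", "ALA", "A", 1, " ", 0.5, 0.5, 0.5, 1, "H"),
    bb(6, "SER", "A", 2, 3.8, 0),
    # altloc pair on CA of residue 3: keep the higher-occupancy A conformer
    pdb_line("ATOM", 10, "N", " ", "LEU", "A", 3, " ", 6.6, -1.06, 0, 1, "N"),
    pdb_line("ATOM", 11, "CA", "A", "LEU", "A", 3, " ", 7.6, 0, 0, 0.6, "C"),
    pdb_line("ATOM", 12, "CA", "B", "LEU", "A", 3, " ", 7.9, 0, 0, 0.4, "C"),
    pdb_line("ATOM", 13, "C", " ", "LEU", "A", 3, " ", 8.7, 1.05, 0, 1, "C"),
    pdb_line("ATOM", 14, "O", " ", "LEU", "A", 3, " ", 8.7, 2.28, 0, 1, "O"),
    pdb_line("ATOM", 15, "HB2", " ", "LEU", "A", 3, " ", 7, 1, 1, 1, "H"),
    bb(16, "GLY", "B", 1, 1.9, 6.0),
    bb(20, "TYR", "B", 2, 5.7, 6.0),
    pdb_line("ATOM", 24, "CB", " ", "TYR", "B", 2, " ", 5.7, 0, 4.46, 1, "C"),
    pdb_line("HETATM", 25, "O", " ", "HOH", "A", 90, " ", 30, 30, 30, 1, "O"),
    pdb_line("HETATM", 26, "SE", " ", "MSE", "A", 91, " ", 35, 30, 30, 1, "SE"),
    "END")
  writeLines(lines, path)
  path
}

# -- hand-placed toy structures --------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# each residue: list(chain, resno, resid, xyz = vector or matrix of coords)
toy_structure <- function(residues, id = "toy") {
  rows <- lapply(residues, function(r) {
    xyz <- matrix(r$xyz, ncol = 3)
    data.frame(chain = r$chain, resno = r$resno, ins = "",
               resid = r$resid %||% "ALA",
               atom = paste0("C", seq_len(nrow(xyz))), element = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], canonical = TRUE,
               stringsAsFactors = FALSE)
  })
  grappi:::new_structure(id, do.call(rbind, rows))
}

# -- misc -------------------------------------------------------------------

random_rigid <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 15))
}

# consistent node permutation of a featurized graph
permute_graph <- function(g, perm) {
  inv <- order(perm)
  remap <- function(e) {
    if (!nrow(e)) return(e)
    m <- matrix(inv[e], ncol = 2)
    cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  }
  g$nodes <- g$nodes[perm, , drop = FALSE]
  g$node_features <- g$node_features[perm, , drop = FALSE]
  g$internal_edges <- remap(g$internal_edges)
  g$external_edges <- remap(g$external_edges)
  g
}

# small featurized graph set for network tests (default features, no PSSM)
fixture_graphs <- function(n_graphs = 6, seed = 20, n_res = 6,
                           levels = c(0, 2, 6)) {
  ref <- make_reference_complex(n_res = n_res, seed = seed)
  dec <- make_decoys(ref, levels = levels,
                     n_per_level = ceiling(n_graphs / length(levels)),
                     seed = seed + 1)
  g <- suppressMessages(build_graphs(dec$structures))
  list(ref = ref, decoys = dec, graphs = g)
}
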