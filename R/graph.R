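#' @title Interface graph construction
#' @description Converts a two-chain structure into a residue-level interface
#'   graph. Contact residues (any heavy atom within the interface cutoff of the
#'   other chain) form the nodes; external edges connect cross-chain node pairs
#'   within the interface cutoff, internal edges connect same-chain node pairs
#'   within the (much shorter) internal cutoff. All cutoff comparisons use
#'   minimal heavy-atom distances and are inclusive (<=).
#' @name graph_build
NULL

#' Graph construction configuration
#'
#' @param interface_cutoff Heavy-atom distance (Angstrom) defining contact
#'   residues and external edges. Default 8.5.
#' @param internal_cutoff Heavy-atom distance (Angstrom) defining internal
#'   (same-chain) edges between contact residues. Default 3.0.
#' @param features Character vector of node feature names to compute at
#'   featurization time; see [featurize()].
#' @return A `grappi_graph_config` list.
#' @export
graph_config <- function(interface_cutoff = 8.5, internal_cutoff = 3.0,
                         features = c("type", "charge", "polarity", "bsa")) {
  stopifnot(interface_cutoff > 0, internal_cutoff > 0,
            internal_cutoff <= interface_cutoff)
  structure(list(interface_cutoff = interface_cutoff,
                 internal_cutoff = internal_cutoff,
                 features = features),
            class = "grappi_graph_config")
}

# squared-distance-free pairwise distance between two coordinate matrices
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

# pool an atom-atom distance matrix to residue-residue minima
min_pool <- function(D, frow, fcol) {
  ri <- split(seq_len(nrow(D)), frow)
  ci <- split(seq_len(ncol(D)), fcol)
  out <- matrix(NA_real_, length(ri), length(ci),
                dimnames = list(names(ri), names(ci)))
  for (i in seq_along(ri)) {
    sub <- D[ri[[i]], , drop = FALSE]
    cm <- vapply(ci, function(jx) min(sub[, jx]), numeric(1))
    out[i, ] <- cm
  }
  out
}

# residue-residue minimal heavy-atom distance matrix between the two chains;
# rows/cols named by residue key, ordered as in residue_table
cross_residue_min_dist <- function(structure) {
  chs <- structure_chains(structure)
  if (length(chs) != 2L)
    grappi_stop("structure must have exactly two chains", "grappi_usage_error")
  a <- structure$atoms
  key <- residue_keys(structure)
  selA <- a$chain == chs[1]; selB <- a$chain == chs[2]
  D <- cross_dist(as.matrix(a[selA, c("x", "y", "z")]),
                  as.matrix(a[selB, c("x", "y", "z")]))
  fr <- factor(key[selA], levels = unique(key[selA]))
  fc <- factor(key[selB], levels = unique(key[selB]))
  min_pool(D, fr, fc)
}

#' Detect interface (contact) residues of a two-chain complex
#'
#' A residue is a contact residue if at least one of its heavy atoms lies
#' within `interface_cutoff` of any heavy atom of the other chain.
#'
#' @param structure A two-chain `grappi_structure`.
#' @param config A [graph_config()].
#' @return data.frame of contact residues (columns as [residue_table()]).
#' @export
detect_contact_residues <- function(structure, config = graph_config()) {
  M <- cross_residue_min_dist(structure)
  keepA <- rownames(M)[apply(M, 1, min) <= config$interface_cutoff]
  keepB <- colnames(M)[apply(M, 2, min) <= config$interface_cutoff]
  if (length(keepA) + length(keepB) == 0L)
    grappi_stop(sprintf("no interface between chains at cutoff %.2f A",
                        config$interface_cutoff), "grappi_no_interface")
  rt <- residue_table(structure)
  rt[rt$key %in% c(keepA, keepB), , drop = FALSE]
}

#' Build the residue-level interface graph of a two-chain complex
#'
#' Nodes are the contact residues in deterministic (chain, residue number,
#' insertion code) order. An external edge joins every cross-chain node pair
#' whose minimal heavy-atom distance is within the interface cutoff; an
#' internal edge joins every same-chain node pair within the internal cutoff.
#' Per-edge minimal distances are recorded for the later edge-feature
#' transform. Node features are left unfilled (see [featurize()]).
#'
#' @inheritParams detect_contact_residues
#' @return A `grappi_graph`.
#' @export
build_graph <- function(structure, config = graph_config()) {
  nodes <- detect_contact_residues(structure, config)
  rownames(nodes) <- NULL
  chs <- structure_chains(structure)
  a <- structure$atoms
  key <- residue_keys(structure)

  sel <- key %in% nodes$key
  ac <- a[sel, , drop = FALSE]; kc <- key[sel]

  # external edges: cross-chain minima among contact residues
  iA <- which(ac$chain == chs[1]); iB <- which(ac$chain == chs[2])
  ext <- matrix(integer(0), 0, 2); ext_d <- numeric(0)
  if (length(iA) && length(iB)) {
    D <- cross_dist(as.matrix(ac[iA, c("x", "y", "z")]),
                    as.matrix(ac[iB, c("x", "y", "z")]))
    M <- min_pool(D, factor(kc[iA], levels = unique(kc[iA])),
                  factor(kc[iB], levels = unique(kc[iB])))
    hit <- which(M <= config$interface_cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      ni <- match(rownames(M)[hit[, 1]], nodes$key)
      nj <- match(colnames(M)[hit[, 2]], nodes$key)
      ext <- cbind(pmin(ni, nj), pmax(ni, nj))
      ext_d <- M[hit]
      o <- order(ext[, 1], ext[, 2])
      ext <- ext[o, , drop = FALSE]; ext_d <- ext_d[o]
    }
  }
  if (nrow(ext) == 0L)
    grappi_stop("no interface edges at this cutoff", "grappi_no_interface")

  # internal edges: same-chain minima among contact residues
  int <- matrix(integer(0), 0, 2); int_d <- numeric(0)
  for (ch in chs) {
    ic <- which(ac$chain == ch)
    ks <- unique(kc[ic])
    if (length(ks) < 2L) next
    D <- cross_dist(as.matrix(ac[ic, c("x", "y", "z")]),
                    as.matrix(ac[ic, c("x", "y", "z")]))
    M <- min_pool(D, factor(kc[ic], levels = ks), factor(kc[ic], levels = ks))
    hit <- which(M <= config$internal_cutoff & upper.tri(M), arr.ind = TRUE)
    if (nrow(hit)) {
      ni <- match(rownames(M)[hit[, 1]], nodes$key)
      nj <- match(colnames(M)[hit[, 2]], nodes$key)
      int <- rbind(int, cbind(pmin(ni, nj), pmax(ni, nj)))
      int_d <- c(int_d, M[hit])
    }
  }
  if (nrow(int)) {
    o <- order(int[, 1], int[, 2])
    int <- int[o, , drop = FALSE]; int_d <- int_d[o]
  }

  structure(list(id = structure$id, nodes = nodes,
                 node_features = NULL, feature_names = character(0),
                 internal_edges = int, external_edges = ext,
                 internal_dist = int_d, external_dist = ext_d,
                 internal_edge_feat = NULL, external_edge_feat = NULL,
                 meta = list(chains = chs,
                             interface_cutoff = config$interface_cutoff,
                             internal_cutoff = config$internal_cutoff)),
            class = "grappi_graph")
}

#' Build and featurize interface graphs for a set of structures
#'
#' Convenience wrapper around [build_graph()] + [featurize()] for decoy
#' ensembles. Structures with no interface at the configured cutoff (e.g.
#' fully dissociated docking decoys) cannot be converted into graphs; with
#' `on_no_interface = "skip"` they are dropped with a message, matching how
#' scoring pipelines treat unconvertible models.
#'
#' @param structures List of two-chain `grappi_structure`s.
#' @param config A [graph_config()].
#' @param profiles Optional named list of `grappi_pssm` per chain id.
#' @param on_no_interface `"skip"` or `"stop"`.
#' @return Named list of featurized `grappi_graph`s.
#' @export
build_graphs <- function(structures, config = graph_config(), profiles = NULL,
                         on_no_interface = c("skip", "stop")) {
  on_no_interface <- match.arg(on_no_interface)
  out <- list()
  for (s in structures) {
    g <- tryCatch(featurize(build_graph(s, config), s, profiles, config),
                  grappi_no_interface = function(e) e)
    if (inherits(g, "grappi_no_interface")) {
      if (on_no_interface == "stop") stop(g)
      message("[grappi] skipped ", s$id, ": ", conditionMessage(g))
      next
    }
    out[[g$id]] <- g
  }
  out
}

#' @export
print.grappi_graph <- function(x, ...) {
  cat(sprintf(
    "<grappi_graph> id=%s  nodes=%d  internal_edges=%d  external_edges=%d  features=%s\n",
    x$id, nrow(x$nodes), nrow(x$internal_edges), nrow(x$external_edges),
    if (is.null(x$node_features)) "<unfilled>" else ncol(x$node_features)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# HDF5 serialization. One top-level group per graph id; edge indices are
# stored 0-based for language neutrality and converted back on read.

#' Write a collection of interface graphs (and optional targets) to HDF5
#'
#' Schema: one group per graph id containing `node_keys` (strings
#' `chain:resno:ins:resid`), `node_features` (float matrix), `internal_edge_index`
#' and `external_edge_index` (m x 2 integer, 0-based, i<j), `internal_edge_dist`
#' / `external_edge_dist` and `internal_edge_feat` / `external_edge_feat`
#' (float vectors), plus a `target` subgroup of named scalars. Feature column
#' names, chain ids and cutoffs are stored as group attributes.
#'
#' @param graphs List of `grappi_graph` with unique ids.
#' @param path Output HDF5 file (overwritten).
#' @param targets Optional named list: id -> named list/vector of scalar targets.
#' @return Invisibly, `path`.
#' @export
write_hdf5 <- function(graphs, path, targets = NULL) {
  ids <- vapply(graphs, function(g) g$id, character(1))
  if (anyDuplicated(ids))
    grappi_stop("duplicate graph ids", "grappi_usage_error")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (g in graphs) {
    grp <- g$id
    rhdf5::h5createGroup(path, grp)
    nk <- with(g$nodes, paste(chain, resno, ins, resid, sep = ":"))
    rhdf5::h5write(nk, path, paste0(grp, "/node_keys"))
    if (!is.null(g$node_features))
      rhdf5::h5write(g$node_features, path, paste0(grp, "/node_features"))
    rhdf5::h5write(matrix(as.integer(g$internal_edges - 1L), ncol = 2),
                   path, paste0(grp, "/internal_edge_index"))
    rhdf5::h5write(matrix(as.integer(g$external_edges - 1L), ncol = 2),
                   path, paste0(grp, "/external_edge_index"))
    rhdf5::h5write(as.numeric(g$internal_dist), path,
                   paste0(grp, "/internal_edge_dist"))
    rhdf5::h5write(as.numeric(g$external_dist), path,
                   paste0(grp, "/external_edge_dist"))
    if (!is.null(g$internal_edge_feat))
      rhdf5::h5write(as.numeric(g$internal_edge_feat), path,
                     paste0(grp, "/internal_edge_feat"))
    if (!is.null(g$external_edge_feat))
      rhdf5::h5write(as.numeric(g$external_edge_feat), path,
                     paste0(grp, "/external_edge_feat"))
    rhdf5::h5createGroup(path, paste0(grp, "/target"))
    tg <- targets[[g$id]]
    if (!is.null(tg)) {
      tg <- as.list(tg)
      for (nm in names(tg)) {
        val <- tg[[nm]]
        if (is.character(val) || is.factor(val)) val <- as.character(val)
        rhdf5::h5write(val, path, paste0(grp, "/target/", nm))
      }
    }
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, grp)
    rhdf5::h5writeAttribute(g$feature_names %||% character(0), gid, "feature_names")
    rhdf5::h5writeAttribute(g$meta$chains, gid, "chains")
    rhdf5::h5writeAttribute(g$meta$interface_cutoff, gid, "interface_cutoff")
    rhdf5::h5writeAttribute(g$meta$internal_cutoff, gid, "internal_cutoff")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

read_one_graph <- function(path, id) {
  g <- rhdf5::h5read(path, id, read.attributes = FALSE)
  at <- rhdf5::h5readAttributes(path, id)
  nk <- do.call(rbind, strsplit(as.character(g$node_keys), ":", fixed = TRUE))
  nodes <- data.frame(chain = nk[, 1], resno = as.integer(nk[, 2]),
                      ins = nk[, 3], resid = nk[, 4],
                      key = paste(nk[, 1], nk[, 2], nk[, 3], sep = ":"),
                      stringsAsFactors = FALSE)
  nf <- g$node_features
  fn <- as.character(at$feature_names %||% character(0))
  if (!is.null(nf)) {
    nf <- as.matrix(nf)
    if (length(fn) && ncol(nf) != length(fn))
      grappi_stop(sprintf(
        "schema mismatch in group '%s': %d feature columns vs %d feature names",
        id, ncol(nf), length(fn)), "grappi_schema_error")
    colnames(nf) <- fn
  }
  as_idx <- function(m) {
    m <- matrix(as.integer(m), ncol = 2)
    m + 1L
  }
  tg <- lapply(g$target %||% list(), function(v) if (is.array(v)) as.vector(v) else v)
  structure(list(id = id, nodes = nodes, node_features = nf,
                 feature_names = fn,
                 internal_edges = as_idx(g$internal_edge_index),
                 external_edges = as_idx(g$external_edge_index),
                 internal_dist = as.numeric(g$internal_edge_dist),
                 external_dist = as.numeric(g$external_edge_dist),
                 internal_edge_feat = if (!is.null(g$internal_edge_feat))
                   as.numeric(g$internal_edge_feat),
                 external_edge_feat = if (!is.null(g$external_edge_feat))
                   as.numeric(g$external_edge_feat),
                 target = tg,
                 meta = list(chains = as.character(at$chains),
                             interface_cutoff = as.numeric(at$interface_cutoff),
                             internal_cutoff = as.numeric(at$internal_cutoff))),
            class = "grappi_graph")
}

#' Read interface graphs back from an HDF5 file written by [write_hdf5()]
#'
#' @param path HDF5 file.
#' @param ids Optional character vector restricting which graphs to load
#'   (errors if an id is absent); `NULL` loads all, `character(0)` none.
#' @return Named list of `grappi_graph`, each carrying its `target` list.
#' @export
read_hdf5 <- function(path, ids = NULL) {
  if (!file.exists(path))
    grappi_stop(paste0("file not found: ", path), "grappi_io_error")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  avail <- ls$name[ls$otype == "H5I_GROUP"]
  if (is.null(ids)) ids <- avail
  missing <- setdiff(ids, avail)
  if (length(missing))
    grappi_stop(paste0("graph id(s) not in file: ",
                       paste(missing, collapse = ",")), "grappi_io_error")
  out <- lapply(ids, function(id) read_one_graph(path, id))
  names(out) <- ids
  out
}
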