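#' @title Protein structure input/output
#' @description Reading and writing of two-chain protein complexes as a typed
#'   hierarchy restricted to protein heavy atoms. Parsing is delegated to
#'   \pkg{bio3d}; the selection semantics (ATOM records only, requested chains
#'   only, hydrogens and waters removed, alternate locations resolved by
#'   occupancy) are applied on top.
#' @name structure_io
NULL

new_structure <- function(id, atoms) {
  stopifnot(is.data.frame(atoms))
  structure(list(id = id, atoms = atoms), class = "grappi_structure")
}

#' @export
print.grappi_structure <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("<grappi_structure> id=%s  chains=%s  residues=%d  atoms=%d\n",
              x$id, paste(structure_chains(x), collapse = ","),
              length(unique(rk)), nrow(x$atoms)))
  invisible(x)
}

#' Chain identifiers of a structure, in stored order
#' @param structure A `grappi_structure`.
#' @return Character vector of chain ids.
#' @export
structure_chains <- function(structure) unique(structure$atoms$chain)

#' Per-atom residue keys (`chain:resno:ins`)
#'
#' The triple (chain id, residue number, insertion code) uniquely identifies a
#' residue within a structure and is the node identity used across the package.
#'
#' @param structure A `grappi_structure`.
#' @return Character vector, one entry per atom.
#' @export
residue_keys <- function(structure) {
  with(structure$atoms, paste(chain, resno, ins, sep = ":"))
}

#' Residue table of a structure
#' @param structure A `grappi_structure`.
#' @return data.frame with one row per residue: `chain`, `resno`, `ins`,
#'   `resid`, `key`, in deterministic (chain, number, insertion code) order.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, a$ins, sep = ":")
  first <- !duplicated(key)
  r <- data.frame(chain = a$chain[first], resno = a$resno[first],
                  ins = a$ins[first], resid = a$resid[first],
                  key = key[first], stringsAsFactors = FALSE)
  r[order(match(r$chain, structure_chains(structure)), r$resno, r$ins), ,
    drop = FALSE]
}

#' Atom coordinates as a numeric matrix
#' @param structure A `grappi_structure`.
#' @return n x 3 matrix of coordinates in Angstrom.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Read a two-chain protein complex from a PDB file
#'
#' Parses ATOM records of the first model, keeps exactly the two requested
#' chains, removes hydrogens (and deuterium), waters and all HETATM-derived
#' residues, and resolves alternate locations by keeping the highest-occupancy
#' conformer (ties: first listed). Residues whose name is not one of the 20
#' canonical amino acids are retained but flagged via the `canonical` column;
#' their feature encoding is decided at featurization time.
#'
#' @param path Path to a PDB-format file.
#' @param chains Character vector of exactly two chain identifiers.
#' @return A `grappi_structure` whose `id` is the file stem.
#' @export
read_structure <- function(path, chains) {
  if (!file.exists(path))
    grappi_stop(paste0("file not found: ", path), "grappi_io_error")
  if (length(chains) != 2L || anyDuplicated(chains))
    grappi_stop("exactly two distinct chain ids are required",
                "grappi_usage_error")

  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^ATOM  ", lines)
  for (i in atom_idx) {
    ln <- lines[i]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz) || any(!is.finite(xyz)))
      grappi_stop(sprintf("unparsable ATOM record at line %d of %s", i, path),
                  "grappi_parse_error")
  }
  if (sum(grepl("^MODEL ", lines)) > 1L)
    warning("multiple MODEL records; only the first model is read")

  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  elem <- a$elesy
  guess <- toupper(sub("^[0-9]*", "", a$elety))
  elem[is.na(elem) | elem == ""] <- substr(guess[is.na(elem) | elem == ""], 1, 1)
  a$element <- toupper(elem)
  a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]

  missing <- setdiff(chains, unique(a$chain))
  if (length(missing))
    grappi_stop(paste0("chain not found: ", paste(missing, collapse = ",")),
                "grappi_chain_error")
  a <- a[a$chain %in% chains, , drop = FALSE]

  # alternate locations: per (residue, atom name) keep max occupancy, ties first
  grp <- paste(a$chain, a$resno, a$insert, a$elety, sep = ":")
  keep <- unlist(lapply(split(seq_len(nrow(a)), grp), function(ix) {
    ix[which.max(a$o[ix])]
  }), use.names = FALSE)
  a <- a[sort(keep), , drop = FALSE]

  for (ch in chains)
    if (!any(a$chain == ch))
      grappi_stop(paste0("chain has zero protein residues: ", ch),
                  "grappi_chain_error")

  atoms <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                      ins = a$insert, resid = toupper(a$resid),
                      atom = a$elety, element = a$element,
                      x = a$x, y = a$y, z = a$z,
                      canonical = is_canonical(a$resid),
                      stringsAsFactors = FALSE)
  atoms <- atoms[order(match(atoms$chain, chains), atoms$resno, atoms$ins), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  if (any(!atoms$canonical))
    warning(sprintf("%d non-canonical residue atom(s) retained and flagged",
                    sum(!atoms$canonical)))
  new_structure(tools::file_path_sans_ext(basename(path)), atoms)
}

#' Write a structure as standard PDB ATOM records
#'
#' Fixed-column wwPDB format with coordinates to three decimals. A structure
#' written and re-read reproduces residue keys and coordinates to 1e-3 A.
#'
#' @param structure A non-empty `grappi_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  if (is.null(a) || nrow(a) == 0L)
    grappi_stop("cannot write an empty structure", "grappi_usage_error")
  n <- nrow(a)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   insert = ifelse(a$ins == "", NA, a$ins),
                   elety = a$atom, eleno = seq_len(n),
                   o = rep(1, n), b = rep(0, n), elesy = a$element)
  invisible(path)
}

# Apply a rigid transform (rotation matrix R acting on row vectors, then
# translation t) to all coordinates, or to one chain only.
transform_structure <- function(structure, R, t, chain = NULL, center = c(0, 0, 0)) {
  a <- structure$atoms
  sel <- if (is.null(chain)) rep(TRUE, nrow(a)) else a$chain == chain
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, center) %*% R, 2, center + t, "+")
  a[sel, c("x", "y", "z")] <- xyz
  new_structure(structure$id, a)
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix, det corrected to +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
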