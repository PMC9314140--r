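# ---------------------------------------------------------------------------
# Structure container
#
# A structure3d is a thin S3 wrapper around an atom table. Columns mirror the
# PDB ATOM record fields we care about; hydrogens, waters and other
# heteroatoms are excluded on read because every downstream geometry
# (contacts, SASA, representative points) is defined on protein heavy atoms.
# ---------------------------------------------------------------------------

ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "element",
               "x", "y", "z", "o")

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns `chain` (single character), `resno`
#'   (integer author numbering), `insert` (insertion code, `""` if none),
#'   `resid` (3-letter residue name), `elety` (atom name), `element`
#'   (element symbol), `x`, `y`, `z` (coordinates in Angstrom) and `o`
#'   (occupancy).
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms) {
  missing <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms <- atoms[, ATOM_COLS]
  atoms$chain  <- as.character(atoms$chain)
  atoms$insert <- ifelse(is.na(atoms$insert), "", as.character(atoms$insert))
  atoms$resno  <- as.integer(atoms$resno)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(duplicated(unique(atoms$chain))))
    stop("duplicated chain ids")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  rs <- residue_table(x)
  cat("structure3d:", length(unique(x$atoms$chain)), "chain(s),",
      nrow(rs), "residues,", nrow(x$atoms), "heavy atoms\n")
  for (ch in unique(x$atoms$chain))
    cat("  chain ", ch, ": ", sum(rs$chain == ch), " residues\n", sep = "")
  invisible(x)
}

#' Residue key
#'
#' Residues are addressed throughout the package by a key
#' `"<chain>:<resno>:<icode>"` built from the author chain id, author
#' sequence number and insertion code (empty when absent).
#'
#' @param chain,resno,insert vectors of chain id, residue number, insertion
#'   code.
#' @return character vector of keys.
#' @export
res_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste(chain, resno, insert, sep = ":")
}

#' Table of residues in a structure
#'
#' @param s a `structure3d`.
#' @return data.frame with one row per residue, in file order: `chain`,
#'   `resno`, `insert`, `resid`, `key`.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- res_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             key = key[first], stringsAsFactors = FALSE)
}

#' Chain ids of a structure, in file order
#' @param s a `structure3d`.
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

#' Extract one chain as a structure
#' @param s a `structure3d`.
#' @param chain chain id.
#' @export
chain_structure <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  if (!nrow(a)) stop("no such chain: ", chain)
  structure3d(a)
}

#' Representative residue points (C-beta, C-alpha fallback)
#'
#' The pairwise residue distances used by the interface-probability score
#' are measured between C-beta atoms; glycine (and any residue with a
#' missing C-beta) falls back to C-alpha.
#'
#' @param s a `structure3d`.
#' @return numeric matrix (n residues x 3) with residue keys as rownames;
#'   residues with neither CB nor CA are dropped.
#' @export
rep_points <- function(s) {
  a <- s$atoms
  key <- res_key(a$chain, a$resno, a$insert)
  is_cb <- a$elety == "CB"
  is_ca <- a$elety == "CA"
  keys <- unique(key)
  # prefer CB: order CA rows first so CB overwrites in the match below
  sel <- c(which(is_ca), which(is_cb))
  m <- matrix(NA_real_, length(keys), 3,
              dimnames = list(keys, c("x", "y", "z")))
  for (i in sel) m[key[i], ] <- c(a$x[i], a$y[i], a$z[i])
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Atom coordinates as a matrix
#' @param s a `structure3d`.
#' @return numeric matrix (n atoms x 3).
#' @export
coords <- function(s) {
  cbind(x = s$atoms$x, y = s$atoms$y, z = s$atoms$z)
}

#' Replace atom coordinates
#' @param s a `structure3d`.
#' @param xyz numeric matrix (n atoms x 3).
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' One-letter amino-acid sequence of a chain
#' @param s a `structure3d`.
#' @param chain chain id.
#' @return single string; non-standard residues become `X`.
#' @export
chain_sequence <- function(s, chain) {
  rs <- residue_table(s)
  rs <- rs[rs$chain == chain, , drop = FALSE]
  if (!nrow(rs)) stop("no such chain: ", chain)
  aa <- suppressWarnings(bio3d::aa321(rs$resid))
  aa[is.na(aa) | !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  paste(aa, collapse = "")
}

# ---------------------------------------------------------------------------
# PDB reading / writing
# ---------------------------------------------------------------------------

#' Read a protein structure from a PDB file
#'
#' Hydrogens, waters and HETATM records are dropped; alternate locations
#' are resolved to the highest-occupancy conformer (ties keep the first
#' encountered). MODEL records are honored via `model_index`.
#'
#' @param path PDB file path.
#' @param model_index 1-based model number to extract (default 1).
#' @return A [structure3d()].
#' @export
read_structure <- function(path, model_index = 1) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e)))
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  if (model_index < 1 || model_index > nmod)
    stop("model_index ", model_index, " out of range (file has ",
         nmod, " model(s))")
  a <- pdb$atom
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else pdb$xyz
  a$x <- xyz[seq(1, length(xyz), 3)]
  a$y <- xyz[seq(2, length(xyz), 3)]
  a$z <- xyz[seq(3, length(xyz), 3)]
  keep <- a$type == "ATOM" &
    !(toupper(a$elesy) %in% c("H", "D")) &
    !(a$resid %in% c("HOH", "WAT", "DOD"))
  a <- a[keep, , drop = FALSE]
  if (!nrow(a)) stop("no protein heavy atoms in ", path)
  a$insert <- ifelse(is.na(a$insert), "", a$insert)
  a$alt    <- ifelse(is.na(a$alt), "", a$alt)
  a$o[is.na(a$o)] <- 1
  # altloc: keep the highest-occupancy conformer per (residue, atom name)
  akey <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  ord  <- order(match(akey, unique(akey)), -a$o)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")), ,
         drop = FALSE]
  structure3d(data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert, resid = a$resid,
    elety = a$elety, element = toupper(a$elesy), x = a$x, y = a$y, z = a$z,
    o = a$o, stringsAsFactors = FALSE))
}

#' Write a structure as a single-model PDB file
#'
#' @param s a [structure3d()].
#' @param path output file path.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000,
    ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety), " ",
    a$resid, a$chain, a$resno,
    ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, a$o, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write several posed ligand copies as a multi-MODEL PDB
#'
#' @param structures list of [structure3d()] objects sharing an atom table.
#' @param path output file path.
#' @export
write_models <- function(structures, path) {
  out <- character(0)
  for (i in seq_along(structures)) {
    tf <- tempfile(fileext = ".pdb")
    write_structure(structures[[i]], tf)
    body <- readLines(tf)
    body <- body[body != "END"]
    unlink(tf)
    out <- c(out, sprintf("MODEL     %4d", i), body, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Combine structures into one (e.g. receptor + posed ligand)
#'
#' @param ... `structure3d` objects with disjoint chain ids.
#' @export
combine_structures <- function(...) {
  parts <- list(...)
  at <- do.call(rbind, lapply(parts, function(s) s$atoms))
  if (anyDuplicated(unlist(lapply(parts, chain_ids))))
    stop("chain ids overlap between structures")
  structure3d(at)
}

# ---------------------------------------------------------------------------
# Complex preparation
# ---------------------------------------------------------------------------

#' Relabel the chains of a binary complex
#'
#' The longer chain becomes the receptor (chain A, fixed docking frame) and
#' the shorter the ligand (chain B). Equal lengths keep file order, first
#' chain becoming A.
#'
#' @param bound a two-chain [structure3d()].
#' @return A `structure3d` with chains renamed to "A" (receptor, listed
#'   first) and "B" (ligand).
#' @export
relabel_chains <- function(bound) {
  ids <- chain_ids(bound)
  if (length(ids) != 2)
    stop("expected exactly 2 chains, found: ", paste(ids, collapse = ", "))
  rs <- residue_table(bound)
  n <- vapply(ids, function(ch) sum(rs$chain == ch), integer(1))
  ord <- if (n[2] > n[1]) c(2, 1) else c(1, 2)
  a <- bound$atoms
  new <- c("A", "B")[match(a$chain, ids[ord])]
  a$chain <- new
  a <- a[order(match(a$chain, c("A", "B"))), , drop = FALSE]
  structure3d(a)
}

#' Bundle bound and unbound structures of one complex
#'
#' @param bound relabeled two-chain bound complex (chains A, B).
#' @param unbound_receptor,unbound_ligand single-chain unbound structures.
#' @return list of class `complex_pair`.
#' @export
complex_pair <- function(bound, unbound_receptor, unbound_ligand) {
  stopifnot(identical(chain_ids(bound), c("A", "B")))
  rs <- residue_table(bound)
  if (sum(rs$chain == "A") < sum(rs$chain == "B"))
    stop("receptor (A) must have at least as many residues as ligand (B)")
  structure(list(bound = bound,
                 unbound_receptor = unbound_receptor,
                 unbound_ligand = unbound_ligand,
                 receptor_id = "A", ligand_id = "B"),
            class = "complex_pair")
}

# ---------------------------------------------------------------------------
# Residue mapping (bound <-> unbound numbering)
# ---------------------------------------------------------------------------

#' Map residue numbering between two sequences by global alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 (gap open 11, gap
#' extend 1); aligned non-gap columns become mapping pairs, so the mapping
#' is one-to-one and order-preserving in both sequences.
#'
#' Gap costs follow the common BLAST/biopython convention: a gap of length
#' L costs `gap_open + (L - 1) * gap_extend` (the opening charge covers the
#' first gap position).
#'
#' @param seq_bound,seq_unbound one-letter amino-acid strings (X allowed).
#' @param gap_open,gap_extend positive gap penalties.
#' @return data.frame of class `residue_mapping` with columns `bound_pos`,
#'   `unbound_pos` (1-based positions) and attributes `coverage_bound`,
#'   `coverage_unbound`.
#' @export
map_residues <- function(seq_bound, seq_unbound, gap_open = 11,
                         gap_extend = 1) {
  if (!nzchar(seq_bound) || !nzchar(seq_unbound))
    stop("empty sequence")
  bl62 <- get_blosum62()
  # Biostrings charges open + L * extend for a length-L gap; shift the
  # opening penalty so the first gap position costs `gap_open` in total
  pa <- Biostrings::pairwiseAlignment(
    seq_bound, seq_unbound, type = "global",
    substitutionMatrix = bl62,
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  bp <- cumsum(p != "-")
  up <- cumsum(s != "-")
  keep <- p != "-" & s != "-"
  m <- data.frame(bound_pos = bp[keep], unbound_pos = up[keep])
  attr(m, "coverage_bound")   <- nrow(m) / nchar(seq_bound)
  attr(m, "coverage_unbound") <- nrow(m) / nchar(seq_unbound)
  attr(m, "score") <- Biostrings::score(pa)
  class(m) <- c("residue_mapping", "data.frame")
  m
}

get_blosum62 <- local({
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

#' Write a residue mapping as TSV
#'
#' Columns: bound_chain, bound_resnum, bound_icode, unbound_resnum,
#' unbound_icode.
#'
#' @param mapping a `residue_mapping` from [map_residues()].
#' @param bound,unbound the structures the mapping refers to.
#' @param chain_bound,chain_unbound chain ids.
#' @param path output TSV path.
#' @export
write_mapping <- function(mapping, bound, unbound, chain_bound,
                          chain_unbound, path) {
  rb <- residue_table(bound);   rb <- rb[rb$chain == chain_bound, ]
  ru <- residue_table(unbound); ru <- ru[ru$chain == chain_unbound, ]
  df <- data.frame(
    bound_chain   = chain_bound,
    bound_resnum  = rb$resno[mapping$bound_pos],
    bound_icode   = rb$insert[mapping$bound_pos],
    unbound_resnum = ru$resno[mapping$unbound_pos],
    unbound_icode  = ru$insert[mapping$unbound_pos])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop bound residues without an unbound correspondence
#'
#' @param bound a [structure3d()].
#' @param mappings named list (by chain id) of `residue_mapping` objects;
#'   chains without an entry are kept whole.
#' @return trimmed `structure3d` with original residue order.
#' @export
trim_unmatched <- function(bound, mappings) {
  rs <- residue_table(bound)
  keep_keys <- unlist(lapply(chain_ids(bound), function(ch) {
    kk <- rs$key[rs$chain == ch]
    m <- mappings[[ch]]
    if (is.null(m)) return(kk)
    if (!nrow(m)) stop("empty mapping for chain ", ch)
    kk[m$bound_pos]
  }))
  a <- bound$atoms
  a <- a[res_key(a$chain, a$resno, a$insert) %in% keep_keys, , drop = FALSE]
  structure3d(a)
}

# ---------------------------------------------------------------------------
# Rigid superposition (Kabsch)
# ---------------------------------------------------------------------------

#' Least-squares rigid superposition of paired atoms
#'
#' Atoms are paired by (residue key, atom name); `mobile_keys`/`ref_keys`
#' optionally restrict and re-key the residues considered (parallel vectors
#' mapping mobile residue keys onto reference residue keys). The returned
#' rotation is proper (det = +1).
#'
#' @param mobile,reference `structure3d` objects.
#' @param atom_names atom-name selection (default backbone N, CA, C, O).
#' @param mobile_keys,ref_keys optional parallel residue-key vectors pairing
#'   mobile residues with reference residues; default pairs identical keys.
#' @return list of class `rigid_transform`: `R` (3x3 rotation), `t`
#'   (length-3 translation), `rmsd` (Angstrom over the paired atoms),
#'   `n_atoms`.
#' @export
superpose <- function(mobile, reference, atom_names = c("N", "CA", "C", "O"),
                      mobile_keys = NULL, ref_keys = NULL) {
  am <- mobile$atoms;    am$key <- res_key(am$chain, am$resno, am$insert)
  ar <- reference$atoms; ar$key <- res_key(ar$chain, ar$resno, ar$insert)
  if (is.null(mobile_keys)) {
    common <- intersect(unique(am$key), unique(ar$key))
    mobile_keys <- ref_keys <- common
  }
  stopifnot(length(mobile_keys) == length(ref_keys))
  P <- NULL; Q <- NULL
  for (i in seq_along(mobile_keys)) {
    for (nm in atom_names) {
      im <- which(am$key == mobile_keys[i] & am$elety == nm)
      ir <- which(ar$key == ref_keys[i] & ar$elety == nm)
      if (length(im) == 1 && length(ir) == 1) {
        P <- rbind(P, c(am$x[im], am$y[im], am$z[im]))
        Q <- rbind(Q, c(ar$x[ir], ar$y[ir], ar$z[ir]))
      }
    }
  }
  if (is.null(P) || nrow(P) < 3)
    stop("fewer than 3 paired atoms for superposition")
  kabsch(P, Q)
}

#' Kabsch rotation between paired coordinate sets
#'
#' @param P,Q n x 3 matrices of paired coordinates (P mobile, Q reference).
#' @return `rigid_transform` mapping P onto Q.
#' @export
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cq - as.numeric(R %*% cp)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  structure(list(R = R, t = tvec, rmsd = rmsd, n_atoms = nrow(P)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param x n x 3 coordinate matrix or a `structure3d`.
#' @param tr a `rigid_transform`.
#' @export
apply_transform <- function(x, tr) {
  if (inherits(x, "structure3d"))
    return(set_coords(x, apply_transform(coords(x), tr)))
  x %*% t(tr$R) + matrix(tr$t, nrow(x), 3, byrow = TRUE)
}
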