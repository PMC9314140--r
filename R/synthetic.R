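# ---------------------------------------------------------------------------
# Synthetic toy complexes: two poly-alanine chains packed so that a
# designated contiguous segment of the ligand faces the receptor, burying
# SASA there and nowhere else. Everything downstream (mapping, SASA
# interfaces, decoys, scoring, DockQ) is exercisable on these without any
# external data.
# ---------------------------------------------------------------------------

# Build one extended poly-ALA chain along x. `y_offset(i)` gives the CA
# y-coordinate per residue; `flip` mirrors the side-chain (CB) direction so
# two chains can face each other.
build_chain <- function(n, chain_id, ca_y, x0 = 0, flip = FALSE,
                        spacing = 3.8, start_resno = 1) {
  sgn <- if (flip) -1 else 1
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ca <- c(x0 + spacing * (i - 1), ca_y[i], 0)
    zjit <- 0.5 * (-1)^i       # mild zigzag so the chain is not planar
    at <- rbind(
      N  = ca + c(-1.25, -0.4 * sgn, 0.5 + zjit),
      CA = ca + c(0, 0, zjit),
      C  = ca + c(1.25, -0.4 * sgn, -0.5 + zjit),
      O  = ca + c(1.25, -1.5 * sgn, -0.6 + zjit),
      CB = ca + c(0, 1.3 * sgn, 0.7 + zjit))
    rows[[i]] <- data.frame(
      chain = chain_id, resno = start_resno + i - 1, insert = "",
      resid = "ALA", elety = rownames(at),
      element = substr(rownames(at), 1, 1),
      x = at[, 1], y = at[, 2], z = at[, 3], o = 1,
      stringsAsFactors = FALSE)
  }
  structure3d(do.call(rbind, rows))
}

#' Generate a synthetic bound/unbound toy complex
#'
#' Two idealized extended poly-alanine chains (C-beta built at ideal-ish
#' geometry) are packed face to face over a contiguous `patch_size`-residue
#' segment of the ligand; outside the segment the ligand bends away from
#' the receptor so only the packed patch buries solvent accessible surface.
#' Unbound forms are copies of the bound chains with optional Gaussian
#' coordinate noise and a residue renumbering offset, to exercise mapping
#' and trimming.
#'
#' @param n_res integer length-2: residues in receptor (chain A) and
#'   ligand (chain B); both at least 10, receptor at least as long as the
#'   ligand.
#' @param patch_size residues of the ligand in contact with the receptor.
#' @param perturb standard deviation (Angstrom) of iid Gaussian noise
#'   added to unbound coordinates (0 = identical to bound).
#' @param renumber_offset integer added to unbound residue numbers.
#' @param loop_shift if TRUE, a short non-interface loop of the unbound
#'   ligand is displaced by ~2 Angstrom (exercises the unbound-interface
#'   fallback).
#' @param gap receptor-ligand CA-CA separation across the interface
#'   (Angstrom).
#' @param seed integer seed (fixed seed gives byte-identical output).
#' @return list of class `toy_complex`: `pair` (a [complex_pair()]),
#'   `interface` (ground-truth [interface_set()] from the SASA criterion),
#'   `native_pose` (identity [pose()]).
#' @export
make_toy_complex <- function(n_res = c(24, 16), patch_size = 8,
                             perturb = 0, renumber_offset = 0,
                             loop_shift = FALSE, gap = 6.2, seed = 1) {
  stopifnot(length(n_res) == 2, all(n_res >= 10), n_res[1] >= n_res[2],
            patch_size >= 2, patch_size <= n_res[2])
  set.seed(as.integer(seed))
  nA <- n_res[1]; nB <- n_res[2]
  # receptor: straight chain along x, side chains facing +y
  rec <- build_chain(nA, "A", rep(0, nA))
  # ligand: patch residues run parallel at y = gap; flanks bend away (+y)
  patch_lo <- floor((nB - patch_size) / 2) + 1
  patch_hi <- patch_lo + patch_size - 1
  bend <- vapply(seq_len(nB), function(j) {
    d <- if (j < patch_lo) patch_lo - j else if (j > patch_hi) j - patch_hi
         else 0
    2.2 * d^1.5
  }, numeric(1))
  # center the ligand patch over the receptor
  x0 <- 3.8 * ((nA - nB) / 2)
  lig <- build_chain(nB, "B", gap + bend, x0 = x0, flip = TRUE)
  bound <- combine_structures(rec, lig)
  iface <- extract_native_interface(bound)
  if (!length(iface$interface$A) || !length(iface$interface$B))
    stop("infeasible packing: no buried residues")
  perturb_chain <- function(s) {
    a <- s$atoms
    if (perturb > 0) {
      a$x <- a$x + rnorm(nrow(a), 0, perturb)
      a$y <- a$y + rnorm(nrow(a), 0, perturb)
      a$z <- a$z + rnorm(nrow(a), 0, perturb)
    }
    a$resno <- a$resno + as.integer(renumber_offset)
    structure3d(a)
  }
  u_rec <- perturb_chain(rec)
  u_lig <- perturb_chain(lig)
  if (loop_shift) {
    # push the first two (non-interface, flank) ligand residues off axis
    a <- u_lig$atoms
    sel <- a$resno %in% (min(a$resno) + 0:1)
    a$z[sel] <- a$z[sel] + 2
    u_lig <- structure3d(a)
  }
  structure(list(pair = complex_pair(bound, u_rec, u_lig),
                 interface = iface, native_pose = pose(0L)),
            class = "toy_complex")
}

#' Generate an on-disk synthetic benchmark fixture tree
#'
#' For each complex spec: bound/unbound PDB files, a decoy pose table, and
#' simulated-prediction probability tables at every requested (TPR, PPV)
#' grid point, plus a JSON manifest (seed, specs, per-file checksums).
#' Regenerable bit-exactly from the same seed.
#'
#' @param specs list of argument lists for [make_toy_complex()] (one per
#'   complex; each should carry its own `seed`).
#' @param n_decoys decoys per complex.
#' @param near_native_frac fraction of near-native decoys (default 0.05).
#' @param tpr_ppv_grid two-column matrix of (TPR, PPV) targets; defaults
#'   to the six standard noise grid points.
#' @param out_dir output directory (created).
#' @param seed master seed for decoy generation and prediction noise.
#' @return path of the manifest JSON, invisibly.
#' @export
make_benchmark <- function(specs, n_decoys = 200, near_native_frac = 0.05,
                           tpr_ppv_grid = default_tpr_ppv_grid(),
                           out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  meta <- list()
  for (ci in seq_along(specs)) {
    name <- sprintf("complex%02d", ci)
    cdir <- file.path(out_dir, name)
    dir.create(cdir, showWarnings = FALSE)
    toy <- do.call(make_toy_complex, specs[[ci]])
    rec <- chain_structure(toy$pair$bound, "A")
    lig <- chain_structure(toy$pair$bound, "B")
    write_structure(toy$pair$bound, file.path(cdir, "bound.pdb"))
    write_structure(toy$pair$unbound_receptor,
                    file.path(cdir, "unbound_receptor.pdb"))
    write_structure(toy$pair$unbound_ligand,
                    file.path(cdir, "unbound_ligand.pdb"))
    n_nn <- max(1, round(near_native_frac * n_decoys))
    decoys <- generate_toy_decoys(rec, lig, n_decoys, n_nn,
                                  toy$native_pose, seed = seed + ci)
    write_pose_table(decoys$poses, file.path(cdir, "poses.tsv"),
                     decoys$convention)
    infeasible <- character(0)
    for (g in seq_len(nrow(tpr_ppv_grid))) {
      tag <- sprintf("tpr%s_ppv%s", format(tpr_ppv_grid[g, 1]),
                     format(tpr_ppv_grid[g, 2]))
      # a small surface may not supply enough false positives for low-PPV
      # grid points; record those as infeasible instead of aborting
      pr <- tryCatch(
        simulate_predictions(toy$interface, tpr_ppv_grid[g, 1],
                             tpr_ppv_grid[g, 2],
                             seed = seed * 1000 + ci * 100 + g),
        error = function(e) NULL)
      if (is.null(pr)) { infeasible <- c(infeasible, tag); next }
      write_probabilities(pr, file.path(cdir, paste0("pred_", tag, ".tsv")))
    }
    cf <- list.files(cdir, full.names = TRUE)
    files <- c(files, cf)
    meta[[name]] <- list(spec = specs[[ci]], n_decoys = n_decoys,
                         n_near_native = n_nn,
                         infeasible_grid_points = infeasible)
  }
  manifest <- list(
    seed = seed, near_native_frac = near_native_frac,
    tpr_ppv_grid = unname(apply(tpr_ppv_grid, 1, as.numeric,
                                simplify = FALSE)),
    complexes = meta,
    checksums = as.list(tools::md5sum(sort(files))))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' The standard simulated-prediction noise grid
#'
#' Six (TPR, PPV) combinations: recall degraded at perfect precision
#' (0.25/1, 0.5/1, 0.75/1) and precision degraded at perfect recall
#' (1/0.25, 1/0.5, 1/0.75).
#'
#' @return two-column numeric matrix (tpr, ppv).
#' @export
default_tpr_ppv_grid <- function() {
  cbind(tpr = c(0.25, 0.5, 0.75, 1, 1, 1),
        ppv = c(1, 1, 1, 0.25, 0.5, 0.75))
}
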