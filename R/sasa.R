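# ---------------------------------------------------------------------------
# Solvent accessible surface area, Shrake-Rupley style.
#
# Deterministic Fibonacci sphere (no RNG) so SASA values are bit-stable
# across runs. Heavy atoms only; element-based van der Waals radii.
# ---------------------------------------------------------------------------

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
VDW_DEFAULT <- 1.70

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' @param s a [structure3d()].
#' @param probe_radius solvent probe radius in Angstrom (water, 1.4).
#' @param n_points test points per atom sphere (default 960).
#' @return numeric vector of per-atom SASA in Angstrom^2.
#' @export
atom_sasa <- function(s, probe_radius = 1.4, n_points = 960) {
  xyz <- coords(s)
  n <- nrow(xyz)
  rad <- VDW_RADII[s$atoms$element]
  rad[is.na(rad)] <- VDW_DEFAULT
  sph <- fibonacci_sphere(n_points)
  ext <- rad + probe_radius
  out <- numeric(n)
  # neighbor cutoff: two atom spheres can only occlude each other within
  # the sum of their extended radii
  maxext <- max(ext)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < ext[i] + maxext & seq_len(n) != i)
    nb <- nb[di[nb] < ext[i] + ext[nb]]
    if (!length(nb)) { out[i] <- 4 * pi * ext[i]^2; next }
    pts <- sph * ext[i]
    pts <- sweep(pts, 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
            (pts[, 3] - xyz[j, 3])^2
      free <- free & d2 > ext[j]^2
      if (!any(free)) break
    }
    out[i] <- 4 * pi * ext[i]^2 * sum(free) / n_points
  }
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out))[1]
    stop("SASA failed for residue ",
         res_key(s$atoms$chain[bad], s$atoms$resno[bad], s$atoms$insert[bad]))
  }
  out
}

#' Per-residue solvent accessible surface area
#'
#' @inheritParams atom_sasa
#' @return named numeric vector (residue keys) of SASA in Angstrom^2.
#' @export
residue_sasa <- function(s, probe_radius = 1.4, n_points = 960) {
  a <- atom_sasa(s, probe_radius, n_points)
  key <- res_key(s$atoms$chain, s$atoms$resno, s$atoms$insert)
  v <- tapply(a, factor(key, levels = unique(key)), sum)
  out <- as.numeric(v); names(out) <- names(v)
  out
}

# Theoretical maximum residue SASA (Tien et al. 2013), used for the
# relative-SASA surface cutoff.
MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
MAX_SASA_DEFAULT <- 200
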