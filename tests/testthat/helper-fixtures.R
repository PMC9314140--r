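# Shared fixtures, all generated in code.

# Hand-written minimal PDB texts ------------------------------------------

pdb_two_residues <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   1.400   0.200  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.000  -1.300  -0.200  1.00  0.00           C",
    "ATOM      5  N   GLY A   2       3.300  -1.300  -0.200  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       4.200  -0.200   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.600  -0.600   0.300  1.00  0.00           C",
    "END")
}

pdb_altloc <- function(occ_a = 0.6, occ_b = 0.4) {
  c("ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    sprintf("ATOM      2  CB AALA A   1       2.000   1.000   0.000%6.2f  0.00           C", occ_a),
    sprintf("ATOM      3  CB BALA A   1       2.500   1.500   0.000%6.2f  0.00           C", occ_b),
    "ATOM      4  N   ALA A   1       0.000   0.500   0.000  1.00  0.00           N",
    "END")
}

write_pdb_text <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

# Programmatic structures --------------------------------------------------

# a bare CA/CB chain as a structure3d, for geometry-only tests
point_chain <- function(ca, chain = "A", resid = "ALA", with_cb = FALSE,
                        start_resno = 1) {
  n <- nrow(ca)
  rows <- lapply(seq_len(n), function(i) {
    at <- data.frame(chain = chain, resno = start_resno + i - 1,
                     insert = "", resid = resid, elety = "CA",
                     element = "C", x = ca[i, 1], y = ca[i, 2],
                     z = ca[i, 3], o = 1, stringsAsFactors = FALSE)
    if (with_cb) {
      cb <- at; cb$elety <- "CB"; cb$y <- cb$y + 1.5
      at <- rbind(at, cb)
    }
    at
  })
  structure3d(do.call(rbind, rows))
}

# random representative-point "chains" + probabilities for scorer fixtures
random_score_fixture <- function(n1, n2, spread = 20) {
  Rpts <- matrix(runif(n1 * 3, 0, spread), n1, 3,
                 dimnames = list(paste0("A:", 1:n1, ":"), NULL))
  Lpts <- matrix(runif(n2 * 3, 0, spread), n2, 3,
                 dimnames = list(paste0("B:", 1:n2, ":"), NULL))
  p_rec <- stats::setNames(runif(n1, 0, 0.99), rownames(Rpts))
  p_lig <- stats::setNames(runif(n2, 0, 0.99), rownames(Lpts))
  list(Rpts = Rpts, Lpts = Lpts, p_rec = p_rec, p_lig = p_lig)
}

# a label-level interface set (no 3D structure), for prediction-noise tests
label_interface_set <- function(n_iface, n_surface_extra,
                                chains = c("A", "B")) {
  iface <- list(); surf <- list()
  for (ch in chains) {
    keys <- paste0(ch, ":", seq_len(n_iface + n_surface_extra), ":")
    iface[[ch]] <- keys[seq_len(n_iface)]
    surf[[ch]] <- keys
  }
  interface_set(iface, surf)
}

shared_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_toy_complex(n_res = c(24, 16), patch_size = 8, seed = 7)
    cache
  }
})
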