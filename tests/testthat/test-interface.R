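test_that("separated chains have an empty interface", {
  a <- point_chain(matrix(c(3.8 * (1:10), rep(0, 20)), 10, 3),
                   chain = "A", with_cb = TRUE)
  b <- point_chain(matrix(c(3.8 * (1:10), rep(100, 10), rep(0, 10)), 10, 3),
                   chain = "B", with_cb = TRUE)
  iset <- extract_native_interface(combine_structures(a, b))
  expect_length(iset$interface$A, 0)
  expect_length(iset$interface$B, 0)
  expect_gt(length(iset$surface$A), 0)
})

test_that("SASA-drop interface matches an independent Shrake-Rupley oracle", {
  toy <- shared_toy()
  iset <- extract_native_interface(toy$pair$bound)
  for (ch in c("A", "B")) {
    oracle <- oracle_interface_keys(toy$pair$bound, ch)
    expect_setequal(iset$interface[[ch]], oracle)
  }
  # interface is contained in the surface
  expect_true(all(iset$interface$A %in% iset$surface$A))
  expect_true(all(iset$interface$B %in% iset$surface$B))
})

test_that("a residue buried in its own chain core is never interface", {
  # central residue enclosed by a dense shell of same-chain atoms
  sph <- 3.0 * dockface:::fibonacci_sphere(80)
  shell <- do.call(rbind, lapply(seq_len(nrow(sph)), function(i)
    data.frame(chain = "A", resno = i + 1, insert = "", resid = "ALA",
               elety = "CA", element = "C", x = sph[i, 1], y = sph[i, 2],
               z = sph[i, 3], o = 1)))
  core <- data.frame(chain = "A", resno = 1, insert = "", resid = "ALA",
                     elety = "CA", element = "C", x = 0, y = 0, z = 0, o = 1)
  partner <- data.frame(chain = "B", resno = 1:2, insert = "", resid = "ALA",
                        elety = "CA", element = "C",
                        x = c(6, 9), y = 0, z = 0, o = 1)
  s <- structure3d(rbind(core, shell, partner))
  iset <- extract_native_interface(s)
  expect_false("A:1:" %in% iset$interface$A)
})

test_that("interface extraction is symmetric under chain order", {
  toy <- shared_toy()
  b <- toy$pair$bound
  flipped <- structure3d(b$atoms[order(match(b$atoms$chain, c("B", "A"))), ])
  i1 <- extract_native_interface(b)
  i2 <- extract_native_interface(flipped)
  expect_setequal(i1$interface$A, i2$interface$A)
  expect_setequal(i1$interface$B, i2$interface$B)
})

test_that("unbound fallback reproduces the bound interface for identical
           coordinates and flags shifted loops", {
  toy <- shared_toy()
  u <- toy$pair$unbound_ligand   # identical to bound chain B (no noise)
  tr <- superpose(u, chain_structure(toy$pair$bound, "B"),
                  atom_names = c("N", "CA", "C", "O"))
  iset <- extract_interface_unbound_fallback(u, toy$pair$bound, tr, "B")
  ref <- extract_native_interface(toy$pair$bound)
  expect_setequal(iset$interface$B, ref$interface$B)
  expect_error(extract_interface_unbound_fallback(u, toy$pair$bound,
                                                  transform = NULL,
                                                  chain = "B"),
               "rigid_transform")
})

test_that("simulated predictions hit the requested TP and FP counts", {
  iset <- label_interface_set(4, 8)
  # tpr 0.5, ppv 1: exactly 2 retained interface residues, no noise
  p <- simulate_predictions(iset, 0.5, 1, seed = 1)
  marked <- lapply(p$prob, function(v) names(v)[v > 0])
  for (ch in c("A", "B")) {
    expect_length(marked[[ch]], 2)
    expect_true(all(marked[[ch]] %in% iset$interface[[ch]]))
  }
  # tpr 1, ppv 1: exactly the native interface
  p2 <- simulate_predictions(iset, 1, 1, seed = 1)
  for (ch in c("A", "B"))
    expect_setequal(names(p2$prob[[ch]])[p2$prob[[ch]] > 0],
                    iset$interface[[ch]])
  # tpr 1, ppv 0.5: 4 TP + 4 FP, measured precision exactly 0.5
  p3 <- simulate_predictions(iset, 1, 0.5, seed = 1)
  for (ch in c("A", "B")) {
    m <- names(p3$prob[[ch]])[p3$prob[[ch]] > 0]
    cr <- confusion_rates(m, iset, ch)
    expect_equal(cr$TP, 4); expect_equal(cr$FP, 4)
    expect_equal(cr$PPV, 0.5)
  }
  # marks carry the capped probability
  expect_true(all(unlist(p3$prob) %in% c(0, 0.99)))
})

test_that("simulated predictions error when the surface cannot supply the
           requested false positives", {
  iset <- label_interface_set(10, 2)
  expect_error(simulate_predictions(iset, 1, 0.25, seed = 1),
               "achievable PPV")
})

test_that("simulated predictions stay within the rounding bound on every
           chain across the noise grid", {
  grid <- default_tpr_ppv_grid()
  iset <- label_interface_set(17, 60)   # awkward size to stress rounding
  for (g in seq_len(nrow(grid))) {
    for (seed in 1:5) {
      p <- simulate_predictions(iset, grid[g, 1], grid[g, 2], seed = seed)
      for (ch in c("A", "B")) {
        m <- names(p$prob[[ch]])[p$prob[[ch]] > 0]
        cr <- confusion_rates(m, iset, ch)
        # the bound itself can be attained exactly (target*n = k + 0.5)
        expect_lte(abs(cr$TPR - grid[g, 1]),
                   0.5 / length(iset$interface[[ch]]) + 1e-12)
        expect_lte(abs(cr$PPV - grid[g, 2]),
                   0.5 / (cr$TP + cr$FP) + 1e-12)
      }
    }
  }
  # determinism: same seed, same marks
  expect_identical(simulate_predictions(iset, 0.75, 0.75, seed = 9),
                   simulate_predictions(iset, 0.75, 0.75, seed = 9))
})

test_that("contact maps reduce to per-residue maxima", {
  m <- matrix(0.7, 1, 1, dimnames = list("A:1:", "B:1:"))
  p <- contacts_to_interface(contact_map(m))
  expect_equal(unname(p$prob$A), 0.7)
  expect_equal(unname(p$prob$B), 0.7)

  z <- matrix(0, 3, 2, dimnames = list(paste0("A:", 1:3, ":"),
                                       paste0("B:", 1:2, ":")))
  pz <- contacts_to_interface(contact_map(z))
  expect_true(all(unlist(pz$prob) == 0))

  set.seed(2)
  r <- matrix(runif(6), 3, 2, dimnames = dimnames(z))
  pr <- contacts_to_interface(contact_map(r))
  for (i in 1:3) expect_equal(unname(pr$prob$A[i]), max(r[i, ]))
  for (j in 1:2) expect_equal(unname(pr$prob$B[j]), max(r[, j]))
  # output never exceeds the map maximum
  expect_lte(max(unlist(pr$prob)), max(r))
})

test_that("distograms convert to contact probabilities by leading-bin mass", {
  d <- array(0, c(1, 1, 37))
  d[1, 1, 1] <- 1
  expect_equal(as.numeric(bins_to_contact(d)), 1)
  d2 <- array(0, c(1, 1, 37)); d2[1, 1, 37] <- 0.5
  expect_equal(as.numeric(bins_to_contact(d2)), 0)
  d3 <- array(1 / 37, c(2, 2, 37))
  expect_equal(as.numeric(bins_to_contact(d3)[1, 1]), 20 / 37)
  d4 <- array(1, c(2, 1, 5)); d4[2, 1, ] <- 0
  expect_error(bins_to_contact(d4), "all-zero")
})

test_that("probability capping bounds values without reordering", {
  p <- interface_probs(list(A = c("A:1:" = 1, "A:2:" = 0.995,
                                  "A:3:" = 0.2)))
  cp <- cap_probabilities(p)
  expect_equal(unname(cp$prob$A), c(0.99, 0.99, 0.2))
  expect_true(cp$capped)
  expect_equal(order(-cp$prob$A), order(-p$prob$A))
  expect_equal(unname(cap_probabilities(
    interface_probs(list(A = c("A:1:" = 0.5))))$prob$A), 0.5)
})

test_that("probability TSV round trip preserves values", {
  toy <- shared_toy()
  p <- simulate_predictions(toy$interface, 0.75, 0.75, seed = 4)
  tf <- tempfile(fileext = ".tsv")
  write_probabilities(p, tf)
  back <- read_probabilities(tf)
  for (ch in c("A", "B"))
    expect_equal(back$prob[[ch]][names(p$prob[[ch]])], p$prob[[ch]])
})
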