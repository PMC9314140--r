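test_that("confusion rates follow the TP/FP/FN definitions", {
  nat <- paste0("A:", 1:4, ":")
  # TP=3, FN=1 -> recall 0.75
  cr <- confusion_rates(paste0("A:", 1:3, ":"), nat)
  expect_equal(cr$TPR, 0.75)
  # TP=2, FP=2 -> precision 0.5
  cr2 <- confusion_rates(paste0("A:", c(1, 2, 8, 9), ":"), nat)
  expect_equal(cr2$PPV, 0.5)
  # perfect prediction
  cr3 <- confusion_rates(nat, nat)
  expect_equal(cr3$TPR, 1); expect_equal(cr3$PPV, 1)
  # empty prediction: recall 0, precision undefined (NA, not 0)
  cr4 <- confusion_rates(character(0), nat)
  expect_equal(cr4$TPR, 0)
  expect_true(is.na(cr4$PPV))
  expect_error(confusion_rates("A:1:", character(0)), "empty native")
})

test_that("precision-recall AUC matches an exhaustive sweep oracle", {
  set.seed(41)
  for (rep in 1:10) {
    n <- 20
    keys <- paste0("A:", 1:n, ":")
    labels <- runif(n) < 0.4
    if (!any(labels)) labels[1] <- TRUE
    probs <- stats::setNames(round(runif(n), 2), keys)  # induce ties
    iset <- interface_set(list(A = keys[labels]), list(A = keys))
    got <- pr_auc(probs, iset, "A")
    want <- oracle_pr(unname(probs), labels)
    expect_equal(got$auc, want$auc, tolerance = 1e-12)
    expect_equal(got$curve$recall, want$curve$recall)
    expect_equal(got$curve$precision, want$curve$precision)
  }
})

test_that("perfect separation gives AUC 1; constant predictor sits at the
           I/S baseline at every threshold", {
  keys <- paste0("A:", 1:20, ":")
  iset <- interface_set(list(A = keys[1:6]), list(A = keys))
  perfect <- stats::setNames(c(rep(0.99, 6), rep(0, 14)), keys)
  expect_equal(pr_auc(perfect, iset, "A")$auc, 1)
  const <- stats::setNames(rep(0.5, 20), keys)
  pc <- pr_auc(const, iset, "A")
  expect_true(all(pc$curve$precision == pc$baseline))
  expect_equal(pc$baseline, 6 / 20)
})

test_that("PR curve points agree with confusion rates at each threshold", {
  set.seed(42)
  keys <- paste0("A:", 1:15, ":")
  labels <- c(rep(TRUE, 5), rep(FALSE, 10))
  probs <- stats::setNames(round(runif(15), 1), keys)
  iset <- interface_set(list(A = keys[labels]), list(A = keys))
  pc <- pr_auc(probs, iset, "A")
  for (k in seq_len(nrow(pc$curve))) {
    t <- pc$curve$threshold[k]
    cr <- confusion_rates(keys[probs >= t], iset, "A")
    expect_equal(cr$TPR, pc$curve$recall[k])
    expect_equal(cr$PPV, pc$curve$precision[k])
  }
})

test_that("prediction with signal beats its label-permuted counterpart
           on average", {
  set.seed(43)
  n <- 30
  keys <- paste0("A:", 1:n, ":")
  labels <- c(rep(TRUE, 10), rep(FALSE, 20))
  probs <- stats::setNames(ifelse(labels, runif(n, 0.5, 1),
                                  runif(n, 0, 0.5)), keys)
  iset <- interface_set(list(A = keys[labels]), list(A = keys))
  auc_signal <- pr_auc(probs, iset, "A")$auc
  perm <- replicate(100, {
    lab2 <- sample(labels)
    pr_auc(probs, interface_set(list(A = keys[lab2]),
                                list(A = keys)), "A")$auc
  })
  expect_gt(auc_signal, mean(perm))
})

test_that("worst-chain selection takes the smaller AUC", {
  expect_equal(worst_chain(0.8, 0.3), 0.3)
  expect_equal(worst_chain(0.5, 0.5), 0.5)
  expect_equal(worst_chain(0.46, 0.32), 0.32)
  expect_lte(worst_chain(0.46, 0.32), 0.46)
})

test_that("per-complex AUC summary emits macro, micro and worst-chain", {
  toy <- shared_toy()
  p <- simulate_predictions(toy$interface, 0.75, 0.75, seed = 5)
  s <- pr_auc_complex(p, toy$interface)
  expect_length(s$per_chain, 2)
  expect_equal(s$macro, mean(s$per_chain))
  expect_equal(s$worst_chain, min(s$per_chain))
  expect_true(s$micro >= 0 && s$micro <= 1)
})

test_that("DockQ of a model identical to its native is exactly 1", {
  toy <- shared_toy()
  q <- dockq(toy$pair$bound, toy$pair$bound)
  expect_identical(q$DockQ, 1)
  expect_equal(q$Fnat, 1)
  expect_lt(q$iRMS, 1e-9)
  expect_lt(q$LRMS, 1e-9)
  expect_equal(q$capri_class, "high")
})

test_that("DockQ decreases monotonically under growing ligand translation
           and bounds stay in [0,1]", {
  toy <- shared_toy()
  rec <- chain_structure(toy$pair$bound, "A")
  lig <- chain_structure(toy$pair$bound, "B")
  shifts <- c(0, 1, 2, 4, 8, 12, 20)
  qs <- vapply(shifts, function(dz) {
    moved <- set_coords(lig, coords(lig) + matrix(c(0, 0, dz),
                                                  nrow(coords(lig)), 3, TRUE))
    dockq(combine_structures(rec, moved), toy$pair$bound)$DockQ
  }, numeric(1))
  expect_true(all(diff(qs) <= 1e-9))
  expect_true(all(qs >= 0 & qs <= 1))
  # a 50 A displacement retains no native contacts: incorrect class
  far <- set_coords(lig, coords(lig) + matrix(c(0, 50, 0),
                                              nrow(coords(lig)), 3, TRUE))
  qf <- dockq(combine_structures(rec, far), toy$pair$bound)
  expect_equal(qf$Fnat, 0)
  expect_lt(qf$DockQ, 0.23)
  expect_equal(qf$capri_class, "incorrect")
})

test_that("DockQ combines its three terms with the published scaling", {
  # displaced model with known components: recompute the combination
  toy <- shared_toy()
  rec <- chain_structure(toy$pair$bound, "A")
  lig <- chain_structure(toy$pair$bound, "B")
  moved <- set_coords(lig, coords(lig) + matrix(c(0, 0, 3),
                                                nrow(coords(lig)), 3, TRUE))
  q <- dockq(combine_structures(rec, moved), toy$pair$bound)
  expect_equal(q$DockQ,
               (q$Fnat + 1 / (1 + (q$iRMS / 1.5)^2) +
                1 / (1 + (q$LRMS / 8.5)^2)) / 3)
  expect_true(q$iRMS > 0 && q$LRMS > 0)
})

test_that("success rate counts complexes with an acceptable model in the
           top N", {
  res <- list(c(0.8, 0.1), c(0.1, 0.05), c(0.3, 0.9), c(0.05, 0.4))
  expect_equal(success_rate(res, n = 1), 0.5)
  expect_equal(success_rate(res, n = 2), 0.75)
  # SR is monotone in N
  set.seed(44)
  rnd <- replicate(10, runif(10, 0, 0.6), simplify = FALSE)
  expect_lte(success_rate(rnd, 1), success_rate(rnd, 5))
  expect_lte(success_rate(rnd, 5), success_rate(rnd, 10))
  expect_error(success_rate(list()), "empty")
})

test_that("difficulty classes follow the i-RMSD / fnon-nat thresholds", {
  expect_equal(classify_difficulty(1.0, 0.2), "easy")
  expect_equal(classify_difficulty(2.5, 0.1), "hard")
  expect_equal(classify_difficulty(1.8, 0.5), "medium")
  # gaps and boundaries resolve toward higher difficulty
  expect_equal(classify_difficulty(2.2, 0.0), "hard")
  expect_equal(classify_difficulty(1.5, 0.2), "medium")
  expect_equal(classify_difficulty(1.2, 0.8), "medium")
  expect_equal(classify_difficulty(1.8, 0.2), "medium")
  expect_error(classify_difficulty(-1, 0.2), "i_rmsd")
})

test_that("interface center-of-mass deviation measures patch displacement", {
  toy <- shared_toy()
  expect_lt(interface_cm_deviation(toy$pair$bound, toy$pair$bound,
                                   toy$interface), 1e-9)
  rec <- chain_structure(toy$pair$bound, "A")
  lig <- chain_structure(toy$pair$bound, "B")
  # ligand slid 10 A along x (parallel to the interface): the ligand-side
  # residues shift by 10, receptor side stays, so the pooled centroid
  # moves by 10 * nB / (nA + nB)
  moved <- set_coords(lig, coords(lig) + matrix(c(10, 0, 0),
                                                nrow(coords(lig)), 3, TRUE))
  nA <- length(toy$interface$interface$A)
  nB <- length(toy$interface$interface$B)
  dev <- interface_cm_deviation(combine_structures(rec, moved),
                                toy$pair$bound, toy$interface)
  expect_equal(dev, 10 * nB / (nA + nB), tolerance = 1e-6)
})

test_that("rotation about the interface center leaves the CM deviation
           near zero while DockQ drops", {
  toy <- shared_toy()
  rec <- chain_structure(toy$pair$bound, "A")
  lig <- chain_structure(toy$pair$bound, "B")
  # rotate the ligand 180 degrees about the axis through its own
  # interface centroid, normal to the interface plane
  keysB <- toy$interface$interface$B
  ctr <- colMeans(rep_points(lig)[keysB, , drop = FALSE])
  R <- diag(c(-1, 1, -1))        # rotation by pi about the y axis
  moved <- set_coords(lig, sweep(sweep(coords(lig), 2, ctr) %*% t(R),
                                 2, ctr, `+`))
  model <- combine_structures(rec, moved)
  dev <- interface_cm_deviation(model, toy$pair$bound, toy$interface)
  q <- dockq(model, toy$pair$bound)$DockQ
  qn <- dockq(toy$pair$bound, toy$pair$bound)$DockQ
  expect_lt(dev, 3)        # patch stays in place...
  expect_lt(q, qn - 0.2)   # ...but the model quality collapses
})
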