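# Independent oracles, deliberately written as naive reference
# implementations separate from the package code paths.

# Needleman-Wunsch with affine gaps (Gotoh), BLOSUM62 -----------------------
# Returns aligned position pairs (1-based), matching map_residues' contract.
oracle_nw_align <- function(s1, s2, gap_open = 11, gap_extend = 1) {
  bl <- get("get_blosum62", asNamespace("dockface"))()
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_extend * (i - 2)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_extend * (j - 2)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- bl[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
    }
  }
  # traceback
  pairs <- NULL
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  while (i > 1 || j > 1) {
    if (state == 1) {
      pairs <- rbind(c(i - 1, j - 1), pairs)
      s <- bl[a[i - 1], b[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      up <- c(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
      state <- c(1, 2)[which.max(up)]
      i <- i - 1
    } else {
      lf <- c(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
      state <- c(1, 3)[which.max(lf)]
      j <- j - 1
    }
  }
  list(pairs = pairs,
       score = max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
}

# SASA-drop interface oracle ------------------------------------------------
# Naive Shrake-Rupley with seeded random sphere points; returns per-residue
# SASA. Used to cross-check which residues lose area upon binding, not the
# exact area values.
oracle_sasa <- function(s, probe = 1.4, n_points = 2000, seed = 42) {
  set.seed(seed)
  u <- matrix(rnorm(n_points * 3), n_points, 3)
  u <- u / sqrt(rowSums(u^2))
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  at <- s$atoms
  r <- radii[at$element]; r[is.na(r)] <- 1.70
  r <- r + probe
  xyz <- cbind(at$x, at$y, at$z)
  sasa_atom <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) {
    pts <- sweep(u * r[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_len(nrow(at))) {
      if (j == i) next
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      acc <- acc & (d2 > r[j]^2)
    }
    sasa_atom[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  key <- res_key(at$chain, at$resno, at$insert)
  tapply(sasa_atom, factor(key, levels = unique(key)), sum)
}

oracle_interface_keys <- function(bound, chain, eps = 0.01, ...) {
  alone <- chain_structure(bound, chain)
  sa <- oracle_sasa(alone, ...)
  sc <- oracle_sasa(bound, ...)
  keys <- names(sa)
  keys[sa - sc[keys] > eps]
}

# Brute-force pair-sum score oracle ------------------------------------------
oracle_score <- function(Rpts, Lpts, p_rec, p_lig, d_threshold = 12) {
  s <- 0
  for (i in seq_len(nrow(Rpts))) {
    for (j in seq_len(nrow(Lpts))) {
      dx <- Rpts[i, 1] - Lpts[j, 1]
      dy <- Rpts[i, 2] - Lpts[j, 2]
      dz <- Rpts[i, 3] - Lpts[j, 3]
      d <- sqrt(dx * dx + dy * dy + dz * dz)
      if (d < d_threshold)
        s <- s + (-log(1 - p_rec[[i]] * p_lig[[j]]))
    }
  }
  s
}

# Exhaustive precision-recall sweep oracle -----------------------------------
oracle_pr <- function(probs, labels) {
  th <- sort(unique(probs), decreasing = TRUE)
  out <- data.frame(threshold = th, recall = NA_real_, precision = NA_real_)
  for (k in seq_along(th)) {
    pred <- probs >= th[k]
    out$recall[k] <- sum(pred & labels) / sum(labels)
    out$precision[k] <- sum(pred & labels) / sum(pred)
  }
  # trapezoid over recall, anchored at (0, precision of top threshold)
  r <- c(0, out$recall); p <- c(out$precision[1], out$precision)
  auc <- 0
  for (k in 2:length(r)) auc <- auc + (r[k] - r[k - 1]) * (p[k] + p[k - 1]) / 2
  list(curve = out, auc = auc)
}

# Sequential single-axis rotation oracle --------------------------------------
# Applies individual fixed-axis rotations to a point, in the order implied
# by the convention tag, without building a composed matrix.
oracle_rotate_point <- function(pt, euler_deg, convention) {
  rot1 <- function(p, axis, deg) {
    a <- deg * pi / 180
    c2 <- cos(a); s2 <- sin(a)
    switch(axis,
      x = c(p[1], c2 * p[2] - s2 * p[3], s2 * p[2] + c2 * p[3]),
      y = c(c2 * p[1] + s2 * p[3], p[2], -s2 * p[1] + c2 * p[3]),
      z = c(c2 * p[1] - s2 * p[2], s2 * p[1] + c2 * p[2], p[3]))
  }
  # intrinsic rotations about body axes equal extrinsic rotations about
  # fixed axes applied in reverse order
  steps <- switch(convention,
    "zyz-intrinsic" = list(c("z", 3), c("y", 2), c("z", 1)),
    "zyx-intrinsic" = list(c("x", 3), c("y", 2), c("z", 1)),
    "xyz-extrinsic" = list(c("x", 1), c("y", 2), c("z", 3)))
  for (st in steps) pt <- rot1(pt, st[1], euler_deg[as.integer(st[2])])
  pt
}
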