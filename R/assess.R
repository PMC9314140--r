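# ---------------------------------------------------------------------------
# Quality assessment: interface-prediction metrics (recall/precision,
# precision-recall AUC) and docking-model quality (DockQ, success rates,
# difficulty classes, interface center-of-mass deviation).
# ---------------------------------------------------------------------------

#' Recall (TPR) and precision (PPV) of a binary interface prediction
#'
#' TPR = TP / (TP + FN), PPV = TP / (TP + FP). An empty prediction has
#' recall 0 and undefined precision (returned as `NA`, not 0).
#'
#' @param predicted character vector of predicted interface residue keys.
#' @param native character vector of native interface residue keys, or an
#'   [interface_set()] together with `chain`.
#' @param chain chain id when `native` is an `interface_set`.
#' @return list with `TPR`, `PPV`, `TP`, `FP`, `FN`.
#' @export
confusion_rates <- function(predicted, native, chain = NULL) {
  if (inherits(native, "interface_set")) {
    stopifnot(!is.null(chain))
    native <- native$interface[[chain]]
  }
  if (!length(native)) stop("empty native interface")
  tp <- sum(predicted %in% native)
  fp <- length(predicted) - tp
  fn <- length(native) - tp
  list(TPR = tp / (tp + fn),
       PPV = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       TP = tp, FP = fp, FN = fn)
}

#' Precision-recall curve and area under it for one chain
#'
#' Unique probability values are swept as thresholds in decreasing order;
#' at each threshold residues with `p >= t` are called interface, giving
#' one (recall, precision) point. The default AUC integrates the curve
#' over recall by the trapezoidal rule, with an anchor at recall 0 and the
#' precision of the top threshold; `variant = "step"` instead computes the
#' step-wise average precision `sum((r_k - r_{k-1}) * p_k)`. The random
#' baseline is the interface-to-surface residue count ratio (I/S): a
#' constant predictor attains exactly that precision at every threshold.
#'
#' @param p an [interface_probs()] or a named probability vector.
#' @param native an [interface_set()].
#' @param chain chain id.
#' @param variant `"trapezoid"` (default) or `"step"`.
#' @return list of class `pr_curve`: `curve` (data.frame threshold,
#'   recall, precision), `auc`, `baseline` (I/S ratio), `n_interface`,
#'   `n_surface`.
#' @export
pr_auc <- function(p, native, chain, variant = c("trapezoid", "step")) {
  variant <- match.arg(variant)
  pv <- if (inherits(p, "interface_probs")) p$prob[[chain]] else p
  surf <- native$surface[[chain]]
  iface <- native$interface[[chain]]
  if (!length(iface)) stop("no positive residues on chain ", chain)
  probs <- numeric(length(surf)); names(probs) <- surf
  hit <- match(surf, names(pv))
  probs[!is.na(hit)] <- pv[hit[!is.na(hit)]]
  labels <- surf %in% iface
  th <- sort(unique(probs), decreasing = TRUE)
  rec <- prec <- numeric(length(th))
  for (k in seq_along(th)) {
    pred <- probs >= th[k]
    tp <- sum(pred & labels)
    rec[k] <- tp / sum(labels)
    prec[k] <- tp / sum(pred)
  }
  curve <- data.frame(threshold = th, recall = rec, precision = prec)
  if (variant == "trapezoid") {
    r <- c(0, rec); q <- c(prec[1], prec)
    auc <- sum(diff(r) * (utils::head(q, -1) + q[-1]) / 2)
  } else {
    r <- c(0, rec)
    auc <- sum(diff(r) * prec)
  }
  structure(list(curve = curve, auc = auc,
                 baseline = sum(labels) / length(labels),
                 n_interface = sum(labels), n_surface = length(labels)),
            class = "pr_curve")
}

#' Per-complex PR-AUC summary over both chains
#'
#' Emits the per-chain AUCs, their macro average (mean of per-chain AUCs),
#' the micro AUC (residues of both chains pooled) and the worst-chain AUC.
#'
#' @param p an [interface_probs()].
#' @param native an [interface_set()] with chains matching `p`.
#' @param variant passed to [pr_auc()].
#' @return list with `per_chain`, `macro`, `micro`, `worst_chain`.
#' @export
pr_auc_complex <- function(p, native, variant = "trapezoid") {
  chains <- names(native$interface)
  per <- vapply(chains, function(ch)
    pr_auc(p, native, ch, variant)$auc, numeric(1))
  pooled_p <- unlist(unname(p$prob))
  pooled <- interface_set(
    list(all = unlist(unname(native$interface))),
    list(all = unlist(unname(native$surface))))
  micro <- pr_auc(pooled_p, pooled, "all", variant)$auc
  list(per_chain = per, macro = mean(per), micro = micro,
       worst_chain = min(per))
}

#' Worst-chain selection
#'
#' Of a complex's two per-chain prediction AUCs, return the smaller one.
#'
#' @param auc_receptor,auc_ligand AUC values in \[0, 1\].
#' @export
worst_chain <- function(auc_receptor, auc_ligand) {
  stopifnot(auc_receptor >= 0, auc_receptor <= 1,
            auc_ligand >= 0, auc_ligand <= 1)
  pmin(auc_receptor, auc_ligand)
}

# ---------------------------------------------------------------------------
# DockQ
# ---------------------------------------------------------------------------

BACKBONE <- c("N", "CA", "C", "O")

# residue-pair contacts between the two chains of a complex:
# any heavy-atom pair within `cutoff`
interchain_contacts <- function(s, cutoff) {
  ids <- chain_ids(s)
  a <- chain_structure(s, ids[1]); b <- chain_structure(s, ids[2])
  A <- coords(a); B <- coords(b)
  ka <- res_key(a$atoms$chain, a$atoms$resno, a$atoms$insert)
  kb <- res_key(b$atoms$chain, b$atoms$resno, b$atoms$insert)
  pairs <- character(0)
  c2 <- cutoff^2
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
          (B[, 3] - A[i, 3])^2
    hit <- d2 < c2
    if (any(hit)) pairs <- c(pairs, paste(ka[i], kb[hit], sep = "|"))
  }
  unique(pairs)
}

backbone_coords <- function(s, keys) {
  a <- s$atoms
  k <- res_key(a$chain, a$resno, a$insert)
  sel <- k %in% keys & a$elety %in% BACKBONE
  a <- a[sel, , drop = FALSE]
  m <- cbind(a$x, a$y, a$z)
  rownames(m) <- paste(res_key(a$chain, a$resno, a$insert), a$elety)
  m
}

paired_backbone <- function(model, native, keys) {
  M <- backbone_coords(model, keys)
  N <- backbone_coords(native, keys)
  common <- intersect(rownames(M), rownames(N))
  if (length(common) < 3) stop("fewer than 3 paired backbone atoms")
  list(M = M[common, , drop = FALSE], N = N[common, , drop = FALSE])
}

#' DockQ quality of a docking model against the native complex
#'
#' Combines the fraction of native interchain residue contacts reproduced
#' (Fnat; heavy-atom contacts under 5 Angstrom), the backbone RMSD over
#' the native interface after interface superposition (iRMS; interface =
#' residues in native contacts under a 10 Angstrom shell) and the ligand
#' backbone RMSD after receptor superposition (LRMS):
#'
#'   DockQ = (Fnat + 1/(1+(iRMS/1.5)^2) + 1/(1+(LRMS/8.5)^2)) / 3
#'
#' CAPRI-style classes follow the 0.23 / 0.49 / 0.80 thresholds.
#'
#' Model and native must share chain ids; residues are paired by key
#' (apply [trim_unmatched()] / renumbering beforehand if they differ).
#'
#' @param model,native two-chain [structure3d()] objects; the first chain
#'   is treated as the receptor.
#' @return list of class `dockq_result`: `Fnat`, `fnonnat`, `iRMS`,
#'   `LRMS`, `DockQ`, `capri_class`.
#' @export
dockq <- function(model, native) {
  ids <- chain_ids(native)
  if (length(ids) != 2 || !identical(sort(chain_ids(model)), sort(ids)))
    stop("model and native must share the same two chain ids")
  nat_contacts <- interchain_contacts(native, 5)
  if (!length(nat_contacts))
    stop("no interchain contacts in the native complex")
  mod_contacts <- interchain_contacts(model, 5)
  fnat <- sum(mod_contacts %in% nat_contacts) / length(nat_contacts)
  fnonnat <- if (length(mod_contacts))
    sum(!mod_contacts %in% nat_contacts) / length(mod_contacts) else 0
  # interface residues: native contacts under a widened 10 A shell
  shell <- interchain_contacts(native, 10)
  iface_keys <- unique(unlist(strsplit(shell, "|", fixed = TRUE)))
  pb <- paired_backbone(model, native, iface_keys)
  irms <- kabsch(pb$M, pb$N)$rmsd
  # LRMS: superpose receptors, measure ligand backbone deviation
  rec_keys <- residue_table(native)$key[residue_table(native)$chain == ids[1]]
  lig_keys <- residue_table(native)$key[residue_table(native)$chain == ids[2]]
  pr <- paired_backbone(model, native, rec_keys)
  tr <- kabsch(pr$M, pr$N)
  pl <- paired_backbone(model, native, lig_keys)
  Lm <- apply_transform(pl$M, tr)
  lrms <- sqrt(mean(rowSums((Lm - pl$N)^2)))
  q <- (fnat + 1 / (1 + (irms / 1.5)^2) + 1 / (1 + (lrms / 8.5)^2)) / 3
  cls <- if (q >= 0.80) "high" else if (q >= 0.49) "medium"
         else if (q >= 0.23) "acceptable" else "incorrect"
  structure(list(Fnat = fnat, fnonnat = fnonnat, iRMS = irms, LRMS = lrms,
                 DockQ = q, capri_class = cls),
            class = "dockq_result")
}

#' @export
print.dockq_result <- function(x, ...) {
  cat(sprintf("DockQ %.3f (%s): Fnat %.3f, iRMS %.2f A, LRMS %.2f A\n",
              x$DockQ, x$capri_class, x$Fnat, x$iRMS, x$LRMS))
  invisible(x)
}

#' Top-N success rate over a benchmark
#'
#' SR(N): fraction of complexes with at least one acceptable model
#' (DockQ above `threshold`) among the N top-ranked models.
#'
#' @param results list (one element per complex) of numeric DockQ vectors
#'   ordered by model rank.
#' @param n number of top models considered.
#' @param threshold acceptability threshold (default 0.23).
#' @export
success_rate <- function(results, n = 10, threshold = 0.23) {
  stopifnot(n >= 1)
  if (!length(results)) stop("empty result set")
  mean(vapply(results, function(v) any(utils::head(v, n) > threshold),
              logical(1)))
}

#' Docking difficulty class from unbound-bound interface deviation
#'
#' Easy: i-RMSD under 1.5 Angstrom and non-native contact fraction under
#' 0.4; hard: i-RMSD of 2.2 Angstrom or more; everything between is
#' medium. Boundary values resolve upward in difficulty.
#'
#' @param i_rmsd interface C-alpha RMSD (Angstrom) between unbound and
#'   bound forms.
#' @param f_non_nat fraction of non-native contacts in the superposed
#'   unbound complex.
#' @return character vector: "easy", "medium" or "hard".
#' @export
classify_difficulty <- function(i_rmsd, f_non_nat) {
  if (any(i_rmsd < 0) || any(f_non_nat < 0) || any(f_non_nat > 1))
    stop("i_rmsd must be >= 0 and f_non_nat in [0,1]")
  ifelse(i_rmsd >= 2.2, "hard",
         ifelse(i_rmsd < 1.5 & f_non_nat < 0.4, "easy", "medium"))
}

#' Interface center-of-mass deviation of a docking model
#'
#' After superposing the model on the native receptor, the distance
#' between the centroid of the native-interface residues' representative
#' points in the native complex and the same residues in the model. Small
#' deviations with low DockQ diagnose correct-patch / wrong-orientation
#' failures (rotational ambiguity).
#'
#' @param model,native two-chain [structure3d()] objects with matching
#'   residue keys.
#' @param native_iface an [interface_set()] for the native complex.
#' @return deviation in Angstrom.
#' @export
interface_cm_deviation <- function(model, native, native_iface) {
  keys <- unlist(unname(native_iface$interface))
  if (!length(keys)) stop("empty native interface")
  ids <- chain_ids(native)
  rec_keys <- residue_table(native)$key[residue_table(native)$chain == ids[1]]
  pr <- paired_backbone(model, native, rec_keys)
  tr <- kabsch(pr$M, pr$N)
  pn <- rep_points(native)
  pm <- rep_points(model)
  if (!all(keys %in% rownames(pn)) || !all(keys %in% rownames(pm)))
    stop("interface residues missing from model or native")
  cm_nat <- colMeans(pn[keys, , drop = FALSE])
  cm_mod <- colMeans(apply_transform(pm[keys, , drop = FALSE], tr))
  sqrt(sum((cm_nat - cm_mod)^2))
}

#' Write per-model DockQ results as TSV
#' @param df data.frame with columns pose_id, Fnat, iRMS, LRMS, DockQ,
#'   class.
#' @param path output file.
#' @export
write_dockq_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
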