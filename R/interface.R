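# ---------------------------------------------------------------------------
# Native interfaces, prediction ingestion and normalization, and simulated
# noisy predictions at controlled recall (TPR) and precision (PPV).
# ---------------------------------------------------------------------------

#' Interface / surface residue sets of a complex
#'
#' @param interface named list (by chain) of interface residue keys.
#' @param surface named list (by chain) of surface residue keys; must be a
#'   superset of `interface` per chain.
#' @return list of class `interface_set`.
#' @export
interface_set <- function(interface, surface) {
  stopifnot(identical(names(interface), names(surface)))
  for (ch in names(interface))
    if (!all(interface[[ch]] %in% surface[[ch]]))
      stop("interface residues of chain ", ch, " not all on the surface")
  structure(list(interface = interface, surface = surface),
            class = "interface_set")
}

#' @export
print.interface_set <- function(x, ...) {
  for (ch in names(x$interface))
    cat("chain ", ch, ": ", length(x$interface[[ch]]), " interface / ",
        length(x$surface[[ch]]), " surface residues\n", sep = "")
  invisible(x)
}

#' Extract the native interface of a bound complex by SASA difference
#'
#' A residue belongs to the interface when its solvent accessible surface
#' area in the isolated chain exceeds its SASA in the complex (burial upon
#' binding). Surface residues are those with relative SASA of the isolated
#' chain above `surface_rel_cutoff`.
#'
#' @param bound two-chain [structure3d()].
#' @param probe_radius solvent probe radius in Angstrom.
#' @param delta_cutoff minimum SASA loss (Angstrom^2) to call a residue
#'   interface; a small positive value guards against numerical noise.
#' @param surface_rel_cutoff relative-SASA cutoff defining surface residues.
#' @param n_points sphere points for the SASA computation.
#' @return An [interface_set()].
#' @export
extract_native_interface <- function(bound, probe_radius = 1.4,
                                     delta_cutoff = 0.01,
                                     surface_rel_cutoff = 0.05,
                                     n_points = 960) {
  ids <- chain_ids(bound)
  if (length(ids) != 2) stop("bound complex must have two chains")
  sasa_cplx <- residue_sasa(bound, probe_radius, n_points)
  iface <- list(); surf <- list()
  rs <- residue_table(bound)
  for (ch in ids) {
    alone <- chain_structure(bound, ch)
    sasa_alone <- residue_sasa(alone, probe_radius, n_points)
    keys <- names(sasa_alone)
    delta <- sasa_alone - sasa_cplx[keys]
    iface[[ch]] <- keys[delta > delta_cutoff]
    resid <- rs$resid[match(keys, rs$key)]
    mx <- MAX_SASA[resid]; mx[is.na(mx)] <- MAX_SASA_DEFAULT
    surf[[ch]] <- keys[sasa_alone / mx > surface_rel_cutoff]
    # burial implies solvent exposure in the isolated chain
    surf[[ch]] <- union(surf[[ch]], iface[[ch]])
    ord <- match(keys, rs$key)
    surf[[ch]]  <- keys[keys %in% surf[[ch]]]
    iface[[ch]] <- keys[keys %in% iface[[ch]]]
  }
  interface_set(iface, surf)
}

#' Interface extraction fallback on superposed unbound coordinates
#'
#' For residues with no bound correspondence the SASA-difference criterion
#' is evaluated on the unbound chain superposed onto its bound counterpart:
#' the given chain of the bound complex is replaced by the transformed
#' unbound chain and the interface re-extracted.
#'
#' @param unbound single-chain [structure3d()] (unbound form).
#' @param bound two-chain bound complex.
#' @param transform `rigid_transform` superposing `unbound` onto its bound
#'   chain, e.g. from [superpose()].
#' @param chain id of the bound chain that `unbound` replaces.
#' @inheritParams extract_native_interface
#' @return An [interface_set()] for the composite complex.
#' @export
extract_interface_unbound_fallback <- function(unbound, bound, transform,
                                               chain,
                                               probe_radius = 1.4,
                                               delta_cutoff = 0.01,
                                               surface_rel_cutoff = 0.05,
                                               n_points = 960) {
  if (missing(transform) || !inherits(transform, "rigid_transform"))
    stop("a rigid_transform superposing unbound onto bound is required")
  ids <- chain_ids(bound)
  if (!chain %in% ids) stop("bound complex has no chain ", chain)
  moved <- apply_transform(unbound, transform)
  moved$atoms$chain <- chain
  other <- chain_structure(bound, setdiff(ids, chain))
  composite <- if (ids[1] == chain) combine_structures(moved, other)
               else combine_structures(other, moved)
  extract_native_interface(composite, probe_radius, delta_cutoff,
                           surface_rel_cutoff, n_points)
}

#' Per-residue interface probabilities
#'
#' @param prob named list (by chain) of named numeric vectors (residue key
#'   -> probability in \[0, 1\]).
#' @param provenance one of "native", "simulated", "external".
#' @param capped logical; whether the singularity cap has been applied.
#' @return list of class `interface_probs`.
#' @export
interface_probs <- function(prob, provenance = "external", capped = FALSE) {
  for (ch in names(prob)) {
    p <- prob[[ch]]
    if (any(p < 0 | p > 1)) stop("probabilities outside [0,1] on chain ", ch)
    if (is.null(names(p))) stop("probabilities must be named by residue key")
  }
  structure(list(prob = prob, provenance = provenance, capped = capped),
            class = "interface_probs")
}

#' Cap interface probabilities to avoid scoring singularities
#'
#' The pair score contains -ln(1 - p_i * p_j), which is singular at
#' p = 1; probabilities are therefore capped (default 0.99) before scoring.
#' Capping never reorders residues by probability.
#'
#' @param p an [interface_probs()].
#' @param cap upper limit (default 0.99).
#' @export
cap_probabilities <- function(p, cap = 0.99) {
  p$prob <- lapply(p$prob, function(v) pmin(v, cap))
  p$capped <- TRUE
  p
}

#' Simulate noisy interface predictions at target recall and precision
#'
#' Starting from the native interface, randomly selected interface residues
#' are dropped (marked non-interface) until the retained true-positive
#' count is `round(target_tpr * n_interface)`; then randomly selected
#' non-interface surface residues are added as false positives until the
#' precision reaches `target_ppv` (FP = round(TP * (1 - PPV)/PPV)). Marked
#' residues carry probability 0.99, all other surface residues 0. A single
#' seeded generator is consumed in chain order.
#'
#' @param native an [interface_set()] with nonempty interface per chain.
#' @param target_tpr,target_ppv targets in (0, 1].
#' @param seed integer seed; fixed seed gives identical output.
#' @return An [interface_probs()] with provenance "simulated".
#' @export
simulate_predictions <- function(native, target_tpr, target_ppv, seed) {
  stopifnot(target_tpr > 0, target_tpr <= 1,
            target_ppv > 0, target_ppv <= 1)
  set.seed(as.integer(seed))
  prob <- list()
  for (ch in names(native$interface)) {
    iface <- native$interface[[ch]]
    surf <- native$surface[[ch]]
    if (!length(iface)) stop("empty native interface on chain ", ch)
    n_tp <- round(target_tpr * length(iface))
    tp <- if (n_tp >= length(iface)) iface else sample(iface, n_tp)
    n_fp <- round(n_tp * (1 - target_ppv) / target_ppv)
    pool <- setdiff(surf, iface)
    if (n_fp > length(pool))
      stop(sprintf(paste0("chain %s: %d false positives requested but only",
                          " %d non-interface surface residues available",
                          " (achievable PPV >= %.3f)"),
                   ch, n_fp, length(pool),
                   n_tp / (n_tp + length(pool))))
    fp <- if (n_fp > 0) sample(pool, n_fp) else character(0)
    v <- stats::setNames(numeric(length(surf)), surf)
    v[c(tp, fp)] <- 0.99
    prob[[ch]] <- v
  }
  interface_probs(prob, provenance = "simulated", capped = TRUE)
}

#' Interchain contact-probability map
#'
#' @param p matrix of contact probabilities in \[0, 1\] with receptor
#'   residue keys as rownames and ligand residue keys as colnames.
#' @return matrix of class `contact_map`.
#' @export
contact_map <- function(p) {
  if (!length(p)) stop("empty contact map")
  if (any(p < 0 | p > 1)) stop("contact probabilities outside [0,1]")
  structure(p, class = c("contact_map", class(p)))
}

#' Reduce a contact map to per-residue interface probabilities
#'
#' Each residue receives the maximum contact probability over its partners
#' (row maxima for the receptor, column maxima for the ligand), the usual
#' surrogate when comparing contact predictors against interface
#' predictors.
#'
#' @param cmap a [contact_map()] or plain matrix.
#' @return An [interface_probs()] with chains named "A" (rows) and "B"
#'   (columns).
#' @export
contacts_to_interface <- function(cmap) {
  if (!length(cmap)) stop("empty contact map")
  m <- unclass(cmap)
  pr <- apply(m, 1, max)
  pl <- apply(m, 2, max)
  if (is.null(names(pr))) names(pr) <- as.character(seq_along(pr))
  if (is.null(names(pl))) names(pl) <- as.character(seq_along(pl))
  interface_probs(list(A = pr, B = pl), provenance = "external")
}

#' Convert binned distance probabilities (distogram) to contact
#' probabilities
#'
#' The contact probability of a residue pair is the probability mass in
#' the first `n_contact_bins` distance bins over the total mass; with the
#' conventional 37-bin 2-20 Angstrom binning the first 20 bins correspond
#' to the 12 Angstrom scoring threshold.
#'
#' @param distogram 3-d array `[receptor residue, ligand residue, bin]` of
#'   nonnegative bin probabilities.
#' @param n_contact_bins number of leading bins counted as contact
#'   (default 20).
#' @return A [contact_map()].
#' @export
bins_to_contact <- function(distogram, n_contact_bins = 20) {
  stopifnot(length(dim(distogram)) == 3)
  if (any(distogram < 0)) stop("negative bin probability")
  tot <- apply(distogram, c(1, 2), sum)
  if (any(tot == 0)) {
    bad <- which(tot == 0, arr.ind = TRUE)[1, ]
    stop("all-zero bin vector for residue pair (", bad[1], ", ", bad[2], ")")
  }
  nb <- min(n_contact_bins, dim(distogram)[3])
  num <- apply(distogram[, , seq_len(nb), drop = FALSE], c(1, 2), sum)
  m <- num / tot
  dimnames(m) <- dimnames(distogram)[1:2]
  contact_map(m)
}

# ---------------------------------------------------------------------------
# TSV interchange
# ---------------------------------------------------------------------------

#' Write interface probabilities as TSV (chain, resnum, icode, probability)
#' @param p an [interface_probs()].
#' @param path output file.
#' @export
write_probabilities <- function(p, path) {
  rows <- do.call(rbind, lapply(names(p$prob), function(ch) {
    parts <- strsplit(names(p$prob[[ch]]), ":", fixed = TRUE)
    data.frame(chain = ch,
               resnum = vapply(parts, function(x) x[2], ""),
               icode = vapply(parts, function(x)
                 if (length(x) >= 3) x[3] else "", ""),
               probability = as.numeric(p$prob[[ch]]))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read interface probabilities from TSV
#' @param path TSV with columns chain, resnum, icode, probability.
#' @param provenance provenance tag to attach.
#' @export
read_probabilities <- function(path, provenance = "external") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer",
                                         "character", "numeric"),
                          na.strings = NULL)
  prob <- lapply(split(df, df$chain), function(d)
    stats::setNames(d$probability, res_key(d$chain, d$resnum, d$icode)))
  interface_probs(prob, provenance = provenance)
}
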