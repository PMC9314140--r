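# ---------------------------------------------------------------------------
# Interface-probability rescoring of docking poses.
#
# The score of a pose is
#
#   S = sum_{i in receptor} sum_{j in ligand} -ln(1 - p_i * p_j)   if d_ij < d_t
#                                             0                    otherwise
#
# where p_i, p_j are per-residue interface probabilities (capped at 0.99 to
# avoid the singularity at p = 1) and d_ij is the distance between the
# residues' representative points (C-beta, C-alpha for glycine). The default
# threshold d_t is 12 Angstrom.
# ---------------------------------------------------------------------------

# Probability lookup: residues without an entry contribute p = 0.
prob_vector <- function(keys, p_chain) {
  v <- numeric(length(keys))
  if (!is.null(p_chain)) {
    hit <- match(keys, names(p_chain))
    v[!is.na(hit)] <- p_chain[hit[!is.na(hit)]]
  }
  if (any(v >= 1))
    stop("uncapped probability of 1 would make the score singular; ",
         "apply cap_probabilities() first")
  v
}

score_points <- function(Rpts, Lpts, p_rec, p_lig, d_threshold) {
  n1 <- nrow(Rpts); n2 <- nrow(Lpts)
  ii <- rep(seq_len(n1), each = n2)
  jj <- rep(seq_len(n2), times = n1)
  dx <- Rpts[ii, 1] - Lpts[jj, 1]
  dy <- Rpts[ii, 2] - Lpts[jj, 2]
  dz <- Rpts[ii, 3] - Lpts[jj, 3]
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  pp <- p_rec[ii] * p_lig[jj]
  sel <- which(d < d_threshold & pp > 0)
  s <- 0
  for (k in sel) s <- s + (-log(1 - pp[k]))
  s
}

#' Score a docking pose with interface probabilities
#'
#' Sums `-ln(1 - p_i * p_j)` over every receptor-ligand residue pair whose
#' representative points (C-beta, C-alpha fallback) lie within
#' `d_threshold`. Residues without a probability entry contribute p = 0.
#'
#' @param receptor receptor: a [structure3d()], or an n x 3 matrix of
#'   representative points with residue keys as rownames.
#' @param ligand posed ligand: a [structure3d()] or an n x 3 coordinate
#'   matrix of representative points with residue keys as rownames.
#' @param p_rec,p_lig named probability vectors (residue key -> p), or an
#'   [interface_probs()] in which case the chains "A"/"B" (or the sole
#'   chain) are used.
#' @param d_threshold contact distance threshold in Angstrom (default 12;
#'   8 and 10 are the common alternatives).
#' @return nonnegative numeric score.
#' @export
score_pose <- function(receptor, ligand, p_rec, p_lig, d_threshold = 12) {
  stopifnot(d_threshold > 0)
  Rpts <- if (inherits(receptor, "structure3d")) rep_points(receptor)
          else receptor
  Lpts <- if (inherits(ligand, "structure3d")) rep_points(ligand) else ligand
  pr <- prob_vector(rownames(Rpts), resolve_chain_probs(p_rec))
  pl <- prob_vector(rownames(Lpts), resolve_chain_probs(p_lig))
  score_points(Rpts, Lpts, pr, pl, d_threshold)
}

resolve_chain_probs <- function(p) {
  if (inherits(p, "interface_probs")) {
    if (length(p$prob) == 1) return(p$prob[[1]])
    stop("pass a single chain's probabilities (e.g. p$prob[[\"A\"]])")
  }
  p
}

#' Score every pose of a decoy set
#'
#' Ligand representative points are transformed per pose directly (rigid
#' motion commutes with point extraction), with the rotation origin at the
#' ligand's atom centroid as in [pose_to_coords()].
#'
#' @param decoys a [decoy_set()].
#' @param p an [interface_probs()] with entries for chains "A" (receptor)
#'   and "B" (ligand), or a list with those names.
#' @param d_threshold contact threshold in Angstrom.
#' @return numeric vector of scores, one per pose, in pose order.
#' @export
score_decoys <- function(decoys, p, d_threshold = 12) {
  prob <- if (inherits(p, "interface_probs")) p$prob else p
  Rpts <- rep_points(decoys$receptor)
  Lpts <- rep_points(decoys$ligand_reference)
  ctr <- colMeans(coords(decoys$ligand_reference))
  pr <- prob_vector(rownames(Rpts), prob[["A"]])
  pl <- prob_vector(rownames(Lpts), prob[["B"]])
  vapply(decoys$poses, function(ps) {
    R <- euler_matrix(ps$euler, decoys$convention)
    moved <- sweep(sweep(Lpts, 2, ctr) %*% t(R), 2,
                   ctr + ps$translation, `+`)
    score_points(Rpts, moved, pr, pl, d_threshold)
  }, numeric(1))
}

#' Rank poses by score
#'
#' Descending score; ties keep the original pose order (stable sort).
#'
#' @param decoys a [decoy_set()] (or any list of poses with `$id`).
#' @param scores numeric vector, one score per pose.
#' @param top_n size of the retained head of the ranking (default 10).
#' @return list with `ranked` (data.frame pose_id, score, rank) and `top`
#'   (the first `top_n` rows).
#' @export
rank_poses <- function(decoys, scores, top_n = 10) {
  poses <- if (inherits(decoys, "decoy_set")) decoys$poses else decoys
  if (length(poses) != length(scores))
    stop("length mismatch: ", length(poses), " poses vs ",
         length(scores), " scores")
  ids <- vapply(poses, function(p) p$id, integer(1))
  ord <- order(-scores, seq_along(scores))
  ranked <- data.frame(pose_id = ids[ord], score = scores[ord],
                       rank = seq_along(ord))
  list(ranked = ranked, top = utils::head(ranked, top_n))
}

# ---------------------------------------------------------------------------
# Distance restraints from interface predictions
# ---------------------------------------------------------------------------

#' Build a distance-restraint set from interface predictions
#'
#' Takes the `k` residues with the highest probability per chain (ties by
#' residue order). For categorical predictors, where every marked residue
#' carries the same probability and no ranking exists, `k` marked residues
#' are drawn uniformly at random instead. Each restraint requires the
#' residue to lie within `[d_min, d_max]` of the partner chain; a model
#' passes when at least `min_satisfied` restraints hold.
#'
#' @param p an [interface_probs()].
#' @param k restraints per chain (default 10).
#' @param d_min,d_max distance window in Angstrom (defaults 2 and 8).
#' @param min_satisfied minimum satisfied restraints for a pass (default 5).
#' @param seed seed for the categorical random draw.
#' @return list of class `restraint_set` with `residues` (per-chain key
#'   list), `d_min`, `d_max`, `min_satisfied`, `short` (TRUE when a chain
#'   had fewer than `k` positive residues).
#' @export
make_restraints <- function(p, k = 10, d_min = 2, d_max = 8,
                            min_satisfied = 5, seed = 1) {
  stopifnot(k >= 1, d_min < d_max)
  set.seed(as.integer(seed))
  short <- FALSE
  residues <- lapply(p$prob, function(v) {
    pos <- v[v > 0]
    if (length(pos) < k) {
      short <<- TRUE
      return(names(pos))
    }
    if (length(unique(pos)) == 1) {
      # categorical marks: no ranking available, draw at random
      idx <- sort(sample(seq_along(pos), k))
      return(names(pos)[idx])
    }
    ord <- order(-pos, seq_along(pos))
    names(pos)[ord[seq_len(k)]]
  })
  if (short)
    warning("fewer than ", k, " positive residues on some chain; ",
            "restraint set is short")
  structure(list(residues = residues, d_min = d_min, d_max = d_max,
                 min_satisfied = min_satisfied, short = short),
            class = "restraint_set")
}

#' Check restraint satisfaction on a docking model
#'
#' A restraint is satisfied when the minimum heavy-atom distance from its
#' residue to any atom of the partner chain lies within the window.
#'
#' @param receptor receptor [structure3d()] (chain A).
#' @param ligand posed ligand [structure3d()] (chain B).
#' @param restraints a `restraint_set` from [make_restraints()].
#' @return list with `satisfied` (count), `total`, `pass` (logical) and
#'   `per_restraint` (named logical vector).
#' @export
check_restraints <- function(receptor, ligand, restraints) {
  chains <- list(A = receptor, B = ligand)
  per <- logical(0)
  for (ch in names(restraints$residues)) {
    own <- chains[[ch]]
    partner <- chains[[setdiff(names(chains), ch)]]
    if (is.null(own)) stop("no structure for chain ", ch)
    P <- coords(partner)
    ak <- res_key(own$atoms$chain, own$atoms$resno, own$atoms$insert)
    for (key in restraints$residues[[ch]]) {
      idx <- which(ak == key)
      if (!length(idx)) stop("restraint residue not in model: ", key)
      A <- coords(own)[idx, , drop = FALSE]
      dmin <- min_cross_distance(A, P)
      per[key] <- dmin >= restraints$d_min & dmin <= restraints$d_max
    }
  }
  satisfied <- sum(per)
  list(satisfied = satisfied, total = length(per),
       pass = satisfied >= restraints$min_satisfied, per_restraint = per)
}

#' Serialize a restraint set as JSON
#'
#' The layout (per-residue entries with a relaxed distance window and a
#' minimum-satisfied count) matches what restraint-accepting docking
#' servers consume.
#'
#' @param restraints a `restraint_set`.
#' @param path output JSON file.
#' @export
write_restraints <- function(restraints, path) {
  obj <- list(
    d_min = restraints$d_min, d_max = restraints$d_max,
    min_satisfied = restraints$min_satisfied,
    restraints = do.call(rbind, lapply(names(restraints$residues),
      function(ch) {
        parts <- strsplit(restraints$residues[[ch]], ":", fixed = TRUE)
        data.frame(chain = ch,
                   resnum = as.integer(vapply(parts, `[`, "", 2)),
                   icode = vapply(parts, function(x)
                     if (length(x) >= 3) x[3] else "", ""))
      })))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a score table as TSV (pose_id, score, rank)
#' @param ranked data.frame from [rank_poses()] (`$ranked`).
#' @param path output file.
#' @export
write_scores <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
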