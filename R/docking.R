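# ---------------------------------------------------------------------------
# Rigid-body poses: a translation vector plus three Euler angles per decoy,
# the parameterization emitted by FFT scan-stage docking programs.
# ---------------------------------------------------------------------------

EULER_CONVENTIONS <- c("zyz-intrinsic", "zyx-intrinsic", "xyz-extrinsic")

#' Construct a rigid-body docking pose
#'
#' @param id integer pose id.
#' @param translation numeric length-3 translation in Angstrom, applied to
#'   the ligand after rotation about its centroid.
#' @param euler numeric length-3 Euler angles in degrees; normalized to
#'   \[0, 360).
#' @return list of class `pose`.
#' @export
pose <- function(id, translation = c(0, 0, 0), euler = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(euler) == 3,
            all(is.finite(translation)), all(is.finite(euler)))
  structure(list(id = as.integer(id),
                 translation = as.numeric(translation),
                 euler = as.numeric(euler) %% 360),
            class = "pose")
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix for an Euler-angle triple
#'
#' Supported conventions: `zyz-intrinsic` (default; R = Rz(a1) Ry(a2)
#' Rz(a3)), `zyx-intrinsic` (Rz(a1) Ry(a2) Rx(a3)) and `xyz-extrinsic`
#' (rotations about the fixed x, then y, then z axes; R = Rz(a3) Ry(a2)
#' Rx(a1)).
#'
#' @param euler_deg numeric length-3 angles in degrees.
#' @param convention convention tag.
#' @return 3x3 rotation matrix.
#' @export
euler_matrix <- function(euler_deg, convention = "zyz-intrinsic") {
  if (!convention %in% EULER_CONVENTIONS)
    stop("unknown Euler convention: ", convention,
         " (supported: ", paste(EULER_CONVENTIONS, collapse = ", "), ")")
  a <- euler_deg * pi / 180
  switch(convention,
    "zyz-intrinsic" = rot_z(a[1]) %*% rot_y(a[2]) %*% rot_z(a[3]),
    "zyx-intrinsic" = rot_z(a[1]) %*% rot_y(a[2]) %*% rot_x(a[3]),
    "xyz-extrinsic" = rot_z(a[3]) %*% rot_y(a[2]) %*% rot_x(a[1]))
}

#' Apply a pose to ligand coordinates
#'
#' The ligand is rotated about its centroid by the pose's Euler triple and
#' then translated; the receptor frame is untouched.
#'
#' @param ligand a [structure3d()] (the reference ligand).
#' @param pose a [pose()].
#' @param convention Euler convention tag (see [euler_matrix()]).
#' @return n_atoms x 3 coordinate matrix of the posed ligand.
#' @export
pose_to_coords <- function(ligand, pose, convention = "zyz-intrinsic") {
  X <- coords(ligand)
  R <- euler_matrix(pose$euler, convention)
  ctr <- colMeans(X)
  sweep(sweep(X, 2, ctr) %*% t(R), 2, ctr + pose$translation, `+`)
}

#' Apply a pose, returning the posed ligand structure
#' @inheritParams pose_to_coords
#' @export
apply_pose <- function(ligand, pose, convention = "zyz-intrinsic") {
  set_coords(ligand, pose_to_coords(ligand, pose, convention))
}

#' Ordered set of docking decoys for one complex
#'
#' @param receptor fixed-frame receptor [structure3d()].
#' @param ligand_reference reference ligand structure (poses transform it).
#' @param poses list of [pose()] objects with unique ids.
#' @param convention Euler convention of the poses.
#' @return list of class `decoy_set`.
#' @export
decoy_set <- function(receptor, ligand_reference, poses,
                      convention = "zyz-intrinsic") {
  ids <- vapply(poses, function(p) p$id, integer(1))
  if (anyDuplicated(ids)) stop("pose ids are not unique")
  structure(list(receptor = receptor, ligand_reference = ligand_reference,
                 poses = poses, convention = convention),
            class = "decoy_set")
}

# ---------------------------------------------------------------------------
# Pose tables (GRAMM-style scan-stage output)
# ---------------------------------------------------------------------------

#' Parse a whitespace-delimited pose table
#'
#' Rows: `id tx ty tz e1 e2 e3`; comment lines start with `#`. Row order
#' is preserved as the initial (scan-stage) rank.
#'
#' @param path file path.
#' @return list of [pose()] objects in file order.
#' @export
parse_pose_table <- function(path) {
  lines <- readLines(path)
  poses <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 7 || any(is.na(v)))
      stop("malformed pose row at line ", i, " of ", path)
    poses[[length(poses) + 1]] <- pose(v[1], v[2:4], v[5:7])
  }
  poses
}

#' Write a pose table
#'
#' @param poses list of [pose()] objects.
#' @param path output file.
#' @param convention Euler convention, recorded in the header so reruns are
#'   reproducible.
#' @export
write_pose_table <- function(poses, path, convention = "zyz-intrinsic") {
  hdr <- c("# pose table: id tx ty tz e1 e2 e3",
           paste0("# euler_convention: ", convention))
  rows <- vapply(poses, function(p)
    sprintf("%d %.6f %.6f %.6f %.6f %.6f %.6f", p$id,
            p$translation[1], p$translation[2], p$translation[3],
            p$euler[1], p$euler[2], p$euler[3]), "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Toy decoy generation (stands in for the FFT scan stage)
# ---------------------------------------------------------------------------

min_cross_distance <- function(A, B) {
  # minimum interatomic distance between two coordinate sets
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    m <- min(d2)
    if (m < best) best <- m
  }
  sqrt(best)
}

#' Generate a toy decoy set spanning near-native to wrong-site poses
#'
#' `n_near_native` poses perturb the native pose (each Euler angle within
#' +/-5 degrees, so the total rotation stays below 15 degrees, and
#' translations of up to 3 Angstrom); the remaining poses are random
#' orientations placed along random directions from the receptor so that
#' the two surfaces touch (minimum interatomic distance between 2.5 and
#' 5 Angstrom).
#'
#' @param receptor,ligand [structure3d()] objects (ligand in its native
#'   placement relative to the receptor).
#' @param n total pose count.
#' @param n_near_native number of near-native poses (placed first).
#' @param native_pose the [pose()] that reproduces the native placement of
#'   `ligand` (identity if `ligand` is already placed).
#' @param seed integer; fixed seed gives an identical pose table.
#' @param convention Euler convention tag.
#' @return A [decoy_set()].
#' @export
generate_toy_decoys <- function(receptor, ligand, n, n_near_native,
                                native_pose = pose(0L), seed = 1,
                                convention = "zyz-intrinsic") {
  stopifnot(n >= n_near_native, n_near_native >= 0)
  set.seed(as.integer(seed))
  Rcoords <- coords(receptor)
  Lref <- coords(ligand)
  ctrL <- colMeans(Lref)
  ctrR <- colMeans(Rcoords)
  poses <- vector("list", n)
  for (k in seq_len(n_near_native)) {
    de <- runif(3, -5, 5)
    dt <- runif(3, -1, 1)
    dt <- dt / max(1e-9, sqrt(sum(dt^2))) * runif(1, 0, 3)
    poses[[k]] <- pose(k, native_pose$translation + dt,
                       native_pose$euler + de)
  }
  for (k in seq(from = n_near_native + 1, length.out = n - n_near_native)) {
    placed <- FALSE
    for (attempt in seq_len(1000)) {
      eu <- c(runif(1, 0, 360), runif(1, 0, 180), runif(1, 0, 360))
      R <- euler_matrix(eu, convention)
      Lrot <- sweep(sweep(Lref, 2, ctrL) %*% t(R), 2, ctrL, `+`)
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      # bracket the touching distance along direction u, then bisect
      lo <- 0
      hi <- 2 * (max(sqrt(rowSums(sweep(Rcoords, 2, ctrR)^2))) +
                 max(sqrt(rowSums(sweep(Lref, 2, ctrL)^2))) + 10)
      ok <- FALSE
      for (it in seq_len(60)) {
        mid <- (lo + hi) / 2
        shift <- ctrR + mid * u - ctrL
        d <- min_cross_distance(Rcoords,
                                sweep(Lrot, 2, shift, `+`))
        if (d < 2.5) lo <- mid
        else if (d > 5) hi <- mid
        else { ok <- TRUE; break }
      }
      if (ok) {
        poses[[k]] <- pose(k, ctrR + mid * u - ctrL, eu)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place a touching, non-clashing pose in 1000 attempts")
  }
  decoy_set(receptor, ligand, poses, convention)
}
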