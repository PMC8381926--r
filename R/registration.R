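#' Registration quality metrics
#'
#' Mirrors the quality metrics used in marker-based radiostereometry: the
#' condition number describes the spread of the marker configuration (high
#' values mean near-degenerate, e.g. almost collinear, configurations) and
#' the mean error of rigid-body fitting is the RMS marker residual after the
#' best rigid fit (high values mean unstable markers).
#'
#' @param mean_error_mm RMS residual after the rigid fit (mm).
#' @param condition_number ratio of largest to smallest singular value of
#'   the centred point matrix; `Inf` for degenerate sets.
#' @param n_points number of points used.
#' @param converged logical convergence flag (always `TRUE` for closed-form
#'   fits).
#' @param iterations iteration count (0 for closed-form fits).
#' @return An object of class `registration_quality`.
#' @export
registration_quality <- function(mean_error_mm, condition_number, n_points,
                                 converged = TRUE, iterations = 0L) {
  if (!is.na(mean_error_mm) && mean_error_mm < 0)
    stop("mean_error_mm must be >= 0", call. = FALSE)
  if (!is.na(condition_number) && is.finite(condition_number) &&
      condition_number < 1 - 1e-9)
    stop("condition_number must be >= 1", call. = FALSE)
  structure(list(mean_error_mm = mean_error_mm,
                 condition_number = condition_number,
                 n_points = n_points, converged = converged,
                 iterations = as.integer(iterations)),
            class = "registration_quality")
}

#' @export
print.registration_quality <- function(x, ...) {
  cat(sprintf(
    "<registration_quality> ME = %.4f mm, CN = %.2f, n = %s, %s (%d iter)\n",
    x$mean_error_mm, x$condition_number, format(x$n_points),
    if (isTRUE(x$converged)) "converged" else "NOT converged",
    x$iterations))
  invisible(x)
}

as_points <- function(x) {
  if (inherits(x, "bead_set")) return(x$points)
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  x
}

#' Condition number of a marker configuration
#'
#' Ratio of the largest to the smallest singular value of the centred
#' coordinate matrix (rows are points minus their centroid). 1 for an
#' isotropic configuration (e.g. a regular tetrahedron); `Inf` for
#' rank-deficient (collinear) sets. Invariant under rigid motion and under
#' uniform scaling of the configuration.
#'
#' @param points n x 3 matrix (or [bead_set()]) with n >= 3.
#' @return A scalar >= 1, possibly `Inf`.
#' @export
condition_number <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 3L)
    stop("condition_number requires at least 3 points", call. = FALSE)
  centred <- sweep(p, 2L, colMeans(p))
  sv <- svd(centred, nu = 0, nv = 0)$d
  if (sv[3] <= sv[1] * 1e-12) return(Inf)
  sv[1] / sv[3]
}

#' Least-squares rigid fit of matched point sets (Kabsch)
#'
#' Finds the proper rigid transform minimising
#' \eqn{\sum_i |R s_i + t - t_i|^2} for 1:1 matched source and target
#' points, via SVD of the cross-covariance with reflection correction. The
#' returned quality carries the RMS residual (the radiostereometric "mean
#' error of rigid-body fitting") and the condition number of the source
#' configuration.
#'
#' @param source,target n x 3 matrices (or [bead_set()]s), matched row by
#'   row, n >= 3 and non-collinear.
#' @return A list `(transform, quality)`.
#' @export
kabsch_fit <- function(source, target) {
  s <- as_points(source)
  t_ <- as_points(target)
  if (nrow(s) != nrow(t_))
    stop("source and target must have the same number of points",
         call. = FALSE)
  if (nrow(s) < 3L)
    stop("rigid fit requires at least 3 matched points", call. = FALSE)
  cs <- colMeans(s)
  ct <- colMeans(t_)
  sc <- sweep(s, 2L, cs)
  tc <- sweep(t_, 2L, ct)
  sv_src <- svd(sc, nu = 0, nv = 0)$d
  if (sv_src[2] <= sv_src[1] * 1e-9)
    stop("degenerate (collinear) point set: centred source matrix has rank ",
         "< 2; rigid fit is not well-posed", call. = FALSE)
  H <- crossprod(sc, tc)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  tr <- ct - drop(R %*% cs)
  transform <- rigid_transform(R, tr)
  resid <- rt_apply(transform, s) - t_
  rms <- sqrt(mean(rowSums(resid^2)))
  cn <- if (sv_src[3] <= sv_src[1] * 1e-12) Inf else sv_src[1] / sv_src[3]
  list(transform = transform,
       quality = registration_quality(rms, cn, nrow(s), TRUE, 0L))
}

#' Marker quality gate
#'
#' Pass/fail decision in the radiostereometric style: the examination fails
#' when the condition number reaches `cn_max` (default 100) or the mean
#' error of rigid-body fitting reaches `me_max_mm` (default 0.30 mm). All
#' failing reasons are enumerated.
#'
#' @param quality a [registration_quality()].
#' @param cn_max condition-number limit.
#' @param me_max_mm mean-error limit in mm.
#' @return A list `(pass, reasons)` where `reasons` is a character vector,
#'   empty on pass.
#' @export
quality_gate <- function(quality, cn_max = 100, me_max_mm = 0.30) {
  stopifnot(inherits(quality, "registration_quality"))
  reasons <- character(0)
  cn <- quality$condition_number
  if (is.na(cn) || !is.finite(cn) || cn >= cn_max)
    reasons <- c(reasons, sprintf(
      "condition number %s >= limit %g (marker spread too degenerate)",
      format(cn, digits = 4), cn_max))
  me <- quality$mean_error_mm
  if (is.na(me) || me >= me_max_mm)
    reasons <- c(reasons, sprintf(
      "mean error of rigid body fitting %s mm >= limit %g mm (markers unstable)",
      format(me, digits = 4), me_max_mm))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Match beads between two examinations
#'
#' Applies `init` to set A, then pairs beads by mutual nearest neighbour.
#' Unmatched beads on either side are tolerated and reported (the 3-d
#' analogue of marker dropout), as long as at least 3 mutual pairs remain.
#' Nearest-neighbour ties are broken towards the smaller label index, so
#' matching is deterministic.
#'
#' @param set_a,set_b [bead_set()]s with at least 3 beads each.
#' @param init initial `rigid_transform` mapping A's frame towards B's
#'   (identity by default).
#' @param max_pair_distance_mm pairs farther apart than this after `init`
#'   are rejected (default `Inf`).
#' @return A data.frame with columns `label_a`, `label_b`, `distance_mm`;
#'   attributes `unmatched_a` and `unmatched_b` list dropped labels.
#' @export
match_beads <- function(set_a, set_b, init = rt_identity(),
                        max_pair_distance_mm = Inf) {
  stopifnot(inherits(set_a, "bead_set"), inherits(set_b, "bead_set"))
  if (n_beads(set_a) < 3L || n_beads(set_b) < 3L)
    stop("both bead sets need at least 3 beads", call. = FALSE)
  pa <- rt_apply(init, set_a$points)
  pb <- set_b$points
  ab <- .nn_index(pb, pa)   # for each a: nearest b
  ba <- .nn_index(pa, pb)   # for each b: nearest a
  ia <- seq_len(nrow(pa))
  mutual <- ba$index[ab$index] == ia & ab$dist <= max_pair_distance_mm
  pairs <- data.frame(label_a = set_a$labels[ia[mutual]],
                      label_b = set_b$labels[ab$index[mutual]],
                      distance_mm = ab$dist[mutual])
  pairs <- pairs[order(pairs$label_a), , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) < 3L)
    stop(sprintf(
      "only %d mutual bead pair(s) found (need >= 3); check the initial alignment",
      nrow(pairs)), call. = FALSE)
  attr(pairs, "unmatched_a") <- setdiff(set_a$labels, pairs$label_a)
  attr(pairs, "unmatched_b") <- setdiff(set_b$labels, pairs$label_b)
  pairs
}

deterministic_subsample <- function(points, n_max, seed) {
  if (nrow(points) <= n_max) return(points)
  withr::with_seed(as.integer(seed), {
    points[sort(sample.int(nrow(points), n_max)), , drop = FALSE]
  })
}

#' Iterative closest point rigid registration
#'
#' Point-to-point ICP: at each iteration every source point is paired with
#' its nearest target point, the matched-point rigid fit ([kabsch_fit()])
#' is solved in closed form, and the transform is updated. Stops when the
#' change in RMS distance falls below `tol_mm` or after `max_iter`
#' iterations. The best iterate (lowest RMS) is returned; if the RMS never
#' decreased from the initial alignment, `converged` is `FALSE`.
#'
#' @param source,target n x 3 point matrices (world mm); at least 100
#'   points each are recommended.
#' @param init initial `rigid_transform` (identity allowed; see
#'   [coarse_align()]).
#' @param max_iter maximum iterations (default 100).
#' @param tol_mm convergence tolerance on the RMS change (default 1e-4 mm).
#' @param max_target_points the target cloud is subsampled to at most this
#'   many points with a fixed seed (default 50000).
#' @param max_source_points likewise for the source cloud (default 20000).
#' @param seed seed for the deterministic subsampling.
#' @return A list `(transform, quality)`; the quality carries the final RMS
#'   and the iteration count.
#' @export
icp_register <- function(source, target, init = rt_identity(),
                         max_iter = 100L, tol_mm = 1e-4,
                         max_target_points = 50000L,
                         max_source_points = 20000L, seed = 1L) {
  src_full <- as_points(source)
  tgt <- as_points(target)
  if (nrow(src_full) < 3L || nrow(tgt) < 3L)
    stop("ICP needs at least 3 points on each side", call. = FALSE)
  src <- deterministic_subsample(src_full, max_source_points, seed)
  tgt <- deterministic_subsample(tgt, max_target_points, seed + 1L)

  transform <- init
  best <- list(transform = init, rms = Inf, iter = 0L)
  prev_rms <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    moved <- rt_apply(transform, src)
    nn <- .nn_index(tgt, moved)
    rms <- sqrt(mean(nn$dist^2))
    if (rms < best$rms) {
      best <- list(transform = transform, rms = rms, iter = iter)
    }
    if (is.finite(prev_rms) && abs(prev_rms - rms) < tol_mm) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
    fit <- kabsch_fit(src, tgt[nn$index, , drop = FALSE])
    transform <- fit$transform
  }
  # quality at the best iterate
  moved <- rt_apply(best$transform, src)
  nn <- .nn_index(tgt, moved)
  rms <- sqrt(mean(nn$dist^2))
  quality <- registration_quality(rms, condition_number(src), nrow(src),
                                  converged, iter)
  list(transform = best$transform, quality = quality)
}

#' Point-to-plane ICP rigid registration
#'
#' Variant of [icp_register()] that minimises the distance from each
#' transformed source point to the tangent plane of its nearest target
#' point. On smooth surfaces the point-to-plane metric lets the alignment
#' slide along the surface instead of locking onto the sampling pattern, so
#' it converges far faster and avoids the shallow local minima that trap
#' point-to-point ICP. Each iteration solves the small-angle linearised
#' least-squares problem for the 6-DOF update.
#'
#' @param source n x 3 source points (world mm).
#' @param target m x 3 target points with unit normals (e.g. from
#'   [subvoxel_surface_points()] with `with_normals = TRUE`).
#' @param target_normals m x 3 unit normals of the target points; taken
#'   from `attr(target, "normals")` when omitted.
#' @param init initial `rigid_transform`.
#' @param max_iter,tol_mm iteration cap and convergence tolerance on the
#'   change in RMS plane distance.
#' @param max_target_points,max_source_points,seed deterministic
#'   subsampling controls as in [icp_register()].
#' @param anchors optional list with matched point sets `a` (source frame)
#'   and `b` (target frame), e.g. paired fiducial beads. They enter the
#'   least-squares problem as exact point-to-point correspondences with
#'   total weight `anchor_mass` relative to the surface term, pinning
#'   directions in which the surface alone is (nearly) self-similar — such
#'   as rotation along a screw thread.
#' @param anchor_mass total anchor weight as a multiple of the total
#'   surface weight (default 1: anchors and surface contribute equally).
#' @return A list `(transform, quality)`; `mean_error_mm` is the RMS
#'   point-to-plane distance at the final pose.
#' @export
icp_register_plane <- function(source, target, target_normals = NULL,
                               init = rt_identity(), max_iter = 100L,
                               tol_mm = 1e-4, max_target_points = 50000L,
                               max_source_points = 20000L, seed = 1L,
                               anchors = NULL, anchor_mass = 1) {
  src_full <- as_points(source)
  if (is.null(target_normals)) target_normals <- attr(target, "normals")
  if (is.null(target_normals))
    stop("target normals are required (see subvoxel_surface_points)",
         call. = FALSE)
  tgt <- as_points(target)
  stopifnot(nrow(target_normals) == nrow(tgt))
  src <- deterministic_subsample(src_full, max_source_points, seed)
  if (nrow(tgt) > max_target_points) {
    withr::with_seed(as.integer(seed) + 1L, {
      keep <- sort(sample.int(nrow(tgt), max_target_points))
    })
    tgt <- tgt[keep, , drop = FALSE]
    target_normals <- target_normals[keep, , drop = FALSE]
  }
  if (!is.null(anchors)) {
    pa <- as_points(anchors$a)
    pb <- as_points(anchors$b)
    stopifnot(nrow(pa) == nrow(pb), nrow(pa) >= 1L)
    w_anchor <- anchor_mass * nrow(src) / (3 * nrow(pa))
  }
  transform <- init
  best <- list(transform = init, rms = Inf, iter = 0L)
  prev_rms <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    moved <- rt_apply(transform, src)
    nn <- .nn_index(tgt, moved)
    q <- tgt[nn$index, , drop = FALSE]
    n <- target_normals[nn$index, , drop = FALSE]
    r <- rowSums((moved - q) * n)
    rms <- sqrt(mean(r^2))
    if (rms < best$rms) best <- list(transform = transform, rms = rms,
                                     iter = iter)
    if (is.finite(prev_rms) && abs(prev_rms - rms) < tol_mm) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
    # rowwise p x n
    cxp <- cbind(moved[, 2] * n[, 3] - moved[, 3] * n[, 2],
                 moved[, 3] * n[, 1] - moved[, 1] * n[, 3],
                 moved[, 1] * n[, 2] - moved[, 2] * n[, 1])
    A <- cbind(cxp, n)
    if (!is.null(anchors)) {
      ma <- rt_apply(transform, pa)
      ra <- ma - pb
      sw <- sqrt(w_anchor)
      # three axis-aligned point equations per anchor, weighted
      rows <- NULL
      rhs <- NULL
      for (ax in 1:3) {
        e <- c(0, 0, 0); e[ax] <- 1
        cx <- cbind(ma[, 2] * e[3] - ma[, 3] * e[2],
                    ma[, 3] * e[1] - ma[, 1] * e[3],
                    ma[, 1] * e[2] - ma[, 2] * e[1])
        rows <- rbind(rows, sw * cbind(cx,
                                       matrix(e, nrow(ma), 3,
                                              byrow = TRUE)))
        rhs <- c(rhs, sw * ra[, ax])
      }
      A <- rbind(A, rows)
      r <- c(r, rhs)
    }
    x <- tryCatch(solve(crossprod(A) + 1e-9 * diag(6), -crossprod(A, r)),
                  error = function(e) NULL)
    if (is.null(x)) break
    omega <- x[1:3]
    dt <- x[4:6]
    ang <- sqrt(sum(omega^2))
    Rd <- if (ang > 1e-14) rotation_about_axis(omega / ang, ang * 180 / pi)
          else diag(3)
    transform <- rigid_transform(Rd %*% transform$R,
                                 drop(Rd %*% transform$t) + dt)
  }
  moved <- rt_apply(best$transform, src)
  nn <- .nn_index(tgt, moved)
  n <- target_normals[nn$index, , drop = FALSE]
  r <- rowSums((moved - tgt[nn$index, , drop = FALSE]) * n)
  quality <- registration_quality(sqrt(mean(r^2)), condition_number(src),
                                  nrow(src), converged, iter)
  list(transform = best$transform, quality = quality)
}

#' Coarse alignment of two point clouds
#'
#' Deterministic initialisation for ICP and bead matching: aligns centroids
#' and principal axes. The principal-axes rotation is sign-ambiguous, so all
#' four proper sign combinations are evaluated and the one with the smallest
#' median nearest-neighbour distance is kept. Near-isotropic clouds (no
#' well-separated principal axes) fall back to centroid-only alignment with
#' a warning.
#'
#' @param source,target n x 3 point matrices (world mm).
#' @param max_eval_points number of points used to score the sign
#'   candidates.
#' @return A `rigid_transform` mapping source towards target.
#' @export
coarse_align <- function(source, target, max_eval_points = 2000L) {
  src <- as_points(source)
  tgt <- as_points(target)
  if (nrow(src) < 1L || nrow(tgt) < 1L)
    stop("coarse_align needs non-empty clouds", call. = FALSE)
  cs <- colMeans(src)
  ct <- colMeans(tgt)
  if (nrow(src) < 3L || nrow(tgt) < 3L)
    return(rigid_transform(diag(3), ct - cs))
  es <- eigen(stats::cov(src), symmetric = TRUE)
  et <- eigen(stats::cov(tgt), symmetric = TRUE)
  src_eval <- deterministic_subsample(src, max_eval_points, 7L)
  tgt_eval <- deterministic_subsample(tgt, 4L * max_eval_points, 8L)
  # candidates are scored by a short decimated ICP refinement: raw
  # nearest-neighbour distances cannot rank rotations on nearly symmetric
  # shapes (a sphere-like pelvis surface scores almost identically under
  # any rotation), whereas a few ICP iterations separate the basins and
  # additionally hand a better initialisation to the caller
  refine_and_score <- function(cand) {
    fit <- icp_register(src_eval, tgt_eval, init = cand, max_iter = 8L,
                        tol_mm = 1e-6, max_target_points = nrow(tgt_eval),
                        max_source_points = nrow(src_eval))
    list(transform = fit$transform, score = fit$quality$mean_error_mm)
  }
  # centroid-only candidate: for nearly symmetric shapes the principal
  # axes are unstable, and when the true motion is moderate — as between
  # double examinations — plain centroid alignment is the safer start; it
  # competes with the axis candidates on equal terms
  cands <- list(rigid_transform(diag(3), ct - cs))
  gaps <- abs(diff(sort(es$values, decreasing = TRUE)))
  if (all(gaps >= 1e-3 * max(es$values))) {
    Vs <- es$vectors
    Vt <- et$vectors
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      Vt_s <- Vt %*% diag(c(s1, s2, 1))
      R <- Vt_s %*% t(Vs)
      if (det(R) < 0) R <- Vt_s %*% diag(c(1, 1, -1)) %*% t(Vs)
      cands[[length(cands) + 1L]] <-
        rigid_transform(R, ct - drop(R %*% cs))
    }
  } else {
    warning("near-isotropic cloud: principal axes unreliable, relying on centroid alignment")
  }
  refined <- lapply(cands, refine_and_score)
  scores <- vapply(refined, `[[`, 0, "score")
  refined[[which.min(scores)]]$transform
}
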