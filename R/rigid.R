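# Quaternions are length-4 numeric vectors (w, x, y, z), unit norm.

quat_identity <- function() c(1, 0, 0, 0)

quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(quat_identity())
  axis <- axis / n
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# Rotation matrix of a unit quaternion (applied to row-vector points as p %*% t(R)).
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Construct a rigid transform
#'
#' A pose: rotation (unit quaternion, applied about the origin) followed
#' by a translation, mapping molecule-frame points `p` to world-frame
#' points `R p + t`.
#'
#' @param rotation Quaternion `c(w, x, y, z)`; normalized if needed (a
#'   warning is emitted when the norm deviates from 1 by more than 1e-9).
#' @param translation Length-3 numeric, Angstrom.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(1, 0, 0, 0), translation = c(0, 0, 0)) {
  stopifnot(length(rotation) == 4L, length(translation) == 3L,
            all(is.finite(rotation)), all(is.finite(translation)))
  n <- sqrt(sum(rotation^2))
  if (n == 0) stop("zero quaternion is not a rotation")
  if (abs(n - 1) > 1e-9) {
    warning("non-unit quaternion normalized")
    rotation <- rotation / n
  } else {
    rotation <- rotation / n
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> q = (%s), t = (%s) A\n",
              paste(sprintf("%.4f", x$rotation), collapse = ", "),
              paste(sprintf("%.3f", x$translation), collapse = ", ")))
  invisible(x)
}

#' Compose two rigid transforms
#' @param a,b `rigid_transform`s; the result applies `b` first, then `a`.
#' @return A `rigid_transform` equal to `a %after% b`.
#' @export
compose_transforms <- function(a, b) {
  q <- quat_multiply(a$rotation, b$rotation)
  t <- as.numeric(quat_to_matrix(a$rotation) %*% b$translation) + a$translation
  rigid_transform(q / sqrt(sum(q^2)), t)
}

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @return Its inverse.
#' @export
invert_transform <- function(t) {
  qi <- quat_conjugate(t$rotation)
  rigid_transform(qi, -as.numeric(quat_to_matrix(qi) %*% t$translation))
}

#' Apply a rigid transform to points
#'
#' @param points Numeric matrix (n x 3) or length-3 vector, Angstrom.
#' @param t A `rigid_transform`.
#' @return Transformed points, same shape as the input; pairwise
#'   distances are preserved to floating-point accuracy.
#' @export
apply_transform <- function(points, t) {
  stopifnot(inherits(t, "rigid_transform"))
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, nrow = 1L)
  out <- points %*% t(quat_to_matrix(t$rotation))
  out <- sweep(out, 2L, t$translation, "+")
  if (vec) as.numeric(out) else out
}

#' Construct a docking scene
#'
#' The unit that is scored and optimized: a set of molecules, each with a
#' rigid pose placing it in a shared world frame.
#'
#' @param molecules List of [molecule()]s with unique ids.
#' @param transforms Optional list of `rigid_transform`s, one per
#'   molecule; identity poses by default.
#' @return An object of class `scene`.
#' @export
scene <- function(molecules, transforms = NULL) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  stopifnot(length(molecules) >= 1L)
  ids <- vapply(molecules, function(m) m$id, "")
  if (anyDuplicated(ids)) stop("molecule ids must be unique within a scene")
  if (is.null(transforms)) {
    transforms <- replicate(length(molecules), rigid_transform(), simplify = FALSE)
  }
  stopifnot(length(transforms) == length(molecules))
  entries <- Map(function(m, t) {
    stopifnot(inherits(m, "molecule"), inherits(t, "rigid_transform"))
    list(molecule = m, transform = t)
  }, molecules, transforms)
  names(entries) <- ids
  structure(list(entries = entries), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene>: %d molecule(s)\n", length(x$entries)))
  for (e in x$entries) {
    cat(sprintf("  %s: %d atoms\n", e$molecule$id, n_atoms(e$molecule)))
  }
  invisible(x)
}

#' Molecule ids of a scene
#' @param scene A [scene()].
#' @return Character vector of ids.
#' @export
scene_ids <- function(scene) names(scene$entries)

#' Replace the pose of one molecule in a scene
#' @param scene A [scene()].
#' @param id Molecule id.
#' @param transform New `rigid_transform`.
#' @return The updated scene.
#' @export
set_pose <- function(scene, id, transform) {
  if (!id %in% names(scene$entries)) {
    stop(sprintf("unknown molecule id '%s'; scene contains: %s",
                 id, paste(names(scene$entries), collapse = ", ")))
  }
  scene$entries[[id]]$transform <- transform
  scene
}

#' Optimizer configuration
#'
#' @param iterations Number of perturbation trials (>= 0).
#' @param max_translation_step Translation proposals are uniform in a
#'   ball of this radius (Angstrom).
#' @param max_rotation_step Rotation proposals use a uniform random axis
#'   and an angle uniform in `[-max_rotation_step, max_rotation_step]`
#'   (radians).
#' @param seed Integer seed making a run reproducible, or `NULL` to use
#'   the current RNG stream.
#' @param accept_equal Accept moves that leave the score exactly equal
#'   (off by default: strictly-better greedy).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(iterations = 500L, max_translation_step = 1.0,
                             max_rotation_step = 0.1, seed = NULL,
                             accept_equal = FALSE) {
  stopifnot(iterations >= 0, max_translation_step > 0, max_rotation_step > 0)
  structure(list(
    iterations = as.integer(iterations),
    max_translation_step = max_translation_step,
    max_rotation_step = max_rotation_step,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    accept_equal = isTRUE(accept_equal)
  ), class = "optimizer_config")
}

#' Randomly perturb a pose
#'
#' Draws a translation offset uniform in a ball of radius
#' `max_translation_step` and a rotation about `pivot` by a uniformly
#' random axis and an angle uniform in `[-max_rotation_step,
#' +max_rotation_step]`, and composes both with the current pose. Uses
#' the current R RNG stream, so results are deterministic given the RNG
#' state.
#'
#' @param t Current `rigid_transform`.
#' @param cfg An [optimizer_config()].
#' @param pivot World-frame rotation pivot (length-3); the optimizer
#'   passes the posed molecule's centroid.
#' @return The perturbed `rigid_transform`.
#' @export
random_perturbation <- function(t, cfg, pivot = c(0, 0, 0)) {
  stopifnot(inherits(t, "rigid_transform"), inherits(cfg, "optimizer_config"))
  dir <- stats::rnorm(3L)
  nrm <- sqrt(sum(dir^2))
  dir <- if (nrm > 0) dir / nrm else c(1, 0, 0)
  radius <- cfg$max_translation_step * stats::runif(1L)^(1 / 3)
  dt <- dir * radius

  axis <- stats::rnorm(3L)
  angle <- stats::runif(1L, -cfg$max_rotation_step, cfg$max_rotation_step)
  dq <- quat_from_axis_angle(axis, angle)

  # Rotate the posed molecule about the pivot, then translate:
  # p -> dR (p - pivot) + pivot + dt.
  dR <- quat_to_matrix(dq)
  new_q <- quat_multiply(dq, t$rotation)
  new_t <- as.numeric(dR %*% (t$translation - pivot)) + pivot + dt
  rigid_transform(new_q / sqrt(sum(new_q^2)), new_t)
}

#' Greedy rigid-body pose refinement
#'
#' Iteratively proposes random rigid perturbations of one molecule's
#' pose ([random_perturbation()], pivoting rotations at the molecule's
#' current world centroid) and accepts a proposal only when the total
#' scene score strictly decreases (or ties, with `accept_equal`). This is
#' the automatic refinement companion to interactive manipulation: a
#' plain stochastic hill-climb on the binding score.
#'
#' @param scene A parameterized [scene()].
#' @param target_id Id of the molecule whose pose is refined.
#' @param cfg An [optimizer_config()].
#' @param params A [scoring_params()].
#' @return A list of class `pose_optimization`: `transform` (final pose
#'   of the target), `trace` (scene score after 0, 1, ..., iterations
#'   trials; non-increasing), `scene` (scene with the final pose),
#'   `accepted` (number of accepted moves).
#' @export
optimize_pose <- function(scene, target_id, cfg = optimizer_config(),
                          params = scoring_params()) {
  stopifnot(inherits(scene, "scene"))
  if (!target_id %in% names(scene$entries)) {
    stop(sprintf("unknown molecule id '%s'; scene contains: %s",
                 target_id, paste(names(scene$entries), collapse = ", ")))
  }
  if (!is.null(cfg$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(cfg$seed)
  }

  ids <- names(scene$entries)
  others <- setdiff(ids, target_id)
  # Pairs not involving the target are unaffected by its pose.
  base <- 0
  if (length(others) >= 2L) {
    for (i in seq_len(length(others) - 1L)) {
      for (j in seq(i + 1L, length(others))) {
        e <- intermolecular_energy(scene$entries[[others[i]]],
                                   scene$entries[[others[j]]], params)
        base <- base + e$energy
      }
    }
  }
  target_terms <- function(entry) {
    s <- 0
    for (o in others) {
      s <- s + intermolecular_energy(entry, scene$entries[[o]], params)$energy
    }
    s
  }

  entry <- scene$entries[[target_id]]
  local_centroid <- colMeans(atom_coords(entry$molecule))
  current <- base + target_terms(entry)
  trace <- numeric(cfg$iterations + 1L)
  trace[1L] <- current
  accepted <- 0L
  for (it in seq_len(cfg$iterations)) {
    pivot <- apply_transform(local_centroid, entry$transform)
    cand <- entry
    cand$transform <- random_perturbation(entry$transform, cfg, pivot)
    cand_score <- base + target_terms(cand)
    if (cand_score < current || (cfg$accept_equal && cand_score == current)) {
      entry <- cand
      current <- cand_score
      accepted <- accepted + 1L
    }
    trace[it + 1L] <- current
  }
  scene$entries[[target_id]] <- entry
  structure(list(transform = entry$transform, trace = trace,
                 scene = scene, accepted = accepted),
            class = "pose_optimization")
}

#' @export
print.pose_optimization <- function(x, ...) {
  cat(sprintf(
    "<pose_optimization>: %d iterations, %d accepted, score %.4f -> %.4f kcal/mol\n",
    length(x$trace) - 1L, x$accepted, x$trace[1L], x$trace[length(x$trace)]
  ))
  invisible(x)
}
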