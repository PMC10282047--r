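# Seeded generators of synthetic neurons, meshes, masks and feature
# tables with planted structure, so the whole pipeline is testable
# without downloading data. All generators are deterministic given
# their seed and emit objects/files readable by the IO module.

#' Specification of a synthetic neuron morphology class
#'
#' @param n_branches number of bifurcation events (0 = straight path).
#' @param branch_length_mean,branch_length_sd branch length
#'   distribution, micrometres.
#' @param branch_angle_sd angular spread of bifurcations, radians.
#' @param segment_step discretization step of the skeleton,
#'   micrometres.
#' @return a `neuron_class_spec`.
#' @export
neuron_spec <- function(n_branches = 4L, branch_length_mean = 50,
                        branch_length_sd = 10, branch_angle_sd = 0.4,
                        segment_step = 5) {
  stopifnot(n_branches >= 0, branch_length_mean > 0, branch_length_sd >= 0,
            branch_angle_sd >= 0, segment_step > 0)
  structure(list(n_branches = as.integer(n_branches),
                 branch_length_mean = branch_length_mean,
                 branch_length_sd = branch_length_sd,
                 branch_angle_sd = branch_angle_sd,
                 segment_step = segment_step),
            class = "neuron_class_spec")
}

unit <- function(v) v / sqrt(sum(v^2))

# rotate v by `angle` about unit axis k (Rodrigues)
rodrigues <- function(v, k, angle) {
  v * cos(angle) + pracma::cross(k, v) * sin(angle) +
    k * sum(k * v) * (1 - cos(angle))
}

random_perp <- function(d) {
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma::cross(d, a))
}

#' Generate a random neuron skeleton
#'
#' Grows a rooted tree from a soma node: branches of random length are
#' discretized into segments with small angular jitter, and tips
#' bifurcate (two daughters at +/- a random angle) until the requested
#' number of bifurcation events is reached. The resulting tree is a
#' valid sorted SWC skeleton.
#'
#' @param spec a [neuron_spec()].
#' @param seed RNG seed; identical calls produce identical trees.
#' @return a `neuron_tree`.
#' @export
generate_neuron <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "neuron_class_spec"))
  with_seed(seed, {
    nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                        radius = 1, parent = -1L)
    splits_left <- spec$n_branches
    # FIFO queue of growing tips: (parent node id, direction)
    queue <- list(list(parent = 1L, dir = c(0, 0, 1)))
    while (length(queue) > 0) {
      tip <- queue[[1]]; queue <- queue[-1]
      len <- max(spec$segment_step,
                 stats::rnorm(1, spec$branch_length_mean, spec$branch_length_sd))
      nseg <- max(1L, as.integer(round(len / spec$segment_step)))
      # node spacing is irregular in real tracings; the jitter also keeps
      # path radii incommensurate so even sampling is well posed. The
      # segment lengths are normalized to sum to the drawn branch length.
      segs <- stats::runif(nseg, 0.8, 1.2)
      segs <- segs * (len / sum(segs))
      dir <- tip$dir
      parent <- tip$parent
      pos <- as.numeric(nodes[nodes$id == parent, c("x", "y", "z")])
      for (s in seq_len(nseg)) {
        jitter <- stats::rnorm(3, 0, spec$branch_angle_sd * 0.2)
        dir <- unit(dir + jitter)
        pos <- pos + dir * segs[s]
        id <- nrow(nodes) + 1L
        nodes <- rbind(nodes, data.frame(id = id, type = 3L, x = pos[1],
                                         y = pos[2], z = pos[3],
                                         radius = 0.5, parent = parent))
        parent <- id
      }
      if (splits_left > 0) {
        splits_left <- splits_left - 1L
        axis <- random_perp(dir)
        ang <- abs(stats::rnorm(1, spec$branch_angle_sd, spec$branch_angle_sd / 4))
        queue[[length(queue) + 1L]] <- list(parent = parent,
                                            dir = unit(rodrigues(dir, axis, ang)))
        queue[[length(queue) + 1L]] <- list(parent = parent,
                                            dir = unit(rodrigues(dir, axis, -ang)))
      }
    }
    new_neuron_tree(nodes)
  })
}

#' Apply a random rigid motion to a tree or point cloud
#'
#' Random rotation (optionally composed with a reflection) plus
#' translation; Euclidean intracellular distance matrices are exactly
#' preserved.
#'
#' @param x a `neuron_tree` or `point_cloud`.
#' @param seed RNG seed.
#' @param reflect also reflect through the first coordinate plane.
#' @return the transformed copy.
#' @export
rigid_transform <- function(x, seed = 1L, reflect = FALSE) {
  with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    if (reflect) Q[, 1] <- -Q[, 1]
    tr <- stats::runif(3, -100, 100)
    if (inherits(x, "neuron_tree")) {
      xyz <- as.matrix(x[, c("x", "y", "z")]) %*% t(Q)
      x$x <- xyz[, 1] + tr[1]; x$y <- xyz[, 2] + tr[2]; x$z <- xyz[, 3] + tr[3]
      x
    } else if (inherits(x, "point_cloud")) {
      x$points <- sweep(x$points %*% t(Q), 2, -tr)
      x
    } else stop_morphgw("rigid_transform needs a neuron_tree or point_cloud",
                        "morphgw_value_error")
  })
}

#' Bend a neuron tree at a joint node
#'
#' Rotates the entire subtree below the joint rigidly about an axis
#' through the joint, emulating a bending deformation of the cell:
#' all edge lengths (hence the geodesic intracellular matrix) are
#' exactly preserved while Euclidean distances change.
#'
#' @param tree a `neuron_tree`.
#' @param joint_id id of the joint node.
#' @param angle rotation angle, radians.
#' @param axis rotation axis (default: a seeded random unit vector).
#' @param seed RNG seed for the default axis.
#' @return the bent `neuron_tree`.
#' @export
bend_tree <- function(tree, joint_id, angle, axis = NULL, seed = 1L) {
  stopifnot(inherits(tree, "neuron_tree"))
  j <- match(joint_id, tree$id)
  if (is.na(j))
    stop_morphgw("joint node not found", "morphgw_value_error")
  if (is.null(axis)) axis <- with_seed(seed, unit(stats::rnorm(3)))
  axis <- unit(axis)
  # collect strict descendants of the joint
  pos <- match(tree$parent, tree$id)
  desc <- logical(nrow(tree))
  for (i in seq_len(nrow(tree))) {
    k <- i
    while (!is.na(pos[k])) {
      k <- pos[k]
      if (k == j) { desc[i] <- TRUE; break }
    }
  }
  if (angle != 0 && any(desc)) {
    centre <- as.numeric(tree[j, c("x", "y", "z")])
    xyz <- as.matrix(tree[desc, c("x", "y", "z")])
    rot <- t(apply(xyz, 1, function(v) rodrigues(v - centre, axis, angle) + centre))
    tree$x[desc] <- rot[, 1]; tree$y[desc] <- rot[, 2]; tree$z[desc] <- rot[, 3]
  }
  new_neuron_tree(as.data.frame(tree))
}

#' Generate a feature table with planted localized structure
#'
#' Localized features are community indicators (scaled by `strength`)
#' plus unit Gaussian noise; null features are iid Gaussian noise;
#' confounded features depend only on a uniform age covariate (1-5
#' days). The indices of truly localized features are returned as
#' ground truth.
#'
#' @param communities integer community label per cell.
#' @param n_localized,n_null,n_confounded feature counts.
#' @param strength mean shift of localized features, in noise SD
#'   units.
#' @param covariate_strength age effect size of confounded features.
#' @param seed RNG seed.
#' @return list with `features` (cells x features matrix), `truth`
#'   (logical: truly localized), and `covariates` (data frame with
#'   `age`).
#' @export
generate_features <- function(communities, n_localized = 5L, n_null = 15L,
                              n_confounded = 0L, strength = 3,
                              covariate_strength = 1, seed = 1L) {
  N <- length(communities)
  comm <- as.integer(factor(communities))
  with_seed(seed, {
    age <- sample(1:5, N, replace = TRUE)
    cols <- list()
    truth <- logical(0)
    ks <- sort(unique(comm))
    for (i in seq_len(n_localized)) {
      target <- ks[((i - 1) %% length(ks)) + 1]
      cols[[length(cols) + 1L]] <- strength * (comm == target) + stats::rnorm(N)
      truth <- c(truth, TRUE)
    }
    for (i in seq_len(n_confounded)) {
      cols[[length(cols) + 1L]] <- covariate_strength * age + stats::rnorm(N)
      truth <- c(truth, FALSE)
    }
    for (i in seq_len(n_null)) {
      cols[[length(cols) + 1L]] <- stats::rnorm(N)
      truth <- c(truth, FALSE)
    }
    F <- do.call(cbind, cols)
    colnames(F) <- c(sprintf("localized_%d", seq_len(n_localized)),
                     if (n_confounded > 0) sprintf("confounded_%d", seq_len(n_confounded)),
                     sprintf("null_%d", seq_len(n_null)))
    list(features = F, truth = truth, covariates = data.frame(age = age))
  })
}

#' Synthetic icosphere mesh
#'
#' Icosahedron subdivided `subdiv` times with vertices projected onto
#' the sphere of the given radius; used as a mesh fixture with a known
#' geodesic structure.
#'
#' @param subdiv number of 4-to-1 triangle subdivisions.
#' @param radius sphere radius, micrometres.
#' @return a `tri_mesh`.
#' @export
synthetic_icosphere <- function(subdiv = 2L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- t(apply(v, 1, unit))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "_")
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, unit((v[a, ] + v[b, ]) / 2))
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(integer(0), 0, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; cc <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  structure(list(vertices = v * radius, faces = f), class = "tri_mesh")
}

#' Synthetic single-object disk mask
#'
#' @param radius_px disk radius in pixels.
#' @param size image side in pixels.
#' @param pixel_size micrometres per pixel.
#' @return a `seg_mask`.
#' @export
synthetic_disk_mask <- function(radius_px = 20, size = 64, pixel_size = 1) {
  ctr <- (size + 1) / 2
  px <- outer(seq_len(size), seq_len(size),
              function(r, c) (r - ctr)^2 + (c - ctr)^2 <= radius_px^2)
  new_seg_mask(px, pixel_size)
}

#' Write a mesh as an ascii OBJ file
#'
#' @param mesh a `tri_mesh`.
#' @param path output path.
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  lines <- c(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
             if (nrow(mesh$faces) > 0)
               sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]))
  writeLines(lines, path)
  invisible(path)
}
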