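# Readers and writers for the external representations of cells:
# SWC neuron skeletons, ascii OBJ/PLY triangular meshes, 2D binary
# segmentation masks, and the condensed text format used to store
# pairwise distance matrices. All coordinates are micrometres.

#' Read an SWC neuron reconstruction
#'
#' Parses the 7-column SWC format (node id, structure code, x, y, z,
#' radius, parent id) into a `neuron_tree`. Comment lines starting with
#' `#` and blank lines are skipped; columns beyond the seventh are
#' ignored. The file must describe a single rooted tree: exactly one
#' node with parent id -1, every other parent id referring to an
#' existing node. By default a file in which any child row precedes its
#' parent row is rejected as unsorted; `resort = TRUE` instead
#' re-sorts the nodes topologically (root first, file order among
#' siblings).
#'
#' @param path path to an SWC file.
#' @param resort if `TRUE`, topologically re-sort an unsorted file
#'   instead of rejecting it.
#' @param keep_largest if `TRUE`, a file containing several disconnected
#'   components (several roots) is reduced to its largest component
#'   instead of being rejected.
#' @return a `neuron_tree`: a data frame with columns `id`, `type`,
#'   `x`, `y`, `z`, `radius`, `parent`, sorted so parents precede
#'   children.
#' @export
read_swc <- function(path, resort = FALSE, keep_largest = FALSE) {
  if (!file.exists(path))
    stop_morphgw(sprintf("SWC file not found: %s", path), "morphgw_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    stop_morphgw("SWC file has no data rows", "morphgw_parse_error")
  fields <- strsplit(lines, "[[:space:]]+")
  ncols <- vapply(fields, length, integer(1))
  if (any(ncols < 7))
    stop_morphgw("SWC rows must have at least 7 columns", "morphgw_parse_error")
  m <- t(vapply(fields, function(f) as.numeric(f[1:7]), numeric(7)))
  if (any(!is.finite(m)))
    stop_morphgw("non-numeric value in SWC columns 1-7", "morphgw_parse_error")
  nodes <- data.frame(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5],
    radius = m[, 6], parent = as.integer(m[, 7])
  )
  if (anyDuplicated(nodes$id))
    stop_morphgw("duplicated node ids in SWC file", "morphgw_parse_error")

  roots <- which(nodes$parent == -1L)
  if (length(roots) == 0)
    stop_morphgw("SWC file has no root (parent id -1)", "morphgw_structure_error")
  if (length(roots) > 1) {
    if (!keep_largest)
      stop_morphgw(
        sprintf("SWC file has %d roots (disconnected components)", length(roots)),
        "morphgw_multiple_roots_error"
      )
    nodes <- swc_largest_component(nodes, roots)
    roots <- which(nodes$parent == -1L)
  }
  dangling <- !(nodes$parent %in% c(-1L, nodes$id))
  if (any(dangling))
    stop_morphgw(
      sprintf("dangling parent id(s): node %s refers to missing parent %s",
              nodes$id[which(dangling)[1]], nodes$parent[which(dangling)[1]]),
      "morphgw_dangling_parent_error"
    )

  pos <- match(nodes$parent, nodes$id)          # NA for the root
  unsorted <- which(!is.na(pos) & pos >= seq_len(nrow(nodes)))
  if (length(unsorted) > 0) {
    if (!resort)
      stop_morphgw(
        sprintf("unsorted SWC: node %s (row %d) precedes its parent",
                nodes$id[unsorted[1]], unsorted[1]),
        "morphgw_unsorted_error"
      )
    nodes <- swc_toposort(nodes, roots)
  }
  new_neuron_tree(nodes)
}

swc_largest_component <- function(nodes, roots) {
  pos <- match(nodes$parent, nodes$id)
  comp <- integer(nrow(nodes))
  # label each node with the root of its chain by following parents
  for (i in seq_len(nrow(nodes))) {
    j <- i
    seen <- 0L
    while (!is.na(pos[j])) {
      j <- pos[j]
      seen <- seen + 1L
      if (seen > nrow(nodes))
        stop_morphgw("cycle detected in SWC parent pointers", "morphgw_structure_error")
    }
    comp[i] <- j
  }
  sizes <- table(comp)
  keep_root <- as.integer(names(sizes)[which.max(sizes)])
  nodes[comp == keep_root, , drop = FALSE]
}

swc_toposort <- function(nodes, roots) {
  pos <- match(nodes$parent, nodes$id)
  children <- split(seq_len(nrow(nodes))[!is.na(pos)], pos[!is.na(pos)])
  order_out <- integer(0)
  queue <- roots
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    order_out <- c(order_out, i)
    kids <- children[[as.character(i)]]
    if (!is.null(kids)) queue <- c(queue, sort(kids))
  }
  if (length(order_out) != nrow(nodes))
    stop_morphgw("SWC parent pointers contain a cycle or unreachable nodes",
                 "morphgw_structure_error")
  nodes[order_out, , drop = FALSE]
}

new_neuron_tree <- function(nodes) {
  rownames(nodes) <- NULL
  pos <- match(nodes$parent, nodes$id)
  nonroot <- which(nodes$parent != -1L)
  if (length(nonroot) > 0) {
    dx <- nodes$x[nonroot] - nodes$x[pos[nonroot]]
    dy <- nodes$y[nonroot] - nodes$y[pos[nonroot]]
    dz <- nodes$z[nonroot] - nodes$z[pos[nonroot]]
    len <- sqrt(dx^2 + dy^2 + dz^2)
    if (any(len <= 0))
      stop_morphgw(
        sprintf("zero-length edge at node %s", nodes$id[nonroot[which(len <= 0)[1]]]),
        "morphgw_zero_edge_error"
      )
  }
  structure(nodes, class = c("neuron_tree", "data.frame"))
}

#' Write a neuron tree to an SWC file
#'
#' Inverse of [read_swc()]; coordinates and radii are written with 17
#' significant digits so the round trip is exact.
#'
#' @param tree a `neuron_tree`.
#' @param path output path.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "neuron_tree"))
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   tree$id, tree$type, tree$x, tree$y, tree$z,
                   tree$radius, tree$parent)
  writeLines(c("# SWC written by morphgw", lines), path)
  invisible(path)
}

#' @exportS3Method base::print
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree> %d nodes, %d edges, total cable %.3g um\n",
              nrow(x), sum(x$parent != -1L), tree_total_length(x)))
  invisible(x)
}

tree_edge_lengths <- function(tree) {
  pos <- match(tree$parent, tree$id)
  nonroot <- which(tree$parent != -1L)
  cbind(
    child = nonroot,
    parent = pos[nonroot],
    length = sqrt((tree$x[nonroot] - tree$x[pos[nonroot]])^2 +
                  (tree$y[nonroot] - tree$y[pos[nonroot]])^2 +
                  (tree$z[nonroot] - tree$z[pos[nonroot]])^2)
  )
}

tree_total_length <- function(tree) {
  e <- tree_edge_lengths(tree)
  if (nrow(e) == 0) 0 else sum(e[, "length"])
}

#' Read a triangular surface mesh (ascii OBJ or PLY)
#'
#' Vertex order is preserved exactly as in the file; even vertex
#' subsampling relies on it. Faces must be triangles with in-range,
#' distinct indices. A mesh with zero faces is accepted as an ordered
#' point cloud (a message is emitted).
#'
#' @param path path to an ascii `.obj` or `.ply` file; the format is
#'   chosen by extension (OBJ assumed otherwise).
#' @return a `tri_mesh`: list with `vertices` (V x 3 matrix) and
#'   `faces` (F x 3 integer matrix, 1-based).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path))
    stop_morphgw(sprintf("mesh file not found: %s", path), "morphgw_io_error")
  ext <- tolower(tools::file_ext(path))
  mesh <- if (ext == "ply") read_ply_ascii(path) else read_obj_ascii(path)
  validate_tri_mesh(mesh)
}

read_obj_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vs <- grep("^v[[:space:]]", lines, value = TRUE)
  fs <- grep("^f[[:space:]]", lines, value = TRUE)
  verts <- t(vapply(strsplit(trimws(vs), "[[:space:]]+"), function(f) {
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (any(!is.finite(v))) stop_morphgw("unparseable OBJ vertex line", "morphgw_parse_error")
    v
  }, numeric(3)))
  faces <- if (length(fs) == 0) matrix(integer(0), 0, 3) else
    t(vapply(strsplit(trimws(fs), "[[:space:]]+"), function(f) {
      if (length(f) != 4)
        stop_morphgw("only triangular OBJ faces are supported", "morphgw_parse_error")
      idx <- suppressWarnings(as.integer(sub("/.*$", "", f[2:4])))
      if (any(is.na(idx)))
        stop_morphgw(sprintf("unparseable OBJ face line: '%s'", paste(f, collapse = " ")),
                     "morphgw_parse_error")
      idx
    }, integer(3)))
  list(vertices = verts, faces = faces)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    stop_morphgw("not a PLY file", "morphgw_parse_error")
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop_morphgw("PLY header has no end_header", "morphgw_parse_error")
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format[[:space:]]+ascii", header)))
    stop_morphgw("only ascii PLY is supported", "morphgw_parse_error")
  elems <- grep("^element[[:space:]]", header)
  nvert <- nface <- 0L
  vprops <- character(0)
  cur <- ""
  for (i in seq_along(header)) {
    tok <- strsplit(header[i], "[[:space:]]+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      if (cur == "vertex") nvert <- as.integer(tok[3])
      if (cur == "face") nface <- as.integer(tok[3])
    } else if (tok[1] == "property" && cur == "vertex" && tok[2] != "list") {
      vprops <- c(vprops, tok[3])
    }
  }
  xyz <- match(c("x", "y", "z"), vprops)
  if (any(is.na(xyz)))
    stop_morphgw("PLY vertex element lacks x/y/z properties", "morphgw_parse_error")
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nvert + nface)
    stop_morphgw("PLY body shorter than declared element counts", "morphgw_parse_error")
  verts <- t(vapply(strsplit(trimws(body[seq_len(nvert)]), "[[:space:]]+"),
                    function(f) as.numeric(f[xyz]), numeric(3)))
  faces <- if (nface == 0) matrix(integer(0), 0, 3) else
    t(vapply(strsplit(trimws(body[nvert + seq_len(nface)]), "[[:space:]]+"),
             function(f) {
               k <- as.integer(f[1])
               if (is.na(k) || k != 3)
                 stop_morphgw("only triangular PLY faces are supported", "morphgw_parse_error")
               as.integer(f[2:4]) + 1L   # PLY indices are 0-based
             }, integer(3)))
  list(vertices = verts, faces = faces)
}

validate_tri_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(v) == 0) stop_morphgw("mesh has no vertices", "morphgw_parse_error")
  if (nrow(f) > 0) {
    if (any(f < 1L) || any(f > nrow(v)))
      stop_morphgw("mesh face index out of range", "morphgw_face_index_error")
    if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
      stop_morphgw("degenerate mesh face with repeated vertex index",
                   "morphgw_degenerate_face_error")
  } else {
    message("mesh has no faces; treating it as an ordered point cloud")
  }
  structure(list(vertices = v, faces = f), class = "tri_mesh")
}

#' @exportS3Method base::print
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a binary 2D segmentation mask
#'
#' Loads a single-channel PNG or TIFF image, binarizes it (non-zero =
#' foreground) and checks that the foreground forms exactly one
#' 8-connected component.
#'
#' @param path image path (`.png` or `.tif`/`.tiff`).
#' @param pixel_size physical size of one pixel, micrometres.
#' @return a `seg_mask`: list with `pixels` (logical matrix) and
#'   `pixel_size`.
#' @export
read_mask <- function(path, pixel_size = 1) {
  if (!file.exists(path))
    stop_morphgw(sprintf("mask file not found: %s", path), "morphgw_io_error")
  if (pixel_size <= 0)
    stop_morphgw("pixel_size must be positive", "morphgw_value_error")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  new_seg_mask(img != 0, pixel_size)
}

new_seg_mask <- function(pixels, pixel_size) {
  ncomp <- count_components_8(pixels)
  if (ncomp == 0)
    stop_morphgw("empty mask: no foreground pixels", "morphgw_empty_mask_error")
  if (ncomp > 1)
    stop_morphgw(sprintf("multiple objects in mask (%d components)", ncomp),
                 "morphgw_multiple_objects_error")
  structure(list(pixels = pixels, pixel_size = pixel_size), class = "seg_mask")
}

# 8-connected component count by flood fill on the logical grid.
count_components_8 <- function(px) {
  lab <- matrix(0L, nrow(px), ncol(px))
  ncomp <- 0L
  fg <- which(px, arr.ind = TRUE)
  if (nrow(fg) == 0) return(0L)
  for (s in seq_len(nrow(fg))) {
    r0 <- fg[s, 1]; c0 <- fg[s, 2]
    if (lab[r0, c0] != 0L) next
    ncomp <- ncomp + 1L
    stack <- matrix(c(r0, c0), 1, 2)
    lab[r0, c0] <- ncomp
    while (nrow(stack) > 0) {
      r <- stack[nrow(stack), 1]; cc <- stack[nrow(stack), 2]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccc <- cc + dc
        if (rr >= 1 && rr <= nrow(px) && ccc >= 1 && ccc <= ncol(px) &&
            px[rr, ccc] && lab[rr, ccc] == 0L) {
          lab[rr, ccc] <- ncomp
          stack <- rbind(stack, c(rr, ccc))
        }
      }
    }
  }
  ncomp
}

#' Pairwise GW distance space over a set of cells
#'
#' Container pairing an ordered vector of cell ids with the symmetric
#' matrix of pairwise Gromov-Wasserstein distances. Couplings to a
#' designated reference cell may be attached by [gw_pairwise()].
#'
#' @param D symmetric non-negative matrix with zero diagonal.
#' @param cell_ids character vector of cell identifiers (defaults to
#'   the matrix dimnames or `cell_1 ... cell_N`).
#' @return a `gw_space` object.
#' @export
gw_space <- function(D, cell_ids = NULL) {
  check_square_distance_matrix(D, "GW matrix")
  if (!is_symmetric_zero_diag(D))
    stop_morphgw("GW matrix must be symmetric with zero diagonal",
                 "morphgw_asymmetric_error")
  if (any(D < 0))
    stop_morphgw("GW matrix has negative entries", "morphgw_value_error")
  ids <- cell_ids %||% rownames(D) %||% sprintf("cell_%d", seq_len(nrow(D)))
  if (length(ids) != nrow(D))
    stop_morphgw("cell_ids length does not match matrix size", "morphgw_shape_error")
  dimnames(D) <- list(ids, ids)
  structure(list(cell_ids = as.character(ids), D = D), class = "gw_space")
}

#' @exportS3Method base::print
print.gw_space <- function(x, ...) {
  cat(sprintf("<gw_space> %d cells, median GW distance %.4g\n",
              length(x$cell_ids), stats::median(condense_matrix(x$D))))
  invisible(x)
}

#' Write / read a GW distance matrix in condensed text form
#'
#' The file stores the cell ids followed by the upper triangle of the
#' matrix in row-major order, one value per line with 17 significant
#' digits, so that `read_gw_matrix(write_gw_matrix(x))` reproduces the
#' matrix exactly.
#'
#' @param space a `gw_space`.
#' @param path file path.
#' @return `read_gw_matrix` returns a `gw_space`.
#' @export
write_gw_matrix <- function(space, path) {
  stopifnot(inherits(space, "gw_space"))
  D <- space$D
  if (max(abs(D - t(D))) > 0)
    stop_morphgw("refusing to write an asymmetric matrix", "morphgw_asymmetric_error")
  n <- nrow(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# morphgw condensed distance matrix v1",
               sprintf("n %d", n), space$cell_ids,
               sprintf("%.17g", condense_matrix(D))), con)
  invisible(path)
}

#' @rdname write_gw_matrix
#' @export
read_gw_matrix <- function(path) {
  if (!file.exists(path))
    stop_morphgw(sprintf("matrix file not found: %s", path), "morphgw_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  head1 <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(head1) != 2 || head1[1] != "n")
    stop_morphgw("missing 'n <N>' header in distance-matrix file", "morphgw_parse_error")
  n <- as.integer(head1[2])
  need <- 1 + n + n * (n - 1) / 2
  if (length(lines) != need)
    stop_morphgw(sprintf("distance-matrix file has %d rows, expected %d",
                         length(lines), need), "morphgw_parse_error")
  ids <- trimws(lines[1 + seq_len(n)])
  vals <- as.numeric(lines[(1 + n + 1):need])
  if (any(!is.finite(vals)))
    stop_morphgw("non-finite distance in matrix file", "morphgw_value_error")
  if (any(vals < 0))
    stop_morphgw("negative distance in matrix file", "morphgw_value_error")
  gw_space(uncondense_matrix(vals, n), ids)
}
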