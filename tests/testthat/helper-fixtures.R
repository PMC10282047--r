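# Shared fixtures: tiny hand-built trees, SWC writers, and generated
# cell sets used across the test files.

# a straight path along x: nodes at x = xs
path_tree <- function(xs = c(0, 5, 10)) {
  n <- length(xs)
  morphgw:::new_neuron_tree(data.frame(
    id = seq_len(n), type = c(1L, rep(3L, n - 1)), x = xs, y = 0, z = 0,
    radius = 1, parent = c(-1L, seq_len(n - 1))
  ))
}

# Y-shaped tree: trunk along +z then two arms of slightly different
# lengths (incommensurate radii keep even sampling well posed)
y_tree <- function(trunk = 9.3, arm = 10.1, arm2 = 7.6, step = 1) {
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 1, parent = -1L)
  add_path <- function(nodes, from_id, dir, len, step) {
    pos <- as.numeric(nodes[nodes$id == from_id, c("x", "y", "z")])
    parent <- from_id
    nseg <- max(1, round(len / step))
    seg <- len / nseg
    for (s in seq_len(nseg)) {
      pos <- pos + dir * seg
      id <- nrow(nodes) + 1L
      nodes <- rbind(nodes, data.frame(id = id, type = 3L, x = pos[1],
                                       y = pos[2], z = pos[3],
                                       radius = 0.5, parent = parent))
      parent <- id
    }
    nodes
  }
  nodes <- add_path(nodes, 1L, c(0, 0, 1), trunk, step)
  top <- nodes$id[nrow(nodes)]
  nodes <- add_path(nodes, top, c(sqrt(0.5), 0, sqrt(0.5)), arm, step)
  nodes <- add_path(nodes, top, c(-sqrt(0.5), 0, sqrt(0.5)), arm2, step)
  morphgw:::new_neuron_tree(nodes)
}

write_swc_lines <- function(lines, dir = tempdir()) {
  path <- tempfile(fileext = ".swc", tmpdir = dir)
  writeLines(lines, path)
  path
}

# a set of geodesic icdms from two morphology classes plus their GW
# space; memoised because several test files reuse it
two_class_cells <- local({
  cache <- NULL
  function(n_per_class = 20, n_points = 50) {
    if (!is.null(cache)) return(cache)
    cells <- list(); labels <- character(0); trees <- list()
    for (cl in c("a", "b")) {
      spec <- neuron_spec(n_branches = if (cl == "a") 2L else 8L)
      for (i in seq_len(n_per_class)) {
        tr <- generate_neuron(spec, seed = i + 100 * (cl == "b"))
        pc <- sample_swc_even(tr, n_points)
        d <- geodesic_matrix_swc(tr, pc)
        d$cell_id <- sprintf("%s_%02d", cl, i)
        trees[[length(trees) + 1L]] <- tr
        cells[[length(cells) + 1L]] <- d
        labels <- c(labels, cl)
      }
    }
    cache <<- list(cells = cells, labels = labels, trees = trees,
                   space = gw_pairwise(cells))
    cache
  }
})
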