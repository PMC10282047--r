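test_that("read_swc parses a simple sorted file", {
  p <- write_swc_lines(c(
    "# comment line",
    "1 1 0 0 0 1 -1",
    "2 3 1 0 0 0.5 1",
    "3 3 2 0 0 0.5 2"
  ))
  tree <- read_swc(p)
  expect_s3_class(tree, "neuron_tree")
  expect_equal(nrow(tree), 3)
  e <- morphgw:::tree_edge_lengths(tree)
  expect_equal(unname(e[, "length"]), c(1, 1))
})

test_that("unsorted SWC is rejected by default and resorted on request", {
  p <- write_swc_lines(c(
    "1 1 0 0 0 1 -1",
    "3 3 2 0 0 0.5 2",   # child precedes its parent
    "2 3 1 0 0 0.5 1"
  ))
  expect_error(read_swc(p), class = "morphgw_unsorted_error")
  tree <- read_swc(p, resort = TRUE)
  expect_equal(tree$id, c(1L, 2L, 3L))
  expect_equal(tree$parent, c(-1L, 1L, 2L))
})

test_that("structural defects raise distinct errors", {
  dangling <- write_swc_lines(c("1 1 0 0 0 1 -1", "3 3 1 0 0 1 9"))
  expect_error(read_swc(dangling), class = "morphgw_dangling_parent_error")
  tworoots <- write_swc_lines(c("1 1 0 0 0 1 -1", "2 1 5 0 0 1 -1",
                                "3 3 6 0 0 1 2", "4 3 7 0 0 1 3"))
  expect_error(read_swc(tworoots), class = "morphgw_multiple_roots_error")
  # keep_largest retains the bigger component
  tree <- read_swc(tworoots, keep_largest = TRUE)
  expect_equal(nrow(tree), 3)
  expect_equal(tree$id, c(2L, 3L, 4L))
  zeroedge <- write_swc_lines(c("1 1 0 0 0 1 -1", "2 3 0 0 0 1 1"))
  expect_error(read_swc(zeroedge), class = "morphgw_zero_edge_error")
})

test_that("write_swc / read_swc round-trips valid trees", {
  tree <- generate_neuron(neuron_spec(n_branches = 3), seed = 42)
  p <- tempfile(fileext = ".swc")
  write_swc(tree, p)
  back <- read_swc(p)
  expect_equal(as.data.frame(back), as.data.frame(tree), tolerance = 0)
})

test_that("read_mesh handles OBJ and PLY, preserving vertex order", {
  obj <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "f 1 2 3", "f 1 2 4", "f 1 3 4", "f 2 3 4"), obj)
  m <- read_mesh(obj)
  expect_equal(nrow(m$vertices), 4)
  expect_equal(nrow(m$faces), 4)
  expect_equal(m$vertices[2, ], c(1, 0, 0))

  ply <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0",
               "3 0 1 2"), ply)
  mp <- read_mesh(ply)
  expect_equal(nrow(mp$vertices), 3)
  expect_equal(mp$faces[1, ], c(1L, 2L, 3L))
})

test_that("mesh defects are rejected; faceless PLY is a point cloud", {
  bad <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 9"), bad)
  expect_error(read_mesh(bad), class = "morphgw_face_index_error")
  degen <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 2"), degen)
  expect_error(read_mesh(degen), class = "morphgw_degenerate_face_error")
  nofaces <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               "property float x", "property float y", "property float z",
               "element face 0",
               "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 1 1"), nofaces)
  expect_message(m <- read_mesh(nofaces), "point cloud")
  expect_equal(nrow(m$faces), 0)
})

test_that("read_mask enforces a single foreground object", {
  one <- matrix(0, 10, 10); one[3:6, 3:6] <- 1
  p1 <- tempfile(fileext = ".png"); png::writePNG(one, p1)
  m <- read_mask(p1, pixel_size = 0.5)
  expect_equal(sum(m$pixels), 16)
  expect_equal(m$pixel_size, 0.5)

  p0 <- tempfile(fileext = ".png"); png::writePNG(matrix(0, 10, 10), p0)
  expect_error(read_mask(p0), class = "morphgw_empty_mask_error")

  two <- matrix(0, 10, 10); two[1:3, 1:3] <- 1; two[7:9, 7:9] <- 1
  p2 <- tempfile(fileext = ".png"); png::writePNG(two, p2)
  expect_error(read_mask(p2), class = "morphgw_multiple_objects_error")
})

test_that("condensed GW matrix files round-trip exactly", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  sp <- gw_space(D, c("a", "b", "c"))
  p <- tempfile(fileext = ".gw")
  write_gw_matrix(sp, p)
  lines <- readLines(p)
  expect_equal(as.numeric(lines[(length(lines) - 2):length(lines)]), c(1, 2, 3))
  back <- read_gw_matrix(p)
  expect_identical(back$cell_ids, sp$cell_ids)
  expect_identical(unname(back$D), unname(sp$D))

  # full-precision round trip of irrational values
  set.seed(3)
  pts <- matrix(rnorm(30), 10, 3)
  D2 <- as.matrix(dist(pts))
  sp2 <- gw_space(D2)
  p2 <- tempfile(fileext = ".gw")
  write_gw_matrix(sp2, p2)
  expect_identical(unname(read_gw_matrix(p2)$D), unname(sp2$D))
})

test_that("invalid GW matrices are refused", {
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(gw_space(bad), class = "morphgw_asymmetric_error")
  p <- tempfile()
  writeLines(c("n 2", "a", "b", "-1"), p)
  expect_error(read_gw_matrix(p), class = "morphgw_value_error")
  writeLines(c("n 3", "a", "b", "c", "1", "2"), p)  # too few rows
  expect_error(read_gw_matrix(p), class = "morphgw_parse_error")
})
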