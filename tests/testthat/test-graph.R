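test_that("adjacency building dedups, symmetrizes and finds components", {
  # 2x2 rook grid: every area has exactly 2 neighbours, one component
  g <- generate_lattice(2, 2)
  expect_equal(g$n_areas, 4L)
  expect_equal(nrow(g$edges), 4L)
  expect_equal(g$n_neighbors, rep(2L, 4))
  expect_equal(g$n_components, 1L)

  # both (A,B) and (B,A) collapse to a single edge
  g2 <- build_adjacency(rbind(c("A", "B"), c("B", "A")), c("A", "B"))
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$n_neighbors, c(1L, 1L))

  # areas absent from the edge list become isolated singletons
  g3 <- build_adjacency(rbind(c("0", "1"), c("1", "2")),
                        as.character(0:4))
  expect_equal(g3$n_components, 3L)
  expect_equal(sort(g3$singletons), c(4L, 5L))
  expect_equal(g3$component[1:3], rep(g3$component[1], 3))

  expect_error(build_adjacency(rbind(c("A", "Z")), c("A", "B")), "unknown")
  expect_error(build_adjacency(rbind(c("A", "A")), c("A", "B")), "self-loop")
})

test_that("ICAR quadratic form matches hand and Laplacian oracles", {
  g <- path3_graph()
  expect_equal(icar_quadform(c(5, 5, 5), g), 0)
  expect_equal(icar_quadform(c(0, 1, 3), g), 5)  # 1 + 4 over the two edges
  expect_equal(icar_quadform(c(1, 0, 0, 0), star_graph()), 3)
  expect_error(icar_quadform(c(1, 2), g), "length")

  # field' L field equals the edge-loop oracle on random graphs
  set.seed(42)
  for (rep in 1:10) {
    gr <- random_graph(sample(5:20, 1))
    f <- rnorm(gr$n_areas)
    L <- apomap:::graph_laplacian(gr)
    expect_equal(icar_quadform(f, gr), drop(t(f) %*% L %*% f),
                 tolerance = 1e-10)
    expect_equal(icar_quadform(f, gr), icar_oracle(f, gr), tolerance = 1e-10)
    # invariance to adding a constant
    expect_equal(icar_quadform(f + 17.3, gr), icar_quadform(f, gr),
                 tolerance = 1e-8)
  }
})

test_that("RW1 quadratic form is the first-difference penalty", {
  expect_equal(rw1_quadform(rep(2.5, 6)), 0)
  expect_equal(rw1_quadform(c(0, 1, 3)), 5)
  a <- 1.7; d <- 0.3
  expect_equal(rw1_quadform(c(a, a + d, a + 2 * d)), 2 * d^2)
  expect_error(rw1_quadform(3), "at least 2")

  # equals the ICAR form on the path graph of the same length
  set.seed(7)
  x <- rnorm(6)
  ids <- paste0("p", 1:6)
  pg <- build_adjacency(cbind(ids[-6], ids[-1]), ids)
  expect_equal(rw1_quadform(x), icar_quadform(x, pg))
})

test_that("adjacency files round-trip in both dialects", {
  g <- generate_lattice(2, 3)
  el <- tempfile(fileext = ".csv")
  write_edge_list(g, el)
  g2 <- read_adjacency(el, area_ids = g$area_ids)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$n_neighbors, g$n_neighbors)

  # GAL dialect
  gal <- tempfile(fileext = ".gal")
  lines <- c(sprintf("0 %d", g$n_areas))
  for (i in seq_len(g$n_areas)) {
    nb <- c(g$edges[g$edges[, 1] == i, 2], g$edges[g$edges[, 2] == i, 1])
    lines <- c(lines, sprintf("%s %d", g$area_ids[i], length(nb)))
    if (length(nb)) lines <- c(lines, paste(g$area_ids[nb], collapse = " "))
  }
  writeLines(lines, gal)
  g3 <- read_adjacency(gal)
  expect_equal(g3$n_neighbors, g$n_neighbors)
  expect_equal(g3$n_components, 1L)
})

test_that("lattice generator produces the expected rook structure", {
  p <- generate_lattice(1, 5)
  expect_equal(nrow(p$edges), 4L)      # path graph
  expect_equal(p$n_components, 1L)
  g33 <- generate_lattice(3, 3)
  expect_equal(nrow(g33$edges), 12L)
  expect_equal(sort(unique(g33$n_neighbors)), c(2L, 3L, 4L))
  expect_equal(sum(g33$n_neighbors == 2L), 4L)  # corners
  expect_equal(sum(g33$n_neighbors == 4L), 1L)  # center
  expect_error(generate_lattice(0, 3), ">= 1")
})
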