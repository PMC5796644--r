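# Directed-graph summaries and exports.

test_that("in/out-strengths: hand sums, roles, conservation", {
  A0 <- diag(-0.5, 3)
  st0 <- strengths(A0)
  expect_equal(st0$in_strength, rep(0, 3))
  expect_equal(st0$out_strength, rep(0, 3))

  # hand-computed 2-node case: A[i, j] couples source j to target i
  A <- matrix(c(-0.5, -0.3, 0.2, -0.5), 2, 2)
  st <- strengths(A)
  expect_equal(st$in_strength, c(0.2, -0.3))
  expect_equal(st$out_strength, c(-0.3, 0.2))
  expect_equal(st$role, c("sink", "source"))

  # conservation: totals agree for random matrices, signed or absolute
  for (s in 1:5) {
    set.seed(s)
    M <- matrix(rnorm(49), 7)
    expect_equal(sum(strengths(M)$in_strength),
                 sum(strengths(M)$out_strength))
    expect_equal(sum(strengths(M, absolute = TRUE)$in_strength),
                 sum(strengths(M, absolute = TRUE)$out_strength))
  }
})

test_that("symmetric/antisymmetric split reconstructs exactly", {
  set.seed(1)
  A <- matrix(rnorm(36), 6)
  parts <- sym_antisym(A)
  expect_equal(parts$S + parts$N, A)
  expect_equal(parts$S, t(parts$S))
  expect_equal(parts$N, -t(parts$N))
  # Frobenius orthogonality of the split
  expect_equal(sum(A^2), sum(parts$S^2) + sum(parts$N^2))

  S <- crossprod(A)
  expect_equal(sym_antisym(S)$N, matrix(0, 6, 6))

  # unnormalized convention: plain sum and difference
  u <- sym_antisym(A, scale = "unnormalized")
  expect_equal(u$S, A + t(A))
  expect_equal(u$N, A - t(A))
})

test_that("network down-sampling averages coupling between region sets", {
  # 4 regions in 2 blocks, hand-set entries
  A <- matrix(c(-0.5, 0.1, 0.2, 0.3,
                0.4, -0.5, 0.5, 0.6,
                0.7, 0.8, -0.5, 0.9,
                1.0, 1.1, 1.2, -0.5), 4, 4, byrow = TRUE)
  part <- c("a", "a", "b", "b")
  M <- downsample_to_networks(A, part)
  expect_equal(M["a", "a"], mean(c(0.1, 0.4)))        # diag block, no self
  expect_equal(M["a", "b"], mean(c(0.2, 0.3, 0.5, 0.6)))
  expect_equal(M["b", "a"], mean(c(0.7, 0.8, 1.0, 1.1)))
  expect_equal(M["b", "b"], mean(c(0.9, 1.2)))
  # including self-connections changes diagonal blocks only
  Mi <- downsample_to_networks(A, part, exclude_self = FALSE)
  expect_equal(Mi["a", "b"], M["a", "b"])
  expect_equal(Mi["a", "a"], mean(c(-0.5, 0.1, 0.4, -0.5)))

  # permuting regions with consistent labels leaves the result unchanged
  perm <- c(3, 1, 4, 2)
  expect_equal(downsample_to_networks(A[perm, perm], part[perm])[
    c("a", "b"), c("a", "b")], M)

  # block-constant coupling maps to exactly its block values
  B <- matrix(0.3, 4, 4); B[1:2, 3:4] <- -0.2; diag(B) <- -0.5
  MB <- downsample_to_networks(B, part)
  expect_equal(MB["a", "b"], -0.2)
  expect_equal(MB["b", "a"], 0.3)
  expect_equal(MB["a", "a"], 0.3)

  # singleton partition: scalar average excluding the self-connection
  expect_true(is.na(downsample_to_networks(matrix(-0.5, 1, 1), "x")[1, 1]))
  expect_error(downsample_to_networks(A, c("a", "a", "b", NA)), "label")
})

test_that("group binarized averages count edge evidence over subjects", {
  m1 <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2)
  m2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2)
  m3 <- matrix(c(TRUE, TRUE, TRUE, TRUE), 2)
  A1 <- matrix(c(-0.5, 0.3, 0, -0.5), 2)
  A2 <- matrix(c(-0.4, 0, 0, -0.6), 2)
  A3 <- matrix(c(-0.5, 0.6, -0.2, -0.5), 2)
  g <- group_binarize_average(list(A1, A2, A3), masks = list(m1, m2, m3))
  expect_equal(g$fraction, matrix(c(1, 2 / 3, 1 / 3, 1), 2))
  expect_equal(g$mean_weight[2, 1], mean(c(0.3, 0.6)))
  expect_equal(g$mean_weight[1, 2], -0.2)

  # identical subjects: the fraction matrix is the mask itself
  gi <- group_binarize_average(list(A1, A1), masks = list(m1, m1))
  expect_equal(gi$fraction, m1 * 1)

  expect_error(group_binarize_average(list(A1, matrix(0, 3, 3)),
                                      masks = list(m1, m1)), "size")
})

test_that("graph exports carry signed weighted directed edges", {
  A <- matrix(c(-0.5, 0.4, 0, -0.3, -0.5, 0, 0, 0.2, -0.5), 3, 3,
              byrow = TRUE)
  rownames(A) <- colnames(A) <- c("x", "y", "z")
  csv <- tempfile(fileext = ".csv")
  write_edge_list(A, csv)
  el <- read.csv(csv)
  expect_equal(nrow(el), 3L)
  # A[1, 2] = 0.4 is an edge y -> x
  e1 <- el[el$source == "y" & el$target == "x", ]
  expect_equal(e1$weight, 0.4)
  expect_equal(e1$sign, "excitatory")
  expect_equal(el$sign[el$weight < 0], "inhibitory")

  gml <- tempfile(fileext = ".graphml")
  write_graphml(A, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 3)
  expect_setequal(round(igraph::E(g)$weight, 6), c(0.4, -0.3, 0.2))
})

test_that("region tables parse with the documented columns", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("name,network,x_mm,y_mm,z_mm",
               "PCC,default,0,-52,7",
               "LV1,visual,-7,83,2"), path)
  tab <- read_region_table(path)
  expect_equal(tab$name, c("PCC", "LV1"))
  expect_equal(tab$z_mm, c(7, 2))
  writeLines("a,b\n1,2", path)
  expect_error(read_region_table(path), "columns")
})
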