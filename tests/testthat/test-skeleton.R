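test_that("read_swc parses a chain and rejects malformed files", {
  lines <- c("# comment",
             "1 1 0 0 0 1 -1",
             "2 0 0 2 0 1 1",
             "3 0 0 5 0 1 2")
  sk <- read_swc(lines)
  expect_s3_class(sk, "neuron_skeleton")
  expect_equal(nrow(sk), 3)
  expect_equal(sum(!is.na(sk$parent_id)), 2)
  expect_equal(sk$node_id[is.na(sk$parent_id)], 1L)
  expect_true("soma" %in% sk$tags[[1]])
  expect_equal(total_cable_length(sk), 5)

  two_roots <- c("1 0 0 0 0 1 -1", "2 0 1 0 0 1 -1")
  expect_error(read_swc(two_roots), "multiple roots")
  dup <- c("1 0 0 0 0 1 -1", "1 0 1 0 0 1 1")
  expect_error(read_swc(dup), "duplicate node_id 1 on line 2")
  miss <- c("1 0 0 0 0 1 -1", "2 0 1 0 0 1 9")
  expect_error(read_swc(miss), "parent 9 of node 2")
  expect_error(read_swc(c("1 0 0 0 0 1")), "7 columns")
})

test_that("unit scale converts positions to nm on read and back on write", {
  lines <- c("1 1 0 0 0 1 -1", "2 0 0 3 0 1 1")
  sk <- read_swc(lines, unit_scale = 1000) # file in um
  expect_equal(total_cable_length(sk), 3000)
  back <- write_swc(sk, unit_scale = 1000)
  expect_equal(read_swc(back, unit_scale = 1000), sk, ignore_attr = "swc_type")
})

test_that("write_swc / read_swc round-trips generated skeletons", {
  for (seed in 1:5) {
    sk <- gen_random_skeleton(40, seed = seed)
    tmp <- withr::local_tempfile(fileext = ".swc")
    write_swc(sk, tmp)
    back <- read_swc(tmp, name = skeleton_name(sk))
    expect_equal(back$node_id, sk$node_id)
    expect_equal(back$parent_id, sk$parent_id)
    expect_equal(back$x, sk$x, tolerance = 1e-5)
    expect_equal(total_cable_length(back), total_cable_length(sk),
                 tolerance = 1e-5)
    # writing the parsed skeleton again reproduces the same canonical bytes
    expect_identical(write_swc(back), write_swc(sk))
  }
})

test_that("validate_skeleton reports orphans and cycles", {
  ok <- gen_random_skeleton(30, seed = 7)
  expect_equal(nrow(validate_skeleton(ok)), 0)

  orphan <- tibble::tibble(node_id = 1:3, parent_id = c(NA, 1, 9),
                           x = 0, y = 0, z = 0)
  rep1 <- validate_skeleton(orphan)
  expect_equal(nrow(rep1), 1)
  expect_match(rep1$violation, "missing parent")

  # rewire an edge to create a cycle detached from the root
  cyc <- tibble::as_tibble(gen_random_skeleton(6, seed = 1))
  cyc$parent_id[2] <- cyc$node_id[6] # 2 <- 6 while 6 descends from 2
  rep2 <- validate_skeleton(cyc)
  expect_true(any(grepl("cycle", rep2$violation)))
  expect_error(skeleton(cyc), "invalid skeleton")
})

test_that("strahler order matches the definition on canonical trees", {
  path10 <- chain_skeleton(rep(1, 9))
  expect_true(all(strahler_order(path10)$strahler_order == 1))

  fbt <- full_binary_skeleton(3)
  so <- strahler_order(fbt)
  expect_equal(so$strahler_order[so$node_id == 1], 3)
  expect_true(all(so$strahler_order[so$node_id >= 4] == 1))
})

test_that("strahler order equals the recursive oracle on random trees", {
  for (seed in 1:25) {
    sk <- gen_random_skeleton(sample(5:80, 1), seed = seed)
    got <- strahler_order(sk)
    want <- strahler_oracle(sk)
    expect_equal(stats::setNames(got$strahler_order, got$node_id), want)
  }
})

test_that("strahler order is invariant to child permutation and edge subdivision", {
  sk <- gen_random_skeleton(60, seed = 11)
  base <- strahler_order(sk)

  # permute row order (hence child encounter order)
  perm <- tibble::as_tibble(sk)[sample(nrow(sk)), ]
  sk_perm <- skeleton(perm, name = "perm")
  got <- strahler_order(sk_perm)
  expect_equal(got$strahler_order[match(base$node_id, got$node_id)],
               base$strahler_order)

  # subdivide an edge: insert a pass-through node on edge to node 30
  nodes <- tibble::as_tibble(sk)
  mid_id <- max(nodes$node_id) + 1L
  old_parent <- nodes$parent_id[nodes$node_id == 30]
  nodes$parent_id[nodes$node_id == 30] <- mid_id
  nodes <- dplyr::bind_rows(nodes, tibble::tibble(
    node_id = mid_id, parent_id = old_parent, x = 0, y = 0, z = 0,
    radius = NA_real_, tags = list(character())))
  sub <- strahler_order(skeleton(nodes, name = "sub"))
  expect_equal(sub$strahler_order[match(base$node_id, sub$node_id)],
               base$strahler_order)
})

test_that("geodesic distance sums edge lengths along the unique path", {
  sk <- chain_skeleton(c(2, 3, 5))
  expect_equal(geodesic_distance(sk, 1, 4), 10)
  expect_equal(geodesic_distance(sk, 3, 3), 0)
  expect_equal(geodesic_distance(sk, 2, 4), 8)
  expect_error(geodesic_distance(sk, 1, 99), "unknown node")
})

test_that("geodesic distance equals the igraph shortest-path oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:20) {
    sk <- gen_random_skeleton(sample(10:120, 1), seed = 100 + seed)
    ids <- sample(sk$node_id, 4)
    got <- geodesic_distance(sk, rep(ids[1:2], 2), c(ids[3], ids[4], ids[4], ids[3]))
    want <- geodesic_oracle(sk, ids[1:2], ids[3:4])
    expect_equal(got, c(want[1, 1], want[2, 2], want[1, 2], want[2, 1]),
                 tolerance = 1e-9)
  }
})

test_that("geodesic distance is a metric on random instances", {
  set.seed(42)
  for (rep in 1:8) {
    sk <- gen_random_skeleton(50, seed = 200 + rep)
    ids <- sample(sk$node_id, 3)
    dab <- geodesic_distance(sk, ids[1], ids[2])
    dba <- geodesic_distance(sk, ids[2], ids[1])
    dac <- geodesic_distance(sk, ids[1], ids[3])
    dcb <- geodesic_distance(sk, ids[3], ids[2])
    expect_gte(dab, 0)
    expect_equal(dab, dba)
    expect_equal(geodesic_distance(sk, ids[1], ids[1]), 0)
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("find_dendritic_root honors a manual tag", {
  nodes <- tibble::as_tibble(chain_skeleton(rep(1, 5)))
  nodes$tags[[4]] <- "dendritic_root"
  sk <- skeleton(nodes, name = "tagged")
  expect_equal(find_dendritic_root(sk), 4L)
})

test_that("find_dendritic_root recovers the planted branch point from synapse flow", {
  hits <- 0
  for (seed in 1:30) {
    g <- gen_skeleton(
      n_nodes = 120,
      classes = list(
        synapse_class_spec("KC_input", 40, "post",
                           list(type = "uniform", min = 0, max = 3000)),
        synapse_class_spec("output", 30, "pre",
                           list(type = "uniform", min = 0, max = 3000))),
      tag_root = FALSE, seed = 500 + seed)
    got <- find_dendritic_root(g$skeleton, g$synapses)
    hits <- hits + (got == g$truth$dendritic_root)
  }
  expect_gte(hits, 29) # >= ~99% under clean separation
})

test_that("find_dendritic_root errors without tag and synapses", {
  sk <- chain_skeleton(rep(1, 4)) # no branch point
  expect_error(find_dendritic_root(sk, make_synapses("chain", post_nodes = 2)),
               "no branch point")
  branched <- full_binary_skeleton(3)
  expect_error(find_dendritic_root(branched, NULL), "synapse table required")
  empty <- make_synapses("fbt")
  expect_error(find_dendritic_root(branched, empty), "synapse table required")
})

test_that("extract_axonlets returns planted all-presynaptic subtrees only", {
  g <- gen_skeleton(
    n_nodes = 200,
    classes = list(
      synapse_class_spec("KC_input", 60, "post",
                         list(type = "uniform", min = 0, max = 5000))),
    n_axonlets = 2, axonlet_synapses = 5, seed = 77)
  ax <- extract_axonlets(g$skeleton, g$synapses, g$truth$dendritic_root)
  expect_setequal(ax$axonlet_root, g$truth$axonlet_roots)
  expect_true(all(ax$n_presynapses == 5))
  expect_lte(sum(ax$cable_length_nm), total_cable_length(g$skeleton))

  # contaminate one axonlet with a postsynapse: it must be excluded
  syn2 <- dplyr::bind_rows(g$synapses, tibble::tibble(
    connector_id = max(g$synapses$connector_id) + 1L,
    pre_neuron = "KC", pre_node = NA_integer_,
    post_neuron = skeleton_name(g$skeleton),
    post_node = g$truth$axonlet_roots[1]))
  ax2 <- extract_axonlets(g$skeleton, syn2, g$truth$dendritic_root)
  expect_false(g$truth$axonlet_roots[1] %in% ax2$axonlet_root)
  expect_true(g$truth$axonlet_roots[2] %in% ax2$axonlet_root)

  # no presynapses anywhere -> no axonlets
  g0 <- gen_skeleton(
    n_nodes = 120,
    classes = list(
      synapse_class_spec("KC_input", 30, "post",
                         list(type = "uniform", min = 0, max = 3000))),
    seed = 78)
  ax0 <- extract_axonlets(g0$skeleton, g0$synapses, g0$truth$dendritic_root)
  expect_equal(nrow(ax0), 0)
})
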