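test_that("synapse count bounds reproduce the published table exactly", {
  b <- synapse_count_bounds(c(17, 16, 47))
  expect_equal(b$lower, c(16.6, 15.6, 46.0))
  expect_equal(b$upper, c(18.4, 17.3, 50.8))
  expect_equal(synapse_count_bounds(0), tibble::tibble(found = 0L, lower = 0, upper = 0))
  expect_error(synapse_count_bounds(-1), "non-negative")
  expect_error(synapse_count_bounds(3.5), "non-negative integers")
  expect_error(detection_rates(post_found_rate = 1.2), "\\[0, 1\\]")
})

test_that("bounds bracket the found count and scale linearly", {
  found <- c(0L, 1L, 5L, 40L, 400L)
  b <- synapse_count_bounds(found)
  expect_true(all(b$lower <= b$found))
  expect_true(all(b$found <= b$upper))
  # linear before rounding (reported values differ only by the 1-decimal round)
  b10 <- synapse_count_bounds(found * 10)
  expect_true(all(abs(b10$lower - 10 * found * (1 - 0.022)) <= 0.05))
  expect_true(all(abs(b10$upper - 10 * found * (1 + 0.083 * 0.978)) <= 0.05))
})

test_that("distance profiles measure geodesic distance per class", {
  sk <- chain_skeleton(c(3, 4)) # nodes 1-2-3, root at 1
  syn <- make_synapses("chain", post_nodes = c(1, 1), pre_nodes = 3)
  p_in <- distance_profile(sk, syn, "input", dendritic_root = 1)
  expect_equal(p_in$distance_nm, c(0, 0))
  p_out <- distance_profile(sk, syn, "output", dendritic_root = 1)
  expect_equal(p_out$distance_nm, 7)
  expect_error(distance_profile(sk, syn, "MVP2_input", 1), "no sites")
  g <- glance(p_in)
  expect_equal(g$n, 2)
  expect_equal(g$median_nm, 0)
})

test_that("planted proximal and distal classes separate in the profile medians", {
  g <- gen_skeleton(
    n_nodes = 400,
    classes = list(
      synapse_class_spec("MVP2_input", 40, "post",
                         list(type = "gaussian", mean = 1500, sd = 400)),
      synapse_class_spec("KC_input", 40, "post",
                         list(type = "gaussian", mean = 6000, sd = 400))),
    seed = 21)
  prox <- distance_profile(g$skeleton, g$synapses, "MVP2_input", g$truth$dendritic_root)
  dist <- distance_profile(g$skeleton, g$synapses, "KC_input", g$truth$dendritic_root)
  expect_lt(stats::median(prox$distance_nm), stats::median(dist$distance_nm))
  cmp <- compare_localization(prox, dist)
  expect_lt(cmp$median_difference_nm, 0)
  expect_lt(cmp$p_value, 0.05)
})

test_that("mixture fitting recovers the generating family", {
  set.seed(7)
  uni <- rnorm(500, 5000, 800)
  f1 <- fit_distance_distribution(uni)
  expect_equal(f1$n_components, 1)
  expect_equal(f1$selected_model, "Gaussian")
  # recovered mean within 3 standard errors
  expect_lt(abs(f1$means - 5000), 3 * 800 / sqrt(500))

  bi <- c(rnorm(250, 3000, 500), rnorm(250, 3000 + 6 * 500, 500))
  f2 <- fit_distance_distribution(bi)
  expect_equal(f2$n_components, 2)
  expect_equal(f2$selected_model, "bimodal Gaussian")
  expect_equal(sum(f2$weights), 1)
  expect_equal(f2$means, c(3000, 6000), tolerance = 0.05)
  expect_true(all(f2$sds > 0))
  expect_lt(f2$bic["bimodal_gaussian"], f2$bic["gaussian"])

  expect_error(fit_distance_distribution(rnorm(5)), "insufficient sample")
  expect_error(fit_distance_distribution(rep(3, 20)), "zero variance")
})

test_that("mixture selection agrees with an independent mixture package", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(11)
  cases <- list(rnorm(400, 10, 2),
                c(rnorm(200, 0, 1), rnorm(200, 8, 1)))
  for (x in cases) {
    mine <- fit_distance_distribution(x)
    ref <- mclust::Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE)
    expect_equal(mine$n_components, ref$G)
    if (mine$n_components == 2) {
      expect_equal(sort(mine$means), sort(unname(ref$parameters$mean)),
                   tolerance = 0.05)
    }
  }
})

test_that("compare_localization is antisymmetric and handles degenerate input", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(compare_localization(a, a)$median_difference_nm, 0)
  set.seed(3)
  x <- rnorm(100, 1000, 5)
  cmp <- compare_localization(x, x + 10)
  expect_equal(cmp$median_difference_nm, -10, tolerance = 1e-9)
  expect_lt(cmp$p_value, 0.05)
  flip <- compare_localization(x + 10, x)
  expect_equal(flip$median_difference_nm, -cmp$median_difference_nm)
  expect_equal(flip$p_value, cmp$p_value)
  deg <- compare_localization(1, 2)
  expect_equal(deg$p_value, 1)
  expect_error(compare_localization(numeric(), 1), "empty")
})

test_that("connectivity_table counts one contact per post target", {
  syn <- tibble::tibble(
    connector_id = c(1L, 1L),
    pre_neuron = "A", pre_node = 10L,
    post_neuron = c("B", "B"), post_node = c(5L, 6L))
  m <- connectivity_table(syn)
  expect_equal(m["A", "B"], 2L)
  expect_equal(sum(m), 2L)

  empty <- syn[0, ]
  m0 <- connectivity_table(empty, neurons = c("A", "B"))
  expect_true(all(m0 == 0L))

  expect_warning(connectivity_table(syn, neurons = c("A", "C")), "dropped")
})

test_that("connectivity_table equals a brute-force tally on random tables", {
  set.seed(9)
  for (rep in 1:10) {
    neurons <- paste0("n", 1:5)
    n <- sample(20:60, 1)
    syn <- tibble::tibble(
      connector_id = seq_len(n),
      pre_neuron = sample(neurons, n, replace = TRUE),
      pre_node = 1L,
      post_neuron = sample(neurons, n, replace = TRUE),
      post_node = 1L)
    m <- connectivity_table(syn, neurons)
    for (i in neurons) for (j in neurons) {
      expect_identical(m[i, j],
                       sum(syn$pre_neuron == i & syn$post_neuron == j))
    }
    # row sums = total post targets per presynaptic neuron
    expect_equal(rowSums(m), as.double(table(factor(syn$pre_neuron, neurons))),
                 ignore_attr = TRUE)
  }
})

test_that("dendrogram layout preserves topology and marks", {
  ch <- chain_skeleton(rep(2, 6))
  lay <- layout_dendrogram(ch)
  expect_equal(lay$y, as.numeric(0:6)) # depth along the chain
  expect_equal(length(unique(lay$x)), 1) # collinear

  sk <- gen_random_skeleton(70, seed = 13)
  lay2 <- layout_dendrogram(sk)
  edges_layout <- lay2[!is.na(lay2$parent_id), c("node_id", "parent_id")]
  edges_skel <- tibble::as_tibble(sk)[!is.na(sk$parent_id), c("node_id", "parent_id")]
  expect_setequal(paste(edges_layout$node_id, edges_layout$parent_id),
                  paste(edges_skel$node_id, edges_skel$parent_id))
  # depth equals topological distance from root
  expect_equal(lay2$y[lay2$node_id == 1], 0)

  marks <- tibble::tibble(node_id = sample(sk$node_id, 12),
                          mark = rep(c("MVP2_input", "KC_input", "output"), 4))
  lay3 <- layout_dendrogram(sk, marks)
  kept <- lay3[!is.na(lay3$mark), c("node_id", "mark")]
  expect_equal(nrow(kept), 12)
  expect_setequal(paste(kept$node_id, kept$mark), paste(marks$node_id, marks$mark))
  expect_error(layout_dendrogram(sk, tibble::tibble(node_id = 9999, mark = "x")),
               "unknown node")
})
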