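# Independent oracles and small fixture builders shared across tests.

# Chain skeleton with given segment lengths (along y).
chain_skeleton <- function(seg_lengths, name = "chain") {
  n <- length(seg_lengths) + 1
  skeleton(tibble::tibble(
    node_id = seq_len(n),
    parent_id = c(NA_integer_, seq_len(n - 1)),
    x = 0, y = cumsum(c(0, seg_lengths)), z = 0), name = name)
}

# Full binary tree of the given depth (depth 1 = single root), unit edges.
full_binary_skeleton <- function(depth) {
  n <- 2^depth - 1
  parent <- c(NA_integer_, floor((2:n) / 2))
  skeleton(tibble::tibble(node_id = seq_len(n), parent_id = parent,
                          x = seq_len(n), y = 0, z = 0), name = "fbt")
}

# Naive recursive Strahler oracle working on id-indexed children lists.
strahler_oracle <- function(sk) {
  nodes <- tibble::as_tibble(sk)
  kids <- split(nodes$node_id, factor(nodes$parent_id, levels = nodes$node_id))
  rec <- function(id) {
    ch <- kids[[as.character(id)]]
    if (is.null(ch) || length(ch) == 0) return(1L)
    sub <- vapply(ch, rec, integer(1))
    mx <- max(sub)
    if (sum(sub == mx) >= 2L) mx + 1L else mx
  }
  stats::setNames(vapply(nodes$node_id, rec, integer(1)), nodes$node_id)
}

# Weighted shortest-path oracle via igraph on the skeleton's edge list.
geodesic_oracle <- function(sk, from, to) {
  nodes <- tibble::as_tibble(sk)
  e <- nodes[!is.na(nodes$parent_id), ]
  p <- match(e$parent_id, nodes$node_id)
  c_ <- match(e$node_id, nodes$node_id)
  w <- sqrt((nodes$x[c_] - nodes$x[p])^2 + (nodes$y[c_] - nodes$y[p])^2 +
              (nodes$z[c_] - nodes$z[p])^2)
  gr <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$parent_id), to = as.character(e$node_id)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node_id)))
  igraph::distances(gr, v = as.character(from), to = as.character(to),
                    weights = w)
}

# Synapse table builder: post sites on `post_nodes` of `neuron` (from partner),
# pre sites on `pre_nodes` of `neuron` (onto a dummy target).
make_synapses <- function(neuron, post_nodes = integer(), pre_nodes = integer(),
                          partner = "KC") {
  n_post <- length(post_nodes); n_pre <- length(pre_nodes)
  tibble::tibble(
    connector_id = seq_len(n_post + n_pre),
    pre_neuron = c(rep(partner, n_post), rep(neuron, n_pre)),
    pre_node = c(rep(NA_integer_, n_post), as.integer(pre_nodes)),
    post_neuron = c(rep(neuron, n_post), rep("target", n_pre)),
    post_node = c(as.integer(post_nodes), rep(NA_integer_, n_pre)))
}
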