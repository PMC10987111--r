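# Independent naive implementation of the attention network, written as
# straight loops over the closed-form equations. Used as the oracle the
# vectorized implementation is checked against; kept free of any code from
# the package's forward pass.

naive_gat_forward <- function(params, config, graphs) {
  slope <- config$leaky_slope
  vapply(graphs, function(g) {
    H <- g$node_features
    n <- nrow(H)
    nbrs <- lapply(seq_len(n), function(i) {
      c(i, g$arcs[g$arcs[, "dst"] == i, "src"])
    })
    for (l in seq_len(config$n_layers)) {
      nh <- config$heads_per_layer[l]
      outs <- vector("list", nh)
      for (h in seq_len(nh)) {
        pre <- sprintf("l%d_h%d_", l, h)
        W <- params[[paste0(pre, "W")]]
        ad <- drop(params[[paste0(pre, "a_dst")]])
        as_ <- drop(params[[paste0(pre, "a_src")]])
        O <- matrix(0, n, ncol(W))
        for (i in seq_len(n)) {
          js <- nbrs[[i]]
          e <- vapply(js, function(j) {
            v <- sum(ad * drop(H[i, ] %*% W)) + sum(as_ * drop(H[j, ] %*% W))
            if (v > 0) v else slope * v
          }, numeric(1))
          a <- exp(e - max(e)); a <- a / sum(a)
          s <- rep(0, ncol(W))
          for (k in seq_along(js)) {
            s <- s + a[k] * drop(H[js[k], ] %*% W)
          }
          O[i, ] <- ifelse(s > 0, s, exp(s) - 1)
        }
        outs[[h]] <- O
      }
      H <- if (config$head_agg_modes[l] == "flatten") {
        do.call(cbind, outs)
      } else {
        Reduce(`+`, outs) / nh
      }
    }
    emb <- c(colMeans(H), apply(H, 2, max))
    A1 <- drop(emb %*% params$W1) + drop(params$b1)
    sum(pmax(A1, 0) * params$w2) + drop(params$b2)
  }, numeric(1))
}

# all connected labeled graphs on 1..max_n nodes, as molgraph-like lists
# with random node features (enumeration by brute force over edge subsets)
enumerate_connected_graphs <- function(max_n, d_node, seed = 1) {
  withr::with_seed(seed, {
    out <- list()
    for (n in seq_len(max_n)) {
      pairs <- if (n > 1) t(utils::combn(n, 2)) else
        matrix(integer(0), ncol = 2)
      n_pairs <- nrow(pairs)
      for (mask in 0:(2^n_pairs - 1)) {
        sel <- which(bitwAnd(mask, 2^(seq_len(n_pairs) - 1)) > 0)
        edges <- pairs[sel, , drop = FALSE]
        # connectivity by union-find
        parent <- seq_len(n)
        find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
        for (k in seq_len(nrow(edges))) {
          parent[find(edges[k, 1])] <- find(edges[k, 2])
        }
        if (length(unique(vapply(seq_len(n), find, 1L))) != 1L) next
        arcs <- if (nrow(edges)) {
          cbind(src = c(edges[, 1], edges[, 2]),
                dst = c(edges[, 2], edges[, 1]))
        } else {
          cbind(src = integer(0), dst = integer(0))
        }
        out[[length(out) + 1L]] <- list(
          node_features = matrix(rnorm(n * d_node), n, d_node),
          arcs = arcs, n_atoms = n,
          canonical_smiles = sprintf("synthetic-graph-%d", length(out) + 1L),
          schema_version = feature_schema()$version)
      }
    }
    out
  })
}
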