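# Independent brute-force reference implementations. These deliberately take
# different routes than the package code (explicit set operations, per-path
# DAG recursion via shortest-path powers, triple loops) so agreement is a
# genuine two-route check.

oracle_jaccard <- function(u, v) {
  su <- which(u == 1)
  sv <- which(v == 1)
  un <- union(su, sv)
  if (!length(un)) return(0)
  length(intersect(su, sv)) / length(un)
}

# pairwise Jaccard over concatenated modality blocks, one pair at a time
oracle_drug_similarity <- function(blocks) {
  X <- do.call(cbind, blocks)
  n <- nrow(X)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- oracle_jaccard(X[i, ], X[j, ])
    }
  }
  S
}

# ancestor contributions via the closed form delta^(shortest directed
# distance from the ancestor down to the node), using igraph
oracle_contributions <- function(dag, node, delta) {
  g <- igraph::graph_from_data_frame(dag$edges, directed = TRUE,
                                     vertices = data.frame(name = dag$nodes))
  dist <- igraph::distances(g, v = dag$nodes, to = node, mode = "out")[, 1]
  anc <- dag$nodes[is.finite(dist)]
  stats::setNames(delta^dist[anc], anc)
}

oracle_disease_similarity <- function(dag, diseases, delta) {
  contribs <- lapply(diseases, function(d) {
    oracle_contributions(dag, unname(dag$disease2node[d]), delta)
  })
  n <- length(diseases)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ci <- contribs[[i]]
      cj <- contribs[[j]]
      shared <- intersect(names(ci), names(cj))
      if (length(shared)) {
        S[i, j] <- sum(ci[shared] + cj[shared]) / (sum(ci) + sum(cj))
      }
    }
  }
  dimnames(S) <- list(diseases, diseases)
  S
}

oracle_graph_conv <- function(H, Ahat, W) {
  n <- nrow(H)
  p <- ncol(W)
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    for (q in seq_len(p)) {
      acc <- 0
      for (j in seq_len(n)) {
        for (m in seq_len(ncol(H))) {
          acc <- acc + Ahat[i, j] * H[j, m] * W[m, q]
        }
      }
      out[i, q] <- max(acc, 0)
    }
  }
  out
}

oracle_attention_coefficients <- function(H, A, Wg, a, slope) {
  n <- nrow(H)
  d <- ncol(Wg)
  G <- H %*% Wg
  lrelu <- function(x) if (x >= 0) x else slope * x
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nbr <- which(A[i, ] != 0)
    if (!length(nbr)) nbr <- i
    e <- vapply(nbr, function(j) {
      lrelu(sum(a * c(G[i, ], G[j, ])))
    }, numeric(1))
    w <- exp(e - max(e))
    alpha[i, nbr] <- w / sum(w)
  }
  alpha
}

oracle_graph_attention <- function(H, A, heads, slope) {
  n <- nrow(H)
  d <- ncol(heads[[1]]$Wg)
  acc <- matrix(0, n, d)
  for (h in heads) {
    alpha <- oracle_attention_coefficients(H, A, h$Wg, h$a, slope)
    G <- H %*% h$Wg
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (alpha[i, j] != 0) acc[i, ] <- acc[i, ] + alpha[i, j] * G[j, ]
      }
    }
  }
  M <- acc / length(heads)
  ifelse(M > 0, M, exp(pmin(M, 0)) - 1)
}

oracle_decode <- function(H, n_drugs, n_diseases, decoder) {
  out <- matrix(0, n_drugs, n_diseases)
  for (i in seq_len(n_drugs)) {
    for (j in seq_len(n_diseases)) {
      z <- c(H[i, ], H[n_drugs + j, ])
      hid <- pmax(drop(z %*% decoder$W1) + decoder$b1, 0)
      out[i, j] <- 1 / (1 + exp(-(sum(hid * decoder$w2) + decoder$b2)))
    }
  }
  out
}

# trapezoidal ROC integration over unique thresholds (second AUC route)
oracle_trapezoid_auc <- function(pos, neg) {
  th <- sort(unique(c(pos, neg, -Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  sum(diff(c(0, fpr)) * (utils::head(c(0, tpr), -1) + utils::tail(c(0, tpr), -1)) / 2)
}

# --- small random fixtures -------------------------------------------------

random_modalities <- function(n_drugs, dims, seed, p = 0.3) {
  set.seed(seed)
  ids <- sprintf("d%02d", seq_len(n_drugs))
  out <- list()
  for (k in names(dims)) {
    X <- matrix(rbinom(n_drugs * dims[[k]], 1, p), n_drugs, dims[[k]],
                dimnames = list(ids, sprintf("%s%03d", k, seq_len(dims[[k]]))))
    out[[k]] <- modality_matrix(k, X)
  }
  out
}

# random DAG over n nodes: edges only from lower to higher index
random_test_dag <- function(n_nodes, seed, n_diseases = NULL, edge_p = 0.25) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  edges <- NULL
  for (v in 2:n_nodes) {
    parents <- which(runif(v - 1) < edge_p)
    if (!length(parents)) parents <- sample.int(v - 1, 1)
    edges <- rbind(edges, data.frame(parent = ids[parents], child = ids[v]))
  }
  mapping <- NULL
  if (!is.null(n_diseases)) {
    picked <- sample(ids[-1], n_diseases)
    mapping <- stats::setNames(picked, sprintf("dis%02d", seq_len(n_diseases)))
  }
  mesh_dag(edges, mapping)
}

tiny_bundle <- function(seed = 1, n_drugs = 10, n_diseases = 12, density = 0.15) {
  gen <- generate_bundle(synthetic_spec(
    n_drugs = n_drugs, n_diseases = n_diseases, latent_rank = 2,
    density = density,
    modality_dims = c(target = 8, enzyme = 6, pathway = 5, substructure = 9, ddi = 7),
    informativeness = c(target = 0.8, enzyme = 0.8, pathway = 0.8,
                        substructure = 0.8, ddi = 0.8),
    seed = seed))
  gen$bundle
}

tiny_config <- function(...) {
  args <- utils::modifyList(list(embed_dim = 4, n_heads = 2, n_levels = 2,
                                 dropout = 0, iterations = 0, seed = 7),
                            list(...))
  do.call(model_config, args)
}

quiet_bundle <- function(...) suppressMessages(suppressWarnings(tiny_bundle(...)))
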