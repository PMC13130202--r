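#' Model configuration
#'
#' Collects every tunable of the hybrid graph model. Defaults follow the
#' method's description where it is explicit (three context-injection levels,
#' weighted-sum branch fusion, LeakyReLU attention scoring) and common
#' graph-attention practice elsewhere (4 heads, slope 0.2, ELU after
#' attention, dropout 0.1, Xavier-uniform initialization). The hyperparameter
#' search grid used on the full-scale benchmark is learning rate in
#' \{1e-4, 5e-4, 1e-3, 5e-3, 1e-2\} and embedding dimension in
#' \{64, 128, 256\}; any embedding dimension >= 2 is accepted so that
#' desk-scale experiments can run smaller.
#'
#' @param n_levels number of graph-convolution + context-injection levels.
#' @param embed_dim width of every learned projection.
#' @param n_heads number of independent attention heads K.
#' @param leaky_slope negative slope of the LeakyReLU in attention scoring.
#' @param delta discount factor of the disease semantic similarity.
#' @param dropout dropout rate on node embeddings during training.
#' @param learning_rate Adam step size.
#' @param iterations full-batch training iterations.
#' @param fusion `"weighted_sum"` (softmax-mixed branch outputs) or
#'   `"concat"` (horizontal concatenation).
#' @param modalities drug feature modalities fed to the projection branches
#'   (default: target, enzyme, pathway, substructure - the four descriptor
#'   branches; the DDI profile enters through the similarity matrix).
#' @param similarity_modalities modalities concatenated for the Jaccard drug
#'   similarity (default: all five).
#' @param pos_weight weight of positive entries in the loss; `NULL` = ratio
#'   of negatives to positives in the training matrix.
#' @param seed integer seed driving initialization, dropout and fold splits.
#' @return an object of class `multidda_config`.
#' @export
model_config <- function(n_levels = 3, embed_dim = 64, n_heads = 4,
                         leaky_slope = 0.2, delta = 0.5, dropout = 0.1,
                         learning_rate = 0.005, iterations = 500,
                         fusion = c("weighted_sum", "concat"),
                         modalities = c("target", "enzyme", "pathway", "substructure"),
                         similarity_modalities = NULL,
                         pos_weight = NULL, seed = 0L) {
  fusion <- match.arg(fusion)
  modalities <- resolve_modalities(modalities)
  if (!is.null(similarity_modalities)) similarity_modalities <- resolve_modalities(similarity_modalities)
  if (n_levels < 1) stopf("n_levels must be >= 1")
  if (embed_dim < 2) stopf("embed_dim must be >= 2")
  if (n_heads < 1) stopf("n_heads (K) must be >= 1")
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  if (delta <= 0 || delta >= 1) stopf("delta must lie strictly inside (0, 1)")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (iterations < 0) stopf("iterations must be >= 0")
  structure(list(n_levels = as.integer(n_levels), embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads), leaky_slope = leaky_slope,
                 delta = delta, dropout = dropout, learning_rate = learning_rate,
                 iterations = as.integer(iterations), fusion = fusion,
                 modalities = modalities,
                 similarity_modalities = similarity_modalities,
                 pos_weight = pos_weight, seed = as.integer(seed)),
            class = "multidda_config")
}

#' @export
print.multidda_config <- function(x, ...) {
  cat(sprintf(paste0("<multidda config: %d level(s), embed_dim %d, K=%d heads, %s fusion,\n",
                     "  lr %g, %d iterations, dropout %g, delta %g, branches: %s, seed %d>\n"),
              x$n_levels, x$embed_dim, x$n_heads, x$fusion, x$learning_rate,
              x$iterations, x$dropout, x$delta,
              paste(x$modalities, collapse = "+"), x$seed))
  invisible(x)
}

# width of the fused drug-context block appended at each level
context_width <- function(config) {
  if (config$fusion == "concat") config$embed_dim * length(config$modalities)
  else config$embed_dim
}

#' Initialize model parameters
#'
#' Xavier-uniform weights, zero biases, zero mixing logits. Level 1 consumes
#' the width-(|C|+|D|) initial features; every later level consumes the
#' previous embedding widened by the injected drug context, and its weight
#' matrix absorbs the widened input back to `embed_dim`.
#'
#' @param n_nodes number of graph nodes |C| + |D|.
#' @param modality_dims named integer vector of feature counts for the branch
#'   modalities in `config$modalities`.
#' @param config a `multidda_config`.
#' @param seed RNG seed; default `config$seed`.
#' @return an object of class `multidda_params`.
#' @export
init_params <- function(n_nodes, modality_dims, config, seed = config$seed) {
  missing <- setdiff(config$modalities, names(modality_dims))
  if (length(missing)) stopf("modality_dims missing: %s", paste(missing, collapse = ", "))
  set.seed(seed)
  d <- config$embed_dim
  ow <- context_width(config)
  widths <- c(n_nodes, rep(d + ow, config$n_levels)) # input width per level
  levels <- vector("list", config$n_levels)
  for (l in seq_len(config$n_levels)) {
    branches <- lapply(config$modalities, function(k) {
      list(P = xavier_uniform(modality_dims[[k]], d), b = numeric(d))
    })
    names(branches) <- config$modalities
    levels[[l]] <- list(W = xavier_uniform(widths[l], d),
                        branches = branches,
                        mix = numeric(length(config$modalities)))
  }
  w_final <- d + ow
  heads <- lapply(seq_len(config$n_heads), function(k) {
    list(Wg = xavier_uniform(w_final, d),
         a = stats::runif(2 * d, -sqrt(6 / (2 * d + 1)), sqrt(6 / (2 * d + 1))))
  })
  decoder <- list(W1 = xavier_uniform(2 * d, d), b1 = numeric(d),
                  w2 = drop(xavier_uniform(d, 1)), b2 = 0)
  structure(list(levels = levels, heads = heads, decoder = decoder),
            class = "multidda_params")
}

#' @export
print.multidda_params <- function(x, ...) {
  n <- length(flatten_params(x))
  cat(sprintf("<multidda params: %d level(s), %d head(s), %d scalar parameters>\n",
              length(x$levels), length(x$heads), n))
  invisible(x)
}

#' Flatten / rebuild a parameter set
#'
#' Used by the optimizer and by finite-difference checks; the two functions
#' are exact inverses for a fixed skeleton.
#'
#' @param params a `multidda_params` (or any congruent nested numeric list).
#' @return `flatten_params`: one numeric vector.
#' @export
flatten_params <- function(params) {
  leaves <- list()
  walk <- function(x) {
    if (is.list(x)) for (el in x) walk(el) else leaves[[length(leaves) + 1L]] <<- as.numeric(x)
  }
  walk(unclass(params))
  unlist(leaves, recursive = FALSE, use.names = FALSE)
}

#' @rdname flatten_params
#' @param flat numeric vector from [flatten_params()].
#' @param skeleton a params object providing the shapes.
#' @export
unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    v <- flat[pos + seq_len(n)]
    pos <<- pos + n
    if (is.matrix(x)) dim(v) <- dim(x)
    v
  }
  out <- fill(unclass(skeleton))
  if (pos != length(flat)) stopf("flat vector length %d does not match skeleton (%d)", length(flat), pos)
  class(out) <- class(skeleton)
  out
}

#' Single graph-convolution step
#'
#' \eqn{ReLU(\hat A H W)}: neighborhood-averaged features under the
#' renormalized adjacency, linearly transformed, rectified.
#'
#' @param H node feature matrix (nodes x width).
#' @param Ahat normalized adjacency from [normalize_adjacency()].
#' @param W weight matrix (width x out).
#' @return the propagated feature matrix.
#' @export
graph_conv <- function(H, Ahat, W) {
  if (!all(is.finite(H))) stopf("graph_conv: non-finite input features")
  relu(Ahat %*% H %*% W)
}

#' Per-modality projection branch
#'
#' \eqn{ReLU(X_k P_k + b_k)}: one fully connected projection of a binary drug
#' feature matrix into the shared latent space.
#'
#' @param X binary drug feature matrix (|C| x n_k).
#' @param P projection matrix (n_k x embed_dim).
#' @param b bias vector (embed_dim).
#' @return non-negative |C| x embed_dim matrix.
#' @export
modality_branch <- function(X, P, b) {
  if (ncol(X) != nrow(P)) stopf("modality_branch: %d features vs %d projection rows", ncol(X), nrow(P))
  relu(sweep(X %*% P, 2L, b, `+`))
}

#' Fuse per-modality branch outputs
#'
#' Under `weighted_sum` fusion the branch outputs are mixed with
#' softmax-normalized learnable weights, so the model adaptively assigns
#' importance to each feature type; under `concat` they are concatenated
#' horizontally.
#'
#' @param projections named list of equally shaped |C| x embed_dim matrices.
#' @param mix_weights numeric logits, one per projection (ignored for
#'   `concat`).
#' @param fusion `"weighted_sum"` or `"concat"`.
#' @return the fused drug context matrix.
#' @export
fuse_branches <- function(projections, mix_weights = numeric(length(projections)),
                          fusion = "weighted_sum") {
  if (!length(projections)) stopf("fuse_branches: no projections supplied")
  if (fusion == "concat") return(do.call(cbind, projections))
  if (length(mix_weights) != length(projections)) {
    stopf("fuse_branches: %d logits for %d projections", length(mix_weights), length(projections))
  }
  w <- softmax_vec(mix_weights)
  Reduce(`+`, Map(`*`, projections, as.list(w)))
}

#' Inject fused drug context into node embeddings
#'
#' Drug rows become \eqn{[h_i \| o_i]}; disease rows are zero-padded to the
#' same width so the next graph convolution sees uniform dimensionality.
#'
#' @param H node embeddings ((|C|+|D|) x width).
#' @param O fused drug context (|C| x context width).
#' @param n_drugs number of drug rows |C|.
#' @return widened embedding matrix.
#' @export
inject_context <- function(H, O, n_drugs) {
  if (nrow(O) != n_drugs) stopf("inject_context: O has %d rows, expected %d drugs", nrow(O), n_drugs)
  if (nrow(H) < n_drugs) stopf("inject_context: H has fewer rows than drugs")
  pad <- matrix(0, nrow(H) - n_drugs, ncol(O))
  cbind(H, rbind(O, pad))
}

# neighborhoods: nonzero adjacency entries, with a self-loop for any
# otherwise isolated node
attention_mask <- function(A, self_loop_fallback = TRUE) {
  M <- A != 0
  iso <- which(rowSums(M) == 0)
  if (length(iso)) {
    if (!self_loop_fallback) stopf("node %d has no neighbor and no self-loop", iso[1])
    M[cbind(iso, iso)] <- TRUE
  }
  M
}

#' Attention coefficients of one head
#'
#' For each node i and neighbor j (nonzero adjacency entries, with a
#' self-loop added for isolated nodes):
#' \deqn{\alpha_{ij} = softmax_{j \in N_i}\big(LeakyReLU(a^T [W_g h_i \| W_g h_j])\big)}
#' Rows sum to 1 over each node's neighborhood.
#'
#' @param H node embeddings.
#' @param A adjacency defining the neighborhoods.
#' @param Wg head projection (width x head dim).
#' @param a attention vector of length 2 x head dim.
#' @param leaky_slope LeakyReLU negative slope.
#' @param self_loop_fallback add a self-loop for isolated nodes (else error).
#' @return dense coefficient matrix, zero outside neighborhoods.
#' @export
attention_coefficients <- function(H, A, Wg, a, leaky_slope = 0.2,
                                   self_loop_fallback = TRUE) {
  d <- ncol(Wg)
  if (length(a) != 2 * d) stopf("attention vector must have length %d", 2 * d)
  M <- attention_mask(A, self_loop_fallback)
  G <- H %*% Wg
  f <- drop(G %*% a[seq_len(d)])
  g <- drop(G %*% a[d + seq_len(d)])
  E <- leaky_relu(outer(f, g, `+`), leaky_slope)
  E[!M] <- -Inf
  softmax_rows(E)
}

#' Multi-head graph attention layer
#'
#' \eqn{h_i' = ELU\big(\frac{1}{K}\sum_k \sum_{j \in N_i} \alpha^k_{ij} W_g^k h_j\big)}:
#' each head aggregates neighbors weighted by its own attention
#' coefficients; head outputs are averaged, then passed through ELU.
#'
#' @param H node embeddings.
#' @param A adjacency defining neighborhoods.
#' @param heads list of K head parameter sets, each `list(Wg, a)`.
#' @param leaky_slope LeakyReLU negative slope for the attention scores.
#' @return refined node embeddings ((|C|+|D|) x head dim).
#' @export
graph_attention <- function(H, A, heads, leaky_slope = 0.2) {
  K <- length(heads)
  if (K < 1) stopf("graph_attention: need at least one head")
  acc <- 0
  for (h in heads) {
    alpha <- attention_coefficients(H, A, h$Wg, h$a, leaky_slope)
    acc <- acc + alpha %*% (H %*% h$Wg)
  }
  elu(acc / K)
}

#' Pairwise MLP decoder
#'
#' Every (drug i, disease j) pair is scored as
#' \eqn{sigmoid(w_2^T ReLU(W_1 [h_i \| h_j] + b_1) + b_2)}: a two-layer MLP
#' on the concatenated final embeddings, producing the predicted association
#' matrix with entries in (0, 1).
#'
#' @param H final node embeddings (drugs first).
#' @param n_drugs,n_diseases block sizes.
#' @param decoder `list(W1, b1, w2, b2)`.
#' @return |C| x |D| score matrix.
#' @export
decode <- function(H, n_drugs, n_diseases, decoder) {
  if (!all(is.finite(H))) stopf("decode: non-finite embeddings")
  ic <- rep.int(seq_len(n_drugs), n_diseases)
  id <- rep(seq_len(n_diseases), each = n_drugs)
  Z <- cbind(H[ic, , drop = FALSE], H[n_drugs + id, , drop = FALSE])
  hid <- relu(sweep(Z %*% decoder$W1, 2L, decoder$b1, `+`))
  s <- sigmoid(drop(hid %*% decoder$w2) + decoder$b2)
  matrix(s, n_drugs, n_diseases)
}

# ---------------------------------------------------------------------------
# full forward pass with cache, and its analytic backward pass
# ---------------------------------------------------------------------------

# dropout masks: list(levels = list per level, att = matrix) of 0/(1/(1-p))
# multipliers, or NULL for none (evaluation / gradient checks)
make_dropout_masks <- function(n_nodes, config) {
  p <- config$dropout
  if (p <= 0) return(NULL)
  d <- config$embed_dim
  ow <- context_width(config)
  lvl <- lapply(seq_len(config$n_levels), function(l) {
    matrix(stats::rbinom(n_nodes * (d + ow), 1, 1 - p) / (1 - p), n_nodes, d + ow)
  })
  att <- matrix(stats::rbinom(n_nodes * d, 1, 1 - p) / (1 - p), n_nodes, d)
  list(levels = lvl, att = att)
}

forward_pass <- function(graph, X_list, params, config, masks = NULL,
                         Amask = NULL) {
  nC <- graph$n_drugs
  nD <- graph$n_diseases
  N <- nC + nD
  d <- config$embed_dim
  Ahat <- graph$Ahat
  if (is.null(Amask)) Amask <- attention_mask(graph$A)
  L <- config$n_levels
  cache <- list(levels = vector("list", L), heads = vector("list", config$n_heads))
  H <- graph$H0
  for (l in seq_len(L)) {
    W <- params$levels[[l]]$W
    AH <- Ahat %*% H
    Pre <- AH %*% W
    Hc <- relu(Pre)
    branches <- params$levels[[l]]$branches
    Bpre <- B <- vector("list", length(branches))
    names(Bpre) <- names(B) <- names(branches)
    for (k in names(branches)) {
      Bpre[[k]] <- sweep(X_list[[k]] %*% branches[[k]]$P, 2L, branches[[k]]$b, `+`)
      B[[k]] <- relu(Bpre[[k]])
    }
    if (config$fusion == "concat") {
      wts <- NULL
      O <- do.call(cbind, B)
    } else {
      wts <- softmax_vec(params$levels[[l]]$mix)
      O <- Reduce(`+`, Map(`*`, B, as.list(wts)))
    }
    Hl <- cbind(Hc, rbind(O, matrix(0, nD, ncol(O))))
    mk <- if (!is.null(masks)) masks$levels[[l]] else NULL
    Hout <- if (is.null(mk)) Hl else Hl * mk
    cache$levels[[l]] <- list(AH = AH, Pre = Pre, Bpre = Bpre, B = B,
                              wts = wts, O = O, mask = mk)
    H <- Hout
  }
  HL <- H
  acc <- 0
  slope <- config$leaky_slope
  for (k in seq_along(params$heads)) {
    hp <- params$heads[[k]]
    G <- HL %*% hp$Wg
    f <- drop(G %*% hp$a[seq_len(d)])
    g <- drop(G %*% hp$a[d + seq_len(d)])
    Sarg <- outer(f, g, `+`)
    E <- leaky_relu(Sarg, slope)
    E[!Amask] <- -Inf
    alpha <- softmax_rows(E)
    Z <- alpha %*% G
    cache$heads[[k]] <- list(G = G, Sarg = Sarg, alpha = alpha)
    acc <- acc + Z
  }
  Mmat <- acc / length(params$heads)
  Hatt <- elu(Mmat)
  amask <- if (!is.null(masks)) masks$att else NULL
  Hatt_used <- if (is.null(amask)) Hatt else Hatt * amask
  ic <- rep.int(seq_len(nC), nD)
  id <- rep(seq_len(nD), each = nC)
  Z2 <- cbind(Hatt_used[ic, , drop = FALSE], Hatt_used[nC + id, , drop = FALSE])
  preH <- sweep(Z2 %*% params$decoder$W1, 2L, params$decoder$b1, `+`)
  hid <- relu(preH)
  out <- drop(hid %*% params$decoder$w2) + params$decoder$b2
  scores <- matrix(sigmoid(out), nC, nD)
  cache <- c(cache, list(HL = HL, Mmat = Mmat, amask = amask, Z2 = Z2,
                         preH = preH, hid = hid, ic = ic, id = id,
                         Amask = Amask, scores = scores))
  list(scores = scores, cache = cache)
}

# gradients of the weighted BCE loss w.r.t. every parameter; returns
# list(loss, grads) with grads congruent to params
backward_pass <- function(graph, X_list, params, config, cache, labels,
                          include, pos_weight) {
  nC <- graph$n_drugs
  nD <- graph$n_diseases
  d <- config$embed_dim
  s <- cache$scores
  M <- sum(include)
  eps <- 1e-12
  loss <- -sum(include * (pos_weight * labels * log(s + eps) +
                          (1 - labels) * log(1 - s + eps))) / M
  dout_mat <- include * ((1 - labels) * s - pos_weight * labels * (1 - s)) / M
  dout <- as.vector(dout_mat) # column-major pair order, matching decode
  dec <- params$decoder
  grads <- params # same skeleton; overwritten below
  db2 <- sum(dout)
  dhid <- outer(dout, dec$w2)
  dw2 <- drop(crossprod(cache$hid, dout))
  dpre <- dhid * (cache$preH > 0)
  dW1 <- crossprod(cache$Z2, dpre)
  db1 <- colSums(dpre)
  dZ2 <- tcrossprod(dpre, dec$W1)
  grads$decoder <- list(W1 = dW1, b1 = db1, w2 = dw2, b2 = db2)
  dHc <- rowsum(dZ2[, seq_len(d), drop = FALSE], cache$ic)
  dHd <- rowsum(dZ2[, d + seq_len(d), drop = FALSE], cache$id)
  dHatt <- rbind(dHc, dHd)
  if (!is.null(cache$amask)) dHatt <- dHatt * cache$amask
  dM <- dHatt * elu_grad(cache$Mmat)
  K <- length(params$heads)
  HL <- cache$HL
  dHL <- 0
  slope <- config$leaky_slope
  for (k in seq_len(K)) {
    hp <- params$heads[[k]]
    hc <- cache$heads[[k]]
    dZ <- dM / K
    dalpha <- tcrossprod(dZ, hc$G)
    dG <- crossprod(hc$alpha, dZ)
    rowdot <- rowSums(hc$alpha * dalpha)
    dE <- hc$alpha * (dalpha - rowdot)
    dS <- dE * leaky_relu_grad(hc$Sarg, slope)
    df <- rowSums(dS)
    dg <- colSums(dS)
    a_src <- hp$a[seq_len(d)]
    a_dst <- hp$a[d + seq_len(d)]
    dG <- dG + outer(df, a_src) + outer(dg, a_dst)
    da <- c(drop(crossprod(hc$G, df)), drop(crossprod(hc$G, dg)))
    dWg <- crossprod(HL, dG)
    dHL <- dHL + tcrossprod(dG, hp$Wg)
    grads$heads[[k]] <- list(Wg = dWg, a = da)
  }
  dH <- dHL
  for (l in rev(seq_len(config$n_levels))) {
    lv <- cache$levels[[l]]
    lp <- params$levels[[l]]
    if (!is.null(lv$mask)) dH <- dH * lv$mask
    dHc_l <- dH[, seq_len(d), drop = FALSE]
    dOpad <- dH[, -seq_len(d), drop = FALSE]
    dO <- dOpad[seq_len(nC), , drop = FALSE]
    nb <- length(lp$branches)
    dB <- vector("list", nb)
    names(dB) <- names(lp$branches)
    if (config$fusion == "concat") {
      de <- config$embed_dim
      for (ki in seq_len(nb)) {
        dB[[ki]] <- dO[, (ki - 1) * de + seq_len(de), drop = FALSE]
      }
      dmix <- numeric(nb)
    } else {
      dwts <- vapply(seq_len(nb), function(ki) sum(dO * lv$B[[ki]]), numeric(1))
      for (ki in seq_len(nb)) dB[[ki]] <- lv$wts[ki] * dO
      dmix <- lv$wts * (dwts - sum(lv$wts * dwts))
    }
    gb <- lp$branches
    for (k in names(lp$branches)) {
      dBpre <- dB[[k]] * (lv$Bpre[[k]] > 0)
      gb[[k]] <- list(P = crossprod(X_list[[k]], dBpre), b = colSums(dBpre))
    }
    dPre <- dHc_l * (lv$Pre > 0)
    dW <- crossprod(lv$AH, dPre)
    grads$levels[[l]] <- list(W = dW, branches = gb, mix = dmix)
    if (l > 1) {
      dH <- graph$Ahat %*% tcrossprod(dPre, lp$W)
    }
  }
  list(loss = loss, grads = grads)
}

# one-call objective used by the trainer and by finite-difference checks
loss_and_grad <- function(graph, X_list, params, config, labels, include,
                          pos_weight, masks = NULL, Amask = NULL) {
  fw <- forward_pass(graph, X_list, params, config, masks, Amask)
  bw <- backward_pass(graph, X_list, params, config, fw$cache, labels,
                      include, pos_weight)
  list(loss = bw$loss, grads = bw$grads, scores = fw$scores)
}

branch_inputs <- function(bundle, config) {
  missing <- setdiff(config$modalities, names(bundle$modalities))
  if (length(missing)) stopf("bundle lacks modality: %s", paste(missing, collapse = ", "))
  lapply(bundle$modalities[config$modalities], `[[`, "values")
}

#' End-to-end forward pass of the hybrid model
#'
#' Composes the full architecture: initial structural features, `n_levels`
#' rounds of graph convolution + per-modality branch projection + fused
#' drug-context injection, multi-head graph attention, and the pairwise MLP
#' decoder. Deterministic given parameters (no dropout is applied at
#' evaluation).
#'
#' @param graph a `multidda_graph`.
#' @param bundle a `multidda_bundle` providing the branch inputs.
#' @param params a `multidda_params`.
#' @param config a `multidda_config`.
#' @return |C| x |D| score matrix with drug/disease dimnames.
#' @export
forward <- function(graph, bundle, params, config) {
  X_list <- branch_inputs(bundle, config)
  s <- forward_pass(graph, X_list, params, config)$scores
  dimnames(s) <- list(graph$drug_ids, graph$disease_ids)
  s
}

#' Save / load a model checkpoint
#'
#' Single-file archive (RDS) of every parameter tensor plus the resolved
#' configuration and a manifest (format tag, package version, creation time).
#'
#' @param params a `multidda_params`.
#' @param config the `multidda_config` the parameters were trained under.
#' @param path archive path.
#' @export
save_checkpoint <- function(params, config, path) {
  saveRDS(list(manifest = list(format = "multidda_checkpoint/1",
                               package = as.character(utils::packageVersion("multidda")),
                               created = format(Sys.time(), tz = "UTC")),
               params = unclass(params), config = unclass(config)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$manifest$format, "multidda_checkpoint/1")) {
    stopf("%s is not a multidda checkpoint", path)
  }
  list(params = structure(x$params, class = "multidda_params"),
       config = structure(x$config, class = "multidda_config"))
}
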