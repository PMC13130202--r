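make_small_graph <- function(seed = 3, nC = 5, nD = 7) {
  set.seed(seed)
  Sc <- crossprod(matrix(runif(nC * nC), nC)) / nC
  diag(Sc) <- 1
  Sd <- crossprod(matrix(runif(nD * nD), nD)) / nD
  diag(Sd) <- 1
  Ak <- matrix(rbinom(nC * nD, 1, 0.3), nC, nD)
  assemble_adjacency(pmin(Sc, 1), pmin(Sd, 1), Ak)
}

test_that("graph convolution matches the triple-loop oracle", {
  set.seed(1)
  H <- matrix(abs(rnorm(12)), 4, 3)
  expect_equal(graph_conv(H, diag(4), diag(3)), H) # identity propagation
  expect_equal(graph_conv(matrix(0, 4, 3), diag(4), matrix(rnorm(6), 3, 2)),
               matrix(0, 4, 2))
  for (seed in 1:4) {
    set.seed(seed)
    H <- matrix(rnorm(6 * 4), 6, 4)
    A <- matrix(runif(36), 6, 6)
    A <- (A + t(A)) / 2
    Ahat <- normalize_adjacency(A)
    W <- matrix(rnorm(4 * 3), 4, 3)
    expect_equal(graph_conv(H, Ahat, W), oracle_graph_conv(H, Ahat, W),
                 tolerance = 1e-10)
  }
  expect_error(graph_conv(matrix(NaN, 2, 2), diag(2), diag(2)), "non-finite")
})

test_that("modality branch is an affine projection with ReLU clamp", {
  X <- matrix(0, 3, 4)
  P <- matrix(rnorm(8), 4, 2)
  expect_equal(modality_branch(X, P, c(0, 0)), matrix(0, 3, 2))
  set.seed(2)
  X <- matrix(rbinom(12, 1, 0.5), 3, 4)
  b <- rnorm(2)
  out <- modality_branch(X, P, b)
  ref <- pmax(sweep(X %*% P, 2, b, `+`), 0)
  expect_equal(out, ref)
  expect_true(all(out >= 0))
  expect_error(modality_branch(X, matrix(0, 3, 2), b), "features")
})

test_that("branch fusion: softmax mixing and concatenation behave as stated", {
  set.seed(3)
  p1 <- matrix(rnorm(12), 4, 3)
  p2 <- matrix(rnorm(12), 4, 3)
  p3 <- matrix(rnorm(12), 4, 3)
  expect_equal(fuse_branches(list(a = p1), 5), p1) # singleton softmax = 1
  expect_equal(fuse_branches(list(a = p1, b = p1), c(2, -1)), p1) # convexity
  expect_equal(fuse_branches(list(p1, p2, p3), c(0, 0, 0)), (p1 + p2 + p3) / 3)
  expect_equal(fuse_branches(list(a = p1, b = p2), fusion = "concat"),
               cbind(p1, p2))
  expect_error(fuse_branches(list()), "no projections")
})

test_that("context injection concatenates drug context and zero-pads diseases", {
  set.seed(4)
  H <- matrix(rnorm(7 * 3), 7, 3)
  O <- matrix(rnorm(4 * 2), 4, 2)
  out <- inject_context(H, O, 4)
  expect_identical(dim(out), c(7L, 5L))
  expect_equal(out[1:4, 4:5], O) # trailing block is exactly O
  expect_true(all(out[5:7, 4:5] == 0))
  expect_equal(out[, 1:3], H)
  expect_equal(inject_context(H, matrix(0, 4, 2), 4)[, 4:5], matrix(0, 7, 2))
  expect_error(inject_context(H, O, 5), "rows")
})

test_that("attention coefficients are a masked softmax matching the oracle", {
  g <- make_small_graph(5)
  set.seed(5)
  H <- matrix(rnorm(12 * 4), 12, 4)
  Wg <- matrix(rnorm(4 * 3), 4, 3)
  a <- rnorm(6)
  al <- attention_coefficients(H, g$A, Wg, a, 0.2)
  expect_equal(unname(rowSums(al)), rep(1, 12), tolerance = 1e-10)
  expect_equal(al, oracle_attention_coefficients(H, g$A, Wg, a, 0.2),
               tolerance = 1e-10)

  # single-neighbor node attends fully to it; twins share 0.5/0.5
  A1 <- matrix(0, 3, 3)
  A1[1, 2] <- A1[2, 1] <- 1
  H1 <- matrix(rnorm(9), 3, 3)
  al1 <- attention_coefficients(H1, A1, diag(3), rnorm(6), 0.2)
  expect_equal(al1[1, 2], 1) # sole neighbor
  expect_equal(al1[3, 3], 1) # isolated node falls back to its self-loop
  H2 <- rbind(H1[1, ], H1[2, ], H1[2, ])
  A2 <- matrix(1, 3, 3) - diag(3)
  al2 <- attention_coefficients(H2, A2, diag(3), rnorm(6), 0.2)
  expect_equal(al2[1, 2], al2[1, 3]) # identical neighbors, equal weight
  expect_equal(al2[1, 2], 0.5)
})

test_that("multi-head attention aggregates like the loop oracle", {
  g <- make_small_graph(6)
  set.seed(6)
  H <- matrix(rnorm(12 * 4), 12, 4)
  heads <- lapply(1:3, function(k) list(Wg = matrix(rnorm(12), 4, 3), a = rnorm(6)))
  out <- graph_attention(H, g$A, heads, 0.2)
  expect_equal(out, oracle_graph_attention(H, g$A, heads, 0.2), tolerance = 1e-8)

  # duplicate heads average to the single-head output
  expect_equal(graph_attention(H, g$A, heads[c(1, 1)], 0.2),
               graph_attention(H, g$A, heads[1], 0.2), tolerance = 1e-12)
  expect_error(graph_attention(H, g$A, list(), 0.2), "at least one head")
})

test_that("pairwise MLP decoder matches the per-pair oracle", {
  set.seed(7)
  H <- matrix(rnorm(9 * 4), 9, 4)
  dec <- list(W1 = matrix(rnorm(8 * 4), 8, 4), b1 = rnorm(4),
              w2 = rnorm(4), b2 = rnorm(1))
  s <- decode(H, 4, 5, dec)
  expect_equal(s, oracle_decode(H, 4, 5, dec), tolerance = 1e-10)
  expect_true(all(s > 0 & s < 1))

  dec0 <- list(W1 = matrix(0, 8, 4), b1 = rep(0, 4), w2 = rep(0, 4), b2 = 0)
  expect_equal(decode(H, 4, 5, dec0), matrix(0.5, 4, 5)) # sigmoid(0)
})

test_that("full forward pass composes the six component operations", {
  b <- quiet_bundle(seed = 8)
  cfg <- tiny_config()
  tg <- multidda:::build_training_graph(b, cfg)
  g <- tg$graph
  dims <- sapply(b$modalities[cfg$modalities], function(m) ncol(m$values))
  params <- init_params(g$n_drugs + g$n_diseases, dims, cfg)

  s1 <- forward(g, b, params, cfg)
  s2 <- forward(g, b, params, cfg)
  expect_identical(s1, s2) # deterministic

  # hand-composed chain of the exported primitives
  H <- g$H0
  for (l in seq_len(cfg$n_levels)) {
    Hc <- graph_conv(H, g$Ahat, params$levels[[l]]$W)
    projs <- lapply(cfg$modalities, function(k) {
      modality_branch(b$modalities[[k]]$values,
                      params$levels[[l]]$branches[[k]]$P,
                      params$levels[[l]]$branches[[k]]$b)
    })
    O <- fuse_branches(projs, params$levels[[l]]$mix, cfg$fusion)
    H <- inject_context(Hc, O, g$n_drugs)
  }
  Hatt <- graph_attention(H, g$A, params$heads, cfg$leaky_slope)
  ref <- decode(Hatt, g$n_drugs, g$n_diseases, params$decoder)
  expect_equal(unname(s1), ref, tolerance = 1e-12)

  # a single level still runs with consistent shapes
  cfg1 <- tiny_config(n_levels = 1)
  p1 <- init_params(g$n_drugs + g$n_diseases, dims, cfg1)
  s3 <- forward(g, b, p1, cfg1)
  expect_identical(dim(s3), dim(b$associations))
  expect_true(all(s3 > 0 & s3 < 1))
})

test_that("permuting drug order permutes score rows identically", {
  b <- quiet_bundle(seed = 9)
  cfg <- tiny_config()
  dims <- sapply(b$modalities[cfg$modalities], function(m) ncol(m$values))
  tg <- multidda:::build_training_graph(b, cfg)
  params <- init_params(tg$graph$n_drugs + tg$graph$n_diseases, dims, cfg)
  s <- forward(tg$graph, b, params, cfg)

  set.seed(10)
  perm <- sample(nrow(b$associations))
  bp <- b
  bp$associations <- b$associations[perm, ]
  for (k in names(bp$modalities)) {
    bp$modalities[[k]]$values <- bp$modalities[[k]]$values[perm, , drop = FALSE]
    bp$modalities[[k]]$drug_ids <- rownames(bp$modalities[[k]]$values)
  }
  tgp <- multidda:::build_training_graph(bp, cfg)
  # permute parameter rows of the level-1 weight acting on node coordinates
  pp <- params
  n <- tg$graph$n_drugs + tg$graph$n_diseases
  nodeperm <- c(perm, (nrow(b$associations) + 1):n)
  pp$levels[[1]]$W <- params$levels[[1]]$W[nodeperm, , drop = FALSE]
  sp <- forward(tgp$graph, bp, pp, cfg)
  expect_equal(unname(sp), unname(s[perm, ]), tolerance = 1e-9)
})

test_that("analytic gradients agree with central finite differences", {
  b <- quiet_bundle(seed = 11, n_drugs = 6, n_diseases = 6, density = 0.25)
  cfg <- tiny_config()
  tg <- multidda:::build_training_graph(b, cfg)
  X <- multidda:::branch_inputs(b, cfg)
  dims <- sapply(b$modalities[cfg$modalities], function(m) ncol(m$values))
  params <- init_params(12, dims, cfg)
  # evaluate at a generic point: jitter away from ReLU kinks at exactly 0
  set.seed(12)
  theta <- flatten_params(params) + rnorm(length(flatten_params(params)), 0, 0.05)
  params <- unflatten_params(theta, params)
  labels <- unname(b$associations)
  incl <- matrix(1, 6, 6)
  incl[1, 2] <- 0
  lg <- multidda:::loss_and_grad(tg$graph, X, params, cfg, labels, incl, 4)
  ga <- flatten_params(lg$grads)
  f <- function(th) {
    s <- multidda:::forward_pass(tg$graph, X, unflatten_params(th, params), cfg)$scores
    -sum(incl * (4 * labels * log(s) + (1 - labels) * log(1 - s))) / sum(incl)
  }
  eps <- 1e-6
  idx <- sort(sample(length(theta), 250))
  gn <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, numeric(1))
  rel <- abs(gn - ga[idx]) / pmax(1e-6, abs(gn) + abs(ga[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("parameter flattening round-trips and checkpoints restore", {
  cfg <- tiny_config()
  params <- init_params(10, c(target = 5, enzyme = 4, pathway = 3, substructure = 6), cfg)
  th <- flatten_params(params)
  p2 <- unflatten_params(th, params)
  expect_equal(p2, params)
  expect_identical(flatten_params(p2), th)

  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(params, cfg, path)
  ck <- load_checkpoint(path)
  expect_equal(ck$params, params, ignore_attr = TRUE)
  expect_identical(ck$config$embed_dim, cfg$embed_dim)
})
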