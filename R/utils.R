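# internal numeric helpers shared across the model code

relu <- function(x) {
  x[x < 0] <- 0
  x
}

leaky_relu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

leaky_relu_grad <- function(x, slope) {
  g <- array(1, dim(x) %||% length(x))
  g[x < 0] <- slope
  g
}

elu <- function(x) {
  neg <- x <= 0
  x[neg] <- exp(x[neg]) - 1
  x
}

elu_grad <- function(x) {
  g <- array(1, dim(x) %||% length(x))
  neg <- x <= 0
  g[neg] <- exp(x[neg])
  g
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# row-wise softmax of a matrix with -Inf entries allowed (masked out)
softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e[is.na(e)] <- 0 # exp(-Inf - -Inf) guards
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

msgf <- function(fmt, ...) message(sprintf(fmt, ...))

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary_matrix <- function(x) {
  all(x %in% c(0, 1))
}

# index pairs as a 2-column integer matrix, validated against matrix dims
as_pair_matrix <- function(pairs, n_row, n_col, row_ids = NULL, col_ids = NULL) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  if (is.character(pairs)) pairs <- matrix(pairs, ncol = 2)
  if (!is.matrix(pairs) || ncol(pairs) != 2) {
    stopf("pairs must be a 2-column matrix or data frame")
  }
  if (nrow(pairs) == 0) {
    return(matrix(integer(0), 0, 2))
  }
  if (is.character(pairs[1, 1])) {
    i <- match(pairs[, 1], row_ids)
    j <- match(pairs[, 2], col_ids)
    if (anyNA(i) || anyNA(j)) stopf("pair identifiers not found in matrix dimnames")
    pairs <- cbind(i, j)
  }
  storage.mode(pairs) <- "integer"
  if (any(pairs[, 1] < 1L | pairs[, 1] > n_row) ||
      any(pairs[, 2] < 1L | pairs[, 2] > n_col)) {
    stopf("pair indices out of range")
  }
  dimnames(pairs) <- NULL
  pairs
}

xavier_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}
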