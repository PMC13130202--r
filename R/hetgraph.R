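#' Assemble the heterogeneous drug-disease graph
#'
#' Builds the block adjacency over the \eqn{|C| + |D|} drug and disease nodes
#' \deqn{A = \begin{bmatrix} S^c & A_{known} \\ A_{known}^T & S^d \end{bmatrix}}
#' together with its symmetric renormalized form \eqn{\hat A} (see
#' [normalize_adjacency()]) and the initial node features
#' \deqn{H^0 = \begin{bmatrix} 0 & A_{known} \\ A_{known}^T & 0 \end{bmatrix},}
#' i.e. each node starts from its known-association profile only, so the first
#' graph-convolution level learns purely structural knowledge. Drug nodes come
#' first (rows 1..|C|), disease nodes after.
#'
#' @param Sc drug-drug similarity matrix (|C| x |C|).
#' @param Sd disease-disease similarity matrix (|D| x |D|).
#' @param Aknown binary association matrix (|C| x |D|).
#' @return an object of class `multidda_graph`: list with `A`, `Ahat`, `H0`,
#'   `n_drugs`, `n_diseases`, `drug_ids`, `disease_ids`.
#' @export
assemble_adjacency <- function(Sc, Sd, Aknown) {
  nC <- nrow(Aknown)
  nD <- ncol(Aknown)
  if (nrow(Sc) != nC || ncol(Sc) != nC) {
    stopf("drug similarity is %dx%d but association matrix has %d drugs",
          nrow(Sc), ncol(Sc), nC)
  }
  if (nrow(Sd) != nD || ncol(Sd) != nD) {
    stopf("disease similarity is %dx%d but association matrix has %d diseases",
          nrow(Sd), ncol(Sd), nD)
  }
  A <- rbind(cbind(Sc, Aknown), cbind(t(Aknown), Sd))
  H0 <- rbind(cbind(matrix(0, nC, nC), Aknown),
              cbind(t(Aknown), matrix(0, nD, nD)))
  dimnames(A) <- dimnames(H0) <- NULL
  structure(list(A = A, Ahat = normalize_adjacency(A), H0 = H0,
                 n_drugs = nC, n_diseases = nD,
                 drug_ids = rownames(Aknown) %||% as.character(seq_len(nC)),
                 disease_ids = colnames(Aknown) %||% as.character(seq_len(nD))),
            class = "multidda_graph")
}

#' @export
print.multidda_graph <- function(x, ...) {
  cat(sprintf("<heterogeneous graph: %d drug + %d disease nodes, %d known association(s)>\n",
              x$n_drugs, x$n_diseases,
              sum(x$A[seq_len(x$n_drugs), x$n_drugs + seq_len(x$n_diseases)] != 0)))
  invisible(x)
}

#' Symmetric renormalized adjacency with self-loops
#'
#' \eqn{\hat A = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}} with \eqn{\tilde D}
#' the diagonal of row sums of \eqn{A + I}: the standard graph-convolution
#' renormalization, keeping the propagation operator symmetric with spectral
#' radius at most 1.
#'
#' @param A square symmetric non-negative matrix.
#' @return the normalized matrix, same shape.
#' @export
normalize_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stopf("adjacency must be square")
  if (any(A < 0)) stopf("adjacency has negative entries")
  if (max(abs(A - t(A))) > 1e-9) stopf("adjacency must be symmetric")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' Zero out held-out test associations
#'
#' Returns a copy of the association matrix with the given known-positive
#' pairs set to 0, for leakage-safe training: both the adjacency block and the
#' initial features encode the association matrix, so a fold's test positives
#' must vanish from every training-time structure.
#'
#' @param Aknown binary association matrix.
#' @param test_pairs 2-column matrix / data frame of (drug, disease) pairs,
#'   as integer indices or character IDs; each must be a known positive.
#' @return the masked association matrix (the input is left untouched).
#' @export
mask_test_fold <- function(Aknown, test_pairs) {
  idx <- as_pair_matrix(test_pairs, nrow(Aknown), ncol(Aknown),
                        rownames(Aknown), colnames(Aknown))
  if (nrow(idx)) {
    vals <- Aknown[idx]
    if (any(vals != 1)) {
      bad <- which(vals != 1)[1]
      stopf("pair (%d, %d) is not a known positive and cannot be masked",
            idx[bad, 1], idx[bad, 2])
    }
  }
  out <- Aknown
  out[idx] <- 0
  out
}

#' Write / read a heterogeneous graph archive
#'
#' Single-file container (RDS) of the adjacency, its normalized form, the
#' initial features and both ID maps, plus a manifest recording the package
#' version and creation time. Written and read only by this pair of
#' functions.
#'
#' @param graph a `multidda_graph`.
#' @param path archive path.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "multidda_graph"))
  payload <- unclass(graph)
  payload$manifest <- list(format = "multidda_graph/1",
                           package = as.character(utils::packageVersion("multidda")),
                           created = format(Sys.time(), tz = "UTC"))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$manifest$format, "multidda_graph/1")) {
    stopf("%s is not a multidda graph archive", path)
  }
  payload$manifest <- NULL
  structure(payload, class = "multidda_graph")
}
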