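#' Jaccard index of two binary vectors
#'
#' \eqn{|u \cap v| / |u \cup v|}, the overlap of the feature sets encoded by
#' the two presence/absence vectors. When both vectors are all-zero the union
#' is empty and the index is defined as 0 ("no evidence of similarity").
#'
#' @param u,v binary vectors of equal length.
#' @return a number in \[0, 1\].
#' @examples
#' jaccard(c(1, 1, 0, 1), c(1, 0, 1, 1)) # 2 shared / 4 in union = 0.5
#' @export
jaccard <- function(u, v) {
  if (length(u) != length(v)) stopf("jaccard: vectors differ in length (%d vs %d)", length(u), length(v))
  if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1))) stopf("jaccard: vectors must be binary")
  un <- sum(u == 1 | v == 1)
  if (un == 0) return(0)
  sum(u == 1 & v == 1) / un
}

#' Drug-drug similarity over concatenated feature modalities
#'
#' For every pair of drugs the selected binary modality vectors (targets,
#' enzymes, pathways, substructures, drug-drug interaction profiles) are
#' concatenated and compared with the Jaccard index, yielding the symmetric
#' drug similarity matrix \eqn{S^c} used as the drug-drug block of the
#' heterogeneous graph. A drug with at least one feature has diagonal 1; a
#' fully unannotated drug has an empty feature set and diagonal 0.
#'
#' @param x a `multidda_bundle`, or a named list of `multidda_modality`
#'   objects sharing one drug ordering.
#' @param use_modalities modality labels (or short codes `t,e,p,l,n`) to
#'   concatenate; default: every modality present.
#' @return symmetric numeric matrix in \[0,1\] with drug IDs as dimnames.
#' @export
drug_similarity <- function(x, use_modalities = NULL) {
  mods <- if (inherits(x, "multidda_bundle")) x$modalities else x
  if (!length(mods)) stopf("no modality matrices supplied")
  sel <- if (is.null(use_modalities)) names(mods) else resolve_modalities(use_modalities)
  if (!length(sel)) stopf("empty modality subset")
  missing <- setdiff(sel, names(mods))
  if (length(missing)) stopf("modality not in bundle: %s", paste(missing, collapse = ", "))
  blocks <- lapply(mods[sel], `[[`, "values")
  ids <- rownames(blocks[[1]])
  for (b in blocks) {
    if (!identical(rownames(b), ids)) stopf("modality matrices disagree on drug ordering")
  }
  X <- do.call(cbind, blocks)
  inter <- tcrossprod(X)
  r <- rowSums(X)
  un <- outer(r, r, `+`) - inter
  S <- ifelse(un > 0, inter / un, 0)
  dimnames(S) <- list(ids, ids)
  S
}

# contributions of every ancestor node to one disease's semantic value,
# as a named numeric vector; shared by semantic_contribution / disease_similarity
contribution_vector <- function(dag, node, delta) {
  closure <- dag_ancestors(dag, node)
  ord <- dag$topo[dag$topo %in% closure] # parents before children
  contrib <- stats::setNames(numeric(length(closure)), closure)
  contrib[node] <- 1
  # walk ancestors children-first so each child value is final when used
  for (n in rev(ord)) {
    if (n == node) next
    kids <- intersect(dag$children[[n]] %||% character(0), closure)
    contrib[n] <- delta * max(contrib[kids])
  }
  contrib
}

#' Semantic contribution of ancestor nodes to a disease
#'
#' The disease's own DAG node contributes 1; every other ancestor node `n`
#' contributes \eqn{\Delta \cdot \max_{n'} C_d(n')} over the children `n'` of
#' `n` lying on a path toward the disease. The discount \eqn{\Delta \in (0,1)}
#' makes contributions decay with distance from the disease, so broad shared
#' ancestors count less than close ones.
#'
#' @param dag a `multidda_dag` with a disease mapping.
#' @param disease a mapped disease ID (or, if unmapped, a raw node ID).
#' @param delta discount factor in (0, 1); default 0.5.
#' @return an object of class `multidda_contribution`: list with `disease`,
#'   `node`, and named `contributions` over the ancestor closure.
#' @export
semantic_contribution <- function(dag, disease, delta = 0.5) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta >= 1) {
    stopf("delta must lie strictly inside (0, 1)")
  }
  node <- if (!is.null(dag$disease2node) && disease %in% names(dag$disease2node)) {
    unname(dag$disease2node[disease])
  } else if (disease %in% dag$nodes) {
    disease
  } else {
    stopf("disease '%s' is not mapped in the DAG", disease)
  }
  structure(list(disease = disease, node = node,
                 contributions = contribution_vector(dag, node, delta)),
            class = "multidda_contribution")
}

#' @export
print.multidda_contribution <- function(x, ...) {
  cat(sprintf("<semantic contributions of %d ancestor node(s) to %s>\n",
              length(x$contributions), x$disease))
  print(sort(x$contributions, decreasing = TRUE))
  invisible(x)
}

#' Disease-disease semantic similarity over the MeSH-style DAG
#'
#' For diseases \eqn{d_i, d_j} with ancestor closures \eqn{N(d_i), N(d_j)}:
#' \deqn{S^d_{ij} = \frac{\sum_{n \in N(d_i) \cap N(d_j)} (C_{d_i}(n) + C_{d_j}(n))}
#'                       {DV(d_i) + DV(d_j)},}
#' where \eqn{C_d} are the discounted ancestor contributions (see
#' [semantic_contribution()]) and \eqn{DV(d) = \sum_{n \in N(d)} C_d(n)} is
#' the disease's semantic value. The diagonal is exactly 1; diseases sharing
#' no ancestor get similarity 0.
#'
#' @param dag a `multidda_dag` with a disease mapping.
#' @param diseases disease IDs to include, in order; default every mapped
#'   disease.
#' @param delta discount factor in (0, 1); default 0.5.
#' @return symmetric numeric matrix in \[0,1\] with unit diagonal.
#' @export
disease_similarity <- function(dag, diseases = NULL, delta = 0.5) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta >= 1) {
    stopf("delta must lie strictly inside (0, 1)")
  }
  if (is.null(dag$disease2node)) stopf("DAG carries no disease mapping")
  diseases <- diseases %||% names(dag$disease2node)
  unmapped <- setdiff(diseases, names(dag$disease2node))
  if (length(unmapped)) stopf("unmapped disease(s): %s", paste(utils::head(unmapped, 5), collapse = ", "))
  contribs <- lapply(diseases, function(d) {
    contribution_vector(dag, unname(dag$disease2node[d]), delta)
  })
  dv <- vapply(contribs, sum, numeric(1))
  nd <- length(diseases)
  S <- diag(1, nd)
  disjoint <- 0L
  if (nd > 1) {
    for (i in seq_len(nd - 1)) {
      ci <- contribs[[i]]
      for (j in seq(i + 1, nd)) {
        cj <- contribs[[j]]
        shared <- intersect(names(ci), names(cj))
        if (!length(shared)) {
          disjoint <- disjoint + 1L
          next
        }
        S[i, j] <- S[j, i] <- sum(ci[shared] + cj[shared]) / (dv[i] + dv[j])
      }
    }
  }
  if (disjoint) msgf("disease similarity: %d pair(s) share no ancestor (similarity 0)", disjoint)
  dimnames(S) <- list(diseases, diseases)
  S
}
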