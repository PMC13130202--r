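MODALITIES <- c("target", "enzyme", "pathway", "substructure", "ddi")

# short codes used on the command line and in formulas: t, e, p, l, n
MODALITY_CODES <- c(t = "target", e = "enzyme", p = "pathway",
                    l = "substructure", n = "ddi")

resolve_modalities <- function(x) {
  if (is.null(x)) return(MODALITIES)
  x <- as.character(x)
  full <- ifelse(x %in% names(MODALITY_CODES), MODALITY_CODES[x], x)
  bad <- setdiff(full, MODALITIES)
  if (length(bad)) {
    stopf("unknown modality label(s): %s (use %s or codes %s)",
          paste(bad, collapse = ", "), paste(MODALITIES, collapse = ", "),
          paste(names(MODALITY_CODES), collapse = ", "))
  }
  unname(full)
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[!grepl("^#", lines) & nzchar(lines)]
}

read_tsv_directives <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  dir_lines <- lines[grepl("^#%", lines)]
  out <- list()
  for (ln in dir_lines) {
    parts <- strsplit(sub("^#%\\s*", "", ln), "\t", fixed = TRUE)[[1]]
    if (length(parts) == 2) out[[parts[1]]] <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
  }
  out
}

#' Read a binary drug feature (modality) matrix from TSV
#'
#' The file carries one feature modality for a set of drugs: a header row of
#' feature identifiers, then one row per drug whose first field is the drug
#' identifier and whose remaining fields are 0/1 presence flags. Lines starting
#' with `#` are ignored. This is the on-disk form of the per-modality binary
#' descriptors (targets, enzymes, pathways, chemical substructures, or
#' drug-drug interaction profiles) that feed both the Jaccard drug similarity
#' and the model's per-modality projection branches.
#'
#' @param path path to a tab-separated file.
#' @param modality one of `"target"`, `"enzyme"`, `"pathway"`,
#'   `"substructure"`, `"ddi"` (or the short codes `t`, `e`, `p`, `l`, `n`).
#' @return an object of class `multidda_modality`: a list with elements
#'   `modality`, `drug_ids`, `feature_ids` and the binary `values` matrix
#'   (drugs in rows, features in columns, file order preserved).
#' @seealso [write_modality_matrix()], [drug_similarity()]
#' @export
read_modality_matrix <- function(path, modality) {
  modality <- resolve_modalities(modality)
  if (length(modality) != 1) stopf("exactly one modality label expected")
  lines <- read_tsv_lines(path)
  if (length(lines) < 2) stopf("modality file %s has no data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # header may or may not carry a corner label for the ID column
  body_width <- length(fields[[2]])
  feature_ids <- if (length(header) == body_width) header[-1] else header
  n_feat <- length(feature_ids)
  if (anyDuplicated(feature_ids)) {
    stopf("duplicate feature ID in %s: %s", path,
          feature_ids[duplicated(feature_ids)][1])
  }
  body <- fields[-1]
  drug_ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(drug_ids)) {
    stopf("duplicate drug ID in %s: %s", path, drug_ids[duplicated(drug_ids)][1])
  }
  values <- matrix(0, length(body), n_feat,
                   dimnames = list(drug_ids, feature_ids))
  for (r in seq_along(body)) {
    row <- body[[r]]
    if (length(row) != n_feat + 1) {
      stopf("row %s of %s has %d fields, expected %d",
            drug_ids[r], path, length(row), n_feat + 1)
    }
    vals <- suppressWarnings(as.numeric(row[-1]))
    bad <- which(is.na(vals) | !(vals %in% c(0, 1)))
    if (length(bad)) {
      stopf("non-binary value '%s' at row %s, column %s of %s",
            row[bad[1] + 1], drug_ids[r], feature_ids[bad[1]], path)
    }
    values[r, ] <- vals
  }
  modality_matrix(modality, values)
}

#' Construct a modality matrix object from a binary matrix
#'
#' @param modality modality label (see [read_modality_matrix()]).
#' @param values binary matrix with drug IDs as rownames and feature IDs as
#'   colnames.
#' @return a `multidda_modality` object.
#' @export
modality_matrix <- function(modality, values) {
  modality <- resolve_modalities(modality)
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("values must be a matrix with drug rownames and feature colnames")
  }
  if (!is_binary_matrix(values)) stopf("modality matrix entries must be 0/1")
  if (anyDuplicated(rownames(values))) stopf("duplicate drug IDs")
  if (anyDuplicated(colnames(values))) stopf("duplicate feature IDs")
  storage.mode(values) <- "double"
  structure(list(modality = modality,
                 drug_ids = rownames(values),
                 feature_ids = colnames(values),
                 values = values),
            class = "multidda_modality")
}

#' @export
print.multidda_modality <- function(x, ...) {
  zero <- sum(rowSums(x$values) == 0)
  cat(sprintf("<%s modality: %d drugs x %d features, density %.3f%s>\n",
              x$modality, nrow(x$values), ncol(x$values), mean(x$values),
              if (zero) sprintf(", %d all-zero drug row(s)", zero) else ""))
  invisible(x)
}

#' Write a modality matrix to TSV
#'
#' Inverse of [read_modality_matrix()]; the emitted file reads back to an
#' identical object.
#'
#' @param x a `multidda_modality` object.
#' @param path output file path.
#' @export
write_modality_matrix <- function(x, path) {
  stopifnot(inherits(x, "multidda_modality"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("drug_id", x$feature_ids), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(v) paste(format(v, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(x$drug_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Read known drug-disease associations from an edge list
#'
#' Each non-comment line is `drug_id TAB disease_id` with an optional third
#' 0/1 weight column (default 1). Pairs absent from the file are taken as 0
#' (no known association). Directive lines `#% drugs` / `#% diseases` may
#' declare the full identifier universe (comma-separated), so that drugs or
#' diseases without any listed association keep their row/column; the writer
#' emits them, making the round trip lossless.
#'
#' @param path path to the edge-list TSV.
#' @return a binary association matrix (drugs in rows, diseases in columns,
#'   dimnames carry the identifiers).
#' @seealso [write_association_table()]
#' @export
read_association_table <- function(path) {
  lines <- read_tsv_lines(path)
  dirs <- read_tsv_directives(path)
  if (!length(lines)) stopf("association file %s lists no edges", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths < 2 | widths > 3)) {
    stopf("association file %s: line %d has %d fields (want 2 or 3)",
          path, which(widths < 2 | widths > 3)[1], widths[widths < 2 | widths > 3][1])
  }
  drugs_seen <- vapply(fields, `[`, character(1), 1L)
  diseases_seen <- vapply(fields, `[`, character(1), 2L)
  w <- vapply(fields, function(f) if (length(f) == 3) f[3] else "1", character(1))
  wv <- suppressWarnings(as.numeric(w))
  if (anyNA(wv) || !all(wv %in% c(0, 1))) {
    stopf("association file %s: non-binary weight '%s'", path, w[which(is.na(wv) | !(wv %in% c(0, 1)))[1]])
  }
  drug_ids <- dirs[["drugs"]] %||% unique(drugs_seen)
  disease_ids <- dirs[["diseases"]] %||% unique(diseases_seen)
  if (!all(drugs_seen %in% drug_ids)) stopf("edge drug ID not in declared drug universe")
  if (!all(diseases_seen %in% disease_ids)) stopf("edge disease ID not in declared disease universe")
  A <- matrix(0, length(drug_ids), length(disease_ids),
              dimnames = list(drug_ids, disease_ids))
  keep <- wv == 1
  key <- paste(drugs_seen, diseases_seen, sep = "\r")
  if (anyDuplicated(key[keep])) {
    warnf("duplicate association pair(s) in %s; keeping a single 1", path)
  }
  A[cbind(match(drugs_seen[keep], drug_ids), match(diseases_seen[keep], disease_ids))] <- 1
  if (sum(A) == 0) stopf("association file %s declares IDs but zero positive edges", path)
  A
}

#' Write an association matrix as an edge list
#'
#' @param A binary association matrix with drug rownames and disease colnames.
#' @param path output file path.
#' @export
write_association_table <- function(A, path) {
  if (!is.matrix(A) || is.null(rownames(A)) || is.null(colnames(A))) {
    stopf("A must be a matrix with drug rownames and disease colnames")
  }
  if (!is_binary_matrix(A)) stopf("association matrix entries must be 0/1")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("#% drugs\t", paste(rownames(A), collapse = ",")),
               paste0("#% diseases\t", paste(colnames(A), collapse = ","))), con)
  idx <- which(A == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(paste(rownames(A)[idx[, 1]], colnames(A)[idx[, 2]], sep = "\t"), con)
  invisible(path)
}

#' Construct a disease DAG object
#'
#' Represents a MeSH-style hierarchy: nodes are disease descriptors, each
#' directed edge points from a broader parent term to a more specific child.
#' Acyclicity is verified; a cycle aborts with one offending cycle printed.
#'
#' @param edges two-column data frame or matrix of `parent`, `child` node IDs.
#' @param mapping named character vector mapping disease IDs to node IDs, or
#'   `NULL` for an unmapped skeleton.
#' @param nodes optional node IDs beyond those appearing in edges or mapping
#'   (e.g. a single-node DAG with no edges).
#' @return an object of class `multidda_dag` with the node list, edge table,
#'   parent/child adjacency, roots, a topological order, and the
#'   disease-to-node map.
#' @export
mesh_dag <- function(edges, mapping = NULL, nodes = NULL) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stopf("edges must have parent and child columns")
  names(edges)[1:2] <- c("parent", "child")
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  nodes <- unique(c(edges$parent, edges$child, unname(mapping), nodes))
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) {
    stopf("disease hierarchy contains a cycle: %s", find_one_cycle(edges))
  }
  topo <- names(igraph::topo_sort(g, mode = "out"))
  parents <- split(edges$parent, edges$child)
  children <- split(edges$child, edges$parent)
  roots <- setdiff(nodes, edges$child)
  if (!is.null(mapping)) {
    mapping <- stats::setNames(as.character(mapping), names(mapping))
    if (anyDuplicated(names(mapping))) {
      stopf("disease '%s' maps to more than one DAG node",
            names(mapping)[duplicated(names(mapping))][1])
    }
    missing <- setdiff(unname(mapping), nodes)
    if (length(missing)) stopf("mapped node(s) absent from DAG: %s",
                               paste(missing, collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges[, 1:2], parents = parents,
                 children = children, roots = roots, topo = topo,
                 disease2node = mapping),
            class = "multidda_dag")
}

#' @export
print.multidda_dag <- function(x, ...) {
  cat(sprintf("<disease DAG: %d nodes, %d edges, %d root(s), %d mapped disease(s)>\n",
              length(x$nodes), nrow(x$edges), length(x$roots),
              length(x$disease2node)))
  invisible(x)
}

#' Read a MeSH-style disease DAG and its disease mapping
#'
#' @param edge_path TSV of `parent TAB child` node-ID lines.
#' @param mapping_path TSV of `disease_id TAB node_id` lines.
#' @return a `multidda_dag` object (see [mesh_dag()]).
#' @export
read_mesh_dag <- function(edge_path, mapping_path) {
  el <- read_tsv_lines(edge_path)
  if (!length(el)) stopf("DAG edge file %s is empty", edge_path)
  ef <- strsplit(el, "\t", fixed = TRUE)
  if (any(lengths(ef) != 2)) stopf("DAG edge file %s: lines must be parent TAB child", edge_path)
  edges <- data.frame(parent = vapply(ef, `[`, character(1), 1L),
                      child = vapply(ef, `[`, character(1), 2L),
                      stringsAsFactors = FALSE)
  ml <- read_tsv_lines(mapping_path)
  mf <- strsplit(ml, "\t", fixed = TRUE)
  if (any(lengths(mf) != 2)) stopf("mapping file %s: lines must be disease TAB node", mapping_path)
  mapping <- stats::setNames(vapply(mf, `[`, character(1), 2L),
                             vapply(mf, `[`, character(1), 1L))
  mesh_dag(edges, mapping)
}

#' Write a disease DAG and mapping to TSV files
#'
#' @param dag a `multidda_dag` object.
#' @param edge_path,mapping_path output file paths.
#' @export
write_mesh_dag <- function(dag, edge_path, mapping_path) {
  stopifnot(inherits(dag, "multidda_dag"))
  con <- file(edge_path, "w", encoding = "UTF-8")
  writeLines(paste(dag$edges$parent, dag$edges$child, sep = "\t"), con)
  close(con)
  con <- file(mapping_path, "w", encoding = "UTF-8")
  writeLines(paste(names(dag$disease2node), dag$disease2node, sep = "\t"), con)
  close(con)
  invisible(edge_path)
}

# depth-first search for one directed cycle, for error reporting only
find_one_cycle <- function(edges) {
  adj <- split(edges$child, edges$parent)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- mget(v, state, ifnotfound = "new")[[1]]
    if (st == "open") {
      i <- match(v, path)
      found <<- paste(c(path[i:length(path)], v), collapse = " -> ")
      return()
    }
    if (st == "done") return()
    assign(v, "open", state)
    path <<- c(path, v)
    for (w in adj[[v]] %||% character(0)) visit(w)
    path <<- path[-length(path)]
    assign(v, "done", state)
  }
  for (v in unique(edges$parent)) visit(v)
  found %||% "(cycle not localized)"
}

#' Ancestor closure of a DAG node
#'
#' Returns the node itself plus every node reachable by repeatedly following
#' parent edges -- the set over which semantic contributions are defined.
#'
#' @param dag a `multidda_dag`.
#' @param node a node ID.
#' @return character vector of node IDs (closed under the parent relation).
#' @export
dag_ancestors <- function(dag, node) {
  if (!node %in% dag$nodes) stopf("node '%s' not in DAG", node)
  seen <- character(0)
  frontier <- node
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)), seen)
  }
  seen
}

#' Assemble and cross-validate a dataset bundle
#'
#' Reconciles the drug orderings of all modality matrices with the association
#' matrix (restricting to the shared drugs with a warning when they differ),
#' checks that every disease resolves to a DAG node, and logs the dataset
#' summary: number of drugs, diseases, known associations and per-modality
#' dimensions.
#'
#' @param modalities named list of `multidda_modality` objects.
#' @param associations binary association matrix (drugs x diseases).
#' @param dag a `multidda_dag` whose mapping covers all diseases.
#' @return an object of class `multidda_bundle` with elements `modalities`,
#'   `associations`, `dag`.
#' @export
validate_bundle <- function(modalities, associations, dag) {
  if (!length(modalities)) stopf("at least one modality matrix is required")
  stopifnot(inherits(dag, "multidda_dag"))
  names(modalities) <- vapply(modalities, `[[`, character(1), "modality")
  drug_sets <- lapply(modalities, `[[`, "drug_ids")
  shared <- Reduce(intersect, c(list(rownames(associations)), drug_sets))
  if (!length(shared)) stopf("no drug ID shared by all modality matrices and the association table")
  orders_differ <- any(vapply(drug_sets, function(d) !identical(d, rownames(associations)), logical(1)))
  if (orders_differ) {
    shared <- sort(shared)
    warnf("drug ID orderings differ across files; restricting to the %d shared drugs (sorted)",
          length(shared))
  }
  modalities <- lapply(modalities, function(m) {
    m$values <- m$values[shared, , drop = FALSE]
    m$drug_ids <- shared
    m
  })
  associations <- associations[shared, , drop = FALSE]
  unmapped <- setdiff(colnames(associations), names(dag$disease2node))
  if (length(unmapped)) {
    stopf("disease(s) without a DAG mapping: %s",
          paste(utils::head(unmapped, 5), collapse = ", "))
  }
  for (m in modalities) {
    nz <- sum(rowSums(m$values) == 0)
    if (nz) msgf("modality %s: %d drug(s) with no annotated feature", m$modality, nz)
  }
  dims <- vapply(modalities, function(m) ncol(m$values), integer(1))
  msgf("bundle: %d drugs, %d diseases, %d known associations; modality dims: %s",
       nrow(associations), ncol(associations), sum(associations),
       paste(sprintf("%s=%d", names(dims), dims), collapse = ", "))
  structure(list(modalities = modalities, associations = associations, dag = dag),
            class = "multidda_bundle")
}

#' @export
print.multidda_bundle <- function(x, ...) {
  dims <- vapply(x$modalities, function(m) ncol(m$values), integer(1))
  cat(sprintf("<multidda bundle: %d drugs, %d diseases, %d associations (density %.4f)>\n",
              nrow(x$associations), ncol(x$associations), sum(x$associations),
              mean(x$associations)))
  cat("  modalities:", paste(sprintf("%s(%d)", names(dims), dims), collapse = " "), "\n")
  invisible(x)
}

#' Write a complete dataset bundle to a directory
#'
#' Emits one TSV per modality plus `associations.tsv`, `dag_edges.tsv` and
#' `dag_mapping.tsv`, all in the formats the corresponding readers accept.
#'
#' @param bundle a `multidda_bundle`.
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "multidda_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in bundle$modalities) {
    write_modality_matrix(m, file.path(dir, paste0(m$modality, ".tsv")))
  }
  write_association_table(bundle$associations, file.path(dir, "associations.tsv"))
  write_mesh_dag(bundle$dag, file.path(dir, "dag_edges.tsv"),
                 file.path(dir, "dag_mapping.tsv"))
  invisible(dir)
}

#' Read a dataset bundle from a directory written by [write_bundle()]
#'
#' @param dir directory containing the bundle files.
#' @return a validated `multidda_bundle`.
#' @export
read_bundle <- function(dir) {
  mods <- list()
  for (m in MODALITIES) {
    p <- file.path(dir, paste0(m, ".tsv"))
    if (file.exists(p)) mods[[m]] <- read_modality_matrix(p, m)
  }
  if (!length(mods)) stopf("no modality file found in %s", dir)
  A <- read_association_table(file.path(dir, "associations.tsv"))
  dag <- read_mesh_dag(file.path(dir, "dag_edges.tsv"),
                       file.path(dir, "dag_mapping.tsv"))
  validate_bundle(mods, A, dag)
}

#' Read / write a square similarity matrix as TSV
#'
#' Plain header + index TSV of reals in \[0,1\]; used by the CLI `similarity`
#' subcommand and accepted anywhere a similarity matrix is an input.
#'
#' @param path file path.
#' @return for the reader, a numeric matrix with matching row and column IDs.
#' @export
read_similarity_matrix <- function(path) {
  lines <- read_tsv_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ids <- if (length(header) == length(fields[[2]])) header[-1] else header
  body <- fields[-1]
  vals <- t(vapply(body, function(f) as.numeric(f[-1]), numeric(length(ids))))
  rownames(vals) <- vapply(body, `[`, character(1), 1L)
  colnames(vals) <- ids
  if (!identical(rownames(vals), colnames(vals))) stopf("similarity matrix is not square over one ID set")
  vals
}

#' @rdname read_similarity_matrix
#' @param S square numeric matrix with identical row/column names.
#' @export
write_similarity_matrix <- function(S, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(S)), collapse = "\t"), con)
  body <- apply(S, 1L, function(v) paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(S), body, sep = "\t"), con)
  invisible(path)
}
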