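#' Read a small-molecule table
#'
#' Reads a tab-delimited table of small molecules with at least the columns
#' `sm_id` and `smiles`. Row order is preserved.
#'
#' @param path Path to a UTF-8, tab-delimited file with a header row.
#' @return A data.frame with character columns `sm_id` and `smiles`.
#' @export
read_sm_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, quote = "")
  for (col in c("sm_id", "smiles")) {
    if (!col %in% names(tab)) stopf("sm table %s is missing required column '%s'", path, col)
  }
  tab <- tab[, c("sm_id", "smiles"), drop = FALSE]
  dup <- unique(tab$sm_id[duplicated(tab$sm_id)])
  if (length(dup)) stopf("duplicate sm_id values: %s", paste(dup, collapse = ", "))
  blank <- which(!nzchar(trimws(tab$smiles)))
  if (length(blank)) stopf("blank smiles at row(s): %s", paste(blank, collapse = ", "))
  rownames(tab) <- NULL
  tab
}

#' Read miRNA sequences from FASTA
#'
#' The miRNA id is the first whitespace-delimited token of each header.
#' Sequences are uppercased and DNA spellings are unified to RNA (`T` is
#' mapped to `U`); any character outside `A`, `C`, `G`, `U` is an error.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with character columns `mirna_id` and `sequence`.
#' @export
read_mirna_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopf("duplicate miRNA ids in FASTA: %s", paste(dup, collapse = ", "))
  seqs <- chartr("tT", "uU", as.character(set))
  seqs <- toupper(seqs)
  seqs <- chartr("T", "U", seqs)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGU]", seqs[[i]])
    if (bad > 0L) {
      stopf("invalid character '%s' in sequence '%s' at position %d",
            substr(seqs[[i]], bad, bad), ids[[i]], bad)
    }
  }
  data.frame(mirna_id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Read a regulation edge list
#'
#' Reads tab-delimited `(sm_id, mirna_id, relation)` triples. Relation
#' tokens are lower-cased and must normalize to `"up"` or `"down"`.
#' Duplicate triples are collapsed with a warning.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return A `regulation_edge_set`: a data.frame with columns `sm_id`,
#'   `mirna_id`, `relation` and `label` (all positives, label 1).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, quote = "")
  for (col in c("sm_id", "mirna_id", "relation")) {
    if (!col %in% names(tab)) stopf("edge list %s is missing required column '%s'", path, col)
  }
  edge_set(tab$sm_id, tab$mirna_id, tab$relation)
}

#' Construct a regulation edge set
#'
#' @param sm_id,mirna_id,relation Character vectors of equal length;
#'   `relation` entries must normalize (case-insensitively) to `"up"` or
#'   `"down"`.
#' @param label Label attached to every edge (1 for known positives).
#' @return A `regulation_edge_set` data.frame.
#' @export
edge_set <- function(sm_id, mirna_id, relation, label = 1L) {
  relation <- tolower(trimws(relation))
  bad <- setdiff(unique(relation), c("up", "down"))
  if (length(bad)) stopf("unknown relation token(s): %s", paste(bad, collapse = ", "))
  out <- data.frame(sm_id = as.character(sm_id), mirna_id = as.character(mirna_id),
                    relation = relation, stringsAsFactors = FALSE)
  dup <- duplicated(out)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate edge(s)", sum(dup)), call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  out$label <- rep_len(as.integer(label), nrow(out))
  rownames(out) <- NULL
  class(out) <- c("regulation_edge_set", "data.frame")
  out
}

#' Build the attributed multiplex heterogeneous network
#'
#' Vertices are the small molecules and miRNAs appearing in `edges`; each
#' distinct relation becomes one undirected bipartite edge layer, and every
#' vertex carries the attribute vector supplied in `attributes`. Attribute
#' dimensionality must be uniform within each node type. Construction is
#' deterministic and invariant to the input row order.
#'
#' @param edges A `regulation_edge_set`.
#' @param attributes Named list mapping raw vertex ids (both small molecules
#'   and miRNAs) to numeric attribute vectors.
#' @param sm_ids,mirna_ids Optional additional vertex ids to include even
#'   when they carry no edge (they stay isolated in every layer); used to
#'   keep held-out vertices embeddable in inductive mode.
#' @return A `multiplex_graph` object.
#' @export
build_multiplex_graph <- function(edges, attributes, sm_ids = NULL,
                                  mirna_ids = NULL) {
  stopifnot(is.data.frame(edges))
  sm <- sort(unique(c(edges$sm_id, sm_ids)))
  mir <- sort(unique(c(edges$mirna_id, mirna_ids)))
  clash <- intersect(sm, mir)
  if (length(clash)) stopf("id(s) appear on both sides of the bipartition: %s",
                           paste(clash, collapse = ", "))
  need <- c(sm, mir)
  missing <- setdiff(need, names(attributes))
  if (length(missing)) stopf("no attribute vector for vertex/vertices: %s",
                             paste(missing, collapse = ", "))

  vertex <- c(ns_sm(sm), ns_mir(mir))
  type <- c(rep("SM", length(sm)), rep("miRNA", length(mir)))
  attrs <- attributes[need]
  names(attrs) <- vertex
  for (ty in unique(type)) {
    lens <- unique(vapply(attrs[type == ty], length, integer(1)))
    if (length(lens) != 1L) {
      stopf("attribute vectors of type %s have mixed lengths: %s",
            ty, paste(lens, collapse = ", "))
    }
  }

  relations <- sort(unique(edges$relation))
  layers <- lapply(relations, function(r) {
    sub <- edges[edges$relation == r, , drop = FALSE]
    layer <- unique(data.frame(from = ns_sm(sub$sm_id), to = ns_mir(sub$mirna_id),
                               stringsAsFactors = FALSE))
    layer[order(layer$from, layer$to), , drop = FALSE]
  })
  names(layers) <- relations

  adj <- lapply(layers, function(layer) {
    nb <- c(split(layer$to, layer$from), split(layer$from, layer$to))
    lapply(nb, function(v) sort(unique(v)))
  })

  structure(list(
    vertices = data.frame(vertex = vertex, type = type, stringsAsFactors = FALSE),
    layers = layers,
    adjacency = adj,
    attributes = attrs
  ), class = "multiplex_graph")
}

#' Neighbourhood accessor for a multiplex graph layer
#'
#' @param graph A `multiplex_graph`.
#' @param vertex Namespaced vertex id (`"sm:..."` or `"mir:..."`).
#' @param relation Layer name.
#' @return Character vector of namespaced neighbour ids (possibly empty).
#' @export
neighbors_of <- function(graph, vertex, relation) {
  if (!relation %in% names(graph$layers)) stopf("unknown relation layer '%s'", relation)
  if (!vertex %in% graph$vertices$vertex) stopf("unknown vertex '%s'", vertex)
  graph$adjacency[[relation]][[vertex]] %||% character(0)
}

#' @export
print.multiplex_graph <- function(x, ...) {
  cat(sprintf("multiplex_graph: %d vertices (%d SM, %d miRNA), %d layer(s)\n",
              nrow(x$vertices), sum(x$vertices$type == "SM"),
              sum(x$vertices$type == "miRNA"), length(x$layers)))
  for (r in names(x$layers)) cat(sprintf("  layer '%s': %d edges\n", r, nrow(x$layers[[r]])))
  invisible(x)
}

#' Write embeddings in word2vec text format
#'
#' First line is `"N d"`, then one row per vertex: the id followed by `d`
#' values printed with six decimals.
#'
#' @param emb Named list of equal-length numeric vectors, or a numeric
#'   matrix with row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  if (is.matrix(emb)) emb <- setNames(lapply(seq_len(nrow(emb)), function(i) emb[i, ]), rownames(emb))
  lens <- unique(vapply(emb, length, integer(1)))
  if (length(lens) != 1L) stopf("ragged embedding vectors: dims %s", paste(lens, collapse = ", "))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(emb), lens), con)
  for (id in names(emb)) {
    writeLines(paste(id, paste(sprintf("%.6f", emb[[id]]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read embeddings in word2vec text format
#'
#' @param path Path to a file written by [write_embeddings()] (or any
#'   word2vec-style text embedding file).
#' @return A numeric matrix with one row per id.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stopf("empty embedding file: %s", path)
  hdr <- as.integer(strsplit(trimws(lines[[1]]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr)) stopf("malformed word2vec header: '%s'", lines[[1]])
  body <- lines[-1][nzchar(lines[-1])]
  if (length(body) != hdr[[1]]) {
    stopf("header declares %d rows but file has %d", hdr[[1]], length(body))
  }
  parts <- strsplit(body, " ", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1]))
  if (any(vapply(vals, length, integer(1)) != hdr[[2]])) {
    stopf("row width disagrees with header dimension %d", hdr[[2]])
  }
  out <- do.call(rbind, vals)
  rownames(out) <- ids
  out
}
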