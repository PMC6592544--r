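# Similarity-graph reporting over significant hits: graph construction,
# connected components (clusters), public sequences shared across samples,
# and exports.

#' Build the similarity graph over significant hits
#'
#' Vertices are significant hit sequences (one per sample x sigma x VJ);
#' edges connect pairs of same-length amino-acid sequences within Hamming
#' distance 1. By default, edges within a sample additionally require the
#' same VJ class (consistent with the per-VJ statistics), while edges across
#' samples compare the CDR3 only.
#'
#' @param hits a single `enrichment_result` or a named list of them (names =
#'   sample ids); plain data.frames with columns `sigma`, `v_gene`, `j_gene`
#'   (and optionally `significant`) are also accepted.
#' @param vj_match `"within_sample"` (default, as above), `"all_edges"`
#'   (every edge requires matching VJ) or `"none"` (CDR3-only everywhere).
#' @param significant_only keep only rows flagged significant (default TRUE
#'   when the column is present).
#' @return an `igraph` graph with vertex attributes `sigma`, `v_gene`,
#'   `j_gene`, `sample`, `degree_zero`.
#' @export
build_hit_graph <- function(hits, vj_match = c("within_sample", "all_edges", "none"),
                            significant_only = TRUE) {
  vj_match <- match.arg(vj_match)
  if (!is.list(hits) || inherits(hits, "data.frame")) hits <- list(sample = hits)
  if (is.null(names(hits))) names(hits) <- paste0("sample", seq_along(hits))
  vertices <- data.table::rbindlist(lapply(names(hits), function(id) {
    h <- data.table::as.data.table(hits[[id]])
    if (significant_only && "significant" %in% names(h)) h <- h[significant == TRUE]
    if (nrow(h) == 0L) return(NULL)
    unique(data.table::data.table(sigma = h$sigma, v_gene = h$v_gene,
                                  j_gene = h$j_gene, sample = id))
  }), use.names = TRUE)
  if (is.null(vertices) || nrow(vertices) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  vertices[, vid := .I]
  vertices[, name := paste(sample, sigma, v_gene, j_gene, sep = "|")]
  # candidate pairs: same length, Hamming <= 1, via shared one-wildcard masks
  pairs <- list()
  for (L in unique(nchar(vertices$sigma))) {
    sub <- vertices[nchar(sigma) == L]
    masks <- data.table::rbindlist(lapply(seq_len(L), function(i) {
      data.table::data.table(
        mask = paste0(substr(sub$sigma, 1L, i - 1L), ".", substr(sub$sigma, i + 1L, L)),
        vid = sub$vid)
    }))
    # sequences identical in aa also pair through every mask; dedupe below
    m <- merge(masks, masks, by = "mask", allow.cartesian = TRUE)
    m <- m[vid.x < vid.y, .(vid.x, vid.y)]
    if (nrow(m)) pairs[[as.character(L)]] <- unique(m)
  }
  edges <- if (length(pairs)) unique(data.table::rbindlist(pairs)) else
    data.table::data.table(vid.x = integer(), vid.y = integer())
  if (nrow(edges)) {
    a <- vertices[edges$vid.x, .(sample, v_gene, j_gene)]
    b <- vertices[edges$vid.y, .(sample, v_gene, j_gene)]
    same_vj <- a$v_gene == b$v_gene & a$j_gene == b$j_gene
    same_sample <- a$sample == b$sample
    keep <- switch(vj_match,
                   within_sample = !same_sample | same_vj,
                   all_edges = same_vj,
                   none = rep(TRUE, nrow(edges)))
    edges <- edges[keep]
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = vertices$name[edges$vid.x],
                   to = vertices$name[edges$vid.y]),
    directed = FALSE,
    vertices = data.frame(name = vertices$name, sigma = vertices$sigma,
                          v_gene = vertices$v_gene, j_gene = vertices$j_gene,
                          sample = vertices$sample))
  igraph::V(g)$degree_zero <- igraph::degree(g) == 0
  g
}

#' Connected components of a hit graph
#'
#' @param graph an igraph graph from [build_hit_graph].
#' @return `data.table` with columns `name`, `sigma`, `v_gene`, `j_gene`,
#'   `sample`, `component` (integer cluster ids, numbered in order of each
#'   component's lexicographically smallest member).
#' @export
hit_components <- function(graph) {
  if (igraph::vcount(graph) == 0L) {
    return(data.table::data.table(name = character(), sigma = character(),
                                  v_gene = character(), j_gene = character(),
                                  sample = character(), component = integer()))
  }
  comp <- igraph::components(graph)
  dt <- data.table::data.table(
    name = igraph::V(graph)$name, sigma = igraph::V(graph)$sigma,
    v_gene = igraph::V(graph)$v_gene, j_gene = igraph::V(graph)$j_gene,
    sample = igraph::V(graph)$sample, raw = comp$membership)
  # deterministic numbering: by smallest member name within each component
  key <- dt[, .(first = min(name)), by = raw][order(first)]
  key[, component := .I]
  dt <- merge(dt, key[, .(raw, component)], by = "raw")
  dt[, raw := NULL]
  data.table::setorder(dt, component, name)
  dt[]
}

#' Public hits shared across samples
#'
#' Sequences found independently as hits in two or more samples, keyed by
#' exact (CDR3 amino-acid, V, J) identity.
#'
#' @param hits named list of `enrichment_result`s (or hit data.frames), at
#'   least two samples.
#' @param significant_only as in [build_hit_graph].
#' @return `data.table` with `sigma`, `v_gene`, `j_gene`, `n_samples`,
#'   `samples` (comma-separated), plus one logical presence column per sample.
#' @export
public_hits <- function(hits, significant_only = TRUE) {
  stopifnot(is.list(hits), length(hits) >= 2L, !is.null(names(hits)))
  tabs <- lapply(names(hits), function(id) {
    h <- data.table::as.data.table(hits[[id]])
    if (significant_only && "significant" %in% names(h)) h <- h[significant == TRUE]
    if (nrow(h) == 0L) return(NULL)
    unique(data.table::data.table(sigma = h$sigma, v_gene = h$v_gene,
                                  j_gene = h$j_gene, sample = id))
  })
  all <- data.table::rbindlist(Filter(Negate(is.null), tabs))
  empty <- data.table::data.table(sigma = character(), v_gene = character(),
                                  j_gene = character(), n_samples = integer(),
                                  samples = character())
  if (is.null(all) || nrow(all) == 0L) return(empty)
  agg <- all[, .(n_samples = .N, samples = paste(sort(sample), collapse = ",")),
             by = .(sigma, v_gene, j_gene)]
  agg <- agg[n_samples >= 2L]
  if (nrow(agg) == 0L) return(empty)
  for (id in names(hits)) {
    present <- all[sample == id, paste(sigma, v_gene, j_gene)]
    agg[, (id) := paste(sigma, v_gene, j_gene) %in% present]
  }
  data.table::setorder(agg, -n_samples, sigma)
  agg[]
}

#' Export a hit graph
#'
#' Writes GraphML plus a plain edge-list TSV and a components TSV.
#'
#' @param graph an igraph graph from [build_hit_graph].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"hit_graph"`).
#' @return invisibly, the paths written.
#' @export
export_hit_graph <- function(graph, dir, prefix = "hit_graph") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gml <- file.path(dir, paste0(prefix, ".graphml"))
  igraph::write_graph(graph, gml, format = "graphml")
  el <- file.path(dir, paste0(prefix, "_edges.tsv"))
  em <- igraph::as_edgelist(graph)
  data.table::fwrite(data.table::data.table(from = em[, 1], to = em[, 2]),
                     el, sep = "\t")
  comp <- file.path(dir, paste0(prefix, "_components.tsv"))
  data.table::fwrite(hit_components(graph), comp, sep = "\t")
  invisible(c(graphml = gml, edges = el, components = comp))
}
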