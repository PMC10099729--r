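#' Transcript models for one or more genes
#'
#' Validates and normalises a table of transcript exons into the internal
#' representation used by [build_splice_graph()]. Coordinates are 0-based
#' half-open internally; [read_gtf_transcripts()] converts from the 1-based
#' inclusive GTF convention on read.
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand` (`"+"` or `"-"`), `start`, `end` (0-based half-open).
#' @return data.frame of class `transcript_models`, exons sorted by gene,
#'   transcript and genomic coordinate.
#' @export
transcript_models <- function(exons) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss) > 0L)
    stop("missing columns: ", paste(miss, collapse = ", "))
  exons <- as.data.frame(exons)[, need]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end - exons$start < 1L))
    stop("zero- or negative-length exon in transcript ",
         exons$transcript_id[which(exons$end - exons$start < 1L)[1L]])
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ]
  # exons within a transcript must not overlap
  for (tid in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tid, ]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", tid)
  }
  rownames(exons) <- NULL
  class(exons) <- c("transcript_models", "data.frame")
  exons
}

#' Build the contiguous splice graph (CSG) of one gene
#'
#' Collapses all transcript exons of a gene into non-overlapping exonic nodes
#' (the partition of the exonic cover by every exon boundary), numbers the
#' nodes 1..N in transcription order (reverse of genomic order on the minus
#' strand), and connects them with adjacency edges (genomically contiguous
#' nodes inside one exon) and junction edges (splice junctions). Each
#' transcript is recorded as a path of node indices, and every node is typed
#' by [classify_node_type()].
#'
#' @param transcripts a `transcript_models` table restricted to one gene (all
#'   rows must share `gene_id`, `chrom` and `strand`).
#' @return object of class `splice_graph`: list with `gene_id`, `chrom`,
#'   `strand`, `nodes` (data.frame: `node_index`, `start`, `end`,
#'   `node_type`), `edges` (data.frame: `from`, `to`, `kind`) with
#'   `from < to` in transcription order, and `transcript_paths` (named list
#'   of node-index vectors).
#' @export
build_splice_graph <- function(transcripts) {
  # normalise unconditionally: callers may pass reordered rows
  transcripts <- transcript_models(transcripts)
  if (nrow(transcripts) == 0L) stop("no exons supplied")
  if (length(unique(transcripts$gene_id)) != 1L)
    stop("all transcripts must share one gene_id")
  if (length(unique(transcripts$chrom)) != 1L ||
      length(unique(transcripts$strand)) != 1L)
    stop("gene ", transcripts$gene_id[1L],
         ": transcripts on mixed chromosomes or strands")
  gene_id <- transcripts$gene_id[1L]
  strand <- transcripts$strand[1L]

  # partition the exonic cover by all exon boundaries
  bounds <- sort(unique(c(transcripts$start, transcripts$end)))
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1L]
  covered <- vapply(seq_along(seg_start), function(k) {
    any(transcripts$start <= seg_start[k] & transcripts$end >= seg_end[k])
  }, logical(1L))
  seg_start <- seg_start[covered]
  seg_end <- seg_end[covered]
  n <- length(seg_start)
  # transcription order: genomic on '+', reversed on '-'
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  nodes <- data.frame(node_index = seq_len(n),
                      start = seg_start[ord], end = seg_end[ord],
                      node_type = NA_character_,
                      stringsAsFactors = FALSE)
  node_at <- function(s, e) which(nodes$start >= s & nodes$end <= e)

  tids <- unique(transcripts$transcript_id)
  paths <- vector("list", length(tids))
  names(paths) <- tids
  edge_keys <- character(0)
  for (tid in tids) {
    ex <- transcripts[transcripts$transcript_id == tid, , drop = FALSE]
    tx_nodes <- integer(0)
    same_exon <- logical(0)  # TRUE if the step to the next node stays in one exon
    for (r in seq_len(nrow(ex))) {
      idx <- node_at(ex$start[r], ex$end[r])
      # exon must be an exact concatenation of nodes
      seg <- nodes[idx, , drop = FALSE]
      seg <- seg[order(seg$start), ]
      if (nrow(seg) == 0L || seg$start[1L] != ex$start[r] ||
          seg$end[nrow(seg)] != ex$end[r] ||
          (nrow(seg) > 1L && any(seg$start[-1L] != seg$end[-nrow(seg)])))
        stop("internal error: exon not a concatenation of nodes")
      idx <- idx[order(nodes$start[idx])]
      if (strand == "-") idx <- rev(idx)
      tx_nodes <- c(tx_nodes, idx)
      same_exon <- c(same_exon, rep(TRUE, length(idx) - 1L), FALSE)
    }
    same_exon <- same_exon[-length(same_exon)]  # drop trailing marker
    if (strand == "-") {
      # exons were visited in genomic order; transcription order is the
      # ascending node-index order. Recompute same-exon flags from genomic
      # contiguity (a transcription step stays inside one exon iff the next
      # node's genomic end meets this node's genomic start).
      tx_nodes <- sort(tx_nodes)
      same_exon <- if (length(tx_nodes) > 1L) {
        nodes$end[tx_nodes[-1L]] == nodes$start[tx_nodes[-length(tx_nodes)]]
      } else logical(0)
    }
    paths[[tid]] <- tx_nodes
    if (length(tx_nodes) > 1L) {
      kind <- ifelse(same_exon, "adjacency", "junction")
      edge_keys <- c(edge_keys,
                     paste(tx_nodes[-length(tx_nodes)], tx_nodes[-1L], kind))
    }
  }
  edge_keys <- unique(edge_keys)
  if (length(edge_keys) > 0L) {
    parts <- do.call(rbind, strsplit(edge_keys, " ", fixed = TRUE))
    edges <- data.frame(from = as.integer(parts[, 1L]),
                        to = as.integer(parts[, 2L]),
                        kind = parts[, 3L], stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to, edges$kind), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(0), to = integer(0),
                        kind = character(0), stringsAsFactors = FALSE)
  }
  # adjacency edges must be transcription-contiguous by construction
  stopifnot(all(edges$from < edges$to))

  g <- structure(list(gene_id = gene_id,
                      chrom = transcripts$chrom[1L],
                      strand = strand,
                      nodes = nodes, edges = edges,
                      transcript_paths = paths),
                 class = "splice_graph")
  g$nodes$node_type <- vapply(seq_len(n), function(i) classify_node_type(g, i),
                              character(1L))
  g
}

#' @export
print.splice_graph <- function(x, ...) {
  cat("splice_graph: gene", x$gene_id, "(", x$chrom, x$strand, ")\n")
  cat(" ", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      length(x$transcript_paths), "transcripts\n")
  cat("  node types:",
      paste(names(table(x$nodes$node_type)), table(x$nodes$node_type),
            sep = ":", collapse = " "), "\n")
  invisible(x)
}

# --- node typing -----------------------------------------------------------

has_edge <- function(g, from, to, kind = NULL) {
  sel <- g$edges$from == from & g$edges$to == to
  if (!is.null(kind)) sel <- sel & g$edges$kind == kind
  any(sel)
}

#' Classify a splice-graph node into one of the eight event types
#'
#' Ordered rule cascade (first match wins): RI, AF, AL, TS, TE, AA, AD, CE,
#' with NONE for nodes joined only by adjacency in every transcript. RI is a
#' node contiguous with both transcription-order neighbours in some transcript
#' while a junction skips exactly its interval; AF/AL are terminal nodes
#' attached by a junction in a gene with at least two distinct terminal nodes
#' on that side; TS/TE are terminal nodes attached only by adjacency; AA/AD
#' are internal extension nodes contiguous with a neighbour that other
#' transcripts splice into or out of directly.
#'
#' @param graph a `splice_graph`.
#' @param node_index node to classify (1-based, transcription order).
#' @return one of `"CE"`, `"AA"`, `"AD"`, `"AF"`, `"AL"`, `"RI"`, `"TE"`,
#'   `"TS"`, `"NONE"`.
#' @export
classify_node_type <- function(graph, node_index) {
  g <- graph
  i <- node_index
  if (i < 1L || i > nrow(g$nodes)) stop("no such node: ", node_index)
  paths <- g$transcript_paths
  with_i <- Filter(function(p) i %in% p, paths)
  first_nodes <- unique(vapply(paths, `[`, integer(1L), 1L))
  last_nodes <- unique(vapply(paths, function(p) p[length(p)], integer(1L)))
  first_in_all <- length(with_i) > 0L && all(vapply(with_i, function(p)
    p[1L] == i, logical(1L)))
  last_in_all <- length(with_i) > 0L && all(vapply(with_i, function(p)
    p[length(p)] == i, logical(1L)))
  inc <- g$edges[g$edges$from == i | g$edges$to == i, , drop = FALSE]

  # RI: retained intron
  if (has_edge(g, i - 1L, i, "adjacency") &&
      has_edge(g, i, i + 1L, "adjacency") &&
      has_edge(g, i - 1L, i + 1L, "junction"))
    return("RI")
  # AF: alternative first exon
  if (first_in_all && any(inc$kind == "junction") && length(first_nodes) >= 2L)
    return("AF")
  # AL: alternative last exon
  if (last_in_all && any(inc$kind == "junction") && length(last_nodes) >= 2L)
    return("AL")
  # TS: tandem transcription start (terminal, adjacency-attached only)
  if (first_in_all && nrow(inc) > 0L && all(inc$kind == "adjacency"))
    return("TS")
  # TE: tandem alternative polyadenylation site
  if (last_in_all && nrow(inc) > 0L && all(inc$kind == "adjacency"))
    return("TE")
  internal <- !first_in_all && !last_in_all
  # AA: acceptor extension — contiguous with the downstream neighbour that
  # other transcripts junction into directly
  if (internal && has_edge(g, i, i + 1L, "adjacency") &&
      any(g$edges$to == i + 1L & g$edges$from < i & g$edges$kind == "junction"))
    return("AA")
  # AD: donor extension — contiguous with the upstream neighbour that other
  # transcripts junction out of directly
  if (internal && has_edge(g, i - 1L, i, "adjacency") &&
      any(g$edges$from == i - 1L & g$edges$to > i & g$edges$kind == "junction"))
    return("AD")
  if (any(inc$kind == "junction")) return("CE")
  "NONE"
}

# --- event path enumeration ------------------------------------------------

#' Enumerate all local isoform paths through a node's splicing event
#'
#' The event is anchored at the nearest upstream and downstream nodes that
#' every transcript spanning the node's position passes through; all distinct
#' edge-paths between the anchors are enumerated by depth-first search. When
#' an anchor does not exist (terminal events), enumeration starts from the
#' distinct first (or ends at the distinct last) nodes of the spanning
#' transcripts.
#'
#' @param graph a `splice_graph`.
#' @param node_index event node.
#' @param max_paths cap on enumerated paths; events whose path count exceeds
#'   it are flagged `truncated` and treated as unquantifiable downstream.
#' @return object of class `event_paths`: list with `gene_id`, `node_index`,
#'   `anchors` (`c(u, v)`, `NA` when absent), `paths` (list of node-index
#'   vectors), `path_edges` (list of edge data.frames), `contains_node`
#'   (logical per path), `truncated`.
#' @export
enumerate_event_paths <- function(graph, node_index, max_paths = 128L) {
  g <- graph
  i <- node_index
  n <- nrow(g$nodes)
  if (i < 1L || i > n) stop("no such node: ", node_index)
  paths <- g$transcript_paths
  spanning <- Filter(function(p) min(p) <= i && max(p) >= i, paths)
  if (length(spanning) == 0L) spanning <- Filter(function(p) i %in% p, paths)
  deg <- sum(g$edges$from == i | g$edges$to == i)
  if (deg == 0L) {
    if (n > 1L)
      stop("node ", i, " of gene ", g$gene_id,
           " has no incident edges (annotation inconsistency)")
    return(structure(list(gene_id = g$gene_id, node_index = i,
                          anchors = c(NA_integer_, NA_integer_),
                          paths = list(i),
                          path_edges = list(g$edges[0, ]),
                          contains_node = TRUE, truncated = FALSE),
                     class = "event_paths"))
  }
  common <- Reduce(intersect, spanning)
  u <- if (any(common < i)) max(common[common < i]) else NA_integer_
  v <- if (any(common > i)) min(common[common > i]) else NA_integer_
  starts <- if (!is.na(u)) u else
    unique(vapply(spanning, `[`, integer(1L), 1L))
  ends <- if (!is.na(v)) v else
    unique(vapply(spanning, function(p) p[length(p)], integer(1L)))
  lo <- min(starts, i)
  hi <- max(ends, i)

  adj <- split(seq_len(nrow(g$edges)), g$edges$from)
  out <- list()
  truncated <- FALSE
  walk <- function(node, trail) {
    if (truncated) return(invisible())
    if (node %in% ends && length(trail) > 1L) {
      if (length(out) >= max_paths) { truncated <<- TRUE; return(invisible()) }
      out[[length(out) + 1L]] <<- trail
      return(invisible())
    }
    for (e in adj[[as.character(node)]]) {
      nxt <- g$edges$to[e]
      if (nxt > hi) next
      walk(nxt, c(trail, nxt))
    }
    invisible()
  }
  for (s in sort(starts)) walk(s, s)
  # degenerate events (anchorless single-node transcripts)
  if (length(out) == 0L) out <- list(i)
  keys <- vapply(out, paste, character(1L), collapse = ",")
  out <- out[!duplicated(keys)]
  out <- out[order(vapply(out, paste, character(1L), collapse = ","))]
  path_edges <- lapply(out, function(p) {
    if (length(p) < 2L) return(g$edges[0, ])
    sel <- mapply(function(a, b) which(g$edges$from == a & g$edges$to == b)[1L],
                  p[-length(p)], p[-1L])
    g$edges[sel, , drop = FALSE]
  })
  structure(list(gene_id = g$gene_id, node_index = i,
                 anchors = c(if (is.na(u)) NA_integer_ else u,
                             if (is.na(v)) NA_integer_ else v),
                 paths = out, path_edges = path_edges,
                 contains_node = vapply(out, function(p) i %in% p, logical(1L)),
                 truncated = truncated),
            class = "event_paths")
}

#' @export
print.event_paths <- function(x, ...) {
  cat("event_paths: gene", x$gene_id, "node", x$node_index, "--",
      length(x$paths), "paths",
      if (x$truncated) "(TRUNCATED)" else "", "\n")
  for (k in seq_along(x$paths))
    cat("  ", paste(x$paths[[k]], collapse = "-"),
        if (x$contains_node[k]) " [contains node]" else "", "\n", sep = "")
  invisible(x)
}

# --- GTF I/O ---------------------------------------------------------------

#' Read transcript models from a GTF file
#'
#' Uses rtracklayer for parsing; keeps `exon` features and converts the GTF's
#' 1-based inclusive coordinates to the internal 0-based half-open convention.
#'
#' @param path GTF file.
#' @return `transcript_models` table for all genes in the file.
#' @export
read_gtf_transcripts <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   stop("failed to parse GTF ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  transcript_models(data.frame(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE))
}

#' Write the node table of one or more splice graphs
#'
#' Emits one row per node with 1-based inclusive coordinates:
#' `gene_id, node_index, chrom, start, end, strand, node_type`.
#'
#' @param graphs a `splice_graph` or list of them.
#' @param path output TSV path.
#' @return the node table, invisibly.
#' @export
write_node_table <- function(graphs, path) {
  if (inherits(graphs, "splice_graph")) graphs <- list(graphs)
  tab <- do.call(rbind, lapply(graphs, function(g) {
    data.frame(gene_id = g$gene_id, node_index = g$nodes$node_index,
               chrom = g$chrom, start = g$nodes$start + 1L,
               end = g$nodes$end, strand = g$strand,
               node_type = g$nodes$node_type, stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
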