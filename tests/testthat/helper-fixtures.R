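# shared fixtures and independent oracles

# two-transcript cassette-exon gene: T1 includes the middle exon, T2 skips it
cassette_transcripts <- function(strand = "+") {
  transcript_models(data.frame(
    gene_id = "g1",
    transcript_id = rep(c("T1", "T2"), c(3L, 2L)),
    chrom = "chr1", strand = strand,
    start = c(0, 200, 400, 0, 400),
    end = c(100, 300, 500, 100, 500)))
}

cassette_graph <- function(strand = "+") build_splice_graph(
  cassette_transcripts(strand))

# cassette exon whose inclusion isoform also has an acceptor extension:
# three local paths through the event (skip / short / long)
cassette_aa_transcripts <- function() {
  transcript_models(data.frame(
    gene_id = "g2",
    transcript_id = rep(c("T1", "T2", "T3"), c(3L, 2L, 3L)),
    chrom = "chr1", strand = "+",
    start = c(0, 200, 400, 0, 400, 0, 160, 400),
    end = c(100, 300, 500, 100, 500, 100, 300, 500)))
}

# brute-force oracle: partition of the exonic cover by all exon boundaries
oracle_partition <- function(exons) {
  bounds <- sort(unique(c(exons$start, exons$end)))
  segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
  keep <- vapply(seq_len(nrow(segs)), function(k)
    any(exons$start <= segs$start[k] & exons$end >= segs$end[k]), logical(1L))
  segs[keep, , drop = FALSE]
}

# brute-force oracle: all increasing node sequences from `from` to `to`
# whose consecutive pairs are edges (subset enumeration, no DFS)
oracle_paths <- function(graph, from, to) {
  mid <- setdiff(seq(from, to), c(from, to))
  has <- function(a, b) any(graph$edges$from == a & graph$edges$to == b)
  out <- list()
  for (k in 0:length(mid)) {
    combos <- if (k == 0L) list(integer(0)) else
      utils::combn(mid, k, simplify = FALSE)
    for (cmb in combos) {
      p <- c(from, sort(cmb), to)
      if (all(mapply(has, p[-length(p)], p[-1L])))
        out[[length(out) + 1L]] <- p
    }
  }
  out[order(vapply(out, paste, character(1L), collapse = ","))]
}

# brute-force oracle: every single-change scenario explaining a leaf pattern
oracle_single_change <- function(states, tree) {
  tips <- tree$tip.label
  a_set <- tips[states[tips] == "A"]
  c_set <- tips[states[tips] == "C"]
  if (length(a_set) == 0L || length(c_set) == 0L)
    return(list(uniform = TRUE, scenarios = list()))
  clades <- lapply(tree$edge[, 2L], function(child) {
    if (child <= length(tips)) tips[child]
    else tips[unlist(lapply(child, function(n) {
      desc <- integer(0)
      stack <- n
      while (length(stack) > 0L) {
        cur <- stack[1L]
        stack <- stack[-1L]
        kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
        for (kk in kids) {
          if (kk <= length(tips)) desc <- c(desc, kk) else stack <- c(stack, kk)
        }
      }
      desc
    }))]
  })
  scen <- list()
  for (cl in clades) {
    if (setequal(cl, a_set))
      scen[[length(scen) + 1L]] <- list(clade = sort(cl), direction = "gain")
    if (setequal(cl, c_set))
      scen[[length(scen) + 1L]] <- list(clade = sort(cl), direction = "loss")
  }
  list(uniform = FALSE, scenarios = scen)
}

# synthetic multi-path event where every path owns two private edges:
# paths (1, j, m + 2) for j = 2..m+1
private_edge_event <- function(m) {
  paths <- lapply(seq_len(m), function(j) c(1L, j + 1L, m + 2L))
  edges <- do.call(rbind, lapply(paths, function(p)
    data.frame(from = p[-length(p)], to = p[-1L], kind = "junction",
               stringsAsFactors = FALSE)))
  structure(list(gene_id = "toy", node_index = 2L,
                 anchors = c(1L, m + 2L), paths = paths,
                 path_edges = lapply(paths, function(p)
                   data.frame(from = p[-length(p)], to = p[-1L],
                              kind = "junction", stringsAsFactors = FALSE)),
                 contains_node = vapply(paths, function(p) 2L %in% p,
                                        logical(1L)),
                 truncated = FALSE),
            class = "event_paths")
}

# exact rank-sum oracle: full enumeration of group assignments
oracle_ranksum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ws <- apply(utils::combn(n, na), 2L, function(idx)
    sum(r[idx]) - na * (na + 1) / 2)
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  list(statistic = w_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}

random_transcript_set <- function(seed, n_tx = 5L, n_iv = 8L) {
  set.seed(seed)
  # pool of candidate exon intervals on a 1kb locus
  starts <- sort(sample(0:90, n_iv) * 10L)
  ends <- starts + sample(2:12, n_iv, replace = TRUE) * 10L
  rows <- list()
  for (t in seq_len(n_tx)) {
    pick <- sort(sample(n_iv, sample(2:4, 1L)))
    # drop overlapping picks to keep per-transcript exons disjoint
    sel <- pick[1L]
    for (p in pick[-1L])
      if (starts[p] >= ends[sel[length(sel)]]) sel <- c(sel, p)
    rows[[t]] <- data.frame(gene_id = "gr", transcript_id = paste0("t", t),
                            chrom = "chrR", strand = "+",
                            start = starts[sel], end = ends[sel],
                            stringsAsFactors = FALSE)
  }
  transcript_models(do.call(rbind, rows))
}
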