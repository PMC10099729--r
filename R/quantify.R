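#' Estimate relative path abundances of one event by EM
#'
#' Edge read counts are assigned to the paths of the event by
#' expectation-maximization: the E-step distributes each edge's count over
#' the paths containing that edge proportionally to the current abundances;
#' the M-step averages each path's assigned reads over its edge count (so a
#' two-edge inclusion route is supported by its mean per-edge coverage, not
#' the sum) and renormalises. Iteration stops when the L1 change drops below
#' `tol` or after `max_iter` iterations.
#'
#' @param event an `event_paths` object (must not be truncated).
#' @param counts named numeric vector of edge read counts, names `"from-to"`
#'   in transcription-order node indices; edges absent from the vector count
#'   as zero.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `path_abundance`: list with `psi_paths` (sums to
#'   1), `converged`, `iterations`, `no_data` (all-zero counts -> uniform
#'   abundances), `total_event_reads`.
#' @export
estimate_path_abundances <- function(event, counts, tol = 1e-6,
                                     max_iter = 1000L) {
  if (event$truncated)
    stop("event is truncated (too many paths); not quantifiable")
  m <- length(event$paths)
  keys <- lapply(event$path_edges, function(e) edge_key(e$from, e$to))
  all_keys <- unique(unlist(keys))
  c_e <- stats::setNames(rep(0, length(all_keys)), all_keys)
  hit <- intersect(names(counts), all_keys)
  c_e[hit] <- as.numeric(counts[hit])
  if (any(c_e < 0)) stop("negative edge counts")
  total <- sum(c_e)
  len <- vapply(keys, length, integer(1L))

  if (m == 1L || length(all_keys) == 0L) {
    return(structure(list(psi_paths = rep(1, m) / m, converged = total > 0,
                          iterations = 0L, no_data = total == 0,
                          total_event_reads = total),
                     class = "path_abundance"))
  }
  membership <- matrix(FALSE, nrow = m, ncol = length(all_keys),
                       dimnames = list(NULL, all_keys))
  for (p in seq_len(m)) membership[p, keys[[p]]] <- TRUE

  psi <- rep(1 / m, m)
  if (total == 0) {
    return(structure(list(psi_paths = psi, converged = FALSE, iterations = 0L,
                          no_data = TRUE, total_event_reads = 0),
                     class = "path_abundance"))
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(psi %*% membership)          # per-edge mixture mass
    w <- numeric(m)
    for (p in seq_len(m)) {
      e <- membership[p, ]
      d <- denom[e]
      share <- ifelse(d > 0, c_e[e] * psi[p] / d, c_e[e] / colSums(membership)[e])
      w[p] <- sum(share) / max(len[p], 1L)
    }
    new_psi <- if (sum(w) > 0) w / sum(w) else rep(1 / m, m)
    if (sum(abs(new_psi - psi)) < tol) {
      psi <- new_psi
      converged <- TRUE
      break
    }
    psi <- new_psi
  }
  structure(list(psi_paths = psi, converged = converged, iterations = it,
                 no_data = FALSE, total_event_reads = total),
            class = "path_abundance")
}

#' Percent-spliced-in of the event node
#'
#' PSI of a node is the summed relative abundance of the event paths that
#' contain the node.
#'
#' @param pa `path_abundance` for the event.
#' @param event the matching `event_paths`.
#' @return PSI in `[0, 1]`.
#' @export
node_psi <- function(pa, event) {
  psi <- sum(pa$psi_paths[event$contains_node])
  min(max(psi, 0), 1)
}

#' Shannon splicing entropy of an event (bits)
#'
#' `-sum(Psi_i * log2(Psi_i))` over the event's path abundances, with
#' `0 * log2(0)` taken as 0. Bounded by `log2(n_paths)`.
#'
#' @param pa `path_abundance`, or a bare numeric abundance vector.
#' @return entropy in bits.
#' @export
splicing_entropy <- function(pa) {
  p <- if (inherits(pa, "path_abundance")) pa$psi_paths else as.numeric(pa)
  if (any(p < 0)) stop("negative abundances")
  s <- sum(p)
  if (s <= 0) stop("abundances sum to zero")
  shannon_bits(p / s)
}

#' Discrete complexity bin K(n) of an event
#'
#' `n = ceiling(log2(n_paths))`, so a K(n) event can produce at most `2^n`
#' spliced outcomes: 2 paths -> K1, 3-4 paths -> K2, 5-8 paths -> K3. A
#' single-path (constitutive-only) event is K0.
#'
#' @param n_paths number of enumerated paths, >= 1.
#' @return integer bin.
#' @export
complexity_bin <- function(n_paths) {
  if (any(n_paths < 1)) stop("n_paths must be >= 1")
  as.integer(ceiling(log2(n_paths) - 1e-12))
}

#' Expression and read-support filter for an event
#'
#' Keeps events in expressed genes (TPM >= `min_tpm`) with at least
#' `min_reads` reads supporting the event.
#'
#' @param q a list/row with `gene_tpm` and `total_event_reads` (an
#'   `event_quant` row works).
#' @param min_tpm,min_reads thresholds (defaults: 1 TPM, 10 reads).
#' @return logical.
#' @export
event_filter <- function(q, min_tpm = 1.0, min_reads = 10) {
  isTRUE(q$gene_tpm >= min_tpm && q$total_event_reads >= min_reads)
}

#' Down-sample edge read counts without replacement
#'
#' Multivariate hypergeometric subsampling of the pooled reads down to
#' `target_total`, preserving the exact total; reproducible for a fixed seed.
#'
#' @param counts named numeric vector of edge counts (integers).
#' @param target_total reads to keep; must not exceed `sum(counts)`.
#' @param seed RNG seed.
#' @return named integer vector with `sum == target_total`.
#' @export
downsample_counts <- function(counts, target_total, seed) {
  counts <- round(counts)
  total <- sum(counts)
  if (target_total > total)
    stop("target_total (", target_total, ") exceeds available reads (",
         total, ")")
  if (target_total == total) return(counts)
  with_seed(seed, {
    out <- counts
    remaining <- total
    t <- target_total
    for (k in seq_along(counts)) {
      remaining <- remaining - counts[k]
      x <- stats::rhyper(1, counts[k], remaining, t)
      out[k] <- x
      t <- t - x
    }
    out
  })
}

#' Quantify every event of a gene in one sample
#'
#' Runs path enumeration and EM abundance estimation for each node of the
#' splice graph and assembles the per-event quantification table.
#'
#' @param graph a `splice_graph`.
#' @param counts named edge-count vector for this gene and sample
#'   (`"from-to"` keys).
#' @param gene_tpm host-gene expression (TPM) in this sample.
#' @param sample_id sample label for the output rows.
#' @param max_paths passed to [enumerate_event_paths()].
#' @param min_tpm,min_reads filter thresholds recorded per row.
#' @return data.frame of class `event_quant` with one row per node:
#'   `sample_id, gene_id, node_index, coord, strand, node_type, psi, entropy,
#'   k_bin, n_paths, total_event_reads, gene_tpm, pass_filter, truncated`.
#' @export
quantify_gene <- function(graph, counts, gene_tpm, sample_id = "sample",
                          max_paths = 128L, min_tpm = 1.0, min_reads = 10) {
  g <- graph
  rows <- lapply(seq_len(nrow(g$nodes)), function(i) {
    ev <- enumerate_event_paths(g, i, max_paths = max_paths)
    if (ev$truncated) {
      return(data.frame(sample_id = sample_id, gene_id = g$gene_id,
                        node_index = i,
                        coord = paste0(g$chrom, ":", g$nodes$start[i] + 1L,
                                       "-", g$nodes$end[i]),
                        strand = g$strand, node_type = g$nodes$node_type[i],
                        psi = NA_real_, entropy = NA_real_, k_bin = NA_integer_,
                        n_paths = length(ev$paths),
                        total_event_reads = NA_real_, gene_tpm = gene_tpm,
                        pass_filter = FALSE, truncated = TRUE,
                        stringsAsFactors = FALSE))
    }
    pa <- estimate_path_abundances(ev, counts)
    q <- data.frame(sample_id = sample_id, gene_id = g$gene_id, node_index = i,
                    coord = paste0(g$chrom, ":", g$nodes$start[i] + 1L, "-",
                                   g$nodes$end[i]),
                    strand = g$strand, node_type = g$nodes$node_type[i],
                    psi = node_psi(pa, ev), entropy = splicing_entropy(pa),
                    k_bin = complexity_bin(length(ev$paths)),
                    n_paths = length(ev$paths),
                    total_event_reads = pa$total_event_reads,
                    gene_tpm = gene_tpm, pass_filter = NA, truncated = FALSE,
                    stringsAsFactors = FALSE)
    q$pass_filter <- event_filter(q, min_tpm = min_tpm, min_reads = min_reads)
    q
  })
  out <- do.call(rbind, rows)
  class(out) <- c("event_quant", "data.frame")
  out
}

#' Write an event quantification table as TSV
#'
#' Columns mirror the per-event report of splice-graph quantifiers:
#' `Gene, Node, Coord, Strand, Type, Psi, Total_Reads, Complexity, Entropy`.
#'
#' @param quant an `event_quant` data.frame (rows from [quantify_gene()]).
#' @param path output TSV.
#' @return the written table, invisibly.
#' @export
write_event_table <- function(quant, path) {
  tab <- data.frame(Gene = quant$gene_id, Node = quant$node_index,
                    Coord = quant$coord, Strand = quant$strand,
                    Type = quant$node_type, Psi = quant$psi,
                    Total_Reads = quant$total_event_reads,
                    Complexity = paste0("K", quant$k_bin),
                    Entropy = quant$entropy, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
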