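# exon-context feature extraction and entropy regression benchmarks

#' Train donor/acceptor position weight matrices from an annotation
#'
#' Collects every annotated splice site of the supplied transcripts (donor:
#' last 3 exonic + first 6 intronic nt; acceptor: last 20 intronic + first 3
#' exonic nt, on the transcribed strand) and builds base-frequency PWMs with
#' a pseudocount of 1.
#'
#' @param transcripts `transcript_models` table.
#' @param genome named [Biostrings::DNAStringSet] (names = chromosomes).
#' @return list with `donor` and `acceptor` 4 x L probability matrices
#'   (rows A, C, G, T).
#' @export
train_splice_pwm <- function(transcripts, genome) {
  win <- splice_site_windows(transcripts, genome)
  list(donor = pwm_from_seqs(win$donor, 9L),
       acceptor = pwm_from_seqs(win$acceptor, 23L))
}

# all donor/acceptor windows of an annotation, transcribed-strand sequences
splice_site_windows <- function(transcripts, genome) {
  donors <- character(0)
  acceptors <- character(0)
  for (tid in unique(transcripts$transcript_id)) {
    ex <- transcripts[transcripts$transcript_id == tid, , drop = FALSE]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2L) next
    chrom <- ex$chrom[1L]
    strand <- ex$strand[1L]
    if (!chrom %in% names(genome)) next
    for (k in seq_len(nrow(ex) - 1L)) {
      # genomic-order junction between exon k and k+1
      left_end <- ex$end[k]       # 0-based half-open
      right_start <- ex$start[k + 1L]
      if (strand == "+") {
        d <- fetch_seq(genome, chrom, left_end - 3L, left_end + 6L, "+")
        a <- fetch_seq(genome, chrom, right_start - 20L, right_start + 3L, "+")
      } else {
        d <- fetch_seq(genome, chrom, right_start - 6L, right_start + 3L, "-")
        a <- fetch_seq(genome, chrom, left_end - 3L, left_end + 20L, "-")
      }
      if (!is.na(d)) donors <- c(donors, d)
      if (!is.na(a)) acceptors <- c(acceptors, a)
    }
  }
  list(donor = donors, acceptor = acceptors)
}

# 0-based half-open genomic fetch on the transcribed strand; NA off the ends
fetch_seq <- function(genome, chrom, start, end, strand) {
  len <- Biostrings::width(genome[chrom])
  if (start < 0L || end > len) return(NA_character_)
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

pwm_from_seqs <- function(seqs, width) {
  seqs <- seqs[!is.na(seqs) & nchar(seqs) == width]
  counts <- matrix(1, nrow = 4L, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in seqs) {
    b <- strsplit(toupper(s), "")[[1L]]
    for (j in seq_len(width))
      if (b[j] %in% rownames(counts))
        counts[b[j], j] <- counts[b[j], j] + 1
  }
  sweep(counts, 2L, colSums(counts), "/")
}

#' Score a splice-site window against a PWM
#'
#' Sum of per-position log2 odds of the observed base against a uniform
#' background (0.25); `N` (or any non-ACGT symbol) contributes 0.
#'
#' @param window sequence string (transcribed strand), length matching the
#'   PWM (donor 9 nt, acceptor 23 nt).
#' @param kind `"donor"` or `"acceptor"`.
#' @param pwms PWM list from [train_splice_pwm()].
#' @return log-odds score in bits; `NA` for a window of wrong length.
#' @export
splice_site_strength <- function(window, kind = c("donor", "acceptor"), pwms) {
  kind <- match.arg(kind)
  pwm <- pwms[[kind]]
  if (is.na(window) || nchar(window) != ncol(pwm)) return(NA_real_)
  b <- strsplit(toupper(window), "")[[1L]]
  score <- 0
  for (j in seq_along(b))
    if (b[j] %in% rownames(pwm))
      score <- score + log2(pwm[b[j], j] / 0.25)
  unname(score)
}

# reconstruct a transcript's exons (runs of adjacency-linked nodes) as
# genomic 0-based half-open intervals, in transcription order
path_exons <- function(graph, tid) {
  p <- graph$transcript_paths[[tid]]
  if (length(p) == 0L) return(NULL)
  runs <- list(p[1L])
  if (length(p) > 1L) {
    for (k in 2L:length(p)) {
      if (has_edge(graph, p[k - 1L], p[k], "adjacency"))
        runs[[length(runs)]] <- c(runs[[length(runs)]], p[k])
      else runs[[length(runs) + 1L]] <- p[k]
    }
  }
  do.call(rbind, lapply(runs, function(r) {
    data.frame(start = min(graph$nodes$start[r]),
               end = max(graph$nodes$end[r]),
               nodes = I(list(r)))
  }))
}

seq_stats <- function(genome, chrom, start, end, strand) {
  s <- fetch_seq(genome, chrom, start, end, strand)
  if (is.na(s) || nchar(s) == 0L)
    return(c(gc = NA_real_, pyrimidine = NA_real_))
  b <- strsplit(toupper(s), "")[[1L]]
  n <- sum(b %in% c("A", "C", "G", "T"))
  if (n == 0L) return(c(gc = 0, pyrimidine = 0))
  c(gc = sum(b %in% c("G", "C")) / n, pyrimidine = sum(b %in% c("C", "T")) / n)
}

#' Extract the exon-context feature vector of a cassette-exon event
#'
#' For a CE node with both flanking exons present in some transcript:
#' lengths and GC of the target/upstream/downstream exons, lengths, GC and
#' pyrimidine content of the flanking introns, the exon's rank in the
#' transcript, and PWM splice-site strengths of the target exon's acceptor
#' and donor and of the upstream-exon donor and downstream-exon acceptor.
#' Upstream/downstream follow transcription order, so features are invariant
#' under strand reversal of the locus.
#'
#' @param graph `splice_graph`.
#' @param genome named [Biostrings::DNAStringSet].
#' @param node_index CE node to profile.
#' @param pwms PWMs from [train_splice_pwm()].
#' @return named numeric vector of 17 features.
#' @export
extract_exon_features <- function(graph, genome, node_index, pwms) {
  g <- graph
  strand <- g$strand
  chrom <- g$chrom
  host <- NULL
  for (tid in sort(names(g$transcript_paths))) {
    ex <- path_exons(g, tid)
    hit <- which(vapply(ex$nodes, function(r) node_index %in% r, logical(1L)))
    if (length(hit) == 1L && hit > 1L && hit < nrow(ex)) {
      host <- list(ex = ex, rank = hit)
      break
    }
  }
  if (is.null(host))
    stop("node ", node_index, " has no transcript with both flanking exons ",
         "(terminal exon)")
  ex <- host$ex
  r <- host$rank
  tgt <- ex[r, ]
  up <- ex[r - 1L, ]
  dn <- ex[r + 1L, ]
  # transcription-order introns as genomic intervals
  intr <- function(a, b) {   # a transcriptionally before b
    if (strand == "+") c(a$end, b$start) else c(b$end, a$start)
  }
  up_in <- intr(up, tgt)
  dn_in <- intr(tgt, dn)
  st_t <- seq_stats(genome, chrom, tgt$start, tgt$end, strand)
  st_u <- seq_stats(genome, chrom, up$start, up$end, strand)
  st_d <- seq_stats(genome, chrom, dn$start, dn$end, strand)
  st_ui <- seq_stats(genome, chrom, up_in[1L], up_in[2L], strand)
  st_di <- seq_stats(genome, chrom, dn_in[1L], dn_in[2L], strand)

  # splice-site windows around the target and flanking junctions;
  # exon_end_g is the transcription-order 3' boundary in genomic coordinates
  donor_win <- function(exon_end_g) {
    if (strand == "+") fetch_seq(genome, chrom, exon_end_g - 3L,
                                 exon_end_g + 6L, "+")
    else fetch_seq(genome, chrom, exon_end_g - 6L, exon_end_g + 3L, "-")
  }
  acceptor_win <- function(exon_start_g) {
    if (strand == "+") fetch_seq(genome, chrom, exon_start_g - 20L,
                                 exon_start_g + 3L, "+")
    else fetch_seq(genome, chrom, exon_start_g - 3L, exon_start_g + 20L, "-")
  }
  # transcription-order boundaries in genomic coordinates
  t_acc <- if (strand == "+") acceptor_win(tgt$start) else acceptor_win(tgt$end)
  t_don <- if (strand == "+") donor_win(tgt$end) else donor_win(tgt$start)
  u_don <- if (strand == "+") donor_win(up$end) else donor_win(up$start)
  d_acc <- if (strand == "+") acceptor_win(dn$start) else acceptor_win(dn$end)

  c(target_len = tgt$end - tgt$start,
    target_gc = unname(st_t["gc"]),
    upstream_exon_len = up$end - up$start,
    upstream_exon_gc = unname(st_u["gc"]),
    downstream_exon_len = dn$end - dn$start,
    downstream_exon_gc = unname(st_d["gc"]),
    upstream_intron_len = up_in[2L] - up_in[1L],
    upstream_intron_gc = unname(st_ui["gc"]),
    upstream_intron_py = unname(st_ui["pyrimidine"]),
    downstream_intron_len = dn_in[2L] - dn_in[1L],
    downstream_intron_gc = unname(st_di["gc"]),
    downstream_intron_py = unname(st_di["pyrimidine"]),
    exon_rank = r,
    acceptor_strength = splice_site_strength(t_acc, "acceptor", pwms),
    donor_strength = splice_site_strength(t_don, "donor", pwms),
    upstream_donor_strength = splice_site_strength(u_don, "donor", pwms),
    downstream_acceptor_strength = splice_site_strength(d_acc, "acceptor",
                                                        pwms))
}

#' Read an externally computed feature table
#'
#' Accepts TSVs with an `event_id` column plus named numeric feature
#' columns, so feature sets computed by other exon-profiling tools can be
#' dropped in.
#'
#' @param path TSV file.
#' @return data.frame with `event_id` first.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"event_id" %in% names(tab)) stop("event_id column required in ", path)
  tab[, c("event_id", setdiff(names(tab), "event_id"))]
}

#' Cross-validated benchmark of mean-entropy regressors
#'
#' Standardises the features, assigns events to `folds` cross-validation
#' folds with a fixed seed, fits the chosen model family on each training
#' split and evaluates held-out predictions: Pearson (PCC) and Spearman
#' (SCC) correlations are averaged over folds (within-fold correlations are
#' unaffected by the fold-mean shifts that bias pooled correlations under
#' the null), while R-squared is computed on the pooled held-out
#' predictions. Feature importance is permutation importance on the
#' held-out data: the increase in pooled MSE when one feature column is
#' shuffled.
#'
#' @param x numeric feature matrix (events x features, named columns).
#' @param y mean splicing entropy targets.
#' @param family `"linear"` (least squares) or `"gbt"` (gradient-boosted
#'   trees via xgboost).
#' @param folds CV folds (5).
#' @param seed RNG seed; fixed seed gives an identical report.
#' @param nrounds,max_depth,eta gbt hyperparameters.
#' @return object of class `regression_report`: list with `family`, `pcc`,
#'   `scc`, `r2`, `per_fold` (data.frame), `importance` (named, sorted
#'   decreasing), `predictions`, `undefined` (`TRUE` when the target is
#'   constant, metrics `NA`).
#' @export
train_entropy_regressor <- function(x, y, family = c("gbt", "linear"),
                                    folds = 5L, seed = 1L, nrounds = 200L,
                                    max_depth = 3L, eta = 0.1) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)")
  if (nrow(x) < 2L * folds) stop("too few events for ", folds, "-fold CV")
  if (stats::sd(y) == 0) {
    return(structure(list(family = family, pcc = NA_real_, scc = NA_real_,
                          r2 = NA_real_, per_fold = NULL, importance = NULL,
                          predictions = NULL, undefined = TRUE),
                     class = "regression_report"))
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")

  fit_one <- function(xtr, ytr) {
    if (family == "linear") {
      df <- data.frame(y = ytr, xtr)
      stats::lm(y ~ ., data = df)
    } else {
      xgboost::xgboost(x = xtr, y = ytr, nrounds = nrounds,
                       max_depth = max_depth, learning_rate = eta,
                       nthreads = 1L, objective = "reg:squarederror",
                       verbosity = 0)
    }
  }
  predict_one <- function(model, xte) {
    if (family == "linear") stats::predict(model, newdata = data.frame(xte))
    else stats::predict(model, xte)
  }

  with_seed(seed, {
    fold_id <- sample(rep_len(seq_len(folds), nrow(xs)))
    preds <- numeric(nrow(xs))
    models <- vector("list", folds)
    per_fold <- data.frame(fold = seq_len(folds), pcc = NA_real_,
                           scc = NA_real_, r2 = NA_real_)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      models[[f]] <- fit_one(xs[tr, , drop = FALSE], y[tr])
      p <- predict_one(models[[f]], xs[!tr, , drop = FALSE])
      preds[!tr] <- p
      if (stats::sd(y[!tr]) > 0 && stats::sd(p) > 0) {
        per_fold$pcc[f] <- stats::cor(p, y[!tr])
        per_fold$scc[f] <- stats::cor(p, y[!tr], method = "spearman")
      }
      per_fold$r2[f] <- 1 - sum((y[!tr] - p)^2) / sum((y[!tr] - mean(y[!tr]))^2)
    }
    base_mse <- mean((preds - y)^2)
    imp <- vapply(colnames(xs), function(feat) {
      pm <- numeric(nrow(xs))
      for (f in seq_len(folds)) {
        te <- which(fold_id == f)
        xp <- xs[te, , drop = FALSE]
        xp[, feat] <- xp[sample(length(te)), feat]
        pm[te] <- predict_one(models[[f]], xp)
      }
      mean((pm - y)^2) - base_mse
    }, numeric(1L))
    structure(list(family = family,
                   pcc = mean(per_fold$pcc, na.rm = TRUE),
                   scc = mean(per_fold$scc, na.rm = TRUE),
                   r2 = 1 - sum((y - preds)^2) / sum((y - mean(y))^2),
                   per_fold = per_fold,
                   importance = sort(imp, decreasing = TRUE),
                   predictions = preds, undefined = FALSE),
              class = "regression_report")
  })
}

#' @export
print.regression_report <- function(x, ...) {
  cat("regression_report:", x$family, "\n")
  if (isTRUE(x$undefined)) {
    cat("  metrics undefined (constant target)\n")
    return(invisible(x))
  }
  cat(sprintf("  held-out PCC %.3f  SCC %.3f  R2 %.3f\n", x$pcc, x$scc, x$r2))
  top <- utils::head(x$importance, 5L)
  cat("  top importance:", paste(names(top), collapse = ", "), "\n")
  invisible(x)
}
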