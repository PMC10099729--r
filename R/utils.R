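# shared internal helpers

edge_key <- function(from, to) paste0(from, "-", to)

# run expr with a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# symmetric-capable Dirichlet sampler via gamma normalisation
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  # guard degenerate all-zero draws at tiny concentrations
  zero <- rowSums(x) == 0
  if (any(zero)) {
    pick <- sample.int(k, sum(zero), replace = TRUE)
    x[cbind(which(zero), pick)] <- 1
  }
  x / rowSums(x)
}

shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
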