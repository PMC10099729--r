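#' Default seven-species study tree
#'
#' Rooted binary phylogeny of the six mammals plus chicken as outgroup:
#' (((((human, chimpanzee), gorilla), macaque), mouse), opossum) vs chicken.
#'
#' @return an [ape::read.tree()] `phylo` object.
#' @export
species_tree7 <- function() {
  ape::read.tree(text =
    "((((((human,chimpanzee),gorilla),macaque),mouse),opossum),chicken);")
}

#' Per-species splicing state from per-tissue statuses
#'
#' A species is alternative (`"A"`) when the event is alternative in at least
#' one tissue; constitutive (`"C"`) when at least one tissue is quantifiable
#' and all quantifiable tissues are constitutive; `NA` otherwise.
#'
#' @param statuses character vector of per-tissue statuses
#'   (`"alternative"`, `"constitutive"`, `"excluded"` or `NA`).
#' @return `"A"`, `"C"` or `NA`.
#' @export
species_splicing_state <- function(statuses) {
  statuses <- statuses[!is.na(statuses)]
  if (any(statuses == "alternative")) return("A")
  if (any(statuses == "constitutive")) return("C")
  NA_character_
}

# leaf set below every branch (edge) of a rooted tree
tree_clades <- function(tree) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  lapply(tree$edge[, 2L], function(child) {
    if (child <= n_tip) tips[child]
    else tips[phangorn_descendants(tree, child)]
  })
}

# tip indices descending from an internal node (no phangorn dependency)
phangorn_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, function(k) {
    if (k <= n_tip) k else phangorn_descendants(tree, k)
  }))
}

# name a clade the way the field labels age groups: single species by name,
# larger clades by their two outermost members in tree order
clade_label <- function(leaves, tree) {
  ord <- tree$tip.label[tree$tip.label %in% leaves]
  if (length(ord) == 1L) return(ord)
  paste0(ord[1L], "-", ord[length(ord)])
}

#' Assign a splicing age to an orthologous event by single-change parsimony
#'
#' Enumerates every scenario in which one gain (constitutive to alternative)
#' or one loss (alternative to constitutive) on a single branch of the rooted
#' species tree explains the observed per-species states. Uniform patterns
#' are the conserved classes (all-A: VCA; all-C: VCC); the root-split
#' patterns matching the designated outgroup get the dedicated
#' mammal-conserved labels (MCA: ingroup A / outgroup C, readable as either
#' an ingroup gain or an outgroup loss; MCC symmetric). Any other pattern
#' explainable by a single change is labelled `<clade>_gain` / `<clade>_loss`
#' by the smaller changed clade, with every consistent scenario recorded;
#' patterns with no single-change explanation are `complex`.
#'
#' @param states named character vector (`"A"`/`"C"`/`NA`) over the tree's
#'   leaves.
#' @param tree rooted binary `phylo`; defaults to [species_tree7()].
#' @param require_complete if `TRUE` (canonical), any `NA` state makes the
#'   event `unassignable`; if `FALSE`, `NA` leaves are dropped and parsimony
#'   runs on the induced subtree (non-canonical tolerant mode).
#' @param outgroup leaf name(s) of the designated outgroup; defaults to the
#'   smaller root child of the tree.
#' @return object of class `age_assignment`: list with `label` and
#'   `scenarios` (list of `list(clade, direction)`).
#' @export
assign_splicing_age <- function(states, tree = species_tree7(),
                                require_complete = TRUE, outgroup = NULL) {
  res <- function(label, scenarios = list())
    structure(list(label = label, scenarios = scenarios),
              class = "age_assignment")
  tips <- tree$tip.label
  states <- states[tips]
  names(states) <- tips
  if (anyNA(states)) {
    if (require_complete) return(res("unassignable"))
    keep <- tips[!is.na(states)]
    if (length(keep) < 2L) return(res("unassignable"))
    tree <- ape::keep.tip(tree, keep)
    tips <- tree$tip.label
    states <- states[tips]
  }
  if (!all(states %in% c("A", "C"))) stop("states must be 'A', 'C' or NA")
  a_set <- tips[states == "A"]
  c_set <- tips[states == "C"]
  if (length(c_set) == 0L) return(res("VCA"))
  if (length(a_set) == 0L) return(res("VCC"))

  clades <- tree_clades(tree)
  scen <- list()
  for (cl in clades) {
    if (setequal(cl, a_set))
      scen[[length(scen) + 1L]] <- list(clade = sort(cl), direction = "gain")
    if (setequal(cl, c_set))
      scen[[length(scen) + 1L]] <- list(clade = sort(cl), direction = "loss")
  }
  if (length(scen) == 0L) return(res("complex"))

  if (is.null(outgroup)) {
    root <- length(tips) + 1L
    kids <- tree$edge[tree$edge[, 1L] == root, 2L]
    sets <- lapply(kids, function(k) {
      if (k <= length(tips)) tips[k]
      else tips[phangorn_descendants(tree, k)]
    })
    outgroup <- sets[[which.min(lengths(sets))]]
  }
  ingroup <- setdiff(tips, outgroup)
  if (setequal(a_set, ingroup) && setequal(c_set, outgroup))
    return(res("MCA", scen))
  if (setequal(c_set, ingroup) && setequal(a_set, outgroup))
    return(res("MCC", scen))

  sizes <- vapply(scen, function(s) length(s$clade), integer(1L))
  best <- scen[[which.min(sizes)]]
  res(paste0(clade_label(best$clade, tree), "_", best$direction), scen)
}

#' @export
print.age_assignment <- function(x, ...) {
  cat("age_assignment:", x$label)
  if (length(x$scenarios) > 0L)
    cat(" (", length(x$scenarios), "single-change scenario(s))", sep = "")
  cat("\n")
  invisible(x)
}

#' Spearman correlation of splicing entropy between two species
#'
#' Rank correlation over orthologous events quantified in both species.
#'
#' @param entropy_a,entropy_b entropy vectors over the same ordered event
#'   set; `NA` pairs are dropped.
#' @return list: `rho`, `n` (shared events), `defined` (`FALSE` when fewer
#'   than 3 shared events).
#' @export
pairwise_entropy_correlation <- function(entropy_a, entropy_b) {
  ok <- !is.na(entropy_a) & !is.na(entropy_b)
  n <- sum(ok)
  if (n < 3L) return(list(rho = NA_real_, n = n, defined = FALSE))
  list(rho = stats::cor(entropy_a[ok], entropy_b[ok], method = "spearman"),
       n = n, defined = TRUE)
}

#' Species with the clearly highest splicing entropy for one event
#'
#' Returns the arg-max species only when the gap between the top two
#' entropies reaches `margin` bits; ties or smaller gaps give `NA`.
#'
#' @param entropies named per-species entropy vector (`NA` allowed).
#' @param margin required top-minus-second gap (bits).
#' @return species name or `NA`.
#' @export
max_entropy_species <- function(entropies, margin = 1.0) {
  e <- entropies[!is.na(entropies)]
  if (length(e) < 2L) return(NA_character_)
  ord <- order(e, decreasing = TRUE)
  if (e[ord[1L]] - e[ord[2L]] >= margin) names(e)[ord[1L]] else NA_character_
}

#' Monotonic trend of splicing entropy along a divergence ordering
#'
#' Input ordered from the most diverged species toward the reference.
#' `"increase"` when non-decreasing with positive total change toward the
#' reference; `"decrease"` symmetric; otherwise `"none"`.
#'
#' @param entropies ordered numeric vector, no missing values.
#' @return `"increase"`, `"decrease"` or `"none"`.
#' @export
monotonic_entropy_trend <- function(entropies) {
  if (anyNA(entropies)) stop("missing values not allowed")
  d <- diff(entropies)
  if (length(d) == 0L) return("none")
  if (all(d >= 0) && sum(d) > 0) return("increase")
  if (all(d <= 0) && sum(d) < 0) return("decrease")
  "none"
}

#' Per-age-group entropy summaries
#'
#' For each splicing-age group: the fraction of events whose maximum entropy
#' over tissues reaches `threshold`, and the fraction whose cross-tissue
#' entropy range (max minus min) reaches `threshold`.
#'
#' @param labels per-event age labels.
#' @param entropy_by_tissue numeric matrix, events x tissues (`NA` =
#'   unquantified); rows aligned with `labels`.
#' @param threshold bits (default 1.0).
#' @return data.frame: `group, n, high_ratio, range_ratio`; empty groups are
#'   absent, groups with no quantified events get `NA` ratios.
#' @export
age_group_summaries <- function(labels, entropy_by_tissue, threshold = 1.0) {
  stopifnot(length(labels) == nrow(entropy_by_tissue))
  groups <- unique(labels)
  out <- lapply(groups, function(gp) {
    m <- entropy_by_tissue[labels == gp, , drop = FALSE]
    quant <- rowSums(!is.na(m)) > 0
    m <- m[quant, , drop = FALSE]
    if (nrow(m) == 0L)
      return(data.frame(group = gp, n = 0L, high_ratio = NA_real_,
                        range_ratio = NA_real_, stringsAsFactors = FALSE))
    mx <- apply(m, 1L, max, na.rm = TRUE)
    mn <- apply(m, 1L, min, na.rm = TRUE)
    data.frame(group = gp, n = nrow(m),
               high_ratio = mean(mx >= threshold),
               range_ratio = mean((mx - mn) >= threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
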