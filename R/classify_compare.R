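#' Alternative / constitutive splicing status of an event in one sample
#'
#' Alternative if `0 < Psi < 0.97` and the event passes the expression/read
#' filter; constitutive if `Psi >= 0.97` and it passes the filter; otherwise
#' excluded (including `Psi == 0` and unquantified events).
#'
#' @param psi PSI value (may be `NA`).
#' @param passes_filter logical from [event_filter()].
#' @param psi_const constitutive threshold (0.97).
#' @return `"alternative"`, `"constitutive"` or `"excluded"`.
#' @export
splicing_status <- function(psi, passes_filter, psi_const = 0.97) {
  if (is.na(psi) || !isTRUE(passes_filter)) return("excluded")
  if (psi >= psi_const) return("constitutive")
  if (psi > 0) return("alternative")
  "excluded"
}

#' High-complexity flag
#'
#' An event shows high splicing complexity when its entropy reaches
#' `threshold` bits (default 1.0, i.e. at least two effective splicing
#' outcomes; 1.5 is the stricter sensitivity cutoff).
#'
#' @param entropy splicing entropy in bits.
#' @param threshold bits.
#' @return logical (vectorised).
#' @export
high_complexity_flag <- function(entropy, threshold = 1.0) {
  entropy >= threshold
}

knm_levels <- c("K1_Low", "K1_Middle", "K1_High",
                "K2_Low", "K2_Middle", "K2_High",
                "K3_Low", "K3_Middle", "K3_High", "Others")

#' Joint complexity/PSI class of an event for a tissue pair
#'
#' Ten-class scheme crossing complexity (K1, K2, K3 with K>=3 folded into K3)
#' with PSI level: Low `(0, 0.2]`, Middle `(0.2, 0.8)`, High `[0.8, 0.97)`.
#' An event unquantifiable in this tissue (no reads, `Psi == 0`, or
#' constitutive `Psi >= 0.97` -- outside the alternative bins) but
#' quantifiable in the partner tissue is `"Others"`; an event unquantifiable
#' in both tissues is dropped (`NA`).
#'
#' @param k_bin complexity bin of the event in this tissue.
#' @param psi PSI in this tissue.
#' @param quantifiable_here,quantifiable_other logical: alternative-quantified
#'   (passes filter, `0 < Psi < 0.97`) in this / the partner tissue.
#' @return one of the ten class labels, or `NA` when the pair is dropped.
#' @export
knm_class <- function(k_bin, psi, quantifiable_here, quantifiable_other) {
  if (!isTRUE(quantifiable_here)) {
    if (isTRUE(quantifiable_other)) return("Others")
    return(NA_character_)
  }
  k <- min(max(k_bin, 1L), 3L)
  m <- if (psi > 0 && psi <= 0.2) "Low"
       else if (psi > 0.2 && psi < 0.8) "Middle"
       else if (psi >= 0.8 && psi < 0.97) "High"
       else return(if (isTRUE(quantifiable_other)) "Others" else NA_character_)
  paste0("K", k, "_", m)
}

#' Classify a shared event set in two tissues
#'
#' Applies [knm_class()] to every event of a tissue pair, deriving
#' quantifiability from filter status and PSI.
#'
#' @param a,b `event_quant` tables for tissues A and B, sharing
#'   `gene_id`/`node_index` rows (joined on those keys).
#' @return data.frame: `gene_id, node_index, class_a, class_b`; dropped pairs
#'   (unquantifiable in both) are removed.
#' @export
classify_tissue_pair <- function(a, b) {
  key_a <- paste(a$gene_id, a$node_index)
  key_b <- paste(b$gene_id, b$node_index)
  shared <- intersect(key_a, key_b)
  a <- a[match(shared, key_a), ]
  b <- b[match(shared, key_b), ]
  quant <- function(x) !is.na(x$psi) & x$pass_filter & x$psi > 0 & x$psi < 0.97
  qa <- quant(a)
  qb <- quant(b)
  cls_a <- cls_b <- character(length(shared))
  for (i in seq_along(shared)) {
    cls_a[i] <- knm_class(a$k_bin[i], a$psi[i], qa[i], qb[i])
    cls_b[i] <- knm_class(b$k_bin[i], b$psi[i], qb[i], qa[i])
  }
  out <- data.frame(gene_id = a$gene_id, node_index = a$node_index,
                    class_a = cls_a, class_b = cls_b,
                    stringsAsFactors = FALSE)
  out[!is.na(out$class_a) & !is.na(out$class_b), ]
}

#' Between-tissue class transition table
#'
#' 10 x 10 contingency counts of the joint class in tissue A against tissue
#' B; marginals equal the per-tissue class histograms of the retained pairs.
#'
#' @param pairs output of [classify_tissue_pair()], or two character vectors
#'   via `tissue_transition_table(class_a, class_b)`.
#' @param class_b optional second class vector.
#' @return 10 x 10 integer matrix (rows = tissue A classes).
#' @export
tissue_transition_table <- function(pairs, class_b = NULL) {
  if (is.null(class_b)) {
    class_a <- pairs$class_a
    class_b <- pairs$class_b
  } else class_a <- pairs
  tab <- table(factor(class_a, levels = knm_levels),
               factor(class_b, levels = knm_levels))
  m <- matrix(as.integer(tab), nrow = length(knm_levels),
              dimnames = list(A = knm_levels, B = knm_levels))
  m
}
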