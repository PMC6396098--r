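#' Binary annotation matrix
#'
#' Entity-by-attribute incidence used to derive similarity layers
#' (herb x efficacy, drug x ATC category). Entries are strictly 0/1.
#'
#' @param incidence numeric or logical matrix; coerced to 0/1 after
#'   validation. Row names are entity ids, column names attribute ids.
#' @return An object of class `annotation_matrix`.
#' @export
annotation_matrix <- function(incidence) {
  m <- as.matrix(incidence)
  if (!all(m %in% c(0, 1))) stop("incidence entries must be exactly 0 or 1")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("row (entity) names must be present and unique")
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    stop("column (attribute) names must be present and unique")
  }
  storage.mode(m) <- "double"
  structure(m, class = c("annotation_matrix", "matrix"))
}

#' Read an annotation matrix from a two-column TSV of (entity, attribute)
#' @param path TSV file, no header: entity id, attribute id.
#' @return An [annotation_matrix()].
#' @export
read_annotation_matrix <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  ents <- sort(unique(tab[[1]]))
  atts <- sort(unique(tab[[2]]))
  m <- matrix(0, length(ents), length(atts), dimnames = list(ents, atts))
  m[cbind(match(tab[[1]], ents), match(tab[[2]], atts))] <- 1
  annotation_matrix(m)
}

#' Cosine similarity of two binary annotation vectors
#'
#' The similarity behind the herb-herb (efficacy profiles) and drug-drug
#' (ATC category profiles) layers: dot(a, b) / (|a| |b|).
#'
#' @param vec_a,vec_b equal-length binary vectors, each with at least one
#'   nonzero entry.
#' @return Similarity in \[0, 1\].
#' @export
cosine_similarity <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b)) stop("vectors must have equal length")
  na <- sqrt(sum(vec_a^2)); nb <- sqrt(sum(vec_b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for an all-zero vector")
  }
  sum(vec_a * vec_b) / (na * nb)
}

#' Jaccard similarity of two attribute sets
#'
#' Alternative drug-drug similarity: |intersection| / |union|.
#'
#' @param set_a,set_b attribute sets (vectors); not both empty.
#' @return Similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) stop("Jaccard similarity undefined for two empty sets")
  length(intersect(set_a, set_b)) / u
}

#' Min-max normalization to \[0, 1\]
#'
#' Linear rescaling x' = (x - min) / (max - min), applied e.g. to
#' protein-protein interaction scores after a hard confidence pre-filter
#' so they can serve as edge weights.
#'
#' @param values numeric vector with at least two distinct values.
#' @return Rescaled vector; the minimum maps to 0 and the maximum to 1.
#' @export
minmax_normalize <- function(values) {
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("values must be finite numerics")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) stop("degenerate range: all values identical")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Similarity edges from an annotation matrix
#'
#' All unordered entity pairs with similarity strictly above `threshold`,
#' weighted by the similarity. Entities with an all-zero annotation row
#' have undefined similarity and are silently excluded.
#'
#' @param matrix an [annotation_matrix()].
#' @param metric `"cosine"` (on 0/1 vectors) or `"jaccard"` (on supports).
#' @param threshold emit pairs with similarity > threshold; in \[0, 1).
#' @param layer layer name to stamp on the emitted edges.
#' @return data.frame `source`, `target`, `layer`, `weight` in the
#'   edge-list format of [hti_network()].
#' @export
similarity_edges <- function(matrix, metric = c("cosine", "jaccard"),
                             threshold = 0, layer = "similarity") {
  metric <- match.arg(metric)
  stopifnot(inherits(matrix, "annotation_matrix"),
            threshold >= 0, threshold < 1)
  m <- unclass(matrix)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  n <- nrow(m)
  if (n < 2) {
    return(data.frame(source = character(), target = character(),
                      layer = character(), weight = numeric()))
  }
  if (metric == "cosine") {
    cp <- tcrossprod(m)
    nrm <- sqrt(diag(cp))
    sim <- cp / outer(nrm, nrm)
  } else {
    inter <- tcrossprod(m)
    sz <- rowSums(m)
    uni <- outer(sz, sz, "+") - inter
    sim <- inter / uni
  }
  idx <- which(upper.tri(sim) & sim > threshold, arr.ind = TRUE)
  data.frame(source = rownames(m)[idx[, 1]],
             target = rownames(m)[idx[, 2]],
             layer = rep(layer, nrow(idx)),
             weight = sim[idx],
             stringsAsFactors = FALSE)
}

#' Filter co-occurrence records by Fisher's exact test
#'
#' Text-mined entity pairs come with a 2x2 contingency table (a, b, c, d);
#' pairs are kept when the two-sided Fisher's exact p-value falls below
#' `alpha`. P-values are computed by [stats::fisher.test()] (conditional
#' hypergeometric enumeration with fixed margins).
#'
#' @param records data.frame with columns `id1`, `id2`, `a`, `b`, `c`, `d`
#'   (non-negative integer cells, positive total).
#' @param alpha significance level in (0, 1); default 0.05.
#' @return `records` restricted to significant pairs, with a `p_value`
#'   column appended (all rows gain the column before filtering).
#' @export
fisher_filter <- function(records, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(records) || nrow(records) == 0) {
    out <- data.frame(id1 = character(), id2 = character(), a = integer(),
                      b = integer(), c = integer(), d = integer(),
                      p_value = numeric())
    return(out)
  }
  cells <- as.matrix(records[, c("a", "b", "c", "d")])
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers")
  }
  if (any(rowSums(cells) == 0)) stop("contingency tables must be non-empty")
  p <- vapply(seq_len(nrow(cells)), function(i) {
    tab <- matrix(cells[i, ], 2, 2, byrow = TRUE)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
  records$p_value <- p
  records[p < alpha, , drop = FALSE]
}

#' Upper-tail binomial significance of a shared-link overlap
#'
#' Probability of observing at least `n_shared` shared links between two
#' networks out of `n_possible_pairs` comparable pairs when each pair
#' independently links with probability `p_edge`:
#' P(X >= n_shared), X ~ Binomial(n_possible_pairs, p_edge).
#' The tail is evaluated in log space for numerical range.
#'
#' @param n_shared observed overlap count (0..n_possible_pairs).
#' @param n_possible_pairs number of comparable pairs.
#' @param p_edge background edge probability in (0, 1). The background
#'   model is an explicit argument: different null models for how links
#'   arise give different p_edge.
#' @return p-value in \[0, 1\].
#' @export
overlap_binomial_pvalue <- function(n_shared, n_possible_pairs, p_edge) {
  stopifnot(n_shared >= 0, n_shared <= n_possible_pairs,
            p_edge > 0, p_edge < 1)
  if (n_shared == 0) return(1.0)
  # P(X >= k) = 1 - P(X <= k-1), in log space via lower.tail = FALSE
  exp(stats::pbinom(n_shared - 1, n_possible_pairs, p_edge,
                    lower.tail = FALSE, log.p = TRUE))
}
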