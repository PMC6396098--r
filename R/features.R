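#' Hadamard product of two embedding vectors
#'
#' The pair-feature operator: the elementwise product of the two node
#' vectors, giving a single d-dimensional feature for an (herb, protein)
#' candidate. Symmetric in its arguments.
#'
#' @param f_u,f_v equal-length numeric vectors.
#' @return Elementwise product.
#' @export
hadamard <- function(f_u, f_v) {
  if (length(f_u) != length(f_v)) {
    stop("hadamard: vectors must have equal length (",
         length(f_u), " vs ", length(f_v), ")")
  }
  f_u * f_v
}

#' Featurize (herb, protein) pairs from an embedding model
#'
#' One feature row per input pair, in input order: the Hadamard product
#' of the two node vectors.
#'
#' @param model an `embedding_model`.
#' @param pairs data.frame with columns `herb`, `protein` (namespaced node
#'   ids), or a 2-column character matrix.
#' @param labels optional vector (`"positive"`/`"negative"`/`"unknown"` or
#'   0/1) attached as an attribute.
#' @return Numeric matrix (n_pairs x d) with attribute `pairs` (the input
#'   pair data.frame) and optional attribute `labels`.
#' @export
featurize_pairs <- function(model, pairs, labels = NULL) {
  stopifnot(inherits(model, "embedding_model"))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("herb", "protein") %in% names(pairs))) {
    names(pairs)[1:2] <- c("herb", "protein")
  }
  vecs <- model$vectors
  iu <- match(pairs$herb, rownames(vecs))
  iv <- match(pairs$protein, rownames(vecs))
  if (anyNA(iu) || anyNA(iv)) {
    miss <- unique(c(pairs$herb[is.na(iu)], pairs$protein[is.na(iv)]))
    stop("no embedding vector for node(s): ",
         paste(head(miss, 5), collapse = ", "))
  }
  x <- vecs[iu, , drop = FALSE] * vecs[iv, , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "pairs") <- pairs[, c("herb", "protein")]
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(pairs))
    attr(x, "labels") <- labels
  }
  x
}

#' Enumerate unknown candidate pairs in memory-bounded blocks
#'
#' Streams the cross product herbs x proteins minus the excluded (known
#' positive) pairs, in blocks, so the full candidate matrix is never
#' materialized. Calls `fun(block)` on each block (a data.frame with
#' columns `herb`, `protein`) and concatenates results.
#'
#' @param herbs,proteins character vectors of namespaced node ids.
#' @param exclude data.frame of pairs to skip (known positives), or NULL.
#' @param block_size pairs per block.
#' @param fun function applied to each block; defaults to identity so the
#'   result (row-bound) is the candidate list itself.
#' @return Row-bound results of `fun` over all blocks.
#' @export
enumerate_candidates <- function(herbs, proteins, exclude = NULL,
                                 block_size = 100000L, fun = identity) {
  herbs <- sort(unique(herbs))
  proteins <- sort(unique(proteins))
  excl <- character(0)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    excl <- paste(exclude[[1]], exclude[[2]], sep = "\r")
  }
  total <- length(herbs) * length(proteins)
  out <- list()
  start <- 1
  while (start <= total) {
    end <- min(start + block_size - 1, total)
    idx <- seq(start, end)
    hi <- ((idx - 1) %/% length(proteins)) + 1
    pi <- ((idx - 1) %% length(proteins)) + 1
    block <- data.frame(herb = herbs[hi], protein = proteins[pi],
                        stringsAsFactors = FALSE)
    if (length(excl) > 0) {
      keep <- !(paste(block$herb, block$protein, sep = "\r") %in% excl)
      block <- block[keep, , drop = FALSE]
    }
    if (nrow(block) > 0) out[[length(out) + 1]] <- fun(block)
    start <- end + 1
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}
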