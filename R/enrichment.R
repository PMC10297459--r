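#' Hypergeometric over-representation analysis against a GMT collection
#'
#' For each term with members (intersected with the universe) of size K, the
#' overlap k with the query of size n out of a universe of N genes is scored
#' by the exact hypergeometric upper tail
#' `p = sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n)`.
#' FDR is Benjamini-Hochberg across all tested terms; terms smaller than
#' `min_size` are reported but flagged untested and excluded from the FDR.
#' Query ids outside the universe are dropped with a logged count. Results
#' are sorted by p, ties broken by term id, so output is deterministic and
#' invariant to query order.
#'
#' @param query character vector of gene ids.
#' @param sets named list of character vectors (see [readGMT()]).
#' @param universe background gene ids; defaults to the union of all set
#'   members, but should normally be the full assayed annotation.
#' @param min_size smallest member count (within the universe) to test.
#' @return data.frame with columns `term`, `description`, `k`, `K`, `n`,
#'   `N`, `p`, `fdr`, `tested`.
#' @examples
#' sets <- list(A = c("g1", "g2", "g3"), B = c("g4", "g5", "g6"))
#' enrichGeneSets(c("g1", "g2"), sets, universe = paste0("g", 1:20))
#' @export
enrichGeneSets <- function(query, sets, universe = NULL, min_size = 3L) {
  if (is.null(universe)) universe <- unique(unlist(sets))
  universe <- unique(universe)
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    message(length(dropped), " query ids outside the universe were dropped")
  }
  query <- intersect(query, universe)
  if (length(query) == 0L) {
    stop("query is empty after restricting to the universe", call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) {
    stop("gene-set collection contains an empty set", call. = FALSE)
  }
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(term) {
    members <- intersect(sets[[term]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, description = unname(desc[term]),
               k = k, K = K, n = n, N = N, p = p,
               tested = K >= min_size, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  res$fdr[res$tested] <- stats::p.adjust(res$p[res$tested], method = "BH")
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("term", "description", "k", "K", "n", "N", "p", "fdr", "tested")]
}
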