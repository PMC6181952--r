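#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated as
#' \code{set_id <tab> description <tab> member1 <tab> member2 ...}.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (unique, nonempty members);
#'   the \code{description} attribute carries the category labels.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad))
        stop("GMT format error: line(s) with fewer than 3 fields: ",
             paste(which(bad), collapse = ", "))
    sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
    names(sets) <- vapply(parts, `[[`, character(1L), 1L)
    attr(sets, "description") <- vapply(parts, `[[`, character(1L), 2L)
    if (any(lengths(sets) == 0L))
        stop("GMT format error: empty gene set(s)")
    sets
}

#' Upper-tail hypergeometric probability
#'
#' \code{P(X >= k)} for \code{X ~ Hypergeometric(N, K, n)}: drawing
#' \code{n} genes from a universe of \code{N} containing \code{K} set
#' members, the probability of at least \code{k} hits. Computed through
#' the log-space tail of the hypergeometric distribution for numerical
#' stability; \code{P(X >= 0) = 1} exactly.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return The upper-tail probability.
#' @export
hypergeometricUpperTail <- function(k, K, n, N) {
    if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N ||
        k > min(K, n))
        stop("domain error: inconsistent hypergeometric counts")
    if (k == 0) return(1)
    stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of a query gene list
#'
#' Tests each gene set for enrichment of the query within a stated
#' universe. The query is de-duplicated and intersected with the
#' universe (genes outside it are dropped with a message); each set is
#' likewise restricted to the universe and skipped when empty there.
#' P-values are Benjamini-Hochberg adjusted across all tested sets and
#' the table is sorted by adjusted p ascending. An empty effective
#' query yields an empty table with a warning.
#'
#' @param query character vector of gene symbols.
#' @param sets named list of gene sets (see [readGmt()]).
#' @param universe character vector of background gene symbols.
#' @return data.frame with \code{set_id}, \code{k}, \code{K}, \code{n},
#'   \code{N}, \code{p_value}, \code{adj_p}.
#' @export
enrich <- function(query, sets, universe) {
    universe <- unique(universe)
    N <- length(universe)
    query <- unique(query)
    dropped <- sum(!query %in% universe)
    if (dropped > 0)
        message(dropped, " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    n <- length(query)
    empty <- data.frame(set_id = character(), k = integer(),
                        K = integer(), n = integer(), N = integer(),
                        p_value = numeric(), adj_p = numeric())
    if (n == 0L) {
        warning("empty effective query; no enrichment computed")
        return(empty)
    }
    rows <- lapply(names(sets), function(id) {
        members <- intersect(sets[[id]], universe)
        K <- length(members)
        if (K == 0L) return(NULL)
        k <- length(intersect(query, members))
        data.frame(set_id = id, k = k, K = K, n = n, N = N,
                   p_value = hypergeometricUpperTail(k, K, n, N),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    if (!length(rows)) {
        warning("no gene set overlaps the universe")
        return(empty)
    }
    out <- do.call(rbind, rows)
    out$adj_p <- bhAdjust(out$p_value)
    out[order(out$adj_p, out$p_value, out$set_id), , drop = FALSE]
}
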