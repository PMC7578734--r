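#' Acupoint co-occurrence matrix
#'
#' Symmetric item-by-item counts of joint appearance across prescriptions:
#' entry (i, j) is the number of prescriptions containing both acupoints,
#' and the diagonal holds each acupoint's own frequency. The normalized
#' matrix expresses counts as percentages of the number of prescriptions N
#' (one decimal, half-up) -- the base under which the top CSAP pair
#' (LU9, PC6) sits above 50\%.
#'
#' @param dataset a \code{transactions} object.
#' @return An object of class \code{cooc_matrix}: a list with \code{items}
#'   (universe order), \code{counts} (integer matrix), \code{normalized}
#'   (percent of N) and \code{N}.
#' @export
#' @examples
#' cm <- cooccurrence_matrix(build_csap_fixture())
#' cm$normalized["LU9", "PC6"]   # 55.6
cooccurrence_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "transactions"))
  m <- to_incidence_matrix(dataset)
  counts <- crossprod(m)            # t(M) %*% M: joint counts, freq on diagonal
  storage.mode(counts) <- "integer"
  structure(list(items = dataset$universe,
                 counts = counts,
                 normalized = matrix(pct_ratio(as.vector(counts), dataset$N, 1L),
                                     nrow = nrow(counts),
                                     dimnames = dimnames(counts)),
                 N = dataset$N),
            class = "cooc_matrix")
}

#' Top co-occurring acupoint pairs
#'
#' Ranks unordered off-diagonal pairs by joint count, descending; ties are
#' broken lexicographically by the pair's codes so the ranking is stable.
#'
#' @param matrix a \code{cooc_matrix}.
#' @param k number of pairs to return; if larger than the number of pairs,
#'   all pairs are returned.
#' @param drop_zero drop pairs that never co-occur (default \code{TRUE}).
#' @return A data frame with columns \code{item1}, \code{item2} (item1 <
#'   item2 lexicographically), \code{count} and \code{normalized_pct}.
#' @export
top_pairs <- function(matrix, k = 10L, drop_zero = TRUE) {
  stopifnot(inherits(matrix, "cooc_matrix"), k >= 1L)
  items <- matrix$items
  if (length(items) < 2L) {
    return(data.frame(item1 = character(), item2 = character(),
                      count = integer(), normalized_pct = numeric()))
  }
  idx <- which(upper.tri(matrix$counts), arr.ind = TRUE)
  a <- items[idx[, 1L]]
  b <- items[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(item1 = a, item2 = b,
                   count = matrix$counts[idx],
                   normalized_pct = matrix$normalized[idx],
                   stringsAsFactors = FALSE)
  if (drop_zero) df <- df[df$count > 0L, , drop = FALSE]
  df <- df[order(-df$count, df$item1, df$item2, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}

#' Write co-occurrence matrices as delimited text
#'
#' Emits square matrices (counts and normalized) with acupoint-code row and
#' column headers.
#'
#' @param matrix a \code{cooc_matrix}.
#' @param counts_path,normalized_path output file paths; either may be
#'   \code{NULL} to skip.
#' @param sep field separator, default comma.
#' @return Invisibly, the written paths.
#' @export
write_cooccurrence <- function(matrix, counts_path = NULL,
                               normalized_path = NULL, sep = ",") {
  stopifnot(inherits(matrix, "cooc_matrix"))
  wr <- function(m, path) {
    df <- data.frame(code = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(counts_path)) wr(matrix$counts, counts_path)
  if (!is.null(normalized_path)) wr(matrix$normalized, normalized_path)
  invisible(c(counts_path, normalized_path))
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat("Co-occurrence matrix:", length(x$items), "acupoints over",
      x$N, "prescriptions\n")
  tp <- top_pairs(x, 3L)
  if (nrow(tp)) {
    cat("Top pairs:\n")
    print.data.frame(tp, row.names = FALSE)
  }
  invisible(x)
}

#' Heat-map of a co-occurrence matrix
#'
#' Cosmetic convenience: renders the normalized matrix with
#' [stats::heatmap()]. The analysis deliverable is the matrix itself.
#'
#' @param x a \code{cooc_matrix}.
#' @param ... passed to [stats::heatmap()].
#' @export
plot.cooc_matrix <- function(x, ...) {
  stats::heatmap(x$normalized, symm = TRUE, Rowv = NA, Colv = NA,
                 scale = "none", ...)
  invisible(x)
}
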