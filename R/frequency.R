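#' Frequency tables
#'
#' A frequency table reports, for each acupoint (or meridian), how many
#' times it was used and its share of the table total, as a percentage
#' rounded half-up to one decimal. Rows are sorted by frequency descending,
#' ties broken by code.
#'
#' @param counts named integer vector of frequencies.
#' @param total denominator for the share column; defaults to
#'   \code{sum(counts)}.
#' @param kind label stored on the table (\code{"acupoint"},
#'   \code{"meridian"}, ...).
#' @return A data frame of class \code{freq_table} with columns \code{code},
#'   \code{frequency}, \code{share_pct}, carrying attributes \code{total}
#'   and \code{kind}.
#' @export
frequency_table <- function(counts, total = sum(counts), kind = "item") {
  stopifnot(length(counts) > 0, !is.null(names(counts)), total > 0)
  ord <- order(-counts, names(counts), method = "radix")
  out <- data.frame(code = names(counts)[ord],
                    frequency = as.integer(counts[ord]),
                    share_pct = pct_ratio(as.integer(counts[ord]), total, 1L),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  attr(out, "kind") <- kind
  class(out) <- c("freq_table", "data.frame")
  out
}

#' Acupoint usage frequencies
#'
#' For each acupoint, the number of prescriptions containing it. Shares use
#' the total number of acupoint usages as denominator (so for the CSAP
#' reference data PC6 appears 25 times out of 130 usages = 19.2%), matching
#' the convention of published acupoint-frequency tables.
#'
#' @param dataset a \code{transactions} object.
#' @return A \code{freq_table} with one row per universe item.
#' @export
#' @examples
#' head(acupoint_frequency(build_csap_fixture()))
acupoint_frequency <- function(dataset) {
  stopifnot(inherits(dataset, "transactions"))
  counts <- vapply(dataset$universe, function(code) itemset_count(dataset, code),
                   integer(1))
  frequency_table(counts, total = dataset$total_usages, kind = "acupoint")
}

#' Meridian usage frequencies
#'
#' Aggregates acupoint usage to the meridian level. Two counting modes are
#' offered because published meridian tables do not always state theirs:
#' \describe{
#'   \item{\code{usage_sum}}{frequency of a meridian = sum of the usage
#'     frequencies of its member acupoints (conserves total usages).}
#'   \item{\code{prescription_count}}{frequency = number of prescriptions
#'     using at least one acupoint of the meridian (each \eqn{\le N}).}
#' }
#' Extra-meridian points (meridian \code{"NONE"}) are reported under the row
#' \code{"extra"}. Shares are percentages of the column total at one decimal.
#'
#' @param dataset a \code{transactions} object.
#' @param registry an \code{acu_registry}; defaults to the dataset's own, or
#'   [csap_registry()].
#' @param mode \code{"usage_sum"} (default) or \code{"prescription_count"}.
#' @return A \code{freq_table} with one row per meridian in use.
#' @export
meridian_frequency <- function(dataset, registry = NULL,
                               mode = c("usage_sum", "prescription_count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "transactions"))
  registry <- registry %||% dataset$registry %||% csap_registry()
  mer <- meridian_of(dataset$universe, registry)
  mer[mer == "NONE"] <- "extra"
  if (mode == "usage_sum") {
    af <- acupoint_frequency(dataset)
    by <- mer[match(af$code, dataset$universe)]
    tmp <- tapply(af$frequency, by, sum)
    counts <- structure(as.integer(tmp), names = names(tmp))
  } else {
    groups <- split(dataset$universe, mer)
    counts <- vapply(groups, function(codes) {
      sum(vapply(dataset$prescriptions,
                 function(s) any(codes %in% s), logical(1)))
    }, integer(1))
  }
  frequency_table(counts, kind = paste0("meridian(", mode, ")"))
}

#' Write a frequency table as delimited text
#'
#' Emits the \code{code, frequency, share_pct} layout with a trailing
#' \code{Total} row.
#'
#' @param x a \code{freq_table}.
#' @param path output file path.
#' @param sep field separator, default comma.
#' @return Invisibly, \code{path}.
#' @export
write_frequency_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "freq_table"))
  df <- as.data.frame(x)
  df$code <- as.character(df$code)
  tot <- data.frame(code = "Total", frequency = sum(df$frequency),
                    share_pct = pct_ratio(sum(df$frequency), attr(x, "total"), 1L))
  utils::write.table(rbind(df, tot), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Frequency table (", attr(x, "kind"), "), total = ",
      attr(x, "total"), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
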