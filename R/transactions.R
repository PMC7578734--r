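#' Prescription transaction datasets
#'
#' A \code{transactions} object holds one record per clinical trial: the set
#' of acupoint codes that trial's prescription used. It is the unit over
#' which supports, co-occurrence counts and network edges are computed.
#'
#' @param prescriptions a named list of character vectors: one set of
#'   acupoint codes per study. Duplicates within a prescription collapse
#'   (set semantics); empty prescriptions are an error.
#' @param registry optional \code{acu_registry} used to canonicalise codes
#'   and, in strict mode, to validate them.
#' @param strict if \code{TRUE} (default when a registry is given), unknown
#'   codes are an error; if \code{FALSE}, they are auto-registered with
#'   meridian \code{"NONE"} and a warning.
#'
#' @return An object of class \code{transactions}: a list with elements
#'   \code{prescriptions} (named list of sorted character vectors),
#'   \code{universe} (codes ordered by descending frequency, ties broken
#'   lexicographically), \code{N}, \code{total_usages}, and \code{registry}.
#' @export
#' @examples
#' tx <- transactions(list(S1 = c("PC6", "LU9"), S2 = "PC6"))
#' tx$N            # 2
#' tx$total_usages # 3
transactions <- function(prescriptions, registry = NULL, strict = !is.null(registry)) {
  if (!length(prescriptions)) stop("dataset has no prescriptions")
  if (is.null(names(prescriptions)) || any(!nzchar(names(prescriptions)))) {
    stop("every prescription needs a study_id name")
  }
  if (anyDuplicated(names(prescriptions))) stop("duplicate study_id")
  prescriptions <- lapply(prescriptions, function(it) {
    it <- unique(normalize_code(as.character(it), registry))
    sort.int(it, method = "radix")
  })
  if (any(lengths(prescriptions) == 0L)) {
    stop("empty prescription(s): ",
         paste(names(prescriptions)[lengths(prescriptions) == 0L], collapse = ", "))
  }
  items <- unlist(prescriptions, use.names = FALSE)
  if (!is.null(registry)) {
    unknown <- setdiff(unique(items), registry$code)
    if (length(unknown)) {
      if (strict) {
        stop("acupoint code(s) not in registry: ", paste(unknown, collapse = ", "))
      }
      warning("auto-registering unknown code(s) with meridian NONE: ",
              paste(unknown, collapse = ", "))
      registry <- rbind(registry,
                        acu_registry(unknown, rep("NONE", length(unknown))))
      class(registry) <- c("acu_registry", "data.frame")
    }
  }
  freq <- table(items)
  # universe: descending frequency, ties lexicographic -- deterministic output
  universe <- names(freq)[order(-as.integer(freq), names(freq), method = "radix")]
  structure(list(prescriptions = prescriptions,
                 universe = universe,
                 N = length(prescriptions),
                 total_usages = length(items),
                 registry = registry),
            class = "transactions")
}

#' Load prescription transactions from a delimited text file
#'
#' Two layouts are supported. \emph{Long}: one row per acupoint usage with
#' columns \code{study_id, acupoint}. \emph{Wide}: a 0/1 incidence table
#' whose first column is \code{study_id} and whose remaining column headers
#' are acupoint codes.
#'
#' Duplicate (study, acupoint) rows collapse to a single set membership and
#' codes are normalised (trimmed, canonical case).
#'
#' @param path file path.
#' @param format \code{"long"} or \code{"wide"}.
#' @param registry,strict see [transactions()].
#' @param sep field separator, default comma.
#' @return A \code{transactions} object.
#' @export
load_transactions <- function(path, format = c("long", "wide"),
                              registry = NULL, strict = !is.null(registry),
                              sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("transaction file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = if (format == "long") "character" else NA)
  if (!nrow(df)) stop("transaction file is empty: ", path)
  if (format == "long") {
    if (ncol(df) < 2L) stop("long format needs columns study_id, acupoint")
    split_items <- split(df[[2L]], factor(df[[1L]], levels = unique(df[[1L]])))
    transactions(split_items, registry = registry, strict = strict)
  } else {
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m) || !all(m %in% c(0, 1))) {
      stop("wide-format cells must all be 0 or 1")
    }
    codes <- colnames(m)
    split_items <- lapply(seq_len(nrow(m)), function(i) codes[m[i, ] == 1])
    names(split_items) <- ids
    transactions(split_items, registry = registry, strict = strict)
  }
}

#' Write transactions to a delimited text file
#'
#' Inverse of [load_transactions()]; the long/wide round trip preserves the
#' dataset exactly (same N, universe and memberships).
#'
#' @param dataset a \code{transactions} object.
#' @param path output file path.
#' @param format \code{"long"} or \code{"wide"}.
#' @param sep field separator, default comma.
#' @return Invisibly, \code{path}.
#' @export
write_transactions <- function(dataset, path, format = c("long", "wide"), sep = ",") {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "transactions"))
  if (format == "long") {
    df <- data.frame(
      study_id = rep(names(dataset$prescriptions), lengths(dataset$prescriptions)),
      acupoint = unlist(dataset$prescriptions, use.names = FALSE))
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    m <- to_incidence_matrix(dataset)
    df <- data.frame(study_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Convert transactions to a 0/1 incidence matrix
#'
#' @param dataset a \code{transactions} object.
#' @return An integer matrix with one row per prescription (rownames =
#'   study ids) and one column per universe item (in universe order); entry
#'   (i, j) is 1 iff prescription i contains item j. Row sums are the
#'   prescription sizes and column sums the acupoint frequencies.
#' @export
to_incidence_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "transactions"))
  m <- vapply(dataset$universe,
              function(code) vapply(dataset$prescriptions,
                                    function(s) code %in% s, logical(1)),
              logical(dataset$N))
  m <- matrix(as.integer(m), nrow = dataset$N,
              dimnames = list(names(dataset$prescriptions), dataset$universe))
  m
}

# Number of prescriptions containing all of `items`.
itemset_count <- function(dataset, items) {
  items <- unique(items)
  sum(vapply(dataset$prescriptions, function(s) all(items %in% s), logical(1)))
}

#' @export
print.transactions <- function(x, ...) {
  cat("Prescription transactions: N =", x$N,
      "| items =", length(x$universe),
      "| total usages =", x$total_usages, "\n")
  cat("Top items:",
      paste(utils::head(x$universe, 5L), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.transactions <- function(object, ...) {
  sizes <- lengths(object$prescriptions)
  cat("Prescription transactions\n")
  cat("  prescriptions:", object$N, "\n")
  cat("  distinct acupoints:", length(object$universe), "\n")
  cat("  total usages:", object$total_usages, "\n")
  cat("  prescription size: min", min(sizes), "/ mean",
      round(mean(sizes), 2), "/ max", max(sizes), "\n")
  invisible(object)
}
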