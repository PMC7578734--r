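#' Apriori frequent-itemset mining
#'
#' Level-wise enumeration of all itemsets whose support (fraction of
#' prescriptions containing every item of the set) meets the floor,
#' exploiting downward closure for candidate pruning: a size-k candidate is
#' counted only if all of its size-(k-1) subsets are frequent.
#'
#' @param dataset a \code{transactions} object.
#' @param min_support_pct support floor in percent, in (0, 100].
#' @param max_size largest itemset size to enumerate.
#' @return A data frame of class \code{acu_itemsets} with columns
#'   \code{items} (codes joined by \code{","}, sorted), \code{size},
#'   \code{count} and \code{support_pct} (2 decimals, half-up), ordered by
#'   size ascending, support descending, then lexicographically.
#' @export
#' @examples
#' fx <- build_csap_fixture()
#' frequent_itemsets(fx, min_support_pct = 15, max_size = 2)
frequent_itemsets <- function(dataset, min_support_pct = 15, max_size = 3L) {
  stopifnot(inherits(dataset, "transactions"),
            min_support_pct > 0, min_support_pct <= 100, max_size >= 1L)
  N <- dataset$N
  m <- to_incidence_matrix(dataset)
  counts1 <- colSums(m)
  keep <- pct_exceeds(counts1, N, min_support_pct)
  level <- lapply(sort.int(colnames(m)[keep], method = "radix"), identity)
  lvl_counts <- vapply(level, function(s) counts1[[s]], numeric(1))
  sets <- level
  set_counts <- lvl_counts
  sizes <- rep(1L, length(level))
  k <- 1L
  while (k < max_size && length(level) > 1L) {
    k <- k + 1L
    freq_keys <- vapply(level, itemset_key, character(1))
    cand <- apriori_candidates(level, freq_keys)
    if (!length(cand)) break
    ccounts <- vapply(cand, function(s) sum(rowSums(m[, s, drop = FALSE]) == k),
                      numeric(1))
    ok <- pct_exceeds(ccounts, N, min_support_pct)
    level <- cand[ok]
    lvl_counts <- ccounts[ok]
    if (!length(level)) break
    sets <- c(sets, level)
    set_counts <- c(set_counts, lvl_counts)
    sizes <- c(sizes, rep(k, length(level)))
  }
  keys <- vapply(sets, itemset_key, character(1))
  out <- data.frame(items = keys, size = sizes, count = as.integer(set_counts),
                    support_pct = pct_ratio(as.integer(set_counts), N, 2L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$size, -out$count, out$items, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- N
  attr(out, "min_support_pct") <- min_support_pct
  class(out) <- c("acu_itemsets", "data.frame")
  out
}

# Join step: merge sorted size-(k-1) itemsets sharing their first k-2 items,
# then prune candidates having an infrequent (k-1)-subset.
apriori_candidates <- function(level, freq_keys) {
  k1 <- length(level[[1L]])
  prefixes <- vapply(level, function(s) paste(s[-k1], collapse = ","), character(1))
  cand <- list()
  for (grp in split(seq_along(level), prefixes)) {
    if (length(grp) < 2L) next
    lasts <- vapply(level[grp], function(s) s[k1], character(1))
    o <- order(lasts, method = "radix")
    grp <- grp[o]
    for (i in seq_len(length(grp) - 1L)) {
      for (j in seq((i + 1L), length(grp))) {
        c_new <- sort.int(union(level[[grp[i]]], level[[grp[j]]]), method = "radix")
        subs_ok <- all(vapply(seq_along(c_new), function(d) {
          itemset_key(c_new[-d]) %in% freq_keys
        }, logical(1)))
        if (subs_ok) cand[[length(cand) + 1L]] <- c_new
      }
    }
  }
  unique(cand)
}

#' Exact rule statistics for one antecedent/consequent pair
#'
#' Computes, from the raw transaction counts, the four standard
#' association-rule quantities: joint support \eqn{\sigma(A \cup b)/N},
#' antecedent support \eqn{\sigma(A)/N}, confidence
#' \eqn{\sigma(A \cup b)/\sigma(A)} and lift (confidence divided by the
#' consequent's support). Percentages and lift are rounded half-up to two
#' decimals from the exact rationals.
#'
#' @param A character vector: the antecedent itemset (non-empty).
#' @param b single acupoint code, not in \code{A}.
#' @param dataset a \code{transactions} object.
#' @return A list with counts (\code{n_joint}, \code{n_antecedent},
#'   \code{n_consequent}, \code{N}) and rounded statistics
#'   (\code{support_joint_pct}, \code{support_antecedent_pct},
#'   \code{confidence_pct}, \code{lift}).
#' @export
#' @examples
#' rule_statistics("ST36", "PC6", build_csap_fixture())
rule_statistics <- function(A, b, dataset) {
  stopifnot(length(A) >= 1L, length(b) == 1L)
  if (b %in% A) stop("consequent must not be part of the antecedent")
  n_a <- itemset_count(dataset, A)
  if (n_a == 0L) stop("confidence undefined: antecedent never occurs")
  n_b <- itemset_count(dataset, b)
  n_ab <- itemset_count(dataset, c(A, b))
  N <- dataset$N
  list(n_joint = n_ab, n_antecedent = n_a, n_consequent = n_b, N = N,
       support_joint_pct = pct_ratio(n_ab, N, 2L),
       support_antecedent_pct = pct_ratio(n_a, N, 2L),
       confidence_pct = pct_ratio(n_ab, n_a, 2L),
       # lift = (n_ab/n_a) / (n_b/N) = n_ab*N / (n_a*n_b), exact rational
       lift = round_half_up_ratio(n_ab * N, n_a * n_b, 2L))
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent antecedent \eqn{A} and every single consequent
#' \eqn{b \notin A} with \eqn{|A| + 1 \le} \code{max_rule_size}, emits the
#' rule \eqn{A \rightarrow b} iff its confidence meets the floor. Two
#' support-reporting conventions exist in the field and both are offered:
#' \code{"antecedent"} reports \eqn{\sigma(A)/N} (the SPSS Modeler
#' convention used in published acupoint rule tables) and \code{"joint"}
#' reports \eqn{\sigma(A \cup b)/N} (the textbook rule-support formula).
#' The convention changes only the reported support column, never which
#' rules qualify.
#'
#' @param itemsets an \code{acu_itemsets} table mined at a support floor at
#'   most the intended antecedent floor.
#' @param dataset the \code{transactions} the itemsets were mined from.
#' @param min_confidence_pct confidence floor in percent.
#' @param support_convention \code{"antecedent"} or \code{"joint"}.
#' @param max_rule_size cap on \eqn{|A| + 1}.
#' @return An object of class \code{acu_rules}; see [mine_rules()].
#' @export
generate_rules <- function(itemsets, dataset, min_confidence_pct = 80,
                           support_convention = c("antecedent", "joint"),
                           max_rule_size = 3L) {
  support_convention <- match.arg(support_convention)
  stopifnot(inherits(itemsets, "acu_itemsets"),
            inherits(dataset, "transactions"), max_rule_size >= 2L)
  N <- dataset$N
  ante <- itemsets[itemsets$size <= max_rule_size - 1L, , drop = FALSE]
  rows <- list()
  counts1 <- vapply(dataset$universe, function(i) itemset_count(dataset, i),
                    integer(1))
  for (r in seq_len(nrow(ante))) {
    A <- split_key(ante$items[r])
    n_a <- ante$count[r]
    for (b in setdiff(dataset$universe, A)) {
      n_ab <- itemset_count(dataset, c(A, b))
      if (pct_exceeds(n_ab, n_a, min_confidence_pct)) {
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = ante$items[r], consequent = b,
          antecedent_size = length(A),
          support_pct = if (support_convention == "antecedent")
            pct_ratio(n_a, N, 2L) else pct_ratio(n_ab, N, 2L),
          confidence_pct = pct_ratio(n_ab, n_a, 2L),
          lift = round_half_up_ratio(n_ab * N, n_a * counts1[[b]], 2L),
          count = n_a, joint_count = n_ab,
          stringsAsFactors = FALSE)
      }
    }
  }
  new_acu_rules(rows, dataset,
                min_support_pct = attr(itemsets, "min_support_pct"),
                min_confidence_pct = min_confidence_pct,
                support_convention = support_convention,
                max_rule_size = max_rule_size)
}

# threshold tests on exact rationals: count/denom >= pct/100
pct_exceeds <- function(num, den, pct) 100 * num >= pct * den

new_acu_rules <- function(rows, dataset, min_support_pct, min_confidence_pct,
                          support_convention, max_rule_size, method = "apriori") {
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(antecedent = character(), consequent = character(),
               antecedent_size = integer(), support_pct = numeric(),
               confidence_pct = numeric(), lift = numeric(),
               count = integer(), joint_count = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$antecedent_size, -out$support_pct, -out$confidence_pct,
                   out$antecedent, out$consequent, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            N = dataset$N,
            min_support_pct = min_support_pct,
            min_confidence_pct = min_confidence_pct,
            support_convention = support_convention,
            max_rule_size = max_rule_size,
            method = method,
            class = c("acu_rules", "data.frame"))
}

#' Mine association rules from prescription transactions
#'
#' The central miner: runs Apriori frequent-itemset search and rule
#' generation in one call with the thresholds used in the CSAP analysis as
#' defaults (minimum antecedent support 15\%, minimum confidence 80\%, rules
#' of at most 3 items, antecedent-support reporting).
#'
#' @inheritParams frequent_itemsets
#' @inheritParams generate_rules
#' @return An object of class \code{acu_rules}: a data frame with one row
#'   per rule and columns \code{antecedent} (codes joined by \code{","}),
#'   \code{consequent}, \code{antecedent_size}, \code{support_pct},
#'   \code{confidence_pct}, \code{lift}, \code{count} (antecedent
#'   frequency) and \code{joint_count}. Thresholds and the convention are
#'   stored as attributes.
#' @export
#' @examples
#' rules <- mine_rules(build_csap_fixture())
#' print(rules)
mine_rules <- function(dataset, min_support_pct = 15, min_confidence_pct = 80,
                       max_rule_size = 3L,
                       support_convention = c("antecedent", "joint")) {
  support_convention <- match.arg(support_convention)
  its <- frequent_itemsets(dataset, min_support_pct,
                           max_size = max(1L, max_rule_size - 1L))
  generate_rules(its, dataset, min_confidence_pct, support_convention,
                 max_rule_size)
}

#' Exhaustive-enumeration rule miner (oracle)
#'
#' Mines the identical rule set to [mine_rules()] by brute force: every
#' antecedent subset of the universe up to size \code{max_rule_size - 1} is
#' counted directly, with no level-wise pruning. Intended as an independent
#' correctness oracle; guarded against large universes because enumeration
#' is exponential.
#'
#' @inheritParams mine_rules
#' @param allow_large set \code{TRUE} to lift the 20-item universe guard.
#' @return An \code{acu_rules} object, ordered identically to the Apriori
#'   path's output.
#' @export
brute_force_rules <- function(dataset, min_support_pct = 15,
                              min_confidence_pct = 80, max_rule_size = 3L,
                              support_convention = c("antecedent", "joint"),
                              allow_large = FALSE) {
  support_convention <- match.arg(support_convention)
  stopifnot(inherits(dataset, "transactions"), max_rule_size >= 2L)
  if (length(dataset$universe) > 20L && !allow_large) {
    stop("universe has more than 20 items; set allow_large = TRUE to enumerate")
  }
  N <- dataset$N
  counts1 <- vapply(dataset$universe, function(i) itemset_count(dataset, i),
                    integer(1))
  items <- sort.int(dataset$universe, method = "radix")
  rows <- list()
  for (sz in seq_len(max_rule_size - 1L)) {
    if (sz > length(items)) break
    for (A in utils::combn(items, sz, simplify = FALSE)) {
      n_a <- itemset_count(dataset, A)
      if (!pct_exceeds(n_a, N, min_support_pct)) next
      for (b in setdiff(items, A)) {
        n_ab <- itemset_count(dataset, c(A, b))
        if (pct_exceeds(n_ab, n_a, min_confidence_pct)) {
          rows[[length(rows) + 1L]] <- data.frame(
            antecedent = itemset_key(A), consequent = b,
            antecedent_size = sz,
            support_pct = if (support_convention == "antecedent")
              pct_ratio(n_a, N, 2L) else pct_ratio(n_ab, N, 2L),
            confidence_pct = pct_ratio(n_ab, n_a, 2L),
            lift = round_half_up_ratio(n_ab * N, n_a * counts1[[b]], 2L),
            count = n_a, joint_count = n_ab,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  new_acu_rules(rows, dataset,
                min_support_pct = min_support_pct,
                min_confidence_pct = min_confidence_pct,
                support_convention = support_convention,
                max_rule_size = max_rule_size, method = "brute_force")
}

#' @export
print.acu_rules <- function(x, ...) {
  cat(sprintf(
    "Association rules: %d rule(s) | min support %s%% (%s convention) | min confidence %s%% | rules of <= %d items\n",
    nrow(x), attr(x, "min_support_pct"), attr(x, "support_convention"),
    attr(x, "min_confidence_pct"), attr(x, "max_rule_size")))
  if (nrow(x)) {
    shown <- data.frame(rule = paste(x$antecedent, "->", x$consequent),
                        support = sprintf("%.2f", x$support_pct),
                        confidence = sprintf("%.2f", x$confidence_pct),
                        lift = sprintf("%.2f", x$lift),
                        frequency = x$count)
    print.data.frame(shown, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.acu_rules <- function(object, ...) {
  print(object)
  if (nrow(object)) {
    cat("\nLift range:", sprintf("%.2f", min(object$lift)), "-",
        sprintf("%.2f", max(object$lift)),
        "| positively associated (lift > 1):", sum(object$lift > 1), "\n")
  }
  invisible(object)
}

#' Write a rule table as delimited text
#'
#' Emits the published rule-table layout: acupoints (antecedent then
#' consequent), support, confidence, lift, antecedent frequency.
#'
#' @param rules an \code{acu_rules} object.
#' @param path output file path.
#' @param sep field separator, default comma.
#' @return Invisibly, \code{path}.
#' @export
write_rules <- function(rules, path, sep = ",") {
  stopifnot(inherits(rules, "acu_rules"))
  df <- data.frame(
    acupoints = paste(gsub(",", " ", rules$antecedent), rules$consequent,
                      sep = ", "),
    support_pct = sprintf("%.2f", rules$support_pct),
    confidence_pct = sprintf("%.2f", rules$confidence_pct),
    lift = sprintf("%.2f", rules$lift),
    frequency = rules$count)
  # the acupoints cell contains commas, so it must be quoted
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = 1L)
  invisible(path)
}
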