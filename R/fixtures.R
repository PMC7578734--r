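# Constraint-reconstructed CSAP reference dataset.
#
# The source study mined 27 acupuncture prescriptions for chronic stable
# angina pectoris but deposited no raw data. Its printed tables nevertheless
# determine the dataset up to equivalence for every statistic this package
# computes: the acupoint-frequency table fixes all 37 marginals (summing to
# 130 usages), and each published rule row fixes a joint count via its
# antecedent frequency and confidence (e.g. LU9 -> PC6 with frequency 16 and
# confidence 93.75% forces sigma(LU9 & PC6) = 15). The dataset below is one
# satisfying assignment, frozen; verify_fixture() re-checks every constraint
# and re-mines the rules at test time.

# The 27 prescriptions. Core structure: 4 prescriptions carry
# {LU6, LU9, HT5, PC6}, one {LU6, LU9, PC6} without HT5, one {HT5, PC6}
# without LU6/LU9; LU9 joins PC6 in 15 of its 16 uses; ST36 avoids LU9
# entirely; low-frequency acupoints are spread so that no unpublished rule
# can reach the 80% confidence trigger, prescription sizes stay near the
# 130/27 ~ 4.8 average, and every acupoint except the experience point
# shares at least one prescription with the PC6 hub, keeping the co-usage
# network hub-dominated (diameter <= 3).
csap_prescription_sets <- function() {
  list(
    S01 = c("LU6", "LU9", "HT5", "PC6", "BL14", "RN17"),
    S02 = c("LU6", "LU9", "HT5", "PC6", "LI11", "RN4"),
    S03 = c("LU6", "LU9", "HT5", "PC6", "LR3", "BL20"),
    S04 = c("LU6", "LU9", "HT5", "PC6", "BL17", "KI3"),
    S05 = c("LU6", "LU9", "PC6", "ST40", "SP6"),
    S06 = c("HT5", "PC6", "RN6", "RN14"),
    S07 = c("LU9", "PC6", "BL15", "BL14", "BL17"),
    S08 = c("LU9", "PC6", "BL15", "LI11", "LR3"),
    S09 = c("LU9", "PC6", "BL15", "ST40", "RN17"),
    S10 = c("LU9", "PC6", "BL15", "RN4", "PC4"),
    S11 = c("LU9", "PC6", "HT7", "BL14", "BL23"),
    S12 = c("LU9", "PC6", "HT7", "LI11", "SP6"),
    S13 = c("LU9", "PC6", "HT7", "LR3", "KI3"),
    S14 = c("LU9", "PC6", "BL17", "ST40"),
    S15 = c("LU9", "PC6", "RN17", "LI4"),
    S16 = c("LU9", "PC6", "RN4", "PC4"),
    S17 = c("LU9", "RN6", "BL20"),
    S18 = c("ST36", "PC6", "BL15", "BL14", "RN14"),
    S19 = c("ST36", "PC6", "BL15", "LI11", "HT3"),
    S20 = c("ST36", "PC6", "BL15", "LR3", "HT4"),
    S21 = c("ST36", "PC6", "HT7", "BL17", "PC2"),
    S22 = c("ST36", "PC6", "HT7", "ST40", "PC3"),
    S23 = c("ST36", "PC6", "HT7", "RN17", "PC7"),
    S24 = c("ST36", "PC6", "BL23", "SP10", "SP8"),
    S25 = c("ST36", "PC6", "SP9", "BL13", "LU1"),
    S26 = c("PC6", "RN12", "LU7", "HT6", "HT1"),
    S27 = c("ST36", "Xiongtong")
  )
}

#' Build the reconstructed CSAP reference dataset
#'
#' Deterministically constructs the frozen 27-prescription transaction set
#' whose marginal and joint counts match every published CSAP table (37
#' acupoints, 130 total usages, and all published rule statistics). See
#' [csap_constraints()] for the constraints it satisfies and
#' [verify_fixture()] for the checker.
#'
#' This is a constraint-equivalent reconstruction, not the historical
#' prescriptions of the 27 underlying trials: any statistic this package
#' computes from it matches the published analysis, but unprinted joint
#' structure of the real data is unknowable.
#'
#' @return A \code{transactions} object with N = 27.
#' @export
#' @examples
#' fx <- build_csap_fixture()
#' fx$N             # 27
#' fx$total_usages  # 130
build_csap_fixture <- function() {
  transactions(csap_prescription_sets(), registry = csap_registry())
}

#' Published constraints on the CSAP dataset
#'
#' The constraint set the reference fixture must satisfy:
#' \describe{
#'   \item{marginals}{the 37 published acupoint frequencies (sum 130), N = 27.}
#'   \item{joints}{joint counts forced exactly by the published rule rows
#'     (antecedent frequency x confidence), e.g. sigma(LU9 & PC6) = 15,
#'     plus sigma(LU6 & LU9 & HT5) = 4 by set algebra.}
#'   \item{guards}{upper bounds keeping every unpublished rule below the 80\%
#'     confidence trigger, e.g. sigma(BL15 & LU9) <= 5 and
#'     sigma(HT7 & X) <= 4 for every X other than PC6.}
#' }
#'
#' @return A list with elements \code{N}, \code{total_usages},
#'   \code{marginals} (named integer vector), \code{joints} (list of
#'   \code{list(items, count)}) and \code{guards} (list of
#'   \code{list(items, max)}; \code{items} may contain one \code{"*"}
#'   wildcard standing for every acupoint of frequency <= 4 not otherwise
#'   named in the guard).
#' @export
csap_constraints <- function() {
  marginals <- c(
    PC6 = 25L, LU9 = 16L, ST36 = 9L, BL15 = 7L, HT7 = 6L, HT5 = 5L, LU6 = 5L,
    BL14 = 4L, LI11 = 4L, LR3 = 4L, BL17 = 4L, ST40 = 4L, RN17 = 4L,
    RN4 = 3L, BL20 = 2L, BL23 = 2L, KI3 = 2L, SP6 = 2L, RN6 = 2L, RN14 = 2L,
    PC4 = 2L, LI4 = 1L, HT1 = 1L, HT3 = 1L, HT4 = 1L, PC2 = 1L, PC3 = 1L,
    PC7 = 1L, SP10 = 1L, SP8 = 1L, SP9 = 1L, BL13 = 1L, LU1 = 1L, RN12 = 1L,
    LU7 = 1L, HT6 = 1L, Xiongtong = 1L)
  joints <- list(
    list(items = c("LU9", "PC6"), count = 15L),
    list(items = c("ST36", "PC6"), count = 8L),
    list(items = c("BL15", "PC6"), count = 7L),
    list(items = c("HT7", "PC6"), count = 6L),
    list(items = c("HT5", "PC6"), count = 5L),
    list(items = c("LU6", "PC6"), count = 5L),
    list(items = c("LU6", "LU9"), count = 5L),
    list(items = c("LU6", "HT5"), count = 4L),
    list(items = c("HT5", "LU9"), count = 4L),
    list(items = c("LU6", "LU9", "HT5"), count = 4L))
  # "*" = every acupoint with frequency <= 4 (none of which may accumulate
  # enough joint weight to seed an unpublished rule)
  guards <- list(
    list(items = c("BL15", "LU9"), max = 5L),
    list(items = c("BL15", "ST36"), max = 5L),
    list(items = c("HT7", "*"), max = 4L),
    list(items = c("HT7", "LU9"), max = 4L),
    list(items = c("HT7", "ST36"), max = 4L),
    list(items = c("HT7", "BL15"), max = 4L),
    list(items = c("HT7", "HT5"), max = 4L),
    list(items = c("HT7", "LU6"), max = 4L),
    list(items = c("ST36", "LU9"), max = 6L),
    list(items = c("ST36", "PC6", "LU9"), max = 11L),
    list(items = c("HT5", "*"), max = 3L),
    list(items = c("LU6", "*"), max = 3L),
    list(items = c("LU6", "LU9", "*"), max = 3L),
    list(items = c("LU6", "PC6", "*"), max = 3L),
    list(items = c("HT5", "PC6", "*"), max = 3L))
  list(N = 27L, total_usages = 130L, marginals = marginals,
       joints = joints, guards = guards)
}

#' Published CSAP rule table and its forced companions
#'
#' The 13 published rule rows, with the antecedent/consequent assignment
#' resolved to the statistic-consistent reading (the printed item order is
#' not a reliable encoding: some rows list the consequent first), plus the
#' three companion rules that the printed counts force above both thresholds
#' but that the published table omits. Companions carry
#' \code{in_published_table = FALSE}.
#'
#' @param include_companions include the three forced-but-unpublished rules
#'   (default \code{TRUE}).
#' @return A data frame with columns \code{antecedent} (codes joined by
#'   \code{","}), \code{consequent}, \code{support_pct},
#'   \code{confidence_pct}, \code{lift}, \code{count} and
#'   \code{in_published_table}.
#' @export
csap_reference_rules <- function(include_companions = TRUE) {
  pub <- data.frame(
    antecedent = c("LU9", "ST36", "BL15", "HT7", "LU6", "LU6", "LU6",
                   "HT5", "HT5", "LU6,LU9", "LU6,PC6", "LU6,LU9", "HT5,PC6"),
    consequent = c("PC6", "PC6", "PC6", "PC6", "HT5", "LU9", "PC6",
                   "LU9", "PC6", "HT5", "HT5", "PC6", "LU9"),
    support_pct = c(59.26, 33.33, 25.93, 22.22, rep(18.52, 9)),
    confidence_pct = c(93.75, 88.89, 100, 100, 80, 100, 100, 80, 100,
                       80, 80, 100, 80),
    lift = c(1.01, 0.96, 1.08, 1.08, 4.32, 1.69, 1.08, 1.35, 1.08,
             4.32, 4.32, 1.08, 1.35),
    count = c(16L, 9L, 7L, 6L, rep(5L, 9)),
    in_published_table = TRUE,
    stringsAsFactors = FALSE)
  comp <- data.frame(
    antecedent = c("HT5", "LU6,PC6", "HT5,PC6"),
    consequent = c("LU6", "LU9", "LU6"),
    support_pct = rep(18.52, 3),
    confidence_pct = c(80, 100, 80),
    lift = c(4.32, 1.69, 4.32),
    count = rep(5L, 3),
    in_published_table = FALSE,
    stringsAsFactors = FALSE)
  if (include_companions) rbind(pub, comp) else pub
}

#' Verify a dataset against the published CSAP constraints
#'
#' Checks every marginal, every exact joint count, every guard bound, and
#' finally re-mines the dataset at the published thresholds (15\% support,
#' 80\% confidence, rules of at most 3 items, antecedent convention) and
#' compares the mined rule set -- statistics included -- against the
#' published rows plus their forced companions. Violations are returned as
#' data, not raised.
#'
#' @param dataset a \code{transactions} object.
#' @param constraints a constraint set, defaults to [csap_constraints()].
#' @return A data frame with columns \code{type}, \code{detail},
#'   \code{expected}, \code{observed}; zero rows means the dataset satisfies
#'   every constraint.
#' @export
#' @examples
#' nrow(verify_fixture(build_csap_fixture()))  # 0
verify_fixture <- function(dataset, constraints = csap_constraints()) {
  stopifnot(inherits(dataset, "transactions"))
  bad <- list()
  flag <- function(type, detail, expected, observed) {
    bad[[length(bad) + 1L]] <<- data.frame(
      type = type, detail = detail,
      expected = as.character(expected), observed = as.character(observed),
      stringsAsFactors = FALSE)
  }
  if (dataset$N != constraints$N) {
    flag("N", "transaction count", constraints$N, dataset$N)
  }
  if (dataset$total_usages != constraints$total_usages) {
    flag("total_usages", "sum of prescription sizes",
         constraints$total_usages, dataset$total_usages)
  }
  marg <- constraints$marginals
  for (code in union(names(marg), dataset$universe)) {
    want <- if (code %in% names(marg)) marg[[code]] else 0L
    got <- itemset_count(dataset, code)
    if (want != got) flag("marginal", code, want, got)
  }
  for (j in constraints$joints) {
    got <- itemset_count(dataset, j$items)
    if (got != j$count) {
      flag("joint", itemset_key(j$items), j$count, got)
    }
  }
  low <- names(marg)[marg <= 4L]
  for (gd in constraints$guards) {
    fixed <- setdiff(gd$items, "*")
    wild <- "*" %in% gd$items
    targets <- if (wild) setdiff(low, fixed) else list(character(0))
    for (x in targets) {
      items <- c(fixed, x)
      got <- itemset_count(dataset, items)
      if (got > gd$max) {
        flag("guard", itemset_key(items), paste("<=", gd$max), got)
      }
    }
  }
  # regression: mined rules must be exactly the published rows + companions
  mined <- mine_rules(dataset, 15, 80, 3L, "antecedent")
  ref <- csap_reference_rules(include_companions = TRUE)
  key <- function(a, b) paste(a, "->", b)
  mk <- key(mined$antecedent, mined$consequent)
  rk <- key(ref$antecedent, ref$consequent)
  for (miss in setdiff(rk, mk)) flag("rule", miss, "mined", "absent")
  for (extra in setdiff(mk, rk)) flag("rule", extra, "absent", "mined")
  both <- intersect(rk, mk)
  for (k in both) {
    m <- mined[mk == k, ][1L, ]
    r <- ref[rk == k, ][1L, ]
    for (col in c("support_pct", "confidence_pct", "lift", "count")) {
      if (!isTRUE(all.equal(m[[col]], r[[col]]))) {
        flag("rule_stat", paste(k, col), r[[col]], m[[col]])
      }
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(type = character(), detail = character(),
               expected = character(), observed = character(),
               stringsAsFactors = FALSE)
}

#' Seeded random transaction generator
#'
#' Draws each acupoint into each prescription independently with its own
#' Bernoulli inclusion probability; prescriptions that come out empty are
#' re-drawn. Used for property tests (e.g. under independence the empirical
#' lift of any rule tends to 1 as the number of transactions grows).
#'
#' @param n_transactions number of prescriptions (>= 1).
#' @param item_probs named numeric vector of inclusion probabilities in
#'   [0, 1]; at least one must be positive.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A \code{transactions} object.
#' @export
#' @examples
#' rd <- random_dataset(50, c(a = 0.6, b = 0.5, c = 0.3), seed = 1)
random_dataset <- function(n_transactions, item_probs, seed) {
  stopifnot(n_transactions >= 1, length(item_probs) >= 1,
            !is.null(names(item_probs)),
            all(item_probs >= 0), all(item_probs <= 1))
  if (all(item_probs == 0)) {
    stop("all inclusion probabilities are zero; cannot draw non-empty prescriptions")
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  items <- names(item_probs)
  draw <- function() items[stats::runif(length(items)) < item_probs]
  sets <- vector("list", n_transactions)
  for (i in seq_len(n_transactions)) {
    s <- draw()
    while (!length(s)) s <- draw()
    sets[[i]] <- s
  }
  names(sets) <- sprintf("T%04d", seq_len(n_transactions))
  transactions(sets)
}
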