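test_that("rule statistics reproduce hand-computed exact rationals", {
  fx <- build_csap_fixture()
  st <- rule_statistics("ST36", "PC6", fx)
  expect_equal(st$n_joint, 8L)
  expect_equal(st$confidence_pct, 88.89)           # 8/9
  expect_equal(st$lift, 0.96)                      # (8/9)/(25/27) = 216/225
  st <- rule_statistics("BL15", "PC6", fx)
  expect_equal(st$confidence_pct, 100)
  expect_equal(st$lift, 1.08)                      # 27/25
  st <- rule_statistics("LU9", "PC6", fx)
  expect_equal(st$support_antecedent_pct, 59.26)   # 1600/27
  expect_equal(st$support_joint_pct, 55.56)        # 1500/27
  expect_equal(st$confidence_pct, 93.75)           # 15/16 exact
  expect_equal(st$lift, 1.01)                      # 405/400 = 1.0125, half-up
})

test_that("saturated items give confidence 100 and lift 1", {
  tx <- toy_tx(list(S1 = c("x", "b"), S2 = c("x", "b"), S3 = c("x", "b")))
  st <- rule_statistics("x", "b", tx)
  expect_equal(st$confidence_pct, 100)
  expect_equal(st$lift, 1)
})

test_that("undefined confidence and misuse raise errors", {
  tx <- toy_tx(list(S1 = "a", S2 = "b"))
  expect_error(rule_statistics("a", "a", tx), "antecedent")
  expect_error(rule_statistics("zz", "a", tx))
})

test_that("half-up rounding on exact rationals follows the printed grid", {
  expect_equal(round_half_up_ratio(405, 400, 2), 1.01)   # 1.0125 -> 1.01
  expect_equal(round_half_up_ratio(1600, 27, 2), 59.26)
  expect_equal(pct_ratio(15, 16, 2), 93.75)
  expect_equal(pct_ratio(25, 130, 1), 19.2)
  expect_equal(pct_ratio(16, 130, 1), 12.3)
  expect_equal(round_half_up_ratio(1, 8, 2), 0.13)       # 0.125 rounds up
  expect_equal(round_half_up_ratio(27, 16, 2), 1.69)     # 1.6875
})

test_that("frequent itemsets honour the support floor and downward closure", {
  fx <- build_csap_fixture()
  its <- frequent_itemsets(fx, 15, max_size = 2)
  keys <- its$items
  expect_true("LU9,PC6" %in% keys)
  expect_equal(its$count[keys == "LU9,PC6"], 15L)
  expect_false("HT5,LU9" %in% keys)   # count 4 = 14.8% < 15%
  # downward closure: every subset of a frequent set is frequent
  for (k in keys[its$size == 2]) {
    for (it in strsplit(k, ",")[[1]]) expect_true(it %in% keys)
  }
  its3 <- frequent_itemsets(fx, 15, max_size = 3)
  for (k in its3$items[its3$size == 3]) {
    parts <- strsplit(k, ",")[[1]]
    for (d in seq_along(parts)) {
      expect_true(paste(sort(parts[-d]), collapse = ",") %in% its3$items)
    }
  }
})

test_that("a single transaction at a tiny floor yields its powerset", {
  tx <- toy_tx(list(S1 = c("a", "b", "c", "d")))
  its <- frequent_itemsets(tx, min_support_pct = 1e-6, max_size = 4)
  expect_equal(nrow(its), 2^4 - 1)
  expect_true(all(its$count == 1L))
})

test_that("apriori equals the brute-force oracle on seeded random data", {
  for (seed in 1:12) {
    probs <- stats::setNames(rep(c(0.5, 0.3, 0.15), length.out = 10),
                             letters[1:10])
    tx <- random_dataset(30, probs, seed = seed)
    ap <- mine_rules(tx, 20, 70, 3)
    bf <- brute_force_rules(tx, 20, 70, 3)
    expect_rules_equal(ap, bf)
  }
})

test_that("the support convention changes only the reported support column", {
  fx <- build_csap_fixture()
  ant <- mine_rules(fx, 15, 80, 3, "antecedent")
  joi <- mine_rules(fx, 15, 80, 3, "joint")
  expect_equal(paste(ant$antecedent, ant$consequent),
               paste(joi$antecedent, joi$consequent))
  expect_equal(ant$confidence_pct, joi$confidence_pct)
  expect_equal(ant$lift, joi$lift)
  i <- ant$antecedent == "LU9" & ant$consequent == "PC6"
  expect_equal(ant$support_pct[i], 59.26)   # sigma(LU9)/27
  expect_equal(joi$support_pct[i], 55.56)   # sigma(LU9 & PC6)/27
  expect_error(mine_rules(fx, 15, 80, 3, "bogus"))
})

test_that("lift is symmetric for singleton-antecedent rule pairs", {
  for (seed in 1:5) {
    tx <- random_dataset(40, stats::setNames(rep(0.5, 6), letters[1:6]),
                         seed = seed)
    r <- mine_rules(tx, 5, 20, 2)
    singles <- r[r$antecedent_size == 1, ]
    for (i in seq_len(nrow(singles))) {
      j <- singles$antecedent == singles$consequent[i] &
        singles$consequent == singles$antecedent[i]
      if (any(j)) expect_equal(singles$lift[which(j)[1]], singles$lift[i])
    }
  }
})

test_that("brute-force guard rejects large universes unless overridden", {
  probs <- stats::setNames(rep(1, 21), paste0("i", 1:21))
  tx <- random_dataset(3, probs, seed = 1)
  expect_error(brute_force_rules(tx, 50, 80), "allow_large")
  expect_silent(brute_force_rules(tx, 50, 80, max_rule_size = 2L,
                                  allow_large = TRUE))
})

test_that("items present in every transaction yield only saturated rules", {
  tx <- toy_tx(list(S1 = c("a", "b", "x"), S2 = c("a", "b", "y"),
                    S3 = c("a", "b", "z")))
  r <- brute_force_rules(tx, 100, 80, max_rule_size = 2L)
  expect_setequal(paste(r$antecedent, r$consequent), c("a b", "b a"))
  expect_true(all(r$confidence_pct == 100))
})

test_that("fixture mining restricted to the core items matches the oracle", {
  fx <- build_csap_fixture()
  core <- c("PC6", "LU9", "ST36", "BL15", "HT7", "HT5", "LU6")
  sets <- lapply(fx$prescriptions, intersect, y = core)
  sets <- sets[lengths(sets) > 0]
  sub <- transactions(sets)
  ap <- mine_rules(sub, 16, 80, 3)
  bf <- brute_force_rules(sub, 16, 80, 3)
  expect_rules_equal(ap, bf)
  expect_gt(nrow(ap), 0)
})
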