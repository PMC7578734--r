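test_that("long-format loading collapses duplicates and normalises codes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_id,acupoint",
               "S1,PC6", "S1, lu9", "S2,pc6", "S1,PC6"), path)
  tx <- load_transactions(path, "long")
  expect_equal(tx$N, 2L)
  expect_setequal(tx$universe, c("PC6", "LU9"))
  expect_equal(tx$total_usages, 3L)
  expect_equal(tx$prescriptions$S1, c("LU9", "PC6"))
})

test_that("wide-format loading validates 0/1 cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_id,PC6,LU9", "S1,1,1", "S2,1,0"), path)
  tx <- load_transactions(path, "wide")
  expect_equal(unname(to_incidence_matrix(tx)[, c("PC6", "LU9")]),
               matrix(c(1L, 1L, 1L, 0L), 2))
  writeLines(c("study_id,PC6", "S1,2"), path)
  expect_error(load_transactions(path, "wide"), "0 or 1")
  writeLines("study_id,PC6", path)
  expect_error(load_transactions(path, "wide"), "empty")
})

test_that("incidence matrix encodes memberships with conserved totals", {
  tx <- toy_tx(list(S1 = c("PC6", "LU9"), S2 = "PC6"))
  m <- to_incidence_matrix(tx)
  expect_equal(m, matrix(c(1L, 1L, 1L, 0L), 2,
                         dimnames = list(c("S1", "S2"), c("PC6", "LU9"))))
  expect_equal(sum(m), tx$total_usages)
  expect_equal(unname(rowSums(m)), lengths(tx$prescriptions, use.names = FALSE))
})

test_that("long -> incidence -> wide round trip reproduces the dataset", {
  tx <- build_csap_fixture()
  wide <- withr::local_tempfile(fileext = ".csv")
  write_transactions(tx, wide, "wide")
  tx2 <- load_transactions(wide, "wide", registry = csap_registry())
  expect_equal(tx2$N, tx$N)
  expect_equal(tx2$universe, tx$universe)
  expect_equal(tx2$prescriptions, tx$prescriptions)

  long <- withr::local_tempfile(fileext = ".csv")
  write_transactions(tx, long, "long")
  tx3 <- load_transactions(long, "long")
  expect_equal(tx3$prescriptions, tx$prescriptions)
})

test_that("shipped long-format fixture matches the in-code builder", {
  path <- system.file("extdata", "csap_prescriptions.csv", package = "acumine")
  tx <- load_transactions(path, "long", registry = csap_registry())
  expect_equal(tx$N, 27L)
  expect_equal(tx$total_usages, 130L)
  expect_equal(tx$prescriptions, build_csap_fixture()$prescriptions)
})

test_that("registry covers the 37-point CSAP vocabulary with its meridian split", {
  reg <- csap_registry()
  expect_equal(nrow(reg), 37L)
  expect_equal(sum(reg$meridian == "NONE"), 1L)
  per <- table(factor(reg$meridian[reg$meridian != "NONE"],
                      levels = meridian_codes()))
  expect_equal(unname(as.integer(per)), c(5L, 4L, 6L, 2L, 6L, 5L, 2L, 1L, 4L, 1L))
})

test_that("meridian lookup resolves codes case-insensitively and flags unknowns", {
  expect_equal(meridian_of("PC6"), "PC")
  expect_equal(meridian_of(" bl15 "), "BL")
  expect_equal(meridian_of("Xiongtong"), "NONE")
  expect_error(meridian_of("ZZ99"), "not in registry")
})

test_that("strict mode rejects unknown codes, permissive auto-registers", {
  sets <- list(S1 = c("PC6", "FAKE1"))
  expect_error(transactions(sets, registry = csap_registry()), "FAKE1")
  expect_warning(tx <- transactions(sets, registry = csap_registry(),
                                    strict = FALSE), "auto-registering")
  expect_equal(meridian_of("FAKE1", tx$registry), "NONE")
})

test_that("registry file round trip preserves codes and meridians", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(csap_registry(), path)
  reg2 <- read_registry(path)
  expect_equal(reg2$code, csap_registry()$code)
  expect_equal(reg2$meridian, csap_registry()$meridian)
})
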