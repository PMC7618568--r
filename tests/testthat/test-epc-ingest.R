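# Certificate ingest: classification, deduplication, harmonisation, linkage.

test_that("keyword ruleset keeps wood a subset of solid", {
  rs <- keyword_ruleset()
  expect_true(all(rs$wood_keywords %in% rs$solid_keywords))
  custom <- keyword_ruleset(wood_keywords = c("Wood", "wood "),
                            solid_keywords = "coal")
  expect_equal(custom$wood_keywords, "wood")  # lowercased, trimmed, unique
  expect_setequal(custom$solid_keywords, c("wood", "coal"))
})

test_that("classification matches known free-text examples", {
  got <- classify_heat_source(
    c("Boiler and radiators, mains gas",
      "Room heaters, wood logs",
      "ROOM HEATERS, COAL",
      "Boiler and radiators, wood pellets",
      "Room heaters, smokeless fuel",
      ""),
    c("", "", "", "", "", ""))
  expect_equal(got$wood_fuel, c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(got$solid_fuel, c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("secondary heat text is searched and wood implies solid", {
  got <- classify_heat_source("Boiler and radiators, mains gas",
                              "Room heaters, wood logs")
  expect_true(got$wood_fuel)
  expect_true(got$solid_fuel)
  # NA text never classifies
  got_na <- classify_heat_source(NA_character_, NA_character_)
  expect_false(got_na$wood_fuel)
  expect_false(got_na$solid_fuel)
})

test_that("property: appending a wood keyword is monotone", {
  set.seed(71)
  base <- replicate(200, paste(sample(letters, 12, TRUE), collapse = ""))
  before <- classify_heat_source(base)
  after <- classify_heat_source(paste(base, "wood logs"))
  expect_true(all(after$wood_fuel))
  expect_true(all(after$solid_fuel))
  # flags never drop when text gains a keyword
  expect_true(all(after$wood_fuel >= before$wood_fuel))
})

test_that("read_epc_csv parses register headers and flags the window", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste("LMK_KEY,UPRN,INSPECTION_DATE,PROPERTY_TYPE,BUILT_FORM,TENURE,",
          "TRANSACTION_TYPE,MAINHEAT_DESCRIPTION,SECONDHEAT_DESCRIPTION",
          sep = ""),
    "K1,U1,2015-06-01,House,Detached,Owner-occupied,marketed sale,gas,None",
    "K2,U2,2005-01-01,Flat,,Rented (private),rental,gas,None",
    "K3,U3,2025-03-01,House,Mid-Terrace,Owner-occupied,marketed sale,gas,None"
  ), f)
  got <- read_epc_csv(f)
  expect_equal(got$certificate_id, c("K1", "K2", "K3"))
  expect_s3_class(got$inspection_date, "Date")
  expect_equal(got$in_window, c(TRUE, FALSE, FALSE))
  # missing column is a named error
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("LMK_KEY,UPRN", "K1,U1"), f2)
  expect_error(read_epc_csv(f2), "INSPECTION_DATE")
})

test_that("deduplication removes exact and whitespace-variant duplicates", {
  rec <- data.frame(
    certificate_id = c("A", "A", "B", "B", "C", ""),
    uprn = c("U1", "U1", "U2", "U2", "U3", "U4"),
    inspection_date = as.Date(c("2020-01-01", "2020-01-01", "2021-05-01",
                                "2022-05-01", "2020-02-02", "2020-03-03")),
    mainheat_text = c("gas boiler", "gas  boiler ", "oil", "oil", "gas", "gas"),
    stringsAsFactors = FALSE)
  got <- deduplicate_certificates(rec)
  expect_equal(sort(got$certificate_id), c("A", "B", "C"))
  # id collision with differing dates keeps the later record
  expect_equal(got$inspection_date[got$certificate_id == "B"],
               as.Date("2022-05-01"))
  expect_equal(attr(got, "n_removed"), 2L)
  expect_equal(attr(got, "n_rejected"), 1L)
  expect_equal(attr(got, "rejected")$reason, "missing certificate_id")
})

test_that("latest-certificate flag breaks ties by certificate id", {
  rec <- data.frame(
    certificate_id = c("C1", "C2", "C3", "C9", "C4"),
    uprn = c("U1", "U1", "U2", "U2", ""),
    inspection_date = as.Date(c("2020-01-01", "2021-01-01",
                                "2020-06-01", "2020-06-01", "2020-01-01")))
  got <- flag_most_recent(rec)
  expect_equal(got$is_latest, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(got$n_certificates, c(2L, 2L, 2L, 2L, 0L))
  # a missing date warns and never wins
  rec$inspection_date[2] <- NA
  expect_warning(got2 <- flag_most_recent(rec), "unparseable")
  expect_equal(got2$is_latest, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("property type harmonises to Census categories", {
  got <- harmonise_property_type(
    c("House", "Bungalow", "House", "house", "Flat", "Maisonette",
      "Park home", "House"),
    c("Detached", "Semi-Detached", "Mid-Terrace", "End-Terrace", "", "",
      "", "weird"))
  expect_equal(as.character(got),
               c("detached", "semi_detached", "terrace", "terrace", "flat",
                 "flat", "other", "other"))
})

test_that("tenure harmonises and new dwellings override tenure", {
  got <- harmonise_tenure(
    c("Owner-occupied", "Rented (private)", "Rented (social)", "",
      "Owner-occupied"),
    c("marketed sale", "rental", "rental", "marketed sale", "new dwelling"))
  expect_equal(as.character(got),
               c("owner_occupied", "rented_private", "rented_social",
                 "missing", "new_build"))
})

test_that("geography linkage is a function of UPRN", {
  rec <- data.frame(uprn = c("U1", "U2", "U9"))
  lk <- data.frame(UPRN = c("U1", "U2"), LSOA21CD = c("L1", "L2"),
                   WD22CD = c("W1", "W1"), LAD22CD = c("D1", "D1"),
                   RGN22CD = c("R1", "R1"))
  expect_message(got <- link_geography(rec, lk), "not matched")
  expect_equal(got$lsoa, c("L1", "L2", NA))
  expect_equal(attr(got, "n_unmatched"), 1L)
  lk_dup <- rbind(lk, lk[1, ])
  expect_error(link_geography(rec, lk_dup), "duplicate UPRN")
})

test_that("summarise_by_flag computes within-column percentages", {
  props <- data.frame(
    wood_fuel = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    property_type = c("detached", "flat", "detached", "flat", "flat", NA))
  got <- summarise_by_flag(props, characteristics = "property_type")
  # wood column: 1 detached + 1 flat over 2 non-missing
  wd <- got[got$flag & got$level == "detached", ]
  expect_equal(wd$count, 1)
  expect_equal(wd$pct, 50)
  # missing rows are counted but carry no percentage
  miss <- got[got$flag & got$level == "Missing", ]
  expect_equal(miss$count, 1)
  expect_true(is.na(miss$pct))
  # no-wood column: 1 detached of 3
  nd <- got[!got$flag & got$level == "detached", ]
  expect_equal(nd$pct, 100 / 3)
})

test_that("weighted summarise_by_flag equals the expanded-row version", {
  agg <- data.frame(
    wood_fuel = c(TRUE, TRUE, FALSE, FALSE),
    property_type = c("detached", "flat", "detached", "flat"),
    n = c(5, 2, 7, 11))
  expanded <- agg[rep(seq_len(nrow(agg)), agg$n), c("wood_fuel",
                                                    "property_type")]
  a <- summarise_by_flag(agg, characteristics = "property_type",
                         weights = "n")
  b <- summarise_by_flag(expanded, characteristics = "property_type")
  expect_equal(a, b)
})
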