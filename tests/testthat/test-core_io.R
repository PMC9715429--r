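test_that("taxonomy loads with 41 unique canonical taxa and merge rules", {
  tax <- foram_taxonomy()
  expect_length(tax$species, 41)
  expect_false(anyDuplicated(tax$species) > 0)
  expect_equal(unname(tax$merge_rules["Globigerinoides ruber ruber"]),
               "Globigerinoides ruber")
  expect_equal(unname(tax$merge_rules["P/D intergrade"]),
               "Neogloboquadrina incompta")
})

test_that("harmonization merges ruber morphotypes and zero-fills absences", {
  tax <- foram_taxonomy()
  ab <- matrix(c(5, 3, 2), 1,
               dimnames = list(NULL, c("Globigerinoides ruber ruber",
                                       "Globigerinoides ruber albus",
                                       "Globigerina bulloides")))
  h <- harmonize_abundance(ab, tax)
  expect_equal(ncol(h), 41)
  expect_equal(unname(h[1, "Globigerinoides ruber"]), 8)
  expect_equal(unname(h[1, "Globigerina bulloides"]), 2)
  expect_equal(sum(h), sum(ab))         # merging conserves total abundance
  expect_equal(sum(h[1, ] == 0), 39)    # unreported taxa are zero
  # idempotence: canonical columns pass through unchanged
  expect_equal(harmonize_abundance(h, tax), h)
})

test_that("unknown taxa are rejected or dropped per flag", {
  tax <- foram_taxonomy()
  ab <- matrix(c(1, 2), 1, dimnames = list(NULL, c("Globigerina bulloides",
                                                   "Notaspecies fakeus")))
  expect_error(harmonize_abundance(ab, tax), "unknown taxa")
  expect_warning(h <- harmonize_abundance(ab, tax, unknown_taxa = "drop"),
                 "dropping")
  expect_equal(sum(h), 1)
})

test_that("read_assemblage validates, harmonizes and round-trips", {
  tax <- foram_taxonomy()
  tf <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(site_id = c("A", "A"), latitude = 40, longitude = -20,
                   age_ka = c(1.2, 5.6), check.names = FALSE)
  df[["Globigerinoides ruber ruber"]] <- c(5, 0)
  df[["Globigerinoides ruber albus"]] <- c(3, 1)
  df[["Neogloboquadrina incompta"]] <- c(10, 20)
  write.csv(df, tf, row.names = FALSE)
  x <- read_assemblage(tf, tax)
  expect_equal(nrow(x), 2)
  expect_equal(x[["Globigerinoides ruber"]], c(8, 1))
  expect_equal(ncol(abundance_matrix(x)), 41)
  # round trip to identical values
  tf2 <- withr::local_tempfile(fileext = ".csv")
  write_assemblage(x, tf2)
  x2 <- read_assemblage(tf2, tax)
  expect_equal(x2, x)
  # empty table -> empty result, no error
  tf3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[0, ], tf3, row.names = FALSE)
  expect_equal(nrow(read_assemblage(tf3, tax)), 0)
})

test_that("read_assemblage rejects bad metadata, negatives and bad sums", {
  tax <- foram_taxonomy()
  tf <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(site_id = "A", latitude = 40, age_ka = 1,
                   `Globigerina bulloides` = 5, check.names = FALSE)
  write.csv(df, tf, row.names = FALSE)
  expect_error(read_assemblage(tf, tax), "missing metadata")
  df2 <- data.frame(site_id = "A", latitude = 40, longitude = 0, age_ka = 1,
                    `Globigerina bulloides` = -2, check.names = FALSE)
  write.csv(df2, tf, row.names = FALSE)
  expect_error(read_assemblage(tf, tax), "negative")
  df3 <- data.frame(site_id = "A", latitude = 40, longitude = 0, age_ka = 1,
                    `Globigerina bulloides` = 55,
                    `Neogloboquadrina incompta` = 30, check.names = FALSE)
  write.csv(df3, tf, row.names = FALSE)
  expect_error(read_assemblage(tf, tax, units = "percent"), "\\[99, 101\\]")
})

test_that("to_relative_abundance normalizes and rejects all-zero samples", {
  expect_equal(to_relative_abundance(c(2, 2, 4)), c(0.25, 0.25, 0.5))
  expect_equal(to_relative_abundance(c(1, 0, 0)), c(1, 0, 0))
  expect_error(to_relative_abundance(c(0, 0, 0)), "degenerate")
  m <- rbind(c(1, 1), c(3, 1))
  expect_equal(rowSums(to_relative_abundance(m)), c(1, 1))
})

test_that("time-window filtering uses a closed interval", {
  x <- toy_table(rbind(c(1, 1), c(1, 1), c(1, 1)), ages = c(2, 20, 25))
  expect_equal(filter_time_window(x, 19, 23)$age_ka, 20)
  x2 <- toy_table(rbind(c(1, 1), c(1, 1)), ages = c(19, 23))
  expect_equal(filter_time_window(x2, 19, 23)$age_ka, c(19, 23))
  expect_equal(nrow(filter_time_window(x[0, ], 19, 23)), 0)
  expect_error(filter_time_window(x, 23, 19), "min_age")
})

test_that("reference set pools, windows and deduplicates", {
  extra <- toy_table(matrix(1, 3, 2), site = "EXT", ages = c(19.5, 20.5, 21.5))
  series <- toy_table(matrix(1, 4, 2), site = "S1",
                      ages = c(5, 20, 22, 23.5))
  rs <- build_reference_set(series, extra, window = c(19, 23))
  expect_s3_class(rs, "reference_set")
  expect_equal(nrow(rs$samples), 5)
  # duplicates by (site_id, age) are removed
  rs2 <- build_reference_set(series, rbind(extra, series[2, ]),
                             window = c(19, 23))
  expect_equal(nrow(rs2$samples), 5)
  # window excluding everything is an error
  expect_error(build_reference_set(series[1, ], NULL, window = c(19, 23)),
               "empty reference")
  # only external samples when series misses the window
  rs3 <- build_reference_set(series[1, , drop = FALSE], extra,
                             window = c(19, 23))
  expect_equal(nrow(rs3$samples), 3)
})

test_that("split_series orders by age and rejects ties", {
  x <- rbind(toy_table(matrix(1, 3, 2), site = "B", ages = c(3, 1, 2)),
             toy_table(matrix(1, 2, 2), site = "A", ages = c(2, 1)))
  s <- split_series(x)
  expect_equal(names(s), c("A", "B"))
  expect_equal(s$B$age_ka, c(1, 2, 3))
  bad <- toy_table(matrix(1, 2, 2), ages = c(1, 1))
  expect_error(split_series(bad), "tied")
})
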