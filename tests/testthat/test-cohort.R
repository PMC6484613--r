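test_that("CSV round-trip preserves records and missingness flags", {
  co <- toy_cohort()
  co$psa[2] <- NA  # one missing PSA
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 3)
  expect_identical(is.na(back$psa), c(FALSE, TRUE, FALSE))
  expect_equal(as.data.frame(back), as.data.frame(co))
})

test_that("invariant violations are rejected with the offending row", {
  co <- as.data.frame(toy_cohort())
  bad <- co; bad$cf_time[2] <- 5; bad$death_time[2] <- 3
  expect_error(validate_cohort(bad), "cf_time exceeds death_time")
  expect_error(validate_cohort(bad), "id b")
  bad <- co; bad$death_time[1] <- 16
  expect_error(validate_cohort(bad), "15-year")
  bad <- co; bad$gleason <- as.character(bad$gleason); bad$gleason[1] <- "4"
  expect_error(validate_cohort(bad), "invalid gleason")
  bad <- co; bad$treatment[3] <- NA
  expect_error(validate_cohort(bad), "never be missing")
  bad <- co[, -2]
  expect_error(validate_cohort(bad), "missing column")
})

test_that("percentages and pooled statistics follow the printed conventions", {
  expect_equal(pct(102, 3769), 2.7)
  expect_equal(pct(1318, 3769), 35.0)
  p <- pooled_stats(means = c(59.9, 67.6), sds = c(7.3, 8.0),
                    ns = c(3769, 775))
  expect_equal(round(p$mean, 1), 61.2)
  expect_equal(round(p$sd, 1), 8.0)
  # degenerate spread
  expect_equal(pooled_stats(c(5, 5), c(0, 0), c(10, 10))$sd, 0)
})

test_that("summarize_cohort computes within-arm summaries and missing counts", {
  co <- toy_cohort()
  co$gland_volume[1] <- NA
  sm <- summarize_cohort(co)
  cont <- sm$continuous
  gv_s <- cont[cont$variable == "gland_volume" & cont$arm == "surgery", ]
  expect_equal(gv_s$n_missing, 1)
  expect_equal(gv_s$mean, 50)  # only subject c observed in the surgery arm
  out <- sm$outcomes
  expect_equal(out$cf[out$arm == "surgery"], 1)
  expect_equal(out$death_after_cf[out$arm == "surgery"], 1)
  expect_equal(sm$pooled_age$n, 3)
  # single-arm cohort of identical ages has SD 0
  one <- toy_cohort()[c(1, 1), ]
  one$id <- c("x", "y")
  expect_equal(summarize_cohort(validate_cohort(as.data.frame(one)))$pooled_age$sd, 0)
  expect_error(summarize_cohort(co[0, ]), "empty")
})

test_that("every printed descriptive percentage is reproduced from its counts", {
  fx <- read.csv(system.file("extdata", "table1_fixture.csv",
                             package = "bayesidm"))
  computed <- pct(fx$num, fx$den)
  agree <- computed == fx$printed_pct
  # two rows of the source table are arithmetically inconsistent with their
  # own printed counts (CCI 0 surgery: 2178/3759 = 57.9, printed 57.7;
  # radiotherapy deaths: 198/775 = 25.5, printed 25.6); every other row must
  # reproduce exactly
  off <- fx[!agree, ]
  expect_equal(nrow(off), 2)
  expect_equal(off$variable, c("cci", "death"))
  expect_equal(off$arm, c("surgery", "radiotherapy"))
  expect_equal(computed[!agree], c(57.9, 25.5))
  # pooled mean age from the arm summaries
  expect_equal(round(pooled_stats(c(59.9, 67.6), ns = c(3769, 775))$mean, 1),
               61.2)
})

test_that("dummy-coding partitions each categorical over a cohort", {
  g <- small_synth(n = 400)
  X <- design_matrix(g$cohort, g$spec, "t12")
  gl <- table(g$cohort$gleason)
  dn <- colSums(X[, c("gleason_7_34", "gleason_7_43", "gleason_8", "gleason_9_10")])
  expect_equal(unname(dn),
               unname(as.numeric(gl[c("7=3+4", "7=4+3", "8", "9/10")])))
  # reference count = rows with all dummies zero
  expect_equal(sum(rowSums(X[, c("gleason_7_34", "gleason_7_43",
                                 "gleason_8", "gleason_9_10")]) == 0),
               unname(as.numeric(gl["5/6"])))
})
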