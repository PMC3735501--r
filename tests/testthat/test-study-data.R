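test_that("the condition catalogue covers the full design cross", {
  cat <- default_condition_catalogue()
  expect_equal(nrow(cat), 26)  # 4 fractions x 3 doses x 2 LPS + blank + LPS

  # exactly one condition with no additions at all and no LPS
  zero <- cat$lps_ug_per_ml == 0 & cat$gos_pct == 0 & cat$fos_pct == 0 &
    cat$aos_pct == 0 & cat$glucose_mg_per_ml == 0
  expect_equal(cat$label[zero], "blank")

  gfa <- cat[cat$label == "LPS + GOS/FOS/AOS 2%", ]
  expect_equal(gfa$gos_pct, 1.5)
  expect_equal(gfa$fos_pct, 1 / 6, tolerance = 1e-4)
  expect_equal(gfa$aos_pct, 1 / 3, tolerance = 1e-4)

  ctrl <- cat[cat$label == "glucose/lactose 2%", ]
  expect_equal(ctrl$glucose_mg_per_ml, 6.222, tolerance = 1e-3)
  expect_equal(ctrl$lactose_mg_per_ml, 7.111, tolerance = 1e-3)

  # GOS/FOS dose ratio 1:9, GOS/FOS/AOS ratio 9:1:2 at every concentration
  gf <- cat[cat$fraction %in% "GOS/FOS", ]
  expect_equal(gf$fos_pct / gf$gos_pct, rep(1 / 9, nrow(gf)),
               tolerance = 1e-9)
  g3 <- cat[cat$fraction %in% "GOS/FOS/AOS", ]
  expect_equal(g3$fos_pct / g3$gos_pct, rep(1 / 9, nrow(g3)),
               tolerance = 1e-9)
  expect_equal(g3$aos_pct / g3$gos_pct, rep(2 / 9, nrow(g3)),
               tolerance = 1e-9)
})

test_that("catalogue doses agree with the formulation arithmetic", {
  cat <- default_condition_catalogue()
  comps <- default_incubation_compositions()
  for (frac in c("GOS", "GOS/FOS", "GOS/FOS/AOS")) {
    for (conc in c(0.5, 1, 2)) {
      comp <- dilute(comps[[paste(frac, "2%")]], 2 / conc)
      lbl <- paste0(frac, " ", format(conc, drop0trailing = TRUE), "%")
      row <- cat[cat$label == lbl, ]
      oligo <- function(nm) {
        if (nm %in% names(comp$oligo_mg)) comp$oligo_mg[[nm]] else 0
      }
      # % w/v columns are per-10-ml masses / 100; sugars are mass / 10 ml
      expect_equal(row$gos_pct * 100, oligo("GOS"))
      expect_equal(row$fos_pct * 100, oligo("FOS"))
      expect_equal(row$aos_pct * 100, oligo("AOS"))
      expect_equal(row$glucose_mg_per_ml * 10, comp$glucose_mg)
      expect_equal(row$lactose_mg_per_ml * 10, comp$lactose_mg)
    }
  }
})

test_that("plate CSV files round-trip and censored rows keep the censoring bound", {
  des <- study_design(n_oligo = 2, n_sugar = 1, n_viability = 0)
  wells <- simulate_dataset(des, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(wells, path)
  back <- read_plate_csv(path)
  expect_equal(back$wells$value, wells$value, tolerance = 1e-12)
  expect_equal(back$wells$below_detection, wells$below_detection)
  expect_equal(back$wells$condition, wells$condition)

  # flagged rows carry the analyte's detection limit as the bound
  cens <- back$wells$below_detection
  expect_true(any(cens))
  expect_equal(back$wells$value[cens],
               unname(detection_limits()[back$wells$analyte[cens]]))
})

test_that("plate CSV validation rejects malformed input with row numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  ok <- data.frame(horse_id = "H1", condition = "blank", analyte = "TNFa",
                   replicate = 1, value = 20, below_detection = FALSE)

  write.csv(ok, path, row.names = FALSE)
  expect_equal(nrow(read_plate_csv(path)$wells), 1)

  bad <- ok; bad$condition <- "GOS 7%"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_plate_csv(path), "GOS 7%")

  # values below the detection limit must be flagged
  bad <- ok; bad$value <- 10.0
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_plate_csv(path), "detection limit.*row")

  bad <- ok; bad$value <- -2
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_plate_csv(path), "[Nn]on-positive")

  bad <- ok; bad$analyte <- "IL6"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_plate_csv(path), "IL6")

  write.csv(ok[, -2], path, row.names = FALSE)
  expect_error(read_plate_csv(path), "missing columns")

  write.csv(ok[0, ], path, row.names = FALSE)
  expect_error(read_plate_csv(path), "no rows")
})

test_that("summary/contrast CSV reports round-trip at the reported precision", {
  summaries <- data.frame(
    condition = c("blank", "LPS"), analyte = "TNFa",
    point_estimate = c(12.649, 1749.41), lower = c(9.81, 1495.2),
    upper = c(15.7, 2050.8), stringsAsFactors = FALSE)
  contrasts <- data.frame(
    condition = "LPS", reference = "blank", analyte = "TNFa",
    percent_change = 13784L, ratio = 138.8, ratio_lower = 110.2,
    ratio_upper = 170.8, significant = TRUE, stringsAsFactors = FALSE)

  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_csv(summaries, contrasts, path)
  back <- read_summary_csv(path)
  expect_equal(back$summaries$point_estimate, c(12.6, 1749.4))
  expect_equal(back$summaries$lower, c(9.8, 1495.2))
  expect_equal(back$contrasts$percent_change, 13784)
  expect_true(back$contrasts$significant)

  # round-trip of the already-rounded values is the identity
  write_summary_csv(back$summaries, back$contrasts, path)
  again <- read_summary_csv(path)
  expect_equal(again$summaries, back$summaries)
  expect_equal(again$contrasts$ratio_lower, back$contrasts$ratio_lower)

  # empty contrast set: file holds summaries only
  write_summary_csv(summaries, NULL, path)
  expect_equal(nrow(read_summary_csv(path)$contrasts), 0)
  expect_error(write_summary_csv(summaries[0, ], NULL, path), "non-empty")
})
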