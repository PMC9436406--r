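slice_df <- function(classes, kinds, values, slice = "s1",
                     culture = "DT1", condition = "control_72h") {
  data.frame(culture_id = culture, slice_id = slice, replicate = 1L,
             condition = condition, annotation_class = classes,
             measure_kind = kinds, value = values, stringsAsFactors = FALSE)
}

test_that("morphology classes map to viable and damaged groups", {
  expect_equal(classify_group("flat"), "viable")
  expect_equal(classify_group(c("cubic", "cylindrical", "clear")),
               rep("viable", 3))
  expect_equal(classify_group(c("swollen", "necro_apoptotic")),
               rep("damaged", 2))
  expect_error(classify_group("perimeter"), "not an outgrowth morphology")
  expect_error(morphology_grouping(viable_weight = 0), "positive")
})

test_that("tumor viability index evaluates its weighted sum and stays in bounds", {
  expect_equal(tumor_viability_index(100, 0), 300)
  expect_equal(tumor_viability_index(0, 0), 0)
  expect_equal(tumor_viability_index(50, 10), 160)
  expect_error(tumor_viability_index(-1, 0), ">= 0")

  set.seed(99)
  v <- runif(500, 0, 60)
  d <- runif(500, 0, 40)
  tvi <- tumor_viability_index(v, d)
  out <- v + d
  expect_true(all(tvi >= out - 1e-12))
  expect_true(all(tvi <= 3 * out + 1e-12))
  # linearity and pure-group limits
  expect_equal(tumor_viability_index(v + 1, d + 2),
               tvi + tumor_viability_index(1, 2))
  expect_equal(tumor_viability_index(0, d), d)
  expect_equal(tumor_viability_index(v, 0), 3 * v)
})

test_that("outgrowth-mode slice readouts follow their definitions", {
  rec <- slice_df(c("perimeter", "flat", "swollen"),
                  c("perimeter", "length", "length"),
                  c(10000, 2000, 1000))
  r <- slice_readouts(rec)
  expect_equal(r$mode, "outgrowth")
  expect_equal(r$outgrowth_pct, 30)
  expect_equal(r$viable_len_pct, 20)
  expect_equal(r$damaged_len_pct, 10)
  expect_equal(r$tvi, 70)
  expect_equal(r$viability_pct, 100 * 20 / 30)
  expect_equal(r$outgrowth_pct, r$viable_len_pct + r$damaged_len_pct,
               tolerance = 1e-9)
})

test_that("area-mode and degenerate slices are handled per policy", {
  area <- slice_df(c("tumor_viable_area", "tumor_damaged_area"),
                   c("area", "area"), c(9000, 1000))
  r <- slice_readouts(area)
  expect_equal(r$mode, "area")
  expect_equal(r$viability_pct, 90)
  expect_true(is.na(r$tvi))
  expect_true(is.na(r$outgrowth_pct))

  bare <- slice_df("perimeter", "perimeter", 10000)
  expect_warning(r0 <- slice_readouts(bare), "no outgrowth")
  expect_equal(r0$outgrowth_pct, 0)
  expect_equal(r0$tvi, 0)
  expect_true(is.na(r0$viability_pct))

  two_perims <- slice_df(c("perimeter", "perimeter"),
                         c("perimeter", "perimeter"), c(100, 100))
  expect_error(slice_readouts(two_perims), "one perimeter")
})

test_that("duplicate annotations of one class on a slice are summed", {
  rec <- slice_df(c("perimeter", "flat", "flat", "swollen"),
                  c("perimeter", "length", "length", "length"),
                  c(10000, 1500, 500, 1000))
  r <- slice_readouts(rec)
  expect_equal(r$viable_len_pct, 20)
  expect_equal(r$tvi, 70)
})

test_that("readouts are invariant to record order", {
  rec <- slice_df(c("perimeter", "flat", "cubic", "swollen", "necro_apoptotic"),
                  c("perimeter", rep("length", 4)),
                  c(8000, 1000, 500, 700, 300))
  base <- slice_readouts(rec)
  set.seed(2)
  for (i in 1:5) {
    perm <- slice_readouts(rec[sample(nrow(rec)), ])
    expect_equal(perm, base)
  }
})

test_that("duplicate averaging uses the arithmetic mean, skipping missing values", {
  ro <- rbind(
    cbind(slice_readouts(slice_df(c("perimeter", "flat"), c("perimeter", "length"),
                                  c(100, 40), slice = "s1"))),
    cbind(slice_readouts(slice_df(c("perimeter", "flat", "swollen"),
                                  c("perimeter", "length", "length"),
                                  c(100, 30, 30), slice = "s2")))
  )
  avg <- average_duplicates(ro)
  expect_equal(nrow(avg), 1)
  expect_equal(avg$n_slices, 2)
  expect_equal(avg$outgrowth_pct, mean(c(40, 60)))
  expect_equal(avg$viability_pct, mean(c(100, 50)))  # both defined here

  # one slice with undefined viability: mean over the remaining one
  suppressWarnings({
    ro2 <- rbind(
      slice_readouts(slice_df("perimeter", "perimeter", 100, slice = "s1")),
      slice_readouts(slice_df(c("perimeter", "flat"), c("perimeter", "length"),
                              c(100, 40), slice = "s2"))
    )
  })
  avg2 <- average_duplicates(ro2)
  expect_equal(avg2$viability_pct, 100)
  expect_equal(avg2$n_slices, 2)

  single <- average_duplicates(ro[1, ])
  expect_equal(single$n_slices, 1)
  expect_equal(single$outgrowth_pct, 40)
})

test_that("cohort matrices carry per-condition and pooled medians", {
  summaries <- data.frame(
    culture_id = rep(c("DT1", "DT2"), each = 2),
    condition = rep(c("control_72h", "se15"), 2),
    mode = "outgrowth",
    viability_pct = c(80, 20, 60, 10),
    outgrowth_pct = c(50, 30, 40, 20),
    tvi = c(200, 50, 150, 30), n_slices = 2,
    stringsAsFactors = FALSE
  )
  cm <- cohort_matrix(summaries, "viability_pct",
                      conditions = c("control_72h", "se15"))
  expect_equal(dim(cm$matrix), c(2, 2))
  expect_equal(unname(cm$condition_medians), c(70, 15))
  expect_equal(cm$pooled_selenite_median, 15)

  # missing cell: median over the remaining culture
  cm2 <- cohort_matrix(summaries[-2, ], "viability_pct",
                       conditions = c("control_72h", "se15"))
  expect_true(is.na(cm2$matrix["DT1", "se15"]))
  expect_equal(unname(cm2$condition_medians["se15"]), 10)

  # identical values everywhere: every median equals that value
  flat <- summaries
  flat$tvi <- 100
  cm3 <- cohort_matrix(flat, "tvi", conditions = c("control_72h", "se15"),
                       selenite_conditions = "se15")
  expect_true(all(cm3$condition_medians == 100))
  expect_equal(cm3$pooled_selenite_median, 100)

  expect_error(cohort_matrix(summaries, "nope"), "unknown readout")
})

test_that("Evans grades follow the banded damage scale", {
  expect_equal(evans_grade(95), "III")
  expect_equal(evans_grade(100), "IV")
  expect_equal(evans_grade(5), "I")
  expect_equal(evans_grade(c(0, 9.99, 10, 50, 50.01, 90, 90.01, 99.99)),
               c("I", "I", "IIa", "IIa", "IIb", "IIb", "III", "III"))
  expect_error(evans_grade(101), "0, 100")
  expect_error(evans_grade(-1), "0, 100")
})

test_that("noise-free synthetic readouts recover ground-truth viability exactly", {
  cfg <- synthetic_config(noise_sd = 0, seed = 17)
  cohort <- generate_cohort(cfg)
  ro <- quantify_slices(cohort$annotations)
  avg <- average_duplicates(ro)
  merged <- merge(avg, cohort$truth, by = c("culture_id", "condition"))
  expect_equal(merged$viability_pct, 100 * merged$viable_frac, tolerance = 1e-9)
  out_mode <- merged[merged$mode.x == "outgrowth", ]
  expect_equal(out_mode$outgrowth_pct, 100 * out_mode$outgrowth_frac,
               tolerance = 1e-9)
})
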