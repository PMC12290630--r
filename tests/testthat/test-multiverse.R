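test_that("the restricted grid has 240 pipelines, the full grid 360", {
  p <- enumerate_pipelines()
  expect_equal(nrow(p), 240L)
  expect_equal(anyDuplicated(p$pipeline), 0L)
  expect_equal(length(unique(p$fwhm)), 5L)
  expect_equal(length(unique(p$motion)), 4L)
  expect_equal(length(unique(p$model)), 3L)
  expect_equal(length(unique(p$contrast)), 4L)

  pf <- enumerate_pipelines(full_motion_grid = TRUE)
  expect_equal(nrow(pf), 360L)
  expect_equal(anyDuplicated(pf$pipeline), 0L)
  # enumeration order is deterministic
  expect_identical(p, enumerate_pipelines())
})

make_records <- function(values_by_sample, pipelines = enumerate_pipelines()) {
  do.call(rbind, lapply(names(values_by_sample), function(s) {
    data.frame(sample_id = s,
               pipelines[, c("fwhm", "motion", "model", "contrast")],
               statistic = "median_icc", value = values_by_sample[[s]],
               stringsAsFactors = FALSE)
  }))
}

test_that("curve ordering is ascending with stable tie-breaks", {
  p <- enumerate_pipelines()[1:3, ]
  recs <- data.frame(sample_id = "s1", p[, c("fwhm", "motion", "model", "contrast")],
                     statistic = "median_icc", value = c(0.3, 0.1, 0.2))
  sc <- build_specification_curve(recs)
  expect_equal(sc$curve$estimate, c(0.1, 0.2, 0.3))
  # ties broken lexicographically by pipeline label => reproducible order
  recs$value <- 0.2
  sc2 <- build_specification_curve(recs)
  expect_equal(sc2$curve$pipeline, sort(p$pipeline))
})

test_that("significance classes follow the interval-vs-null rule", {
  p <- enumerate_pipelines()[1:3, c("fwhm", "motion", "model", "contrast")]
  # three samples tuned to give intervals spanning, above and below zero
  mk <- function(vals) do.call(rbind, lapply(seq_along(vals), function(i) {
    data.frame(sample_id = paste0("s", i), p, statistic = "median_icc",
               value = vals[[i]], stringsAsFactors = FALSE)
  }))
  recs <- mk(list(c(-0.05, 0.10, -0.10), c(0.00, 0.11, -0.11),
                  c(0.05, 0.12, -0.12)))
  sc <- build_specification_curve(recs)
  byp <- setNames(sc$curve$significance_class, sc$curve$pipeline)
  lab <- relimap:::pipeline_label(p)
  expect_equal(unname(byp[lab[1]]), "null_gray")      # interval spans 0
  expect_equal(unname(byp[lab[2]]), "positive_blue")  # all positive
  expect_equal(unname(byp[lab[3]]), "negative_red")   # all negative
})

test_that("single-sample intervals degenerate to the point estimate", {
  sc <- build_specification_curve(make_records(list(s1 = runif(240))))
  expect_equal(sc$curve$lower, sc$curve$estimate)
  expect_equal(sc$curve$upper, sc$curve$estimate)
  expect_equal(nrow(sc$curve), 240L)
  expect_equal(sc$curve$rank, 1:240)
})

test_that("across-sample interval is the t-based mean interval", {
  set.seed(12)
  vals <- list(s1 = runif(240), s2 = runif(240), s3 = runif(240))
  sc <- build_specification_curve(make_records(vals))
  # check one pipeline against a direct computation
  p1 <- sc$curve$pipeline[1]
  recs <- make_records(vals)
  v <- recs$value[relimap:::pipeline_label(recs) == p1]
  se <- sd(v) / sqrt(3)
  row <- sc$curve[sc$curve$pipeline == p1, ]
  expect_equal(row$estimate, mean(v))
  expect_equal(row$lower, mean(v) - qt(0.975, 2) * se)
  expect_equal(row$upper, mean(v) + qt(0.975, 2) * se)
})

test_that("unknown option vocabulary and mixed statistics are rejected", {
  recs <- make_records(list(s1 = runif(240)))
  bad <- recs
  bad$fwhm[1] <- "9.9"
  expect_error(build_specification_curve(bad), "unknown analytic option")
  mixed <- recs
  mixed$statistic[1] <- "median_bs"
  expect_error(build_specification_curve(mixed), "one curve per statistic")
})

test_that("decision panel marks exactly one option per category", {
  sc <- build_specification_curve(make_records(list(s1 = runif(240))))
  expect_equal(nrow(sc$panel), 240L)
  expect_true(all(rowSums(sc$panel) == 4L))  # one level from each category
  expect_equal(rownames(sc$panel), sc$curve$pipeline)
})

test_that("multiverse summaries agree with masked_median per mask", {
  tb <- simulate_dataset(simulation_spec(n_subjects = 20, grid_dims = c(4, 4, 4),
                                         seed = 9))
  maps <- voxelwise_icc(tb$volumes, tb$mask, "icc_3")
  opts <- enumerate_pipelines()[1:2, ]
  recs <- summarize_multiverse(list(maps, maps), opts,
                               tb$supra_mask, tb$sub_mask, sample_id = "sim")
  expect_equal(nrow(recs), 2L * 2L * 3L)  # 2 pipelines x 2 masks x 3 statistics
  supra_icc <- recs$value[recs$mask == "supra" & recs$statistic == "median_icc"][1]
  expect_equal(supra_icc, masked_median(maps$estimate, tb$supra_mask))
  sub_ws <- recs$value[recs$mask == "sub" & recs$statistic == "median_ws"][1]
  expect_equal(sub_ws, masked_median(maps$within_subject_var, tb$sub_mask))
  # overlapping masks are an error
  expect_error(summarize_multiverse(list(maps, maps), opts,
                                    tb$supra_mask, tb$supra_mask),
               "overlap")
})
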