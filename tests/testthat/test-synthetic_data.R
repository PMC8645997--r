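test_that("generated cohorts honour the design ranges and counts", {
  m <- population_model()
  d <- study_design()
  dat <- generate_cohort(d, m, seed = 1)
  expect_s3_class(dat, "pk_dataset")
  expect_equal(length(unique(dat$ID)), 26)
  cov <- unique(dat[, c("ID", "TBW", "BMI", "HT", "AGE")])
  expect_true(all(cov$TBW >= 75 & cov$TBW <= 125))
  expect_true(all(cov$BMI >= 30.04 & cov$BMI <= 40.35))
  expect_true(all(cov$AGE >= 18 & cov$AGE <= 83))
  # 10 rich subjects x 7 samples + 16 sparse x 2 samples
  expect_equal(sum(dat$EVID == 0), 10 * 7 + 16 * 2)
  obs_t <- dat$TIME[dat$EVID == 0]
  expect_true(all(obs_t >= 72 & obs_t <= 80))
  # dose rows are 1-h infusions from the bedside policy
  dose <- dat[dat$EVID == 1, ]
  expect_true(all(dose$AMT / dose$RATE == 1))
  expect_true(all(dose$AMT[dose$TIME == 0] %in% c(100, 150, 200)))
  expect_true(all(dose$AMT[dose$TIME > 0] %in% c(50, 75, 100)))
})

test_that("cohort generation is deterministic under a fixed seed", {
  m <- population_model(); d <- study_design()
  a <- generate_cohort(d, m, seed = 123)
  b <- generate_cohort(d, m, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("per-subject rich sample counts of 4-7 are supported", {
  m <- population_model()
  d <- study_design(rich_n_sampler = function() sample(4:7, 1))
  dat <- generate_cohort(d, m, seed = 4)
  counts <- table(dat$ID[dat$EVID == 0])
  expect_true(all(counts %in% c(2, 4:7)))
  rich <- counts[counts > 2]
  expect_equal(length(rich), 10)
})

test_that("covariate marginals centre on the published medians", {
  m <- population_model(); d <- study_design()
  meds <- vapply(1:200, function(s) {
    dat <- generate_cohort(d, m, seed = 1000 + s)
    median(unique(dat[, c("ID", "TBW")])$TBW)
  }, 0)
  expect_gt(median(meds), 85)
  expect_lt(median(meds), 95)
})

test_that("LLOQ censoring flags exactly the sub-LLOQ rows", {
  m <- population_model(); d <- study_design(lloq = 0)
  dat <- generate_cohort(d, m, seed = 9)
  expect_equal(attr(dat, "n_blq"), 0L)
  dv <- dat$DV[dat$EVID == 0]
  lloq <- quantile(dv, 0.3, names = FALSE) # force a mixed censoring outcome
  cen <- censor_lloq(dat, lloq)
  expect_equal(attr(cen, "n_blq"), sum(dv < lloq))
  expect_true(all(is.na(cen$DV[cen$BLQ == 1])))
  expect_true(all(cen$MDV[cen$BLQ == 1] == 1))
  all_gone <- censor_lloq(dat, 1e9)
  expect_equal(attr(all_gone, "n_blq"), sum(dat$EVID == 0))
  # a high-dose, noise-free cohort never goes below a 0.25 mg/L LLOQ
  m0 <- population_model(omega2 = c(CL = 0, V2 = 0, Q = 0), sigma = 1e-9)
  d0 <- study_design(loading_choices = 200, maintenance_choices = 100,
                     lloq = 0.25)
  dat0 <- generate_cohort(d0, m0, seed = 2)
  expect_equal(attr(dat0, "n_blq"), 0L)
})
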