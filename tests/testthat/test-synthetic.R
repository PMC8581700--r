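test_that("synthesis is bit-reproducible and respects its spec", {
  sp <- voice_spec(160, 1, 3, 15, pause_schedule = rbind(c(1, 0.4),
                                                         c(0.8, 0)),
                   seed = 99)
  r1 <- synthesize_voice(sp)
  r2 <- synthesize_voice(sp)
  expect_identical(r1$samples, r2$samples)
  expect_equal(length(r1$samples), round(2.2 * 16000))
  expect_error(
    synthesize_voice(voice_spec(160, formants_hz = c(500, 9000),
                                formant_bandwidths_hz = c(80, 120),
                                pause_schedule = cbind(1, 0))),
    "resonator")
  expect_error(voice_spec(30), "f0")
})

test_that("the generated cohort matches the study composition", {
  cfg <- cohort_sim_config(duration_s = 2)
  gen <- generate_cohort(cfg, seed = 3)
  co <- gen$cohort
  expect_equal(attr(co, "n"), 141)
  expect_equal(attr(co, "n_female"), 92)
  expect_equal(attr(co, "n_male"), 49)
  expect_lt(abs(mean(co$mmse) - 24), 1)
  # every score valid and factorable as frequency x severity
  valid <- sort(unique(c(0, as.vector(outer(1:4, 1:3)))))
  scores <- c(co$npi_apathy, co$npi_depression, co$npi_anxiety)
  expect_true(all(scores %in% valid))
  # low-severity regime: zeros common, scores rarely above four
  expect_gt(mean(scores == 0), 0.35)
  expect_lt(mean(scores > 4), 0.25)
  # two voice specs per subject, deterministic under the master seed
  expect_length(gen$specs, 2 * 141)
  gen2 <- generate_cohort(cfg, seed = 3)
  expect_identical(gen$latents, gen2$latents)
  expect_identical(as.data.frame(gen$cohort), as.data.frame(gen2$cohort))
})

test_that("gendered base voices and schedules behave as configured", {
  gen <- generate_cohort(cohort_sim_config(n_female = 30, n_male = 30,
                                           duration_s = 8), seed = 7)
  lat <- gen$latents[gen$latents$task == "positive", ]
  expect_gt(mean(lat$f0_hz[lat$gender == "female"]),
            mean(lat$f0_hz[lat$gender == "male"]) + 30)
  # schedules realize their target speech ratio
  ratios <- vapply(gen$specs[1:20], function(sp) {
    sum(sp$pause_schedule[, 1]) / sum(sp$pause_schedule)
  }, numeric(1))
  targets <- gen$latents$speech_ratio_actual[
    match(names(gen$specs)[1:20],
          paste(gen$latents$subject_id, gen$latents$task, sep = "."))]
  expect_lt(max(abs(ratios - targets)), 0.08)
})

test_that("a null effect table leaves parameters unlinked to symptoms", {
  rhos <- vapply(1:10, function(s) {
    gen <- generate_cohort(cohort_sim_config(duration_s = 1), seed = 400 + s)
    lat <- gen$latents[gen$latents$task == "positive", ]
    co <- gen$cohort
    m <- match(lat$subject_id, co$subject_id)
    cor(lat$jitter_pct, co$npi_anxiety[m], method = "spearman")
  }, numeric(1))
  expect_true(all(abs(rhos) <= 0.25))
  expect_lt(abs(mean(rhos)), 0.08)
})

test_that("planted effects calibrate to their target rank correlation", {
  cfg <- cohort_sim_config(
    n_female = 2000, n_male = 0, duration_s = 1,
    effect_table = data.frame(subscale = "apathy",
                              parameter = "speech_ratio", rho = -0.4))
  lat_rho <- vapply(1:8, function(s) {
    gen <- generate_cohort(cfg, seed = 500 + s)
    lat <- gen$latents[gen$latents$task == "positive", ]
    co <- gen$cohort
    cor(lat$speech_ratio, co$npi_apathy[match(lat$subject_id,
                                              co$subject_id)],
        method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(lat_rho) - (-0.4)), 0.03)

  # at the study size, the realized (clamped) parameters stay within 0.1
  cfg2 <- cohort_sim_config(
    duration_s = 1,
    effect_table = data.frame(subscale = "apathy",
                              parameter = "speech_ratio", rho = -0.4))
  act_rho <- vapply(1:10, function(s) {
    gen <- generate_cohort(cfg2, seed = 600 + s)
    lat <- gen$latents[gen$latents$task == "positive", ]
    co <- gen$cohort
    cor(lat$speech_ratio_actual,
        co$npi_apathy[match(lat$subject_id, co$subject_id)],
        method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(act_rho) - (-0.4)), 0.1)
})

test_that("gender- and task-restricted effects stay in their stratum", {
  cfg <- default_paper_scenario(duration_s = 1)
  gen <- generate_cohort(cohort_sim_config(
    n_female = 400, n_male = 400, duration_s = 1,
    effect_table = cfg$effect_table), seed = 12)
  co <- gen$cohort
  rho_of <- function(gender, task) {
    lat <- gen$latents[gen$latents$task == task &
                         gen$latents$gender == gender, ]
    cor(lat$f0_hz, co$npi_anxiety[match(lat$subject_id, co$subject_id)],
        method = "spearman")
  }
  expect_gt(rho_of("female", "negative"), 0.2)
  expect_lt(abs(rho_of("female", "positive")), 0.12)
  expect_lt(abs(rho_of("male", "negative")), 0.12)
})

test_that("configuration errors are caught early", {
  expect_error(cohort_sim_config(
    effect_table = data.frame(subscale = "apathy", parameter = "volume",
                              rho = 0.3)), "unknown acoustic parameter")
  expect_error(cohort_sim_config(npi_zero_inflation = 1.4))
})
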