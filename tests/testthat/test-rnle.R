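test_that("load constant follows the sex/age grid and rejects bad input", {
  expect_equal(rnle_load_constant("male", "under45"), 25)
  expect_equal(rnle_load_constant("male", "over45"), 20)
  expect_equal(rnle_load_constant("female", "under45"), 20)
  expect_equal(rnle_load_constant("female", "over45"), 15)
  expect_error(rnle_load_constant("child", "under45"), "male")
  expect_error(rnle_load_constant("male", "middle"), "under45")
})

base_task <- function(...) {
  args <- utils::modifyList(
    list(sex = "male", age_band = "under45", load_kg = 10,
         horizontal_cm = 40, vertical_origin_cm = 70, vertical_dest_cm = 120,
         asymmetry_deg = 0, lifts_per_min = 4, duration_category = "short",
         coupling = "good"),
    list(...)
  )
  do.call(rnle_task, args)
}

test_that("individual multipliers match their defining formulas", {
  m <- rnle_multipliers(base_task(horizontal_cm = 25))
  expect_equal(m$hm, 1.0)
  expect_equal(rnle_multipliers(base_task(horizontal_cm = 40))$hm, 0.625)
  expect_equal(rnle_multipliers(base_task(horizontal_cm = 20))$hm, 1.0)  # floor
  expect_equal(rnle_multipliers(base_task(horizontal_cm = 64))$hm, 0)    # envelope
  expect_equal(rnle_multipliers(base_task(vertical_origin_cm = 75))$vm, 1.0)
  expect_equal(rnle_multipliers(base_task(vertical_origin_cm = 70))$vm, 0.985)
  expect_equal(rnle_multipliers(base_task(vertical_origin_cm = 176))$vm, 0)
  # displacement: 50 cm -> 0.91; equal heights -> floor at 1
  expect_equal(rnle_multipliers(base_task())$dm, 0.82 + 4.5 / 50)
  expect_equal(rnle_multipliers(base_task(vertical_dest_cm = 70))$dm, 1.0)
  expect_equal(rnle_multipliers(base_task(vertical_dest_cm = 70 + 180))$dm, 0)
  expect_equal(rnle_multipliers(base_task(asymmetry_deg = 90))$am, 1 - 0.0032 * 90)
  expect_equal(rnle_multipliers(base_task(asymmetry_deg = 140))$am, 0)
})

test_that("frequency and coupling lookups use the embedded tables", {
  m <- rnle_multipliers(base_task())  # 4/min, short, V0 = 70 < 75, good
  expect_equal(m$fm, 0.84)
  expect_equal(m$gm, 1.00)
  expect_equal(rnle_multipliers(base_task(coupling = "fair"))$gm, 0.95)
  expect_equal(
    rnle_multipliers(base_task(coupling = "fair", vertical_origin_cm = 80))$gm, 1.00)
  expect_equal(rnle_multipliers(base_task(coupling = "poor"))$gm, 0.90)
  expect_equal(rnle_multipliers(base_task(lifts_per_min = 16))$fm, 0)
  # intermediate frequency rounds up to the next tabulated row
  expect_equal(rnle_multipliers(base_task(lifts_per_min = 3.2))$fm, 0.84)
  expect_equal(
    rnle_multipliers(base_task(lifts_per_min = 9, duration_category = "long"))$fm, 0)
  expect_equal(
    rnle_multipliers(base_task(lifts_per_min = 9, duration_category = "long",
                               vertical_origin_cm = 80))$fm, 0.15)
})

test_that("an identity configuration returns RWL = LC and LI = load/LC", {
  # H at the floor, V at 75, no displacement/asymmetry, slow short good lift
  t <- base_task(load_kg = 25, horizontal_cm = 25, vertical_origin_cm = 75,
                 vertical_dest_cm = 75, lifts_per_min = 0.2)
  r <- rnle_assess(t)
  expect_equal(r$rwl_kg, 25)
  expect_equal(r$li, 1.0)
  expect_equal(r$risk_class, "RISK")  # boundary convention: LI == 1 is RISK
})

test_that("the study's light-load configuration recomputes to LI ~ 0.55", {
  # 6.5 kg, H 40 cm, V 70 -> 120 cm, 4/min: hm .625, vm .985, dm .91, fm .84
  r <- rnle_assess(base_task(load_kg = 6.5))
  expect_equal(r$rwl_kg, 25 * 0.625 * 0.985 * 0.91 * 1 * 0.84 * 1)
  expect_equal(r$li, 6.5 / r$rwl_kg)
  expect_lt(abs(r$li - 0.5525), 0.0001)
  expect_equal(r$risk_class, "NO_RISK")
})

test_that("zero RWL yields an infinite-risk flag, not a number", {
  r <- rnle_assess(base_task(horizontal_cm = 70))  # beyond the 63 cm envelope
  expect_equal(r$rwl_kg, 0)
  expect_false(r$li_defined)
  expect_equal(r$li, Inf)
  expect_equal(r$risk_class, "RISK")
})

test_that("risk classification follows the LI < 1 rule with a conservative boundary", {
  expect_equal(classify_risk(c(0.57, 1.64, 1.0)), c("NO_RISK", "RISK", "RISK"))
  expect_error(classify_risk(-0.1), "non-negative")
})

test_that("multiplier bounds and monotonicity hold on random tasks", {
  set.seed(42)
  n <- 1000
  tasks <- tibble::tibble(
    sex = sample(c("male", "female"), n, TRUE),
    age_band = sample(c("under45", "over45"), n, TRUE),
    load_kg = runif(n, 0.5, 30),
    horizontal_cm = runif(n, 10, 80),
    vertical_origin_cm = runif(n, 0, 180),
    vertical_dest_cm = runif(n, 0, 180),
    asymmetry_deg = runif(n, 0, 150),
    lifts_per_min = runif(n, 0.2, 16),
    duration_category = sample(c("short", "medium", "long"), n, TRUE),
    coupling = sample(c("good", "fair", "poor"), n, TRUE)
  )
  r <- rnle_assess(tasks)
  for (m in c("hm", "vm", "dm", "am", "fm", "gm")) {
    expect_true(all(r[[m]] >= 0 & r[[m]] <= 1), info = m)
  }
  expect_true(all(r$rwl_kg <= r$lc_kg + 1e-12))
  expect_equal(r$rwl_kg,
               r$lc_kg * r$hm * r$vm * r$dm * r$am * r$fm * r$gm)
  # classification round-trip
  expect_equal(r$risk_class, ifelse(r$li < 1, "NO_RISK", "RISK"))
  # rwl non-increasing in H; li strictly increasing in load
  worse <- rnle_assess(dplyr::mutate(tasks, horizontal_cm = horizontal_cm + 5))
  expect_true(all(worse$rwl_kg <= r$rwl_kg + 1e-12))
  heavier <- rnle_assess(dplyr::mutate(tasks, load_kg = load_kg + 1))
  defined <- r$li_defined
  expect_true(all(heavier$li[defined] > r$li[defined]))
})

test_that("task validation rejects out-of-domain values", {
  expect_error(base_task(load_kg = 0), "load_kg")
  expect_error(base_task(lifts_per_min = -1), "lifts_per_min")
  expect_error(base_task(horizontal_cm = -5), "horizontal_cm")
  expect_error(base_task(coupling = "slippery"), "coupling")
})
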