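test_that("outlier rules clamp, exclude and pass through as specified", {
  out <- data.frame(patient_id = c(1, 2), outcome = c(0, 1))
  recs <- make_records(
    patient_id = c(1, 1, 1, 1, 2, 1, 1, 1),
    feature = c("o2_concentration", "ph", "heart_rate", "lactate",
                "heart_rate", "spo2", "cvp", "fluid_input"),
    time = 1:8,
    value = c(15, 6.5, 82, 35, 0, 0, -1, 6000))
  res <- apply_outlier_rules(recs, out)
  # low inspired oxygen is clamped, not dropped
  o2 <- res$records[res$records$feature == "o2_concentration", ]
  expect_equal(o2$value, 21)
  # in-range vital passes through; the dead patient's zero heart rate is
  # retained (the zero-vital rule only fires for survivors)
  hr <- res$records[res$records$feature == "heart_rate", ]
  expect_setequal(hr$value, c(82, 0))
  expect_false(any(res$exclusions$feature == "heart_rate"))
  # exclusions carry rule ids
  expect_setequal(res$exclusions$rule,
                  c("ph_lower", "lactate_high", "spo2_range",
                    "cvp_nonpositive", "fluid_input_range"))
  expect_error(apply_outlier_rules(
    make_records(1, "not_a_feature", 0, 1), out), "unknown feature")
})

test_that("zero vitals are excluded only for patients who survived", {
  out <- data.frame(patient_id = c(1, 2), outcome = c(0, 1))
  recs <- make_records(c(1, 2), c("heart_rate", "heart_rate"), c(0, 0),
                       c(0, 0))
  res <- apply_outlier_rules(recs, out)
  expect_equal(res$exclusions$patient_id, 1)
  expect_equal(res$records$patient_id, 2)
})

test_that("block segmentation averages windows and caps the horizon", {
  out <- data.frame(patient_id = 1, outcome = 0)
  # two heart-rate readings in one window average; stay of 30h gives 5 blocks
  recs <- rbind(
    make_records(1, "heart_rate", c(1, 5), c(80, 100)),
    make_records(1, "heart_rate", c(7, 13, 19, 25), c(90, 90, 90, 29.5)),
    make_records(1, "fluid_input", seq(1, 29, by = 6), rep(500, 5)),
    make_records(1, "fluid_output", seq(2, 29, by = 6), rep(400, 5)))
  blocks <- segment_blocks(recs)
  expect_equal(nrow(blocks), 5)
  expect_equal(blocks$heart_rate[1], 90)   # mean of 80 and 100
  expect_equal(blocks$balance, rep(100, 5))
  # a 120-hour stay is truncated at 18 blocks
  long <- rbind(
    make_records(1, "fluid_input", seq(0.5, 119.5, by = 6), 500),
    make_records(1, "fluid_output", seq(0.5, 119.5, by = 6), 400))
  expect_equal(nrow(segment_blocks(long)), 18)
  expect_error(segment_blocks(recs[0, ]), "empty")
})

test_that("imputation forward-fills labs, KNN-fills the rest, and never
           alters observed values", {
  fix <- small_mdp()
  tr <- fix$mdp$train_blocks
  te <- fix$mdp$test_blocks
  expect_false(anyNA(tr[, state_features()]))
  expect_false(anyNA(te[, state_features()]))

  # forward fill: creatinine observed only at block 1 carries forward
  blocks <- data.frame(patient_id = 1, bloc = 1:4,
                       creatinine = c(90, NA, NA, NA))
  for (f in setdiff(state_features(), c("bloc", "creatinine"))) {
    blocks[[f]] <- rnorm(4)
  }
  blocks$balance <- 0
  imp <- impute_missing(blocks)
  expect_equal(imp$creatinine, rep(90, 4))

  # KNN identity: a single missing heart rate with an exact duplicate
  # neighbour takes the neighbour's value at k = 1
  b2 <- blocks
  b2$creatinine <- 90
  b2$heart_rate <- c(85, 85, 120, 130)
  b2$heart_rate[2] <- NA
  b2[2, setdiff(state_features(), c("bloc", "heart_rate"))] <-
    b2[1, setdiff(state_features(), c("bloc", "heart_rate"))]
  imp2 <- impute_missing(b2, k = 1)
  expect_equal(imp2$heart_rate[2], 85)
  # observed entries untouched
  expect_equal(imp2$heart_rate[-2], c(85, 120, 130))
})

test_that("KNN imputation beats median imputation on masked-value recovery", {
  set.seed(99)
  co <- generate_cohort(cohort_config(n_patients = 250, seed = 5,
                                      missingness_rates = c(cvp = 0)))
  cleaned <- apply_outlier_rules(co$records, co$outcomes)
  blocks <- segment_blocks(cleaned$records)
  blocks <- blocks[!is.na(blocks$cvp), ]
  hide <- sample(nrow(blocks), round(0.2 * nrow(blocks)))
  truth <- blocks$cvp[hide]
  masked <- blocks
  masked$cvp[hide] <- NA
  imp <- impute_missing(masked)
  rmse_knn <- sqrt(mean((imp$cvp[hide] - truth)^2))
  rmse_med <- sqrt(mean((median(masked$cvp, na.rm = TRUE) - truth)^2))
  expect_lt(rmse_knn, rmse_med)
})

test_that("action bins are the training quintiles under interpolation", {
  bins <- fit_action_bins(1:100)
  expect_equal(bins$edges, interp_quantile_oracle(1:100, c(.2, .4, .6, .8)))
  expect_equal(bins$edges, c(20.2, 40.4, 60.6, 80.8))
  expect_error(fit_action_bins(c(1, 2, 3)), "at least 5")
  # degenerate all-equal balances collapse every edge and map to action 2
  degen <- fit_action_bins(rep(7, 10))
  expect_equal(degen$edges, rep(7, 4))
  expect_equal(discretize_balance(c(7, 7), degen), c(2L, 2L))
})

test_that("balance discretization is total, monotone and boundary-correct", {
  bins <- structure(list(edges = c(-110.68, -45.68, -0.67, 45.00)),
                    class = "action_bins")
  expect_equal(discretize_balance(-50, bins), 1L)
  expect_equal(discretize_balance(bins$edges[2], bins), 1L)  # left bin owns edge
  expect_equal(discretize_balance(10000, bins), 4L)
  expect_equal(discretize_balance(-10000, bins), 0L)
  x <- sort(runif(200, -300, 300))
  a <- discretize_balance(x, bins)
  expect_true(all(diff(a) >= 0))          # monotone
  expect_true(all(a %in% 0:4))            # total
  expect_equal(discretize_balance(x, bins), a)  # idempotent recomputation
  expect_error(discretize_balance(NaN, bins), "non-finite")
})

test_that("terminal rewards follow the survival scheme and conserve", {
  out <- data.frame(patient_id = c(1, 2), outcome = c(0, 1))
  blocks <- data.frame(patient_id = c(rep(1, 5), 2), bloc = c(1:5, 1))
  rb <- assign_rewards(blocks, out)
  expect_equal(rb$reward[rb$patient_id == 1], c(0, 0, 0, 0, 15))
  expect_equal(rb$reward[rb$patient_id == 2], -15)
  expect_equal(rb$terminal, c(rep(FALSE, 4), TRUE, TRUE))
  # conservation on a generated cohort: exactly one nonzero terminal reward
  fix <- small_mdp()
  for (b in list(fix$mdp$train_blocks, fix$mdp$test_blocks)) {
    sums <- tapply(b$reward, b$patient_id, sum)
    expect_true(all(sums %in% c(-15, 15)))
    nonzero <- tapply(b$reward != 0, b$patient_id, sum)
    expect_true(all(nonzero == 1))
    expect_true(all(b$reward[b$terminal] != 0))
  }
})

test_that("patient split is reproducible, patient-level and ratio-exact", {
  sp <- split_patients(1:10, ratio = 0.8, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_patients(1:10, ratio = 0.8, seed = 3))
  expect_error(split_patients(1:10, ratio = 1.2), "ratio")
  expect_error(split_patients(1), "at least 2")
  # blocks follow their patient
  fix <- small_mdp()
  expect_length(intersect(fix$mdp$train_blocks$patient_id,
                          fix$mdp$test_blocks$patient_id), 0)
})

test_that("transitions chain within patients and count one per block", {
  fix <- small_mdp()
  tr <- fix$mdp$train_transitions
  expect_equal(length(tr$actions), nrow(fix$mdp$train_blocks))
  nt <- which(!tr$terminal)
  # a' of transition t equals a of transition t+1 (same patient)
  expect_equal(tr$next_actions[nt], tr$actions[nt + 1L])
  expect_identical(tr$states[nt + 1L, ], tr$next_states[nt, ])
  # terminal transitions carry no successor action
  expect_true(all(is.na(tr$next_actions[tr$terminal])))
  # 3-block patient: 2 non-terminal + 1 terminal transition
  out <- data.frame(patient_id = 1, outcome = 0)
  b <- data.frame(patient_id = 1, bloc = 1:3)
  for (f in setdiff(state_features(), "bloc")) b[[f]] <- rnorm(3)
  b$bloc <- 1:3
  b$balance <- c(-5, 5, 0)
  b$action <- c(0L, 1L, 2L)
  b <- assign_rewards(b, out)
  tr3 <- build_transitions(b)
  expect_equal(sum(tr3$terminal), 1)
  expect_equal(length(tr3$actions), 3)
})

test_that("split balance comparison flags planted shifts and not null splits", {
  fix <- small_mdp()
  tab <- check_split_balance(fix$mdp$train_blocks, fix$mdp$test_blocks)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # identical tables cannot be distinguished
  same <- check_split_balance(fix$mdp$train_blocks, fix$mdp$train_blocks)
  expect_true(all(same$p_value > 0.99))
  expect_false(any(same$flagged))
  # a +10 mmHg shift on one feature is flagged
  shifted <- fix$mdp$train_blocks
  shifted$mean_bp <- shifted$mean_bp + 10
  tab2 <- check_split_balance(shifted, fix$mdp$test_blocks)
  expect_true(tab2$flagged[tab2$feature == "mean_bp"])
})

test_that("quintile bins hold balanced mass on continuous training data", {
  set.seed(1)
  bal <- rnorm(10000, -20, 80)
  bins <- fit_action_bins(bal)
  a <- discretize_balance(bal, bins)
  props <- tabulate(a + 1L, 5) / length(bal)
  expect_true(all(abs(props - 0.2) < 0.01))
})
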