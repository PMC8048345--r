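# long table builder: one row per (patient, day, gene)
long_table <- function(patient, day, gene, value) {
  data.frame(patient_id = patient, day = day, gene_id = gene,
             value = value, stringsAsFactors = FALSE)
}

# smooth one-gene cohort observed at chosen days per patient
smooth_cohort <- function(obs_days_by_patient, f = function(t) 5 + 0.3 * t) {
  do.call(rbind, lapply(names(obs_days_by_patient), function(p)
    long_table(p, obs_days_by_patient[[p]], "g1",
               f(obs_days_by_patient[[p]]))))
}

test_that("time-point selection uses a strict missingness threshold", {
  # 10 patients; day coverage engineered to 0.1 / 0.49... / 0.5 / 0.9 missing
  pats <- sprintf("p%03d", 1:100)
  tab <- rbind(
    long_table(pats[1:90], 0, "g1", 1),          # 10% missing
    long_table(pats[1:51], 1, "g1", 1),          # 49% missing
    long_table(pats[1:50], 2, "g1", 1),          # 50% missing
    long_table(pats[1:10], 3, "g1", 1),          # 90% missing
    long_table(pats[91:100], 5, "g1", 1))        # registers p091..p100
  grid <- select_time_points(tab, 0.5)
  expect_equal(grid$selected_days, c(0, 1))   # strictly less than 50%
  expect_equal(unname(grid$missing_frac), c(0.10, 0.49, 0.50, 0.90, 0.90))
  expect_error(select_time_points(tab, 0.05), "no day")
})

test_that("a dense table keeps every day; follow-up shrinks the denominator", {
  pats <- sprintf("p%02d", 1:10)
  dense <- do.call(rbind, lapply(pats, function(p)
    long_table(p, c(0, 1, 2), "g1", 1)))
  expect_equal(select_time_points(dense, 0.5)$selected_days, c(0, 1, 2))

  # half the cohort leaves after day 1: day 2 missingness is 0 among those
  # still under follow-up, 50% among all patients
  gone <- dense[!(dense$patient_id %in% pats[1:5] & dense$day == 2), ]
  sv <- data.frame(patient_id = pats,
                   time_days = c(rep(1, 5), rep(5, 5)),
                   event = rep(1, 10))
  expect_equal(select_time_points(gone, 0.5, surv = sv)$selected_days,
               c(0, 1, 2))
  expect_equal(select_time_points(gone, 0.5)$selected_days, c(0, 1))
})

test_that("constructed drop pattern matches the counting oracle", {
  withr::local_seed(31)
  cfg <- cohort_config(n_patients = 50, n_genes = 3, n_active_genes = 2, seed = 8)
  sim <- simulate_cohort(cfg)
  grid <- select_time_points(sim$expression, 0.5, surv = sim$survival,
                             days = cfg$day_grid)
  # direct counting oracle
  pats <- unique(sim$expression$patient_id)
  for (d in cfg$day_grid) {
    at_risk <- intersect(
      sim$survival$patient_id[sim$survival$time_days >= d], pats)
    seen <- unique(sim$expression$patient_id[sim$expression$day == d])
    frac <- if (length(at_risk) == 0) 1 else
      1 - length(intersect(at_risk, seen)) / length(at_risk)
    expect_equal(unname(grid$missing_frac[as.character(d)]), frac)
    expect_equal(d %in% grid$selected_days, frac < 0.5)
  }
})

test_that("observed cells pass through untouched (idempotence)", {
  tab <- smooth_cohort(list(p1 = c(0, 1, 4, 7), p2 = c(0, 1, 4, 7)))
  ss <- impute_mixed(tab, c(0, 1, 4, 7))
  expect_true(all(ss$provenance == "observed"))
  expect_equal(as.vector(ss$values[1, , 1]), 5 + 0.3 * c(0, 1, 4, 7))
  # imputing an already-complete set changes nothing
  ss2 <- impute_mixed(tab, c(0, 1, 4, 7))
  expect_identical(ss$values, ss2$values)
})

test_that("a day-8 draw is carried back to a required day 7", {
  tab <- smooth_cohort(list(p1 = c(0, 8)))
  ss <- impute_mixed(tab, c(0, 7), max_carry_days = 2)
  expect_equal(ss$provenance[1, 2, 1], "carried_backward")
  expect_equal(ss$values[1, 2, 1], 5 + 0.3 * 8)   # day-8 value at day 7
})

test_that("carry direction, tie-break, and window are respected", {
  # obs at 5 and 8; required 7: future is nearer -> NOCB
  s1 <- impute_mixed(smooth_cohort(list(p1 = c(5, 8))), 7)
  expect_equal(s1$provenance[1, 1, 1], "carried_backward")
  # obs at 5 and 9; required 7: equidistant -> past wins by default
  s2 <- impute_mixed(smooth_cohort(list(p1 = c(5, 9))), 7)
  expect_equal(s2$provenance[1, 1, 1], "carried_forward")
  expect_equal(s2$values[1, 1, 1], 5 + 0.3 * 5)
  s2b <- impute_mixed(smooth_cohort(list(p1 = c(5, 9))), 7,
                      tie_prefer = "future")
  expect_equal(s2b$provenance[1, 1, 1], "carried_backward")
  # obs at 4 and 14, gap > 2 on both sides -> linear interpolation
  tab <- long_table("p1", c(4, 14), "g1", c(2, 12))
  s3 <- impute_mixed(tab, c(4, 7, 14))
  expect_equal(s3$provenance[1, 2, 1], "interpolated")
  expect_equal(s3$values[1, 2, 1], 2 + (12 - 2) * (7 - 4) / (14 - 4))
  # no extrapolation: required day after the last draw stays missing
  s4 <- impute_mixed(long_table("p1", 0, "g1", 1), c(0, 7))
  expect_equal(s4$provenance[1, 2, 1], "missing")
  expect_true(is.na(s4$values[1, 2, 1]))
})

test_that("linear truth is recovered exactly when gaps force interpolation", {
  f <- function(t) -2 + 1.7 * t
  tab <- smooth_cohort(list(p1 = c(0, 10, 28)), f = f)
  ss <- impute_mixed(tab, c(0, 7, 14, 21, 28))
  expect_equal(as.vector(ss$values[1, , 1]), f(c(0, 7, 14, 21, 28)))
  expect_equal(as.vector(ss$provenance[1, , 1]),
               c("observed", "interpolated", "interpolated",
                 "interpolated", "observed"))
})

test_that("complete-case split keeps exactly the resolvable patients", {
  cfg <- cohort_config(n_patients = 60, n_genes = 4, n_active_genes = 2, seed = 12)
  sim <- simulate_cohort(cfg)
  grid <- select_time_points(sim$expression, 0.5, surv = sim$survival)
  ss <- impute_mixed(sim$expression, grid)
  for (h in intersect(c(7, 28), grid$selected_days)) {
    cc <- split_complete_cases(ss, h)
    expect_false(anyNA(cc$values))
    expect_true(all(cc$grid <= h))
    # oracle: patients whose cells resolve at every grid day <= h
    qs <- which(ss$grid <= h)
    ok <- apply(!is.na(ss$values[, qs, , drop = FALSE]), 1, all)
    expect_equal(cc$patients, ss$patients[ok])
  }
  expect_error(split_complete_cases(ss, 999), "grid")
})

test_that("a patient discharged at day 10 survives horizon 7, not 28", {
  obs <- list(p1 = c(0, 1, 4, 7, 9),                 # discharged day 10
              p2 = c(0, 1, 4, 7, 14, 21, 28))
  ss <- impute_mixed(smooth_cohort(obs), c(0, 1, 4, 7, 14, 21, 28))
  expect_equal(split_complete_cases(ss, 7)$patients, c("p1", "p2"))
  expect_equal(split_complete_cases(ss, 28)$patients, "p2")
})

test_that("carry distance never exceeds the window (provenance audit)", {
  cfg <- cohort_config(n_patients = 80, n_genes = 3, n_active_genes = 2, seed = 14)
  sim <- simulate_cohort(cfg)
  grid <- c(0, 1, 4, 7, 14, 21, 28)
  ss <- impute_mixed(sim$expression, grid, max_carry_days = 2)
  obs_days <- split(sim$expression$day, sim$expression$patient_id)
  for (i in seq_along(ss$patients)) {
    od <- sort(unique(obs_days[[ss$patients[i]]]))
    for (q in seq_along(grid)) {
      pv <- ss$provenance[i, q, 1]
      if (pv == "carried_forward")
        expect_lte(grid[q] - max(od[od < grid[q]]), 2)
      if (pv == "carried_backward")
        expect_lte(min(od[od > grid[q]]) - grid[q], 2)
      if (pv == "observed") expect_true(grid[q] %in% od)
    }
  }
})

test_that("mixed imputation beats pure LOCF on smooth trajectories", {
  # smooth per-patient curves, draw-level MCAR gaps; compare cell RMSE of
  # the mixed method vs last-observation-carried-forward on imputed cells
  grid <- c(0, 1, 4, 7, 14, 21, 28)
  all_days <- c(0:9, 11, 13:16, 20:23, 27:29)
  rmse_mixed <- rmse_locf <- numeric(50)
  for (r in 1:50) {
    withr::local_seed(5000 + r)
    n <- 15
    truth <- lapply(seq_len(n), function(i) {
      a <- runif(1, 4, 8); b <- runif(1, -2, 2); rate <- runif(1, 0.05, 0.3)
      function(t) a + b * exp(-rate * t)
    })
    obs <- lapply(seq_len(n), function(i)
      sort(c(0, sample(all_days[-1], 8))))   # keep day 0, thin the rest
    tab <- do.call(rbind, lapply(seq_len(n), function(i)
      long_table(sprintf("p%02d", i), obs[[i]], "g1",
                 truth[[i]](obs[[i]]))))
    ss <- impute_mixed(tab, grid, max_carry_days = 2)
    se_m <- se_l <- c()
    for (i in seq_len(n)) {
      od <- obs[[i]]
      for (q in seq_along(grid)) {
        d <- grid[q]
        if (d %in% od || d > max(od)) next    # only imputable cells
        tv <- truth[[i]](d)
        se_m <- c(se_m, (ss$values[i, q, 1] - tv)^2)
        locf <- truth[[i]](max(od[od < d]))
        se_l <- c(se_l, (locf - tv)^2)
      }
    }
    rmse_mixed[r] <- sqrt(mean(se_m)); rmse_locf[r] <- sqrt(mean(se_l))
  }
  expect_lte(mean(rmse_mixed), mean(rmse_locf))
})
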