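test_that("threshold comparison is inclusive", {
  # a 40% threshold admits a fruit occluded by no more than 60%
  expect_true(fruit_detected(40, 40))
  expect_true(fruit_detected(100, 100))
  expect_false(fruit_detected(0, 5))
  expect_false(fruit_detected(30, 40))
  expect_error(fruit_detected(50, 0), "threshold")
})

test_that("per-plant FD counts registered fruits passing the threshold", {
  reg <- data.frame(plant_id = "p1", fruit_id = sprintf("f%d", 1:4))
  rec <- data.frame(plant_id = "p1", fruit_id = sprintf("f%d", 1:4),
                    viewpoint_label = 1L, fv_percent = c(60, 50, 40, 0))
  tab <- visibility_table(rec, reg)
  expect_equal(plant_fd(tab, "p1", 1L, 50), 50)  # 2 of 4 pass inclusively
  expect_equal(plant_fd(tab, "p1", 1L, 40), 75)
  expect_equal(plant_fd(tab, "p1", 1L, 5), 75)   # the FV-0 fruit never counts
})

test_that("a fruit is detected if any viewpoint of the set meets the threshold", {
  reg <- data.frame(plant_id = "p1", fruit_id = "f1")
  rec <- data.frame(plant_id = "p1", fruit_id = "f1",
                    viewpoint_label = c(1L, 2L), fv_percent = c(0, 70))
  tab <- visibility_table(rec, reg)
  expect_equal(plant_fd(tab, "p1", 1L, 50), 0)
  expect_equal(plant_fd(tab, "p1", c(1L, 2L), 50), 100)
})

test_that("plant FD matches an independent brute-force counter", {
  for (seed in 1:15) {
    tab <- random_table(seed, n_plants = 3, n_fruits = 4, n_viewpoints = 5)
    vset <- sample(1:5, sample(1:5, 1))
    th <- sample(c(5, 30, 50, 80), 1)
    for (p in unique(tab$registry$plant_id))
      expect_equal(plant_fd(tab, p, vset, th),
                   brute_plant_fd(tab, p, vset, th))
  }
})

test_that("FD is undefined for a plant with no registered fruits", {
  tab <- random_table(1)
  expect_error(plant_fd(tab, "nonexistent", 1L, 50), "no registered fruits")
})

test_that("aggregate SD is the sample standard deviation across plants", {
  reg <- data.frame(plant_id = c("p1", "p2"), fruit_id = "f1")
  rec <- data.frame(plant_id = c("p1", "p2"), fruit_id = "f1",
                    viewpoint_label = 1L, fv_percent = c(100, 0))
  r <- aggregate_fd(visibility_table(rec, reg), 1L, 50)
  expect_equal(r$mean_fd, 50)
  expect_equal(r$sd_fd, 100 / sqrt(2), tolerance = 1e-9)  # 70.71068

  # equal per-plant FDs give SD 0
  rec$fv_percent <- c(100, 100)
  expect_equal(aggregate_fd(visibility_table(rec, reg), 1L, 50)$sd_fd, 0)

  # matches a textbook two-pass computation on random tables
  for (seed in 1:10) {
    tab <- random_table(seed, n_plants = 5)
    r <- aggregate_fd(tab, 1:4, 50)
    expect_equal(r$sd_fd, two_pass_sd(r$per_plant), tolerance = 1e-9)
    expect_true(r$mean_fd >= min(r$per_plant) - 1e-12 &&
                  r$mean_fd <= max(r$per_plant) + 1e-12)
    expect_true(all(r$per_plant >= 0 & r$per_plant <= 100))
  }
})

test_that("SD is unavailable for a single plant and FD errors with none", {
  reg <- data.frame(plant_id = "p1", fruit_id = c("f1", "f2", "f3"))
  rec <- data.frame(plant_id = "p1", fruit_id = c("f1", "f2", "f3"),
                    viewpoint_label = 1L, fv_percent = c(50, 0, 0))
  r <- aggregate_fd(visibility_table(rec, reg), 1L, 50)
  expect_equal(r$n_plants, 1)
  expect_true(is.na(r$sd_fd))
  expect_equal(r$mean_fd, 100 / 3, tolerance = 1e-9)

  empty <- visibility_table(
    data.frame(plant_id = character(), fruit_id = character(),
               viewpoint_label = integer(), fv_percent = numeric()),
    data.frame(plant_id = character(), fruit_id = character()))
  expect_error(aggregate_fd(empty, 1L, 50), "no plants")
})

test_that("the default threshold sweep has the 11 standard levels", {
  expect_equal(default_thresholds(),
               c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100))
  tab <- random_table(3)
  sw <- threshold_sweep(tab, 1:4)
  expect_length(sw, 11)
  expect_equal(names(sw), as.character(default_thresholds()))
  expect_error(threshold_sweep(tab, 1:4, numeric(0)), "non-empty")
  expect_error(threshold_sweep(tab, 1:4, c(50, 0)), "0, 100")
})

test_that("mean FD never increases with the threshold", {
  for (seed in 1:12) {
    tab <- random_table(seed, n_plants = 4, n_viewpoints = 5)
    vset <- sample(1:5, sample(1:5, 1))
    fd <- vapply(threshold_sweep(tab, vset), `[[`, numeric(1), "mean_fd")
    expect_true(all(diff(fd) <= 1e-12))
  }
})

test_that("adding a viewpoint never decreases any plant's FD", {
  for (seed in 1:12) {
    tab <- random_table(seed, n_plants = 4, n_viewpoints = 6)
    base <- sample(1:6, sample(1:5, 1))
    extra <- sample(setdiff(1:6, base), 1)
    for (p in unique(tab$registry$plant_id))
      expect_gte(plant_fd(tab, p, c(base, extra), 50),
                 plant_fd(tab, p, base, 50))
  }
})
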