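test_that("subset enumeration yields 2^m - 1 distinct non-empty subsets", {
  for (m in c(1, 2, 3, 5, 9, 14)) {
    subs <- enumerate_subsets(seq_len(m))
    expect_length(subs, 2^m - 1)
    keys <- vapply(subs, subset_key, character(1))
    expect_false(anyDuplicated(keys) > 0)
    expect_true(all(lengths(subs) >= 1))
  }
  expect_error(enumerate_subsets(1:25), "greedy_cover")
  expect_error(enumerate_subsets(integer(0)), "at least one")
})

test_that("a single all-seeing viewpoint needs only one position", {
  reg <- data.frame(plant_id = rep(c("p1", "p2"), each = 2),
                    fruit_id = rep(c("a", "b"), 2))
  rec <- merge(reg, data.frame(viewpoint_label = 1:3))
  rec$fv_percent <- ifelse(rec$viewpoint_label == 2, 100, 0)
  rep <- max_fd_by_size(visibility_table(rec, reg), 1:3, 50)
  expect_equal(rep$positions_needed, 1)
  expect_equal(rep$global_max_fd, 100)
  expect_equal(rep$argmax[[1]], list(2L))
})

test_that("two complementary viewpoints need to be combined", {
  # each viewpoint sees a disjoint half of the fruits perfectly
  reg <- data.frame(plant_id = "p1", fruit_id = c("a", "b"))
  rec <- data.frame(plant_id = "p1", fruit_id = c("a", "b", "a", "b"),
                    viewpoint_label = c(1L, 1L, 2L, 2L),
                    fv_percent = c(100, 0, 0, 100))
  rep <- max_fd_by_size(visibility_table(rec, reg), 1:2, 50)
  expect_equal(rep$by_size$max_fd, c(50, 100))
  expect_equal(rep$positions_needed, 2)
  expect_equal(rep$by_size$n_argmax, c(2L, 1L))  # both singles tie at 50
})

test_that("exhaustive scan matches an independent brute-force oracle", {
  for (seed in 1:6) {
    tab <- random_table(seed, n_plants = 3, n_fruits = 3, n_viewpoints = 6)
    th <- sample(c(30, 50, 70), 1)
    rep <- max_fd_by_size(tab, 1:6, th)
    oracle <- brute_max_fd_by_size(tab, 1:6, th)
    expect_equal(rep$by_size$max_fd, oracle$max_fd, tolerance = 1e-12)
    expect_equal(rep$global_max_fd, oracle$global_max_fd, tolerance = 1e-12)
    expect_equal(rep$positions_needed, oracle$positions_needed)
    for (k in 1:6)
      expect_setequal(vapply(rep$argmax[[k]], subset_key, character(1)),
                      vapply(oracle$argmax[[k]], subset_key, character(1)))
  }
})

test_that("max FD per size is non-decreasing and flat after positions_needed", {
  for (seed in 1:10) {
    tab <- random_table(seed, n_plants = 3, n_viewpoints = 5)
    rep <- max_fd_by_size(tab, 1:5, 50)
    expect_true(all(diff(rep$by_size$max_fd) >= -1e-12))
    after <- rep$by_size$max_fd[rep$by_size$k >= rep$positions_needed]
    expect_true(all(abs(after - rep$global_max_fd) < 1e-9))
  }
})

test_that("favourite positions are the cross-session argmax intersection", {
  tab <- random_table(11, n_plants = 3, n_viewpoints = 4)
  rep1 <- max_fd_by_size(tab, 1:4, 50)
  # identical sessions: intersection equals either argmax list
  fav <- favourite_positions(list(rep1, rep1))
  for (k in 1:4)
    expect_setequal(vapply(fav[[k]], subset_key, character(1)),
                    vapply(rep1$argmax[[k]], subset_key, character(1)))

  # engineered shared optimum: viewpoint 4 sees everything in both sessions,
  # singles 1-3 differ between sessions
  mk <- function(seen_by) {
    reg <- data.frame(plant_id = "p1", fruit_id = c("a", "b"))
    rec <- merge(reg, data.frame(viewpoint_label = 1:4))
    rec$fv_percent <- ifelse(
      rec$viewpoint_label == 4 |
        (rec$viewpoint_label == seen_by & rec$fruit_id == "a"), 100, 0)
    visibility_table(rec, reg)
  }
  rA <- max_fd_by_size(mk(1), 1:4, 50)
  rB <- max_fd_by_size(mk(2), 1:4, 50)
  fav <- favourite_positions(list(rA, rB))
  expect_equal(fav[[1]], list(4L))

  # disjoint argmax lists give an empty intersection, not an error
  mk2 <- function(best) {
    reg <- data.frame(plant_id = "p1", fruit_id = "a")
    rec <- merge(reg, data.frame(viewpoint_label = 1:2))
    rec$fv_percent <- ifelse(rec$viewpoint_label == best, 100, 50)
    visibility_table(rec, reg)
  }
  fav2 <- favourite_positions(list(max_fd_by_size(mk2(1), 1:2, 60),
                                   max_fd_by_size(mk2(2), 1:2, 60)))
  expect_length(fav2[[1]], 0)

  # mismatched label sets are an error
  expect_error(favourite_positions(list(rep1, max_fd_by_size(tab, 1:3, 50))),
               "label sets")
})

test_that("greedy cover is sound and bounded by the exhaustive maximum", {
  # single viewpoint: trajectory equals that viewpoint's FD
  tab1 <- random_table(2, n_viewpoints = 1)
  tr <- greedy_cover(tab1, 1L, 50)
  expect_equal(tr$fd, aggregate_fd(tab1, 1L, 50)$mean_fd)

  for (seed in 1:8) {
    tab <- random_table(seed, n_plants = 3, n_viewpoints = 5)
    tr <- greedy_cover(tab, 1:5, 50)
    rep <- max_fd_by_size(tab, 1:5, 50)
    expect_true(all(diff(tr$fd) >= -1e-12))            # non-decreasing
    expect_true(all(tr$fd <= rep$by_size$max_fd + 1e-9))  # <= exhaustive
  }

  # equal-fruit-count plants: when one viewpoint attains the global max,
  # greedy picks it first
  reg <- data.frame(plant_id = rep(c("p1", "p2"), each = 2),
                    fruit_id = rep(c("a", "b"), 2))
  rec <- merge(reg, data.frame(viewpoint_label = 1:3))
  rec$fv_percent <- ifelse(rec$viewpoint_label == 3, 100,
                           ifelse(rec$fruit_id == "a", 100, 0))
  tab <- visibility_table(rec, reg)
  tr <- greedy_cover(tab, 1:3, 50, k_max = 1)
  expect_equal(tr$label, 3L)
  expect_equal(tr$fd, 100)
})
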