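test_that("peak fit recovers its own model class exactly on noiseless input", {
  x <- 0:99
  y <- 0.1 + 0.8 * exp(-(x - 37)^2 / (2 * 6^2))
  fit <- fit_peak(x, y)
  expect_true(fit$converged)
  expect_equal(fit$baseline, 0.1, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.8, tolerance = 1e-6)
  expect_equal(fit$center, 37, tolerance = 1e-6)
  expect_equal(fit$width, 6, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("peak fit honours its contract on awkward inputs", {
  x <- 0:99
  bimodal <- gauss_mix(x, c(25, 70), c(6, 6), c(0.8, 0.7))
  fit <- fit_peak(x, bimodal)
  expect_gte(fit$center, 0)
  expect_lte(fit$center, 99)
  expect_error(fit_peak(0:3, c(0, 1, 0.5, 0.2)), "5")
  # flat input falls back deterministically to the first argmax
  flat <- fit_peak(x, rep(0.5, 100))
  expect_false(flat$converged)
  expect_equal(flat$center, 0)
})

test_that("mean fitted centre is unbiased on noisy replicates", {
  set.seed(11)
  x <- 0:99
  clean <- 0.1 + 0.8 * exp(-(x - 37)^2 / (2 * 6^2))
  centers <- replicate(60, fit_peak(x, clean + rnorm(100, 0, 0.05))$center)
  expect_lt(abs(mean(centers) - 37), 0.5)
})

test_that("centering subtracts the rounded fitted peak and keeps integer grids", {
  x <- 0:99
  p <- make_profile(x, list(ref = gauss_mix(x, 40, 8, 1),
                            qry = gauss_mix(x, 55, 8, 1)), "img1")
  al <- align_profiles(list(p), "ref")
  expect_equal(al$shifts, 40)
  expect_equal(al$profiles[[1]]$positions, x - 40)
  expect_true(all(al$profiles[[1]]$positions == round(al$profiles[[1]]$positions)))
  # reference peak value sits at 0 on the shifted grid
  sp <- al$profiles[[1]]
  expect_equal(sp$positions[which.max(sp$values$ref)], 0)
})

test_that("common grid is the interval intersection of shifted ranges", {
  x <- 0:99
  p1 <- make_profile(x, list(ref = gauss_mix(x, 30, 8, 1)), "imgA")
  p2 <- make_profile(x, list(ref = gauss_mix(x, 50, 8, 1)), "imgB")
  al <- align_profiles(list(p1, p2), "ref")
  expect_equal(range(al$profiles[[1]]$positions), c(-30, 69))
  expect_equal(range(al$profiles[[2]]$positions), c(-50, 49))
  expect_equal(al$common_grid, -30:49)
})

test_that("grid intersection matches a brute-force oracle on random shift configurations", {
  set.seed(23)
  for (i in 1:15) {
    n <- sample(3:6, 1)
    profiles <- lapply(seq_len(n), function(j) {
      start <- sample(0:30, 1); len <- sample(60:120, 1)
      x <- start:(start + len)
      make_profile(x, list(ref = gauss_mix(x, sample(40:80, 1), 8, 1)),
                   paste0("img", j))
    })
    al <- align_profiles(profiles, "ref")
    # oracle: a position belongs to the common grid iff every shifted profile has it
    all_pos <- sort(unique(unlist(lapply(al$profiles, `[[`, "positions"))))
    oracle <- all_pos[vapply(all_pos, function(p)
      all(vapply(al$profiles, function(pr) p %in% pr$positions, logical(1))),
      logical(1))]
    expect_equal(al$common_grid, oracle)
    # shift bookkeeping: negated shifts restore the originals exactly
    for (j in seq_len(n))
      expect_identical(al$profiles[[j]]$positions + al$shifts[j],
                       as.numeric(profiles[[j]]$positions))
  }
})

test_that("one fit per image shifts all of that image's lines and channels together", {
  x <- 0:99
  mk <- function(center, img, line) make_profile(
    x, list(ref = gauss_mix(x, center, 8, 1),
            qry = gauss_mix(x, center + 10, 8, 1)), img, line)
  # two lines of the same image with slightly different apparent peaks
  al <- align_profiles(list(mk(40, "img1", "l1"), mk(42, "img1", "l2"),
                            mk(60, "img2", "l1")), "ref")
  expect_equal(al$shifts[1], al$shifts[2])     # same image, same shift
  expect_equal(length(al$fits), 2L)
  expect_error(align_profiles(list(), "ref"), "empty")
  expect_error(align_profiles(list(mk(40, "i", "l")), "missing"), "missing")
})

test_that("averaging matches closed-form examples", {
  x <- -10:10
  v <- gauss_mix(x, 0, 4, 1)
  same <- lapply(1:3, function(i) make_profile(x, list(g = v), paste0("img", i)))
  al <- align_profiles(same, "g")
  avg <- average_profiles(al)
  expect_equal(avg$channels$g$mean, v[match(avg$grid, x)])
  expect_equal(avg$channels$g$sem, rep(0, length(avg$grid)))

  two <- list(make_profile(0:5, list(g = rep(0.2, 6)), "a"),
              make_profile(0:5, list(g = rep(0.6, 6)), "b"))
  # bypass peak centering: flat profiles, shift 0 via direct construction
  al2 <- structure(list(reference_channel = "g", profiles = two,
                        shifts = c(0, 0), fits = list(),
                        grouping = c("a", "b"), common_grid = 0:5),
                   class = "aligned_profile_set")
  avg2 <- average_profiles(al2)
  expect_equal(avg2$channels$g$mean, rep(0.4, 6))
  expect_equal(avg2$channels$g$sem, rep(0.2, 6))    # sd(0.2, 0.6)/sqrt(2)
  expect_equal(avg2$n, 2L)
})

test_that("averaging matches an independent two-pass loop oracle", {
  set.seed(31)
  x <- 0:80
  profiles <- lapply(1:6, function(i)
    make_profile(x, list(g = gauss_mix(x, 40, 8, 1) + rnorm(81, 0, 0.05),
                         h = runif(81)), paste0("img", i)))
  al <- align_profiles(profiles, "g")
  avg <- average_profiles(al)
  for (ch in c("g", "h")) {
    mat <- vapply(al$profiles, function(p)
      p$values[[ch]][match(avg$grid, p$positions)], numeric(length(avg$grid)))
    oracle <- loop_mean_sem(mat)
    expect_equal(avg$channels[[ch]]$mean, oracle$mean, tolerance = 1e-12)
    expect_equal(avg$channels[[ch]]$sem, oracle$sem, tolerance = 1e-12)
  }
})

test_that("empty common grid errors with actionable advice", {
  # centering always leaves 0 inside every shifted range, so a truly empty
  # intersection can only come from degenerate inputs; construct one directly
  p1 <- make_profile(0:20, list(g = gauss_mix(0:20, 5, 2, 1)), "a")
  p2 <- make_profile(40:60, list(g = gauss_mix(40:60, 55, 2, 1)), "b")
  al <- structure(list(reference_channel = "g", profiles = list(p1, p2),
                       shifts = c(0, 0), fits = list(),
                       grouping = c("a", "b"), common_grid = numeric(0)),
                  class = "aligned_profile_set")
  expect_error(average_profiles(al), "longer or retargeted")
})

test_that("subpixel mode interpolates onto a shared integer lattice", {
  x <- 0:99
  p <- make_profile(x, list(ref = gauss_mix(x, 40.4, 8, 1)), "img1")
  al <- align_profiles(list(p), "ref", subpixel = TRUE)
  expect_equal(al$shifts[1], 40.4, tolerance = 1e-3)
  expect_true(all(al$profiles[[1]]$positions == round(al$profiles[[1]]$positions)))
})
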