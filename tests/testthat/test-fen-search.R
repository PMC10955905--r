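random_masks <- function(seed, n = 64, strut_p = 0.08) {
  set.seed(seed)
  g <- matrix(rbinom(n * n, 1, strut_p), n, n)
  f <- matrix(0L, n, n)
  # a few fenestration pixels in a compact constellation
  r0 <- sample(8:24, 1); c0 <- sample(1:n, 1)
  for (k in 1:4) {
    rr <- r0 + sample(0:10, 1); cc <- ((c0 + sample(0:10, 1) - 1) %% n) + 1
    f[rr, cc] <- 1L
  }
  storage.mode(g) <- "integer"
  list(graft = mask2d(g, 0.5, al_period = n * 0.5, periodic_al = TRUE),
       fen = mask2d(f, 0.5, al_period = n * 0.5))
}

test_that("count_overlap handles wrap, bounds, and trivial cases", {
  m <- random_masks(1)
  zero_graft <- mask2d(matrix(0L, 64, 64), 0.5, periodic_al = TRUE)
  expect_equal(count_overlap(zero_graft, m$fen, c(13, 5)), 0L)
  # disc on a strut row: equals the nested-loop count
  g <- matrix(0L, 40, 40); g[20, ] <- 1L
  graft <- mask2d(g, 0.5, al_period = 20, periodic_al = TRUE)
  sp <- fenestration_spec("CA", AL = 10, PGD = 10, diameter = 4)
  fen <- build_fenestration_mask(list(sp), 0.5, 20, 20)
  for (off in list(c(0, 0), c(7, -3), c(33, 6)))
    expect_equal(count_overlap(graft, fen, off),
                 brute_overlap(graft$pixels, fen$pixels, off[1], off[2]))
  # shifting the disc past the distal edge is sentinel-invalid
  expect_equal(count_overlap(graft, fen, c(0, 18)), sum(fen$pixels))
  expect_gt(count_overlap(graft, fen, c(0, 18)), 0)
  expect_error(count_overlap(mask2d(g, 0.25, periodic_al = TRUE), fen, c(0, 0)),
               "resolution")
})

test_that("correlation search equals nested-loop brute force on random masks", {
  for (seed in 1:20) {
    m <- random_masks(seed)
    got <- search_alignments(m$graft, m$fen)
    want <- brute_valid_offsets(m$graft, m$fen)
    got_m <- as.matrix(got[order(got$dal_px, got$dpgd_px), ])
    dimnames(got_m) <- NULL
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(got_m[order(got_m[, 1], got_m[, 2]), , drop = FALSE],
                   want)
    }
  }
})

test_that("zero-strut grafts admit every in-bounds offset", {
  zero_graft <- mask2d(matrix(0L, 30, 20), 0.5, periodic_al = TRUE)
  f <- matrix(0L, 30, 20); f[10, 5] <- 1L
  fen <- mask2d(f, 0.5)
  got <- search_alignments(zero_graft, fen)
  expect_equal(nrow(got), 20 * 30)        # all AL x all in-bounds PGD
  # single strut row + single-pixel fenestration: valid set is the
  # complement of the strut row within PGD bounds
  g <- matrix(0L, 30, 20); g[15, ] <- 1L
  graft <- mask2d(g, 0.5, periodic_al = TRUE)
  got2 <- search_alignments(graft, fen)
  expect_equal(nrow(got2), 20 * 29)
  expect_false(any(got2$dpgd_px == 5))    # row 10 + 5 = strut row 15
  expect_error(search_alignments(graft, mask2d(matrix(0L, 30, 20), 0.5)),
               "empty")
})

test_that("select_optimal minimizes the summed Pythagorean deviation", {
  specs <- list(fenestration_spec("CA", AL = 5, PGD = 10, diameter = 4))
  off <- data.frame(dal_px = c(0L, 10L), dpgd_px = c(0L, 0L))
  fit <- select_optimal(off, specs, resolution = 0.5, al_period = 30)
  expect_equal(fit$dAL, 0); expect_equal(fit$dPGD, 0)
  expect_equal(sum(fit$deviations), 0)
  # delta = sqrt(3^2 + 4^2) = 5 at a (3, 4) mm offset
  off2 <- data.frame(dal_px = 6L, dpgd_px = 8L)
  fit2 <- select_optimal(off2, specs, resolution = 0.5, al_period = 30)
  expect_equal(unname(fit2$deviations["CA"]), 5)
  # argmin matches exhaustive evaluation on random valid sets
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(5:40, 1)
    off <- unique(data.frame(dal_px = sample(0:59, n, TRUE),
                             dpgd_px = sample(-20:20, n, TRUE)))
    fit <- select_optimal(off, specs, resolution = 0.5, al_period = 30)
    wrap <- function(x) { w <- ((x + 15) %% 30) - 15; ifelse(w == -15, 15, w) }
    dev <- sqrt(wrap(off$dal_px * 0.5)^2 + (off$dpgd_px * 0.5)^2)
    expect_equal(sum(fit$deviations), min(dev), tolerance = 1e-12)
  }
})

test_that("sum of deviations never increases when valid offsets grow", {
  specs <- list(fenestration_spec("CA", AL = 5, PGD = 10, diameter = 4))
  set.seed(99)
  off <- data.frame(dal_px = sample(0:59, 30, TRUE),
                    dpgd_px = sample(-20:20, 30, TRUE))
  prev <- Inf
  for (k in c(5, 10, 20, 30)) {
    fit <- select_optimal(off[1:k, ], specs, 0.5, 30)
    expect_lte(sum(fit$deviations), prev + 1e-12)
    prev <- sum(fit$deviations)
  }
})

test_that("relaxed search matches brute force on constructed near-misses", {
  res <- 0.25
  n <- 40L
  period <- n * res
  for (seed in 1:20) {
    set.seed(seed)
    da <- sample(0:6, 1); dp <- sample(0:4, 1)
    s_star <- sample(2:10, 1)           # required posterior shift, px
    specs <- list(
      fenestration_spec("SMA", phi = 60, AL = (10 + 0.5) * res,
                        PGD = (10 + 0.5) * res, diameter = 0.2,
                        prioritized = TRUE),
      fenestration_spec("RRA", phi = 100, AL = (20 + 0.5) * res,
                        PGD = (20 + 0.5) * res, diameter = 0.2,
                        prioritized = FALSE))
    px <- matrix(1L, n, n)
    hole <- function(al, pgd, r) {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        dal <- min(abs(j - 1 - al), n - abs(j - 1 - al))
        if (dal^2 + (i - 1 - pgd)^2 <= r^2) px[i, j] <<- 0L
      }
    }
    hole(10 + da, 10 + dp, 1.4)
    hole(20 + da + s_star, 20 + dp, 1.4)
    graft <- mask2d(px, res, al_period = period, periodic_al = TRUE)
    fit <- relaxed_search(graft, specs, res, max_posterior_shift = 3)
    oracle <- brute_relaxed_optimum(graft, specs, res, 3, c(SMA = 1, RRA = 1))
    expect_true(fit$valid)
    expect_true(oracle$feasible)
    expect_equal(sum(fit$deviations), oracle$best_total, tolerance = 1e-9)
    # result is genuinely conflict-free: re-check by direct counting
    for (v in 1:2) {
      sp <- specs[[v]]
      al_shift <- fit$per_vessel_shift[[sp$vessel]][1]
      fen_v <- build_fenestration_mask(
        list(fenestration_spec(sp$vessel, AL = sp$AL + al_shift, PGD = sp$PGD,
                               diameter = sp$diameter)), res, period, period)
      expect_equal(brute_overlap(graft$pixels, fen_v$pixels,
                                 fit$dal_px, fit$dpgd_px), 0L)
    }
    expect_equal(fit$per_vessel_shift[["SMA"]], c(0, 0))  # prioritized rigid
  }
})

test_that("relaxation with zero budget reduces to the plain search", {
  m <- random_masks(3)
  sp <- list(fenestration_spec("CA", AL = 5, PGD = 8, diameter = 1.5),
             fenestration_spec("RRA", AL = 15, PGD = 12, diameter = 1.5))
  f0 <- relaxed_search(m$graft, sp, max_posterior_shift = 0)
  fen <- build_fenestration_mask(sp, m$graft$resolution, m$graft$al_period,
                                 m$graft$pgd_extent)
  plain <- search_alignments(m$graft, fen)
  if (nrow(plain)) {
    f1 <- select_optimal(plain, sp, m$graft$resolution, m$graft$al_period)
    expect_equal(f0$dAL, f1$dAL)
    expect_equal(f0$dPGD, f1$dPGD)
  } else {
    expect_false(f0$valid)
  }
})

test_that("valid sets are invariant under AL translation by the period", {
  m <- random_masks(11)
  got <- search_alignments(m$graft, m$fen)
  rolled <- m$graft$pixels[, c(33:64, 1:32)]
  graft2 <- mask2d(rolled, 0.5, al_period = 32, periodic_al = TRUE)
  got2 <- search_alignments(graft2, m$fen)
  # rolling the graft by half its width shifts every valid dal by the same
  # amount modulo the column count
  shifted <- sort((got$dal_px + 32) %% 64 + 64 * got$dpgd_px)
  expect_equal(sort(got2$dal_px + 64 * got2$dpgd_px), shifted)
})
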