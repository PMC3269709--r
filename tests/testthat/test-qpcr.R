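test_that("standard-curve fits recover known lines exactly", {
  pts <- data.frame(log10_conc = c(0, -1, -2, -3))
  pts$ct <- -3.3125 * pts$log10_conc + 39.562
  sc <- fit_standard_curve(pts)
  expect_equal(sc$slope, -3.3125, tolerance = 1e-12)
  expect_equal(sc$intercept, 39.562, tolerance = 1e-12)
  expect_equal(sc$r_squared, 1)
  expect_equal(round(sc$efficiency, 4), 2.0039)

  set.seed(4)
  sl <- runif(1, -4, -2); ic <- runif(1, 25, 40)
  pts2 <- data.frame(log10_conc = 0:-3, ct = sl * (0:-3) + ic)
  sc2 <- fit_standard_curve(pts2)
  expect_equal(sc2$slope, sl, tolerance = 1e-10)
  expect_equal(sc2$intercept, ic, tolerance = 1e-10)

  expect_error(fit_standard_curve(data.frame(log10_conc = 0:-1,
                                             ct = c(30, 33))), "3 points")
  expect_error(fit_standard_curve(data.frame(log10_conc = c(0, 0, 0),
                                             ct = c(30, 31, 32))),
               "identical")
})

test_that("efficiency follows E = 10^(-1/slope)", {
  expect_equal(round(efficiency(-3.3125), 4), 2.0039)
  expect_equal(round(efficiency(-3.2811), 4), 2.0173)
  expect_equal(round(efficiency(-3.3915), 4), 1.9718)
  expect_equal(efficiency(-1 / log10(2)), 2, tolerance = 1e-6)
  expect_error(efficiency(3.3), "negative")
  # strictly decreasing in |slope|
  slopes <- seq(-4, -2.5, by = 0.25)
  expect_true(all(diff(vapply(slopes, efficiency, numeric(1))) > 0))
})

test_that("ddCt recovers generator fold changes at zero noise", {
  for (folds in list(
    c(egg = 1, L1 = 1.47, L3 = 4.22, L4 = 3.78, L6 = 2.26,
      prepupa = 1.87, pupa = 0.37, adult = 9.07),
    c(egg = 1, L1 = 2.89, L3 = 15.65, L4 = 24.55, L6 = 4.88,
      prepupa = 2.23, pupa = 38.68, adult = 1.81))) {
    tab <- gen_ct_table(fixture_config(seed = 2, ct_noise_sd = 0,
                                       fold_changes = folds))
    rq <- delta_delta_ct(tab, calibrator = "egg")
    expect_equal(setNames(rq$rq, rq$stage), folds, tolerance = 1e-10)
    expect_equal(rq$rq[rq$stage == "egg"], 1)
  }
})

test_that("closed-form ddCt identities hold", {
  tab <- data.frame(stage = rep(c("egg", "adult"), each = 3),
                    replicate = rep(1:3, 2),
                    ct_target = c(23, 23, 23, 23 - 3.181, 23 - 3.181,
                                  23 - 3.181),
                    ct_reference = 15)
  rq <- delta_delta_ct(tab, calibrator = "egg")
  expect_equal(round(rq$rq[rq$stage == "adult"], 2), 9.07)  # 2^3.181
  expect_equal(rq$rq[rq$stage == "egg"], 1)
})

test_that("RQ is invariant to a constant reference-gene shift", {
  tab <- gen_ct_table(fixture_config(seed = 31))
  shifted <- tab
  shifted$ct_reference <- shifted$ct_reference + 1.7
  a <- delta_delta_ct(tab, "egg")
  b <- delta_delta_ct(shifted, "egg")
  expect_equal(a$rq, b$rq, tolerance = 1e-12)

  expect_error(delta_delta_ct(tab, "larva99"), "not present")
  bad <- tab; bad$ct_target[1] <- NA
  expect_error(delta_delta_ct(bad, "egg"), "non-finite")
})

test_that("efficiency-corrected RQ uses the supplied base", {
  tab <- gen_ct_table(fixture_config(seed = 8, ct_noise_sd = 0))
  rq2 <- delta_delta_ct(tab, "egg")
  rqE <- delta_delta_ct(tab, "egg", base = 1.95)
  expect_equal(rqE$rq, 1.95^(-rq2$ddct), tolerance = 1e-12)
})

test_that("Duncan letters: identical groups share, separated groups split", {
  set.seed(10)
  same <- lapply(1:4, function(i) rnorm(3, 10, 0.3))
  names(same) <- paste0("s", 1:4)
  same_letters <- duncan_grouping(lapply(same, function(v) v - mean(v) + 10))
  expect_true(all(same_letters == "a"))

  far <- list(hi = c(50, 50.2, 49.9), lo = c(1, 1.1, 0.8))
  expect_equal(unname(duncan_grouping(far)), c("a", "b"))

  # all-zero variance with unequal means: every mean its own letter
  dg <- duncan_grouping(list(a = c(5, 5), b = c(3, 3), c = c(1, 1)))
  expect_equal(unname(dg), c("a", "b", "c"))
  expect_error(duncan_grouping(list(a = 1:3)), "length")
})

test_that("two-group Duncan agrees with the pooled-variance t-test", {
  set.seed(123)
  for (i in 1:40) {
    a <- rnorm(4, 0, 1)
    b <- rnorm(4, sample(c(0, 0.5, 1.5, 3), 1), 1)
    letters_ <- duncan_grouping(list(a = a, b = b), alpha = 0.05)
    tt <- t.test(a, b, var.equal = TRUE)
    if (tt$p.value < 0.05) expect_false(letters_[["a"]] == letters_[["b"]])
    else expect_true(letters_[["a"]] == letters_[["b"]])
  }
})

test_that("Duncan least significant ranges match published 5% tables (df 20)", {
  se <- 1
  rp <- function(p) qtukey(0.95^(p - 1), p, 20) * se
  expect_equal(round(rp(2), 2), 2.95)
  expect_equal(round(rp(3), 2), 3.10)
  expect_equal(round(rp(5), 2), 3.25)
})

test_that("letter displays are contiguous in mean order for noisy stages", {
  set.seed(55)
  means <- c(10, 9.8, 8, 7.9, 5, 4.9, 2, 1)
  groups <- lapply(means, function(m) rnorm(3, m, 0.4))
  names(groups) <- paste0("g", seq_along(means))
  lets <- duncan_grouping(groups)
  ord <- order(vapply(groups, mean, numeric(1)), decreasing = TRUE)
  sorted_lets <- lets[ord]
  for (l in unique(unlist(strsplit(sorted_lets, "")))) {
    pos <- unname(which(vapply(strsplit(sorted_lets, ""),
                               function(x) l %in% x, logical(1))))
    expect_equal(pos, seq(min(pos), max(pos)), info = l)
  }
  # letters follow descending means: first sorted group holds "a"
  expect_true(grepl("a", sorted_lets[1]))
})

test_that("Ct tables and RQ results survive TSV round trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- gen_ct_table(fixture_config(seed = 12))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_ct_table(path)
  expect_equal(back$ct_target, tab$ct_target, tolerance = 1e-6)
  rq <- delta_delta_ct(back, "egg")
  rq_path <- withr::local_tempfile(fileext = ".tsv")
  write_rq_table(rq, rq_path)
  again <- read.delim(rq_path)
  expect_equal(nrow(again), 8)
  expect_equal(again$rq, round(rq$rq, 4))

  dil <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("log10_conc\tct", "0\t20", "-1\t23.3", "-2\t26.7"), dil)
  expect_equal(nrow(read_dilution_series(dil)), 3)
  expect_error(read_ct_table(dil), "columns")
})
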