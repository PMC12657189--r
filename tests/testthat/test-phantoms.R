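test_that("phantom rendering is deterministic and class-distinctive", {
  a <- render_phantom(2, size = 32, seed = 5)
  b <- render_phantom(2, size = 32, seed = 5)
  expect_identical(a, b)
  imgs <- lapply(0:5, render_phantom, size = 32, seed = 5)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_gt(max(abs(imgs[[i]] - imgs[[j]])), 0)
  }
  expect_true(all(vapply(imgs, function(x) all(x >= 0 & x <= 1),
                         logical(1))))
  expect_error(render_phantom(6, 32, 1), "0..5")
})

test_that("femur phantom contains an elongated bright component", {
  img <- render_phantom(1, size = 64, seed = 17)
  bright <- img > 0.8
  rows <- range(which(rowSums(bright) > 0))
  cols <- range(which(colSums(bright) > 0))
  extent <- sort(c(diff(rows) + 1, diff(cols) + 1))
  expect_gt(extent[2] / extent[1], 3)
})

test_that("speckle is unit-mean, blendable and seeded", {
  img <- matrix(0.6, 64, 64)
  expect_identical(apply_speckle(img, 0, seed = 1), img)
  sp <- apply_speckle(img, 1, seed = 2)
  expect_lt(abs(mean(sp) - 0.6) / 0.6, 0.05)  # law of large numbers
  expect_identical(apply_speckle(img, 0.7, seed = 3),
                   apply_speckle(img, 0.7, seed = 3))
  expect_true(all(sp >= 0))
  expect_error(apply_speckle(img, 1.2), "\\[0, 1\\]")
})

test_that("contrast degradation records the exact restoring gain", {
  img <- render_phantom(0, 32, seed = 3)
  d1 <- degrade_contrast(img, g = 1, jitter = 0)
  expect_identical(d1$image, img)
  expect_equal(d1$alpha_star, 1)
  expect_equal(degrade_contrast(img, g = 0.5, jitter = 0)$alpha_star, 2)
  # round trip: restoring with alpha* recovers the input (jitter 0)
  d <- degrade_contrast(img, g = 0.41, jitter = 0)
  back <- apply_contrast(d$image, d$alpha_star)
  expect_lt(max(abs(back - img)), 1e-6)
  expect_error(degrade_contrast(img, g = 0), "> 0")
})

test_that("largest-remainder apportionment matches an enumeration oracle", {
  # oracle: exhaustive check of the defining property — counts sum to n and
  # no transfer of one unit can reduce the total absolute error
  lr_oracle_ok <- function(counts, n, p) {
    p <- p / sum(p)
    if (sum(counts) != n) return(FALSE)
    err <- counts - n * p
    for (i in seq_along(p)) for (j in seq_along(p)) {
      if (i == j || counts[i] == 0) next
      alt <- counts; alt[i] <- alt[i] - 1; alt[j] <- alt[j] + 1
      if (sum(abs(alt - n * p)) < sum(abs(err)) - 1e-9) return(FALSE)
    }
    TRUE
  }
  table1 <- c(711, 1040, 1626, 1718, 3092, 4213)
  expect_equal(apportion_counts(600, table1),
               c(34L, 50L, 79L, 83L, 150L, 204L))
  set.seed(31)
  for (r in 1:25) {
    k <- sample(2:7, 1)
    p <- runif(k)
    n <- sample(10:500, 1)
    expect_true(lr_oracle_ok(apportion_counts(n, p), n, p))
  }
})

test_that("generated datasets honor counts, split and reproducibility", {
  spec <- phantom_spec(n_total = 120, size = 32, seed = 77)
  ds <- generate_dataset(spec)
  m <- ds$manifest
  expect_equal(nrow(m), 120L)
  expect_setequal(unique(m$class), 0:5)
  expect_equal(as.integer(table(factor(m$class, levels = 0:5))),
               apportion_counts(120, spec$proportions))
  # stratified 70/30 within one sample per class
  for (k in 0:5) {
    n_k <- sum(m$class == k)
    n_tr <- sum(m$class == k & m$split == "train")
    expect_lte(abs(n_tr - 0.7 * n_k), 1)
  }
  expect_true(all(m$split %in% c("train", "test")))
  # alpha* invariants
  expect_true(all(m$alpha_star >= 1 & m$alpha_star <= 3))
  expect_equal(m$alpha_star * m$g, rep(1, 120), tolerance = 1e-12)
  # byte-identical regeneration
  ds2 <- generate_dataset(spec)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$images, ds2$images)
})

test_that("round-trip restoration holds across a jitter-free dataset", {
  spec <- phantom_spec(n_total = 24, size = 32, seed = 13, jitter = 0)
  ds <- generate_dataset(spec)
  for (i in seq_len(nrow(ds$manifest))) {
    restored <- apply_contrast(ds$images[[i]], ds$manifest$alpha_star[i])
    speckled <- apply_speckle(
      render_phantom(ds$manifest$class[i], 32,
                     seed = acam:::derive_seed(13, i * 3)),
      spec$speckle_strength, seed = acam:::derive_seed(13, i * 3 + 1))
    expect_lt(max(abs(restored - speckled)), 1e-6)
  }
})

test_that("dataset export writes the class-folder layout and manifest", {
  ds <- fixture_dataset(n_total = 18, size = 32, seed = 3)
  root <- tempfile()
  mp <- write_dataset(ds, root)
  man <- read.csv(mp)
  expect_equal(nrow(man), 18L)
  expect_true(all(file.exists(man$path)))
  img <- read_gray_png(man$path[1])
  expect_equal(dim(img), c(32L, 32L))
  unlink(root, recursive = TRUE)
})

test_that("test-split gain override only affects the test split", {
  spec <- phantom_spec(n_total = 120, size = 32, seed = 5,
                       test_gain_range = c(0.25, 0.4))
  m <- generate_dataset(spec)$manifest
  expect_true(all(m$g[m$split == "test"] <= 0.4))
  expect_true(all(m$g[m$split == "train"] >= 1 / 3 - 1e-12))
})
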