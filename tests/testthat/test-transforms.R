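test_that("uncorrelated traits give identity transforms", {
  panel <- panel_with_exact_cov(400, diag(4), seed = 2)
  ts <- fit_transforms(panel)
  expect_equal(unname(ts$L), diag(4), tolerance = 1e-10)
  sets <- apply_transforms(panel, ts)
  expect_equal(unname(as.matrix(sets$CT[, 4:7])),
               unname(as.matrix(sets$RT[, 4:7])), tolerance = 1e-10)
})

test_that("the 2x2 case matches the closed form", {
  target <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  panel <- panel_with_exact_cov(300, target, seed = 3)
  ts <- fit_transforms(panel)
  expect_equal(ts$eigenvalues, c(1.5, 0.5), tolerance = 1e-10)
  sets <- apply_transforms(panel, ts)
  z <- scale(as.matrix(panel[, c("T01", "T02")]))
  ct2_expected <- (z[, 2] - 0.5 * z[, 1]) / sqrt(0.75)
  expect_equal(unname(sets$CT$CT02), unname(ct2_expected), tolerance = 1e-10)
})

test_that("fitted scores are exactly uncorrelated on the discovery panel", {
  st <- small_study()
  sets <- st$panels
  pc <- as.matrix(sets$PC[, -(1:3)])
  ct <- as.matrix(sets$CT[, -(1:3)])
  expect_lt(max(abs(cov(pc) - diag(st$transforms$eigenvalues))), 1e-8)
  expect_lt(max(abs(cov(ct) - diag(ncol(ct)))), 1e-8)
  expect_equal(unname(ct[, 1]), unname(as.matrix(sets$RT[, 4])[, 1]),
               tolerance = 1e-12)
  # variance bookkeeping: eigenvalues of a correlation matrix sum to k
  expect_equal(sum(st$transforms$eigenvalues), st$transforms$k, tolerance = 1e-10)
})

test_that("scores reconstruct the standardized traits (round trip)", {
  st <- small_study()
  ts <- st$transforms
  sets <- st$panels
  Z <- as.matrix(sets$RT[, -(1:3)])
  U <- as.matrix(sets$PC[, -(1:3)])
  C <- as.matrix(sets$CT[, -(1:3)])
  expect_lt(max(abs(U %*% t(ts$rotation) - Z)), 1e-10)
  expect_lt(max(abs(C %*% t(ts$L) - Z)), 1e-10)
})

test_that("CT_j is uncorrelated with the preceding raw traits", {
  st <- small_study()
  Z <- as.matrix(st$panels$RT[, -(1:3)])
  C <- as.matrix(st$panels$CT[, -(1:3)])
  for (j in c(2, 10, 25)) {
    expect_lt(max(abs(cor(C[, j], Z[, seq_len(j - 1)]))), 1e-8)
  }
})

test_that("applying transforms is idempotent and checks trait order", {
  st <- small_study()
  again <- apply_transforms(st$phen$discovery, st$transforms)
  expect_equal(again$PC, st$panels$PC)
  scrambled <- st$phen$discovery[, c(1:3, sample(4:28))]
  expect_error(apply_transforms(scrambled, st$transforms), "order")
  missing <- st$phen$discovery[, -5]
  expect_error(apply_transforms(missing, st$transforms), "missing trait")
})

test_that("validation scores obey the linear-map contract", {
  st <- small_study()
  ts <- st$transforms
  val_sets <- apply_transforms(st$phen$validation, ts)
  X <- as.matrix(st$phen$validation[, ts$traits])
  Z <- sweep(sweep(X, 2, ts$means), 2, ts$sds, "/")
  expect_equal(unname(as.matrix(val_sets$PC[, -(1:3)])), unname(Z %*% ts$rotation),
               tolerance = 1e-12)
})

test_that("subset refits behave as nested Cholesky / fresh eigen problems", {
  st <- small_study()
  traits <- panel_traits(st$phen$discovery)
  full <- fit_transforms(st$phen$discovery)
  same <- subset_refit(st$phen$discovery, traits)
  expect_equal(same$eigenvalues, full$eigenvalues)
  expect_equal(same$L, full$L)

  p3 <- st$phen$discovery[, c(1:3, 4:6)]  # first three traits
  f3 <- fit_transforms(p3)
  f2 <- subset_refit(p3, panel_traits(p3)[1:2])
  expect_equal(f2$L, f3$L[1:2, 1:2], tolerance = 1e-12)

  fmid <- subset_refit(p3, panel_traits(p3)[c(1, 3)])
  expect_false(isTRUE(all.equal(fmid$eigenvalues, f3$eigenvalues[1:2])))
  expect_error(subset_refit(p3, panel_traits(p3)[1]), "fewer than 2")
})

test_that("transforms serialize losslessly", {
  st <- small_study()
  path <- withr::local_tempfile(fileext = ".json")
  write_transforms(st$transforms, path)
  back <- read_transforms(path)
  expect_equal(back$rotation, st$transforms$rotation, tolerance = 1e-12)
  expect_equal(back$L, st$transforms$L, tolerance = 1e-12)
  expect_equal(back$means, st$transforms$means, tolerance = 1e-12)
  sets1 <- apply_transforms(st$phen$validation, st$transforms)
  sets2 <- apply_transforms(st$phen$validation, back)
  expect_equal(sets1$CT, sets2$CT, tolerance = 1e-10)
})

test_that("collinear traits are rejected with the pair named", {
  panel <- panel_with_exact_cov(100, diag(3), seed = 4)
  panel$T03 <- panel$T01
  expect_error(fit_transforms(panel), "T01")
})
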