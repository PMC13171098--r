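# TDR subspace, uniform shift, normalised projections, PCA utility.

planted <- function(n_units = 24, w = 0.3, sigma = 0, seed = 5) {
  synth_prep_activity(planted_truth(n_units, w = w, sigma = sigma,
                                    seed = seed))
}

test_that("TDR basis is orthonormal and recovers a planted subspace", {
  px <- planted()
  tdr <- fit_tdr(px$H$NF1, px$F)
  expect_equal(crossprod(tdr$What), diag(2), tolerance = 1e-10)
  # principal angles against the independently computed planted subspace
  Wtrue <- rbind(px$truth$M, px$truth$c)
  Wplus_true <- MASS::ginv(Wtrue)[, 1:2]
  qa <- qr.Q(qr(Wplus_true)); qb <- tdr$What
  angles <- acos(pmin(1, svd(crossprod(qa, qb))$d))
  expect_lt(max(angles), 1e-6)
  # consistent row permutation leaves the basis unchanged
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  tdr_p <- fit_tdr(px$H$NF1[perm, ], px$F[perm, ])
  expect_equal(tdr_p$What, tdr$What, tolerance = 1e-8)
  expect_error(fit_tdr(px$H$NF1, matrix(1, 8, 2)), "rank")
})

test_that("TDR projections form a ring ordered like the targets", {
  px <- planted(sigma = 0)
  tdr <- fit_tdr(px$H$NF1, px$F)
  gm <- colMeans(px$H$NF1)
  # rows equal to the global mean project to zero
  Hm <- matrix(gm, 8, length(gm), byrow = TRUE)
  expect_equal(project_onto_tdr(Hm, tdr, gm), matrix(0, 8, 2),
               tolerance = 1e-10)
  # angular order of the projected points is a cyclic traversal of the
  # target order (the plane map need not be conformal, so the ring may be
  # sheared, but the ordering survives)
  pr <- project_onto_tdr(px$H$NF1, tdr, gm)
  ang <- atan2(pr[, 2], pr[, 1])
  o <- order(ang)
  s <- which(o == 1)
  oc <- o[c(s:8, seq_len(s - 1))]
  expect_true(identical(oc, 1:8) || identical(oc, c(1L, 8:2)))
  # with an orthonormal readout (a conformal plane map) a rotation of the
  # planted force targets rotates the projected ring by exactly that angle
  set.seed(13)
  Mo <- t(qr.Q(qr(matrix(rnorm(24 * 3), 24, 3))))  # orthonormal rows
  Hc <- cbind(px$F, 1) %*% Mo
  tdr_c <- fit_tdr(Hc, px$F)
  th <- -pi / 7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  H_rot <- cbind(px$F %*% t(R), 1) %*% Mo
  p0 <- project_onto_tdr(Hc, tdr_c, colMeans(Hc))
  p1 <- project_onto_tdr(H_rot, tdr_c, colMeans(H_rot))
  a0 <- atan2(p0[, 2], p0[, 1]); a1 <- atan2(p1[, 2], p1[, 1])
  dang <- (a1 - a0 + pi) %% (2 * pi) - pi
  expect_equal(sd(dang), 0, tolerance = 1e-6)
  expect_equal(abs(dang[1]), pi / 7, tolerance = 1e-6)
})

test_that("uniform shift is orthogonal to the TDR plane and recoverable", {
  px <- planted(sigma = 0)
  tdr <- fit_tdr(px$H$NF1, px$F)
  us <- compute_uniform_shift(px$H$FF1, px$H$NF1, tdr)
  expect_equal(drop(t(tdr$What) %*% us$us), c(0, 0), tolerance = 1e-10)
  cosine <- sum(us$us * px$truth$s) /
    sqrt(sum(us$us^2) * sum(px$truth$s^2))
  expect_gt(cosine, 0.999)
  # identical phases give a zero shift
  us0 <- compute_uniform_shift(px$H$NF1, px$H$NF1, tdr)
  expect_equal(sqrt(sum(us0$us^2)), 0, tolerance = 1e-12)
})

test_that("normalised projections anchor NF1 to 0, FF1 to 1, washout to w", {
  for (w in c(0, 0.3, 0.5)) {
    px <- planted(w = w, sigma = 0)
    tdr <- fit_tdr(px$H$NF1, px$F)
    us <- compute_uniform_shift(px$H$FF1, px$H$NF1, tdr)
    pr <- project_and_normalize(px$H, us)
    expect_equal(unname(pr["NF1"]), 0, tolerance = 1e-10)
    expect_equal(unname(pr["FF1"]), 1, tolerance = 1e-10)
    expect_equal(unname(pr["NF2"]), w, tolerance = 1e-8)
    expect_equal(unname(pr["FF2"]), 1, tolerance = 1e-8)
  }
})

test_that("projections are invariant to a common offset when the mean is recomputed", {
  px <- planted(w = 0.4, sigma = 0.02, seed = 9)
  tdr <- fit_tdr(px$H$NF1, px$F)
  us <- compute_uniform_shift(px$H$FF1, px$H$NF1, tdr)
  pr1 <- project_and_normalize(px$H, us)
  off <- rnorm(ncol(px$H$NF1))
  H2 <- lapply(px$H, function(H) sweep(H, 2, off, "+"))
  pr2 <- project_and_normalize(H2, us)
  expect_equal(pr1, pr2, tolerance = 1e-8)
})

test_that("PCA projection captures planted low-rank structure", {
  set.seed(6)
  basis <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  scores <- matrix(rnorm(200 * 3), 200, 3) %*% diag(c(3, 2, 1))
  X <- scores %*% t(basis)
  pc <- pca_project(X, k = 3)
  expect_gt(sum(pc$sdev[1:3]^2) / sum(pc$sdev^2), 0.999)
  expect_true(all(diff(pc$sdev) <= 1e-12))
  # reconstruction from all components is exact
  full <- pca_project(X, k = ncol(X))
  recon <- sweep(full$scores %*% t(pc$rotation[, seq_len(ncol(full$scores))]),
                 2, -pc$center)
  expect_equal(recon, X, tolerance = 1e-8)
})
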