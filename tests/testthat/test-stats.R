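# corona_stats: LDA, metrics, t-tests, ellipses, blind validation, SAXS fit.

make_cohort <- function(n0, n1, mu0, mu1, cov0, cov1 = cov0, seed = 1,
                        labels = c("NOP", "PDAC")) {
  set.seed(seed)
  rmv <- function(n, mu, S) {
    A <- chol(S)
    sweep(matrix(rnorm(2 * n), ncol = 2) %*% A, 2, mu, `+`)
  }
  maglev_cohort(rbind(rmv(n0, mu0, cov0), rmv(n1, mu1, cov1)),
                rep(labels, c(n0, n1)))
}

test_that("LDA recovers symmetric and isotropic geometry", {
  # classes symmetric about the origin along x: boundary is the y-axis
  co <- make_cohort(40, 40, c(-3, 0), c(3, 0), diag(c(1, 1)), seed = 2)
  m <- lda_fit(co, "PDAC")
  expect_lt(abs(m$weights[2] / m$weights[1]), 0.25)
  expect_lt(abs(m$threshold), 0.5)
  # isotropic covariance: w parallel to the mean difference
  co2 <- make_cohort(200, 200, c(0, 0), c(2, 1), diag(2), seed = 3)
  m2 <- lda_fit(co2, "PDAC")
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  expect_lt(ang(m2$weights, c(2, 1)), 0.15)
})

test_that("LDA maximizes the Fisher criterion vs a direction grid", {
  fisher_J <- function(w, co, pos = "PDAC", neg = "NOP") {
    x0 <- co$points[co$labels == neg, ]; x1 <- co$points[co$labels == pos, ]
    Sp <- ((nrow(x0) - 1) * cov(x0) + (nrow(x1) - 1) * cov(x1)) /
      (nrow(x0) + nrow(x1) - 2)
    drop((sum(w * (colMeans(x1) - colMeans(x0))))^2 /
           (t(w) %*% Sp %*% w))
  }
  set.seed(9)
  for (i in 1:10) {
    S <- crossprod(matrix(rnorm(4), 2)) + diag(0.3, 2)
    co <- make_cohort(25, 25, rnorm(2), rnorm(2, 1), S, seed = 30 + i)
    m <- lda_fit(co, "PDAC")
    thetas <- seq(0, pi, length.out = 721)[-721]
    J_grid <- max(vapply(thetas, function(t)
      fisher_J(c(cos(t), sin(t)), co), numeric(1)))
    expect_gte(fisher_J(m$weights, co), J_grid * (1 - 0.01))
  }
})

test_that("classification tallies confusion counts that partition the cohort", {
  co <- make_cohort(30, 30, c(0, 0), c(6, 0), diag(2), seed = 4)
  m <- lda_fit(co, "PDAC")
  # class means classify to their own class
  own <- lda_classify(m, m$class_means)
  expect_equal(own$labels, c("NOP", "PDAC"))
  res <- lda_classify(m, co$points, co$labels)
  cc <- res$confusion
  expect_equal(cc$tn + cc$fp + cc$fn + cc$tp, 60)
  # 6 sigma separation: Gaussian tail bound predicts no errors in 60 draws
  expect_equal(cc$fp + cc$fn, 0)
})

test_that("metrics implement the stated definitions", {
  m1 <- classification_metrics(confusion_counts(tn = 14, fp = 1,
                                                fn = 1, tp = 14))
  expect_equal(round(100 * unlist(m1[1:3]), 1),
               c(specificity = 93.3, sensitivity = 93.3, accuracy = 93.3))
  m2 <- classification_metrics(confusion_counts(tn = 14, fp = 1,
                                                fn = 2, tp = 3))
  expect_equal(m2$specificity, 14 / 15)
  expect_equal(m2$sensitivity, 0.6)
  expect_equal(m2$accuracy, 0.85)
  perfect <- classification_metrics(confusion_counts(10, 0, 0, 10))
  expect_equal(unlist(perfect[1:3]), c(specificity = 1, sensitivity = 1,
                                       accuracy = 1))
  undef <- classification_metrics(confusion_counts(0, 0, 2, 8))
  expect_true(is.na(undef$specificity))
  expect_equal(undef$undefined, "specificity")
})

test_that("metric identity holds on random confusion counts", {
  set.seed(12)
  for (i in 1:50) {
    cc <- confusion_counts(sample(1:30, 1), sample(0:10, 1),
                           sample(0:10, 1), sample(1:30, 1))
    m <- classification_metrics(cc)
    n_neg <- cc$tn + cc$fp; n_pos <- cc$tp + cc$fn
    expect_equal(m$accuracy,
                 (m$specificity * n_neg + m$sensitivity * n_pos) /
                   (n_neg + n_pos))
  }
})

test_that("pooled t-test matches stats::t.test(var.equal = TRUE)", {
  expect_equal(student_t(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  # large shift: textbook-significant
  expect_lt(student_t(c(1, 2, 3), c(11, 12, 13))$p, 1e-3)
  set.seed(17)
  for (i in 1:100) {
    a <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    ref <- t.test(a, b, var.equal = TRUE)
    got <- student_t(a, b)
    expect_lt(abs(got$p - ref$p.value), 1e-10)
    expect_lt(abs(got$t - unname(ref$statistic)), 1e-10)
  }
  # degenerate inputs
  expect_equal(student_t(c(1, 1, 1), c(1, 1))$p, 1)
  dg <- student_t(c(1, 1, 1), c(2, 2))
  expect_equal(dg$p, 0)
  expect_true(dg$degenerate)
})

test_that("p-value matrix is symmetric with unit diagonal", {
  set.seed(23)
  pts <- cbind(rnorm(40), rnorm(40))
  labs <- rep(c("NOP", "breast", "prostate", "PDAC"), each = 10)
  co <- maglev_cohort(pts, labs)
  pm <- pairwise_pvalue_matrix(co)
  expect_equal(pm, t(pm))
  expect_equal(diag(pm), setNames(rep(1, 4), unique(labs)))
  # a strongly shifted class dominates its row
  pts2 <- pts; pts2[labs == "PDAC", 1] <- pts2[labs == "PDAC", 1] + 6
  pm2 <- pairwise_pvalue_matrix(maglev_cohort(pts2, labs))
  others <- setdiff(colnames(pm2), "PDAC")
  expect_lt(max(pm2["PDAC", others]),
            min(pm2[others, others][upper.tri(diag(length(others)))]))
  expect_lt(max(pm2["PDAC", others]), 1e-4)
})

test_that("confidence ellipse has the closed-form isotropic radius", {
  set.seed(31)
  pts <- cbind(rnorm(2000, sd = 2), rnorm(2000, sd = 2))
  e <- confidence_ellipse(pts, 0.95)
  r_expect <- 2 * sqrt(qchisq(0.95, 2))
  expect_equal(unname(e$semi_axes), rep(r_expect, 2), tolerance = 0.08)
  # rotation equivariance
  phi <- 0.7
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  pts_aniso <- cbind(rnorm(500, sd = 3), rnorm(500, sd = 0.5))
  e1 <- confidence_ellipse(pts_aniso)
  e2 <- confidence_ellipse(t(R %*% t(pts_aniso)))
  d_ang <- (e2$orientation - e1$orientation - phi) %% pi
  expect_lt(min(d_ang, pi - d_ang), 0.02)
  expect_equal(e1$semi_axes, e2$semi_axes, tolerance = 1e-6)
})

test_that("95% ellipse Monte-Carlo coverage is 0.95 within 0.01", {
  set.seed(41)
  S <- matrix(c(2, 0.8, 0.8, 1), 2)
  A <- chol(S)
  pts <- matrix(rnorm(2e5), ncol = 2) %*% A
  e <- confidence_ellipse(pts, 0.95)
  expect_equal(mean(in_ellipse(e, pts)), 0.95, tolerance = 0.01 / 0.95)
})

test_that("blind validation enforces donor disjointness and scores holdouts", {
  co <- make_cohort(20, 20, c(0, 0), c(6, 0), diag(2), seed = 5)
  m <- lda_fit(co, "PDAC")
  hold <- make_cohort(5, 5, c(0, 0), c(6, 0), diag(2), seed = 6)
  hold$donor_ids <- paste0("h", 1:10)
  bv <- blind_validation(m, hold)
  expect_equal(bv$metrics$accuracy, 1)            # well-separated classes
  expect_match(bv$provenance$model_hash, "^[0-9a-f]{8}$")
  # donor overlap is a protocol violation
  bad <- hold; bad$donor_ids[1] <- co$donor_ids[1]
  expect_error(blind_validation(m, bad), "protocol violation")
})

test_that("power-law exponent fit is exact on noiseless curves", {
  q <- 10^seq(-1, 0, length.out = 50)
  expect_equal(powerlaw_exponent(q, q^-2)$D, 2, tolerance = 1e-12)
  fit3 <- powerlaw_exponent(q, 7.3 * q^-3)
  expect_equal(fit3$D, 3, tolerance = 1e-12)      # amplitude-independent
  expect_lt(fit3$se, 1e-10)
  expect_error(powerlaw_exponent(q[1:4], q[1:4]^-2), "at least 5")
  expect_error(powerlaw_exponent(-q, q^-2), "positive")
})

test_that("power-law fit recovers the generator exponent from noisy data", {
  sx <- generate_saxs_curve(exponent = 2.01, noise_cv = 0.02, seed = 13)
  fit <- powerlaw_exponent(sx$q, sx$intensity)
  expect_lt(abs(fit$D - 2.01), 2 * fit$se)
})
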