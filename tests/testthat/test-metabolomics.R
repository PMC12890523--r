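test_that("KNN imputation fills gaps from the nearest metabolites", {
  set.seed(20)
  X <- matrix(runif(8 * 5, 10, 20), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("m", 1:5)))
  expect_identical(impute_knn(X), X)   # complete matrix untouched

  # k = 1 with an identical neighbour column: imputed to that neighbour
  Xd <- X
  Xd[, 2] <- Xd[, 1]
  Xd[3, 1] <- NA
  got <- impute_knn(Xd, k = 1)
  expect_equal(got[3, 1], Xd[3, 2])
  expect_equal(got[-3, ], Xd[-3, ])    # observed entries untouched

  # constant matrix: imputed to the constant
  Xc <- matrix(7, 6, 4, dimnames = list(NULL, paste0("m", 1:4)))
  Xc[2, 3] <- NA
  expect_equal(unname(impute_knn(Xc, k = 2)[2, 3]), 7)

  Xbad <- X
  Xbad[, 4] <- NA
  expect_error(impute_knn(Xbad), "no observed value")

  # averaging: with k = 2 and two equally informative neighbours
  Xa <- cbind(m1 = c(1, 2, 3, 4), m2 = c(1, 2, 3, 4) + 0.1,
              m3 = c(1, 2, 3, 4) - 0.1, m4 = c(100, 90, 80, 70))
  Xa[2, 1] <- NA
  expect_equal(unname(impute_knn(Xa, k = 2)[2, 1]), 2)
})

test_that("log2 autoscaling centres and unit-scales each metabolite", {
  X <- cbind(m1 = c(2, 8), m2 = c(4, 16))
  Z <- log2_autoscale(X)
  # log2 {2,8} -> {1,3} -> (x - 2)/sd, sd with the n-1 denominator
  expect_equal(unname(Z[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(Z[, 1]), c(-0.7071, 0.7071), tolerance = 1e-4)

  set.seed(21)
  X2 <- matrix(2^runif(60, 5, 15), 10, 6,
               dimnames = list(NULL, paste0("m", 1:6)))
  Z2 <- log2_autoscale(X2)
  expect_equal(unname(colMeans(Z2)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(Z2, 2, sd)), rep(1, 6), tolerance = 1e-12)
  # idempotent up to the affine transform: rescaling scaled data is a no-op
  expect_equal(log2_autoscale(2^Z2), Z2, tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(log2_autoscale(cbind(m1 = c(-1, 2))), "strictly positive")
  expect_error(log2_autoscale(cbind(m1 = c(2, 2), m2 = c(1, 4))), "m1")
})

test_that("volcano gates follow the declared boundary conventions", {
  # identical groups: nothing significant
  set.seed(22)
  base <- matrix(2^rnorm(40, 12, 0.3), 8, 5,
                 dimnames = list(NULL, paste0("m", 1:5)))
  v0 <- volcano(base, rep(c("a", "b"), each = 4))
  expect_false(any(v0$significant))

  # single metabolite: BH leaves the p-value unchanged
  one <- cbind(m1 = c(10, 10.2, 9.9, 20, 20.4, 19.8))
  v1 <- volcano(one, rep(c("a", "b"), each = 3))
  expect_equal(v1$q, v1$p)

  # raw-scale group means 12 vs 10: FC exactly 1.2, inclusive gate passes
  x12 <- cbind(m1 = c(9.9, 10.1, 11.9, 12.1), m2 = c(9.95, 10.05, 11.5, 11.9))
  v2 <- volcano(x12, rep(c("a", "b"), each = 2), q_threshold = 2)
  expect_equal(v2$fc[1], 1.2)
  expect_true(v2$significant[1])       # q < 2 always; FC gate decides
  expect_false(v2$significant[2])      # FC 1.17 misses the inclusive gate

  # direction-agnostic: a 1/1.3 fold drop also passes the FC gate
  xdn <- cbind(m1 = c(13, 13, 10, 10) + c(-0.1, 0.1, -0.1, 0.1))
  v3 <- volcano(xdn, rep(c("a", "b"), each = 2), q_threshold = 2)
  expect_lt(v3$fc[1], 1)
  expect_true(v3$significant[1])

  expect_error(volcano(base[1:3, ], c("a", "a", "b")), "at least 2")
})

test_that("BH adjustment and type-I behaviour match a brute-force step-up", {
  set.seed(23)
  for (rep_i in 1:10) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # null matrices: BH keeps the expected significant count far below 5%
  sig_counts <- vapply(1:10, function(s) {
    m0 <- make_metabolite_matrix(5, 483, n_affected = 0, effect_log2fc = 0,
                                 missing_rate = 0, noise_sd = 0.5,
                                 seed = 300 + s)
    sum(volcano(m0)$significant)
  }, numeric(1))
  expect_lte(mean(sig_counts), 0.05 * 483)
})

test_that("pathway impact is the VIP-weighted significant fraction", {
  vip <- c(a1 = 2, a2 = 1, a3 = 1, b1 = 0.5, b2 = 0.5, zz = 9)
  map <- data.frame(pathway = c("A", "A", "A", "B", "B"),
                    metabolite = c("a1", "a2", "a3", "b1", "b2"))

  all_sig <- pathway_impact(map, vip, c("a1", "a2", "a3", "b1", "b2"))
  expect_equal(all_sig$impact, c(1, 1))
  expect_equal(attr(all_sig, "total"), 2)

  none <- pathway_impact(map, vip, character(0))
  expect_equal(none$impact, c(0, 0))

  half <- pathway_impact(map, vip, "a1")   # VIPs {2,1,1}, first significant
  expect_equal(half$impact[half$pathway == "A"], 0.5)
  expect_equal(half$impact[half$pathway == "B"], 0)

  # invariant to metabolites outside the pathway
  vip2 <- vip; vip2["zz"] <- 0.001
  half2 <- pathway_impact(map, vip2, c("a1", "zz"))
  expect_equal(half2$impact, half$impact)

  expect_error(pathway_impact(map, vip[-1], "a1"), "absent")
  expect_error(pathway_impact(map, replace(vip, 4:5, 0), "a1"), "zero total")
})

test_that("the full metabolomics workflow flags planted pathways", {
  mm <- make_metabolite_matrix(8, 60, n_affected = 12, effect_log2fc = 1.5,
                               missing_rate = 0.08, noise_sd = 0.3, seed = 24)
  mmc <- impute_knn(mm)
  expect_false(anyNA(mmc$intensities))
  Z <- log2_autoscale(mmc)
  fit <- plsda(Z, mm$group, ncomp = 2)
  v <- vip_scores(fit)
  vres <- volcano(mmc)
  # affected metabolites dominate both the VIP ranking and the volcano set
  expect_gt(mean(rank(-v)[1:12] <= 15), 0.8)
  expect_gt(mean(vres$significant[1:12]), 0.8)
  expect_lt(mean(vres$significant[13:60]), 0.1)

  map <- data.frame(
    pathway = rep(c("planted", "background"), each = 6),
    metabolite = c(colnames(mmc$intensities)[1:6],
                   colnames(mmc$intensities)[31:36]))
  pw <- pathway_impact(map, v, vres$metabolite[vres$significant])
  expect_gt(pw$impact[pw$pathway == "planted"],
            pw$impact[pw$pathway == "background"])

  # CSV round trip of the matrix
  csv <- tempfile(fileext = ".csv")
  write_metabolite_csv(mm, csv)
  back <- read_metabolite_csv(csv)
  expect_equal(back$intensities, mm$intensities)
  expect_equal(back$group, mm$group, ignore_attr = TRUE)
})
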