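test_that("event-count estimate inverts Poisson occupancy", {
  expect_equal(estimate_event_count(1000, 0), 0)
  expect_error(estimate_event_count(1000, 1000), "saturated")
  # round trip m -> expected unique -> m
  for (m in c(1, 50, 500, 5000)) {
    n <- 1000
    u <- n * (1 - exp(-m / n))
    expect_equal(estimate_event_count(n, u), m, tolerance = 1e-9)
  }
  expect_true(all(diff(estimate_event_count(1000, 0:999)) > 0))
  expect_true(all(estimate_event_count(1000, 1:999) >= 1:999))
})

test_that("event-count estimate agrees with a colony-dropping simulation", {
  # oracle: drop round(m) colonies uniformly over n sites and count the
  # distinct sites hit; the estimator applied to the mean unique count
  # should recover m
  n <- 1000
  m_hat <- estimate_event_count(n, 100)
  expect_equal(m_hat, 105.3605, tolerance = 1e-4)
  set.seed(301)
  uniq <- replicate(400, length(unique(sample.int(n, round(m_hat),
                                                  replace = TRUE))))
  expect_lt(abs(mean(uniq) - 100), 3 * sd(uniq) / sqrt(length(uniq)))
})

test_that("location-bias fit recovers flat and planted polynomials", {
  L <- 2e6
  set.seed(11)
  pos <- sort(sample.int(L, 60000)) - 1L
  sites <- data.frame(position = pos, inserted = runif(60000) < 0.18,
                      excluded = FALSE)
  attr(sites, "genome_length") <- L
  flat <- fit_location_bias(sites, L)
  expect_lt(abs(flat$coeffs["a"]), 3 * flat$se["a"] + 1e-3)
  expect_lt(abs(flat$coeffs["b"]), 3 * flat$se["b"] + 1e-2)
  # flat signal: intercept recovers the event rate -log(1 - 0.18)
  expect_equal(unname(flat$coeffs["c"]), -log(1 - 0.18),
               tolerance = 0.05)

  # planted polynomial over a 5 Mb chromosome, >= 50 windows
  L <- 5e6
  set.seed(12)
  pos <- sort(sample.int(L, 150000)) - 1L
  truth <- c(a = 0.003, b = 0.008, c = 0.16)
  lam <- tifa:::loc_poly(midpoint_coord(pos, L), truth)
  sites <- data.frame(position = pos,
                      inserted = runif(length(pos)) < 1 - exp(-lam),
                      excluded = FALSE)
  attr(sites, "genome_length") <- L
  fit <- fit_location_bias(sites, L)
  expect_gt(nrow(fit$windows), 50)
  for (k in c("a", "b", "c")) {
    expect_lt(abs(fit$coeffs[k] - truth[k]), 4 * fit$se[k])
  }
})

test_that("location weights average to one and reproduce the origin bias", {
  coeffs <- c(a = 0.0032, b = 0.0081, c = 0.1615)
  # polynomial evaluation: midpoint value is the intercept
  expect_equal(tifa:::loc_poly(0, coeffs), 0.1615)
  L <- 5e6
  model <- list(loc_coeffs = coeffs, genome_length = L, norm = 1)
  f_origin <- location_weight(0, model)
  f_mid <- location_weight(L / 2, model)
  expect_equal(f_origin / f_mid, 1.249, tolerance = 0.01)

  pos <- seq(0, L - 1, by = 37)
  model$norm <- mean(tifa:::loc_poly(midpoint_coord(pos, L), coeffs))
  expect_equal(mean(location_weight(pos, model)), 1, tolerance = 1e-12)
  # constant polynomial: weight 1 everywhere
  cmodel <- list(loc_coeffs = c(a = 0, b = 0, c = 0.2), norm = 0.2,
                 genome_length = L)
  expect_equal(location_weight(c(0, 1e6, 4e6), cmodel), rep(1, 3))
})

test_that("binomial prescreen keeps unbiased genes only", {
  expect_true(select_unbiased_genes(10, 3, 0.3))
  # s=50, t=0: direct-summation tail prod(1-p) = 0.3^0 * 0.7^50
  tail0 <- prod(rep(0.7, 50))
  expect_equal(tail0, 1.798465e-08, tolerance = 1e-6)
  expect_false(select_unbiased_genes(50, 0, 0.3))
  expect_true(select_unbiased_genes(1, 1, 0.3))
  expect_false(select_unbiased_genes(0, 0, 0.3))  # s = 0 excluded
})

test_that("motif probability estimation is symmetric and handles zeros", {
  cls <- enumerate_motif_classes()$motif_class
  # two classes with identical tallies, one never inserted
  sites <- data.frame(
    motif_class = rep(cls[1:3], each = 100),
    inserted = c(rep(c(TRUE, FALSE), 50), rep(c(TRUE, FALSE), 50),
                 rep(FALSE, 100)),
    excluded = FALSE)
  mp <- estimate_motif_probabilities(sites)
  got <- mp[match(cls[1:3], mp$motif_class), ]
  expect_equal(got$p_hat[1], got$p_hat[2])
  expect_equal(got$p_hat[3], 0)
  expect_gt(got$var[3], 0)     # rule-of-three keeps the weight finite
  expect_true(all(mp$absent[!mp$motif_class %in% cls[1:3]]))
  # saturated class is capped with a warning
  sat <- data.frame(motif_class = rep(cls[1], 10), inserted = TRUE,
                    excluded = FALSE)
  expect_warning(estimate_motif_probabilities(sat), "saturated")
})

test_that("motif spectrum is recovered up to scale on simulated sites", {
  cls <- enumerate_motif_classes()$motif_class
  set.seed(77)
  spectrum <- setNames(10^runif(136), cls)
  n_per <- 600
  lam <- rep(spectrum, each = n_per) * 0.25 / mean(spectrum)
  sites <- data.frame(motif_class = rep(cls, each = n_per),
                      inserted = runif(length(lam)) < 1 - exp(-lam),
                      excluded = FALSE)
  mp <- estimate_motif_probabilities(sites)
  truth_rate <- 0.25 * spectrum[mp$motif_class] / mean(spectrum)
  scale <- sum(mp$p_hat * mp$n) / sum(truth_rate * mp$n)
  # delta-method SE of the zero-truncation estimate
  frac <- mp$u / mp$n
  se <- sqrt(frac * (1 - frac) / mp$n) / (1 - frac)
  z <- (mp$p_hat - scale * truth_rate) / se
  expect_gt(mean(abs(z) < 3), 0.95)
})

test_that("independence fit flags multiplicative vs interacting spectra", {
  cls <- enumerate_motif_classes()
  nt <- c("A", "C", "G", "T")
  qo <- c(A = 1.6, C = 0.6, G = 0.8, T = 1.0)
  qi <- c(A = 0.5, C = 0.9, G = 1.2, T = 1.4)
  qo <- qo / mean(qo); qi <- qi / mean(qi)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  S <- 0.2
  pred <- function(m) {
    S * qo[substr(m, 1, 1)] * qi[substr(m, 2, 2)] *
      qi[comp[substr(m, 5, 5)]] * qo[comp[substr(m, 6, 6)]]
  }
  mp <- data.frame(motif_class = cls$motif_class,
                   n = 1000, u = 200,
                   p_hat = unname(pred(cls$motif_class)),
                   var = 1e-8, absent = FALSE)
  fit <- fit_independent_nucleotide_model(mp)
  expect_lt(fit$chisq, 1e-3)
  expect_gt(fit$p_value, 0.99)
  expect_equal(unname(fit$contributions["pos_m2", ]), unname(qo[nt]),
               tolerance = 1e-3)
  expect_equal(unname(fit$contributions["pos_m1", ]), unname(qi[nt]),
               tolerance = 1e-3)
  expect_equal(fit$scale, S, tolerance = 1e-3)

  # a single class boosted 30% breaks independence detectably
  mp2 <- mp
  mp2$var <- (0.02 * mp2$p_hat)^2
  k <- which(mp2$motif_class == "TATATG")
  mp2$p_hat[k] <- 1.3 * mp2$p_hat[k]
  fit2 <- fit_independent_nucleotide_model(mp2)
  expect_lt(fit2$p_value, 0.01)

  # chi-square invariant under permutation of class order
  set.seed(5)
  fit3 <- fit_independent_nucleotide_model(mp2[sample.int(nrow(mp2)), ])
  expect_equal(fit3$chisq, fit2$chisq, tolerance = 1e-4)

  # a flat spectrum yields flat contributions
  mp4 <- mp
  mp4$p_hat <- 0.2
  fit4 <- fit_independent_nucleotide_model(mp4)
  expect_equal(unname(fit4$contributions), matrix(1, 4, 4),
               tolerance = 1e-3)
})

test_that("site probabilities scale to the event total and saturate", {
  fx <- small_fitted()
  p <- site_probability(fx$sites, fx$model)
  expect_true(all(p >= 0 & p < 1))
  expect_equal(sum(p[fx$sites$excluded]), 0)
  # lambda sums to m by construction: sum(-log(1-p)) = m
  expect_equal(sum(-log(1 - p[!fx$sites$excluded])), fx$model$m_events,
               tolerance = 1e-8)
  # self-consistency: expected unique sites ~ observed unique sites
  # (sum(1 - exp(-lambda_i)) sits below the homogeneous-rate value by a
  # Jensen gap that grows with rate spread, here ~10x)
  keep <- !fx$sites$excluded
  expect_equal(sum(p[keep]), sum(fx$sites$inserted[keep]),
               tolerance = 0.1)
  # uniform model: identical probabilities everywhere
  um <- fx$model
  um$loc_coeffs <- c(a = 0, b = 0, c = 0.2)
  um$norm <- 0.2
  um$motif_probs$p_hat[!um$motif_probs$absent] <- 0.3
  pu <- site_probability(fx$sites, um, m = 1000)
  expect_equal(length(unique(round(pu[!fx$sites$excluded], 12))), 1L)
})
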