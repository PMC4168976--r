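#' Estimate insertion events from unique inserted sites
#'
#' The same insertion may arise in several independent colonies; the number
#' of insertion events is therefore estimated from the TA locations that
#' were *not* hit. With `m` colonies over `n` sites, per-site event counts
#' are approximately Poisson with rate `m/n`, so the expected unique-site
#' count is `n(1 - exp(-m/n))`. Inverting gives `m = -n log(1 - u/n)`.
#'
#' @param n_sites number of TA sites considered.
#' @param u_unique number of distinct sites observed inserted.
#' @return estimated number of insertion events (colonies), `>= u_unique`.
#' @export
estimate_event_count <- function(n_sites, u_unique) {
  stopifnot(n_sites > 0, u_unique >= 0)
  if (any(u_unique >= n_sites))
    stop("all sites inserted: event estimate undefined (saturated)")
  -n_sites * log(1 - u_unique / n_sites)
}

loc_poly <- function(x, coeffs) {
  pmax(0, coeffs[1] * x^2 + coeffs[2] * abs(x) + coeffs[3])
}

#' Signed chromosome coordinate in megabases
#'
#' Maps a 0-based genome position to the signed distance from the
#' chromosome midpoint in Mb, with the replication origin (position 0) at
#' the extremes. This is the coordinate in which the location-bias
#' polynomial `f(x) = a x^2 + b |x| + c` is expressed.
#'
#' @param position 0-based positions.
#' @param genome_length chromosome length (nt).
#' @return numeric vector in `[-L/2, L/2)` Mb.
#' @export
midpoint_coord <- function(position, genome_length) {
  (position - genome_length / 2) / 1e6
}

#' Fit the chromosomal location bias polynomial
#'
#' Slides a window (default 20,000 nt, stepped by 2,000 nt; full-width
#' windows only) along the chromosome; per window the insertion frequency
#' is the Poisson-corrected event estimate at the window's TA sites divided
#' by the window's TA count. The frequencies are fitted against the
#' midpoint coordinate by ordinary least squares of
#' `f(x) = a x^2 + b |x| + c`.
#'
#' @param ta_sites `ta_sites` data.frame with `inserted` flags set.
#' @param genome_length chromosome length.
#' @param window window width in nt.
#' @param step window step in nt.
#' @return list with `coeffs` (named `a`, `b`, `c`), `se` (coefficient
#'   standard errors), and `windows` (center, x, n, u, freq).
#' @export
fit_location_bias <- function(ta_sites, genome_length,
                              window = 20000, step = 2000) {
  starts <- seq(0, genome_length - window, by = step)
  if (length(starts) < 3) stop("need at least 3 full windows")
  pos <- ta_sites$position
  ins <- ta_sites$inserted
  win <- lapply(starts, function(s) {
    in_w <- pos >= s & pos < s + window
    c(n = sum(in_w), u = sum(ins & in_w))
  })
  win <- do.call(rbind, win)
  wdf <- data.frame(center = starts + window / 2,
                    n = win[, "n"], u = win[, "u"])
  empty <- wdf$n == 0
  if (any(empty)) {
    warning(sum(empty), " window(s) without TA sites skipped")
    wdf <- wdf[!empty, , drop = FALSE]
  }
  # saturated windows would make the estimate singular; back off half a site
  u_eff <- pmin(wdf$u, wdf$n - 0.5)
  wdf$freq <- estimate_event_count(wdf$n, u_eff) / wdf$n
  wdf$x <- midpoint_coord(wdf$center, genome_length)
  fit <- stats::lm(freq ~ I(x^2) + abs(x), data = wdf)
  co <- stats::coef(fit)
  coeffs <- c(a = unname(co["I(x^2)"]), b = unname(co["abs(x)"]),
              c = unname(co["(Intercept)"]))
  # consecutive windows share (window - step)/window of their sites, so
  # naive OLS errors are optimistic by about sqrt(window/step)
  se <- sqrt(diag(stats::vcov(fit))) * sqrt(window / step)
  list(coeffs = coeffs,
       se = c(a = unname(se["I(x^2)"]), b = unname(se["abs(x)"]),
              c = unname(se["(Intercept)"])),
       windows = wdf)
}

#' Location weight of a genome position
#'
#' The location polynomial evaluated at the site, normalized by its mean
#' over all TA sites so that the average weight is exactly 1.
#'
#' @param position 0-based positions.
#' @param model a fitted `bias_model` (see [fit_bias_model()]), or a list
#'   with `loc_coeffs`, `norm` and `genome_length`.
#' @return numeric weights, mean 1 over all TA sites.
#' @export
location_weight <- function(position, model) {
  loc_poly(midpoint_coord(position, model$genome_length),
           model$loc_coeffs) / model$norm
}

#' Prescreen genes for motif estimation
#'
#' Motif-specific probabilities must be estimated on genes whose insertion
#' counts are not depleted by essentiality. A gene is kept iff the binomial
#' lower tail `P(X <= t_obs | s, p)` exceeds 0.1, i.e. it contains no fewer
#' insertions than expected by chance.
#'
#' @param s per-gene core TA-site counts.
#' @param t_obs per-gene observed inserted-site counts.
#' @param mean_prob genome-wide mean per-site insertion probability.
#' @return logical vector: gene selected?
#' @export
select_unbiased_genes <- function(s, t_obs, mean_prob) {
  ok <- s > 0
  sel <- rep(FALSE, length(s))
  sel[ok] <- stats::pbinom(t_obs[ok], s[ok], mean_prob) > 0.1
  sel
}

#' Estimate motif-class insertion probabilities
#'
#' Per canonical flanking class: the occurrences `n_j` and unique inserted
#' sites `u_j` are tallied, the event count `m_j` is recovered by the
#' Poisson zero-truncation estimate (multiplicity correction applied per
#' class), and the per-site event rate is `p_hat_j = m_j / n_j`. The
#' variance of the observed proportion, `(u/n)(1-u/n)/n`, supplies the
#' chi-square weights; classes with `u_j = 0` get a rule-of-three variance
#' so weights stay finite. Saturated classes (`u_j = n_j`) are capped with
#' a warning.
#'
#' @param ta_sites `ta_sites` restricted to the sites used for estimation
#'   (typically core sites of prescreened genes), with `inserted` set.
#' @return data.frame: `motif_class`, `n`, `u`, `p_hat`, `var`, `absent`.
#' @export
estimate_motif_probabilities <- function(ta_sites) {
  use <- !ta_sites$excluded & !is.na(ta_sites$motif_class)
  cls <- enumerate_motif_classes()$motif_class
  f <- factor(ta_sites$motif_class[use], levels = cls)
  n <- as.vector(table(f))
  u <- as.vector(tapply(ta_sites$inserted[use], f, sum, default = 0))
  sat <- n > 0 & u >= n
  if (any(sat)) {
    warning(sum(sat), " saturated motif class(es); probability capped")
    u[sat] <- n[sat] - 0.5
  }
  p_hat <- rep(NA_real_, length(cls))
  vr <- rep(NA_real_, length(cls))
  ok <- n > 0
  p_hat[ok] <- estimate_event_count(n[ok], u[ok]) / n[ok]
  frac <- u[ok] / n[ok]
  vr[ok] <- ifelse(u[ok] > 0,
                   frac * (1 - frac) / n[ok],
                   (3 / n[ok]) * (1 - 3 / n[ok]) / n[ok])
  data.frame(motif_class = cls, n = n, u = u, p_hat = p_hat, var = vr,
             absent = !ok, stringsAsFactors = FALSE)
}

motif_positions <- function(motif_class) {
  list(x1 = substr(motif_class, 1, 1), x2 = substr(motif_class, 2, 2),
       x5 = substr(motif_class, 5, 5), x6 = substr(motif_class, 6, 6))
}

#' Test independence of flanking-nucleotide contributions
#'
#' Fits the multiplicative model in which each class probability is the
#' product of independent per-position nucleotide contributions, by
#' weighted least squares with weights inversely proportional to the class
#' variances. Because canonical classes merge the two strand orientations,
#' the contributions are parameterized strand-symmetrically: an outer
#' factor (positions -2/+2, complement-indexed) and an inner factor
#' (positions -1/+1), each normalized to mean 1, times a global scale
#' (7 free parameters). The minimized weighted sum of squares is the
#' chi-square statistic; its p-value uses `classes - 7` degrees of freedom.
#'
#' @param motif_probs data.frame from [estimate_motif_probabilities()].
#' @param maxit optimizer iteration cap.
#' @return list: `contributions` (4 positions x ACGT matrix), `scale`,
#'   `chisq`, `df`, `p_value`, `fitted`, `converged`.
#' @export
fit_independent_nucleotide_model <- function(motif_probs, maxit = 1000) {
  mp <- motif_probs[!motif_probs$absent & motif_probs$var > 0, , drop = FALSE]
  if (nrow(mp) < 16) stop("need at least 16 motif classes with variance")
  nt <- c("A", "C", "G", "T")
  px <- motif_positions(mp$motif_class)
  i1 <- match(px$x1, nt); i2 <- match(px$x2, nt)
  i5 <- match(COMP[px$x5], nt); i6 <- match(COMP[px$x6], nt)
  w <- 1 / mp$var
  # gauge-fixed parameters: factor vectors have geometric mean 1, the
  # overall magnitude lives in the scale term only (7 effective dof)
  unpack <- function(theta) {
    list(qo = exp(theta[1:4] - mean(theta[1:4])),
         qi = exp(theta[5:8] - mean(theta[5:8])),
         s = exp(theta[9]))
  }
  obj <- function(theta) {
    q <- unpack(theta)
    pred <- q$s * q$qo[i1] * q$qi[i2] * q$qi[i5] * q$qo[i6]
    val <- sum(w * (mp$p_hat - pred)^2)
    if (!is.finite(val)) val <- .Machine$double.xmax / 1e10
    val
  }
  init <- c(rep(0, 8), log(max(mean(mp$p_hat), 1e-8)))
  fit <- stats::optim(init, obj, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  if (fit$convergence != 0)
    warning("independence fit did not fully converge; best point returned")
  q <- unpack(fit$par)
  qo <- q$qo; qi <- q$qi; s <- q$s
  scale <- s * mean(qo)^2 * mean(qi)^2
  qo <- qo / mean(qo); qi <- qi / mean(qi)
  contributions <- rbind(pos_m2 = qo, pos_m1 = qi,
                         pos_p1 = qi[match(COMP[nt], nt)],
                         pos_p2 = qo[match(COMP[nt], nt)])
  colnames(contributions) <- nt
  chisq <- fit$value
  df <- nrow(mp) - 7L
  list(contributions = contributions, scale = scale, chisq = chisq,
       df = df, p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       fitted = q$s * q$qo[i1] * q$qi[i2] * q$qi[i5] * q$qo[i6],
       converged = fit$convergence == 0)
}

#' Fit the full insertion-bias model
#'
#' Convenience wrapper: fits the location polynomial on all TA sites,
#' prescreens genes (binomial tail > 0.1) for motif estimation, estimates
#' motif-class probabilities on the prescreened core sites, and records the
#' genome-wide mean insertion probability and the location-weight
#' normalization constant.
#'
#' @param ta_sites `ta_sites` with `inserted` set (after filtering).
#' @param genes gene table from [assign_sites()] (with `core_idx`).
#' @param window,step location-bias window parameters.
#' @return object of class `bias_model`: list with `loc_coeffs`, `loc_se`,
#'   `windows`, `motif_probs`, `mean_prob`, `norm`, `genome_length`,
#'   `n_sites`, `u_sites`, `m_events`, `selected_genes`.
#' @export
fit_bias_model <- function(ta_sites, genes, window = 20000, step = 2000) {
  L <- attr(ta_sites, "genome_length")
  loc <- fit_location_bias(ta_sites, L, window = window, step = step)
  keep <- !ta_sites$excluded
  n <- sum(keep)
  u <- sum(ta_sites$inserted & keep)
  mean_prob <- u / n
  m <- estimate_event_count(n, u)
  t_obs <- vapply(genes$core_idx, function(i) sum(ta_sites$inserted[i]), 0L)
  sel <- select_unbiased_genes(genes$s, t_obs, mean_prob)
  sel_idx <- unique(unlist(genes$core_idx[sel], use.names = FALSE))
  motif <- estimate_motif_probabilities(ta_sites[sel_idx, , drop = FALSE])
  norm <- mean(loc_poly(midpoint_coord(ta_sites$position[keep], L),
                        loc$coeffs))
  structure(list(loc_coeffs = loc$coeffs, loc_se = loc$se,
                 windows = loc$windows, motif_probs = motif,
                 mean_prob = mean_prob, norm = norm, genome_length = L,
                 n_sites = n, u_sites = u, m_events = m,
                 selected_genes = sel),
            class = "bias_model")
}

#' Per-site insertion probabilities
#'
#' Each site's event rate `lambda_i` is proportional to its motif-class
#' rate times its location weight, scaled so the rates sum to the total
#' event count `m` over all non-excluded sites; the probability that the
#' site is observed inserted at least once is `p_i = 1 - exp(-lambda_i)`.
#' Sites in classes without an estimate fall back to the mean rate.
#'
#' @param ta_sites `ta_sites` data.frame.
#' @param model fitted `bias_model`.
#' @param m total insertion events (defaults to the model's estimate).
#' @return numeric vector `p_i` (0 for excluded sites).
#' @export
site_probability <- function(ta_sites, model, m = model$m_events) {
  if (is.null(model$loc_coeffs) || is.null(model$motif_probs))
    stop("bias model is not fitted")
  keep <- !ta_sites$excluded
  rate <- numeric(nrow(ta_sites))
  mrate <- model$motif_probs$p_hat[match(ta_sites$motif_class,
                                         model$motif_probs$motif_class)]
  mrate[is.na(mrate)] <- mean(model$motif_probs$p_hat, na.rm = TRUE)
  w <- location_weight(ta_sites$position, model)
  rate[keep] <- mrate[keep] * w[keep]
  lambda <- rate / sum(rate[keep]) * m
  p <- 1 - exp(-lambda)
  p[!keep] <- 0
  p
}
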