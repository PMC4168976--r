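#' Poisson-binomial probability mass function via the generating function
#'
#' Expands `G(x) = prod_i (1 - p_i + p_i x)` by iterative polynomial
#' multiplication; the coefficient of `x^t` is `P(X = t)`, the probability
#' that exactly `t` of the sites are inserted. Reduces to the binomial mass
#' function when all `p_i` are equal.
#'
#' @param probs per-site insertion probabilities in `[0, 1]`.
#' @return numeric vector of length `length(probs) + 1`: `P(X = 0..s)`.
#' @export
pgf_pmf <- function(probs) {
  stopifnot(all(probs >= 0 & probs <= 1))
  pmf <- 1
  for (p in probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  pmf
}

#' Lower cumulative probability `P(X <= t)`
#' @param pmf probability mass vector over `0..s`.
#' @param t observed count.
#' @return `P(X <= t)`.
#' @export
cumulative_lower <- function(pmf, t) {
  s <- length(pmf) - 1L
  if (t < 0 || t > s) stop("t out of range 0..", s)
  sum(pmf[seq_len(t + 1L)])
}

#' Upper cumulative probability `P(X >= t)`
#' @rdname cumulative_lower
#' @export
cumulative_upper <- function(pmf, t) {
  s <- length(pmf) - 1L
  if (t < 0 || t > s) stop("t out of range 0..", s)
  sum(pmf[seq.int(t + 1L, s + 1L)])
}

#' Normalized deviation of expectation
#'
#' `(E - t_obs) / sqrt(V)`: positive when a gene contains fewer insertions
#' than expected, the signature of essentiality.
#'
#' @param E expected inserted-site count, `sum(p_i)`.
#' @param V variance, `sum(p_i (1 - p_i))`.
#' @param t_obs observed inserted-site count.
#' @return the normalized deviation (`NA` when `V = 0`).
#' @export
nde <- function(E, V, t_obs) {
  ifelse(V > 0, (E - t_obs) / sqrt(V), NA_real_)
}

#' Build per-gene insertion probability models
#'
#' @param ta_sites `ta_sites` data.frame.
#' @param genes gene table from [assign_sites()].
#' @param p per-site probabilities from [site_probability()].
#' @return list of per-gene lists: `gene_id`, `probs`, `E`, `V`, `t_obs`,
#'   `lower` (attainable `P(X <= t)`, `t = 0..s`), `upper`
#'   (attainable `P(X >= t)`).
#' @export
gene_pmfs <- function(ta_sites, genes, p) {
  lapply(seq_len(nrow(genes)), function(g) {
    idx <- genes$core_idx[[g]]
    probs <- p[idx]
    pmf <- pgf_pmf(probs)
    lower <- cumsum(pmf)
    lower[length(lower)] <- 1
    upper <- rev(cumsum(rev(pmf)))
    upper[1] <- 1
    list(gene_id = genes$locus_id[g], probs = probs,
         E = sum(probs), V = sum(probs * (1 - probs)),
         t_obs = sum(ta_sites$inserted[idx]),
         lower = lower, upper = upper)
  })
}

#' Calibrate a call cutoff to a fixed expected false-positive count
#'
#' A gene is (falsely) called when its cumulative probability at the
#' observed count falls strictly below the cutoff `c`. Under the null
#' model, the marginal probability of a false call is the largest
#' attainable cumulative value below `c` (0 if none). The calibrated
#' cutoff is the largest `c` for which the marginals summed over genes do
#' not exceed `expected_fp`, found by bisection on this monotone step
#' function (tolerance 1e-12).
#'
#' @param cum_list list of per-gene attainable cumulative-probability
#'   vectors: `lower` vectors for the essential side, `upper` vectors for
#'   the nonessential side (each sorted when ascending; `upper` vectors are
#'   sorted internally).
#' @param expected_fp target expected number of false positives (default 1).
#' @return list: `cutoff`, `achieved` (summed marginals at the cutoff),
#'   `attainable` (whether the target sum was reachable).
#' @export
calibrate_cutoff <- function(cum_list, expected_fp = 1) {
  sorted <- lapply(cum_list, function(v) sort(v[v > 0 & v < 1 + 1e-15]))
  sorted <- sorted[lengths(sorted) > 0]
  marg_sum <- function(cc) {
    sum(vapply(sorted, function(v) {
      k <- findInterval(cc, v, left.open = FALSE)
      # findInterval gives #{v <= cc}; strict: back off exact ties
      while (k > 0 && v[k] >= cc) k <- k - 1L
      if (k > 0) v[k] else 0
    }, numeric(1)))
  }
  if (length(sorted) == 0 || marg_sum(1) <= 0) {
    warning("no cutoff achieves a positive expected false-positive sum")
    return(list(cutoff = .Machine$double.xmin, achieved = 0,
                attainable = FALSE))
  }
  attainable <- TRUE
  if (marg_sum(1) <= expected_fp) {
    warning("summed marginals cannot reach expected_fp; cutoff at 1")
    attainable <- FALSE
  }
  lo <- 0; hi <- 1
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (marg_sum(mid) <= expected_fp) lo <- mid else hi <- mid
  }
  list(cutoff = lo, achieved = marg_sum(lo), attainable = attainable)
}

#' Scale the nonessential model into an essential-gene insertion model
#'
#' The residual insertion rate in essential genes is estimated as the
#' ratio of observed insertions in essential genes to their expected count
#' under the nonessential model; the essential model multiplies every
#' site probability by this ratio.
#'
#' @param pmfs gene models from [gene_pmfs()].
#' @param essential logical vector: essential call per gene.
#' @return list: `rho` and `probs_scaled` (per-gene scaled probabilities),
#'   or `rho = NA` with a warning when no gene was called essential.
#' @export
essential_model_scaling <- function(pmfs, essential) {
  if (!any(essential)) {
    warning("no essential genes: essential model undefined, ",
            "nonessential calling skipped")
    return(list(rho = NA_real_, probs_scaled = NULL))
  }
  t_sum <- sum(vapply(pmfs[essential], `[[`, numeric(1), "t_obs"))
  e_sum <- sum(vapply(pmfs[essential], `[[`, numeric(1), "E"))
  rho <- t_sum / e_sum
  list(rho = rho,
       probs_scaled = lapply(pmfs, function(g) pmin(1, rho * g$probs)))
}

#' Merge lower- and upper-tail calls into a final classification
#'
#' @param essential,nonessential logical vectors.
#' @return character vector in `{essential, nonessential, conflict,
#'   unknown}`.
#' @export
merge_calls <- function(essential, nonessential) {
  ifelse(essential & nonessential, "conflict",
         ifelse(essential, "essential",
                ifelse(nonessential, "nonessential", "unknown")))
}

#' Call gene essentiality by transposon insertion frequency analysis
#'
#' The complete caller. Under the nonessential (bias) model each gene's
#' Poisson-binomial PMF gives `p_lower = P(X <= t_obs)`; the essential-call
#' cutoff is calibrated so the expected number of false essential calls
#' over the whole gene set equals `expected_fp`, and a gene is essential
#' iff `p_lower < c_ess` (strict). The essential-gene model then scales
#' every site probability by the residual insertion ratio `rho`, gives
#' `p_upper = P(X >= t_obs)`, and a separately calibrated upper-tail
#' cutoff calls nonessential genes. Genes crossing both cutoffs are
#' conflicts; genes crossing neither (including all genes with zero core
#' TA sites) are unknown.
#'
#' @param ta_sites `ta_sites` with `inserted` set.
#' @param genes gene table from [assign_sites()].
#' @param model fitted `bias_model`.
#' @param expected_fp expected false positives per side (default 1).
#' @return object of class `tifa_result`: a data.frame with columns
#'   `gene_id`, `s`, `t_obs`, `E`, `V`, `nde`, `p_lower`, `p_upper`,
#'   `call`, `callable_essential`; attributes `c_ess`, `c_non`, `rho`,
#'   `achieved_fp_ess`, `achieved_fp_non`, `n_genes`, `one_over_n`.
#' @export
tifa_call <- function(ta_sites, genes, model, expected_fp = 1) {
  p <- site_probability(ta_sites, model)
  pmfs <- gene_pmfs(ta_sites, genes, p)
  s <- vapply(pmfs, function(g) length(g$probs), integer(1))
  t_obs <- vapply(pmfs, `[[`, numeric(1), "t_obs")
  E <- vapply(pmfs, `[[`, numeric(1), "E")
  V <- vapply(pmfs, `[[`, numeric(1), "V")

  cal_ess <- calibrate_cutoff(lapply(pmfs, `[[`, "lower"), expected_fp)
  c_ess <- cal_ess$cutoff
  p_lower <- vapply(seq_along(pmfs), function(g) {
    if (s[g] == 0) return(NA_real_)
    pmfs[[g]]$lower[t_obs[g] + 1L]
  }, numeric(1))
  callable <- s > 0 &
    vapply(pmfs, function(g) length(g$lower) > 0 && g$lower[1] < c_ess,
           logical(1))
  essential <- !is.na(p_lower) & p_lower < c_ess & s > 0

  scal <- essential_model_scaling(pmfs, essential)
  p_upper <- rep(NA_real_, length(pmfs))
  nonessential <- rep(FALSE, length(pmfs))
  c_non <- NA_real_
  achieved_non <- NA_real_
  if (!is.na(scal$rho)) {
    upmfs <- lapply(seq_along(pmfs), function(g) {
      pmf <- pgf_pmf(scal$probs_scaled[[g]])
      up <- rev(cumsum(rev(pmf)))
      up[1] <- 1
      up
    })
    cal_non <- calibrate_cutoff(upmfs, expected_fp)
    c_non <- cal_non$cutoff
    achieved_non <- cal_non$achieved
    p_upper <- vapply(seq_along(pmfs), function(g) {
      if (s[g] == 0) return(NA_real_)
      upmfs[[g]][t_obs[g] + 1L]
    }, numeric(1))
    nonessential <- !is.na(p_upper) & p_upper < c_non & s > 0
  }

  res <- data.frame(gene_id = genes$locus_id, s = s, t_obs = t_obs,
                    E = E, V = V, nde = nde(E, V, t_obs),
                    p_lower = p_lower, p_upper = p_upper,
                    call = merge_calls(essential, nonessential),
                    callable_essential = callable,
                    stringsAsFactors = FALSE)
  class(res) <- c("tifa_result", "data.frame")
  attr(res, "c_ess") <- c_ess
  attr(res, "c_non") <- c_non
  attr(res, "rho") <- scal$rho
  attr(res, "achieved_fp_ess") <- cal_ess$achieved
  attr(res, "achieved_fp_non") <- achieved_non
  attr(res, "n_genes") <- nrow(genes)
  attr(res, "one_over_n") <- 1 / nrow(genes)
  attr(res, "site_probs") <- p
  res
}

#' Write a results table and its calibration report
#'
#' @param result `tifa_result` from [tifa_call()].
#' @param path output TSV path; the calibration YAML is written next to it
#'   as `<path>.calibration.yaml`.
#' @return `path`, invisibly.
#' @export
write_tifa_result <- function(result, path) {
  out <- as.data.frame(result)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rep <- list(c_ess = as.numeric(attr(result, "c_ess")),
              c_non = as.numeric(attr(result, "c_non")),
              rho = as.numeric(attr(result, "rho")),
              achieved_fp_ess = as.numeric(attr(result, "achieved_fp_ess")),
              achieved_fp_non = as.numeric(attr(result, "achieved_fp_non")),
              n_genes = attr(result, "n_genes"),
              one_over_n_genes = as.numeric(attr(result, "one_over_n")))
  yaml::write_yaml(rep, paste0(path, ".calibration.yaml"),
                   precision = 15)
  invisible(path)
}
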