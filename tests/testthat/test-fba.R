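test_that("toy chain model reproduces the hand-solved optimum", {
  m <- toy_chain_model(uptake_bound = 10)
  expect_equal(fba_growth(m)$growth, 10)
  # biomass clamped to zero
  m0 <- m
  m0$lb["BIOMASS"] <- 0; m0$ub["BIOMASS"] <- 0
  expect_equal(fba_growth(m0)$growth, 0)
  # removing the sole uptake stops growth
  expect_equal(fba_growth(m, medium = c(EX_A = 0))$growth, 0)
  # medium uptake bound is binding
  expect_equal(fba_growth(m, medium = c(EX_A = 3))$growth, 3)
  # steady state holds at the optimum
  sol <- fba_growth(m)
  expect_true(all(abs(m$S %*% sol$fluxes) < 1e-9))
})

test_that("GPR evaluation matches truth-table enumeration", {
  expect_true(gpr_eval("g1 or g2", "g1"))
  expect_false(gpr_eval("g1 and g2", "g2"))
  expect_false(gpr_eval("(g1 and g2) or g3", c("g1", "g3")))
  expect_true(gpr_eval("", c("g1")))
  expect_error(gpr_eval("g1 and (g2", "g1"), "malformed")
  expect_error(gpr_eval("and g1", character(0)), "malformed")

  genes <- c("g1", "g2", "g3", "g4")
  exprs <- c("g1", "g1 and g2", "g1 or g2", "(g1 and g2) or (g3 and g4)",
             "g1 and (g2 or g3) and g4", "((g1 or g2) and g3) or g4",
             "g1 AND g2 OR g3")
  for (e in exprs) {
    for (mask in 0:15) {
      del <- genes[as.logical(as.integer(intToBits(mask))[1:4])]
      expect_equal(gpr_eval(e, del), gpr_oracle(e, del, genes),
                   info = paste(e, "|", paste(del, collapse = ",")))
    }
  }
})

test_that("single-gene deletions find essential and redundant genes", {
  # main path gated by g1; isozyme path gated by g2 or g3; dead branch g4
  m <- fba_model(list(
    EX_A = list(metabolites = list(A = 1), lb = 0, ub = 10),
    R1 = list(metabolites = list(A = -1, B = 1), lb = 0, ub = 1000,
              gpr = "g1"),
    R2 = list(metabolites = list(B = -1, C = 1), lb = 0, ub = 1000,
              gpr = "g2 or g3"),
    BIOMASS = list(metabolites = list(C = -1), lb = 0, ub = 1000)
  ), biomass = "BIOMASS")
  del <- single_gene_deletions(m)
  calls <- setNames(del$call_1pct, del$gene)
  expect_equal(calls[["g1"]], "essential")
  expect_equal(calls[["g2"]], "nonessential")
  expect_equal(calls[["g3"]], "nonessential")
  # deletions never increase growth
  expect_true(all(del$growth <= attr(del, "wild_type") + 1e-9))
})

test_that("1% and zero growth cutoffs can disagree on residual flux", {
  # deleting g1 leaves a trickle path worth 0.5% of wild type
  m <- fba_model(list(
    EX_A = list(metabolites = list(A = 1), lb = 0, ub = 10),
    Rmain = list(metabolites = list(A = -1, B = 1), lb = 0, ub = 1000,
                 gpr = "g1"),
    Rtrickle = list(metabolites = list(A = -1, B = 1), lb = 0,
                    ub = 0.05, gpr = "g2"),
    BIOMASS = list(metabolites = list(B = -1), lb = 0, ub = 1000)
  ), biomass = "BIOMASS")
  del <- single_gene_deletions(m)
  g1 <- del[del$gene == "g1", ]
  expect_equal(g1$growth, 0.05, tolerance = 1e-9)
  expect_equal(g1$call_1pct, "essential")      # 0.05 < 0.01 * 10.05
  expect_equal(g1$call_zero, "nonessential")   # but not computational zero
  # a wild type below the zero tolerance aborts with a diagnostic
  m_dead <- m
  m_dead$ub["EX_A"] <- 0
  expect_error(single_gene_deletions(m_dead), "does not grow")
})

test_that("blocked reactions are detected and freed by relaxation", {
  # R_c consumes C which nothing produces: blocked as written; making it
  # reversible lets flux run A -> C -> export
  m <- fba_model(list(
    EX_A = list(metabolites = list(A = 1), lb = 0, ub = 10),
    R1 = list(metabolites = list(A = -1, B = 1), lb = 0, ub = 1000),
    R_c = list(metabolites = list(C = -1, A = 1), lb = 0, ub = 1000),
    EX_C = list(metabolites = list(C = -1), lb = 0, ub = 1000),
    BIOMASS = list(metabolites = list(B = -1), lb = 0, ub = 1000)
  ), biomass = "BIOMASS")
  blocked <- blocked_reactions(m)
  expect_true("R_c" %in% blocked)
  expect_false(any(c("EX_A", "R1", "BIOMASS") %in% blocked))
  m_rev <- relax_constraints(m, "no_thermo")
  expect_false("R_c" %in% blocked_reactions(m_rev))
})

test_that("constraint relaxation modes compose and count correctly", {
  m <- toy_chain_model()
  fe <- relax_constraints(m, "free_endpoints")
  expect_equal(ncol(fe$S) - ncol(m$S), nrow(m$S))
  expect_true(all(startsWith(setdiff(colnames(fe$S), colnames(m$S)),
                             "EXPORT_")))
  nt <- relax_constraints(m, "no_thermo")
  expect_true(all(nt$lb < 0))
  expect_equal(nt$ub, -nt$lb)
  both <- relax_constraints(m, "both")
  other <- relax_constraints(relax_constraints(m, "no_thermo"),
                             "free_endpoints")
  expect_equal(both$S, other$S)
  expect_equal(both$lb[colnames(m$S)], other$lb[colnames(m$S)])
})

test_that("the LP core agrees with a ridge-regularized QP oracle", {
  # independent route: quadprog minimizing eps*|v|^2 - c'v under the same
  # constraints approaches the LP optimum from inside
  set.seed(88)
  for (rep in 1:10) {
    n <- 6; m <- 3
    S <- matrix(sample(-2:2, n * m, replace = TRUE,
                       prob = c(1, 2, 6, 2, 1)), m, n)
    colnames(S) <- paste0("r", 1:n)
    lb <- ifelse(runif(n) < 0.5, 0, -runif(n, 0.5, 2))
    ub <- runif(n, 0.5, 2)
    lp <- tifa:::solve_lp(S, lb, ub, "r1", maximize = TRUE)
    expect_equal(lp$status, "optimal")
    expect_true(all(abs(S %*% lp$fluxes) < 1e-8))
    eps <- 1e-7
    cvec <- c(1, rep(0, n - 1))
    qp <- quadprog::solve.QP(
      Dmat = diag(eps, n), dvec = cvec,
      Amat = cbind(t(S), diag(n), -diag(n)),
      bvec = c(rep(0, m), lb, -ub), meq = m)
    expect_equal(lp$growth, sum(cvec * qp$solution), tolerance = 1e-4)
  }
})

test_that("confusion statistics are self-consistent", {
  ct <- confusion_stats(40, 10, 90, 10)
  expect_equal(ct$pct_true_essential, 80)
  expect_equal(ct$pct_true_nonessential, 90)
  expect_equal(ct$pct_correct_overall,
               tifa:::round_half_up(100 * (40 + 90) / 150))
  # from call vectors, restricted to genes called on both sides
  tifa_calls <- c(a = "essential", b = "essential", c = "nonessential",
                  d = "unknown", e = "nonessential")
  fba_calls <- c(a = "essential", b = "nonessential", c = "nonessential",
                 d = "essential", f = "essential")
  ct2 <- confusion_table(tifa_calls, fba_calls)
  expect_equal(unname(ct2$counts),
               c(1, 1, 1, 0))
  expect_equal(ct2$pct_true_essential, 50)
})

test_that("model JSON and medium TSV round-trip", {
  m <- toy_chain_model()
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    biomass = "BIOMASS",
    reactions = list(
      EX_A = list(metabolites = list(A = 1), lb = 0, ub = 10),
      R1 = list(metabolites = list(A = -1, B = 1), lb = 0, ub = 1000,
                gpr = "g1"),
      BIOMASS = list(metabolites = list(B = -1), lb = 0, ub = 1000))),
    path, auto_unbox = TRUE)
  back <- read_fba_model(path)
  expect_equal(back$S, m$S)
  expect_equal(fba_growth(back)$growth, 10)
  med <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("exchange_id\tuptake_bound", "EX_A\t2.5"), med)
  expect_equal(read_medium(med), c(EX_A = 2.5))
  expect_equal(fba_growth(back, read_medium(med))$growth, 2.5)
})
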