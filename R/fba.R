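#' Construct a metabolic model
#'
#' A light container for a stoichiometric network: reactions with bounds
#' and gene-protein-reaction (GPR) boolean strings, a biomass reaction,
#' and optionally a medium (exchange-reaction uptake bounds).
#'
#' @param reactions named list: each element a list with `metabolites`
#'   (named stoichiometric coefficients), `lb`, `ub`, and optional `gpr`.
#' @param biomass id of the biomass reaction.
#' @return object of class `fba_model`: list with `S` (metabolites x
#'   reactions matrix), `lb`, `ub`, `gpr`, `biomass`, `genes`.
#' @export
fba_model <- function(reactions, biomass) {
  stopifnot(biomass %in% names(reactions))
  mets <- sort(unique(unlist(lapply(reactions, function(r)
    names(r$metabolites)), use.names = FALSE)))
  S <- matrix(0, nrow = length(mets), ncol = length(reactions),
              dimnames = list(mets, names(reactions)))
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$metabolites
    S[names(st), j] <- unlist(st)
  }
  lb <- vapply(reactions, function(r) as.numeric(r$lb), numeric(1))
  ub <- vapply(reactions, function(r) as.numeric(r$ub), numeric(1))
  stopifnot(all(lb <= ub))
  gpr <- vapply(reactions, function(r)
    if (is.null(r$gpr)) "" else as.character(r$gpr), character(1))
  genes <- sort(unique(unlist(lapply(gpr, gpr_genes), use.names = FALSE)))
  structure(list(S = S, lb = lb, ub = ub, gpr = gpr, biomass = biomass,
                 genes = genes),
            class = "fba_model")
}

#' Read a metabolic model from JSON
#'
#' Schema: `{"biomass": "...", "reactions": {"<id>": {"metabolites":
#' {"<met>": coef, ...}, "lb": ..., "ub": ..., "gpr": "..."}}}`.
#'
#' @param path JSON file path.
#' @return `fba_model`.
#' @export
read_fba_model <- function(path) {
  doc <- jsonlite::read_json(path)
  fba_model(doc$reactions, doc$biomass)
}

#' Read a medium table
#'
#' Tab-delimited: `exchange_id`, `uptake_bound`.
#'
#' @param path medium TSV path.
#' @return named numeric vector of uptake bounds.
#' @export
read_medium <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$uptake_bound), tab$exchange_id)
}

gpr_tokenize <- function(expression) {
  toks <- regmatches(expression,
                     gregexpr("\\(|\\)|[^()[:space:]]+", expression))[[1]]
  toks
}

gpr_genes <- function(expression) {
  if (!nzchar(trimws(expression))) return(character(0))
  toks <- gpr_tokenize(expression)
  toks[!toks %in% c("(", ")") & !tolower(toks) %in% c("and", "or")]
}

#' Evaluate a gene-protein-reaction rule
#'
#' Boolean semantics over `and`/`or`/parentheses (case-insensitive
#' keywords) with deleted genes false and all other genes true; evaluated
#' by a recursive-descent parser (`or` binds weakest). An empty rule means
#' the reaction needs no gene and is always active.
#'
#' @param expression GPR string, e.g. `"(g1 and g2) or g3"`.
#' @param deleted_genes character vector of knocked-out gene ids.
#' @return logical: is the reaction still active?
#' @export
gpr_eval <- function(expression, deleted_genes = character(0)) {
  if (!nzchar(trimws(expression))) return(TRUE)
  toks <- gpr_tokenize(expression)
  i <- 0L
  peek <- function() if (i < length(toks)) toks[i + 1L] else NA_character_
  advance <- function() { i <<- i + 1L; toks[i] }
  fail <- function() stop("malformed GPR expression: ", expression)
  parse_or <- function() {
    v <- parse_and()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      v <- parse_and() || v
    }
    v
  }
  parse_and <- function() {
    v <- parse_atom()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      v <- parse_atom() && v
    }
    v
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.na(tok)) fail()
    if (tok == "(") {
      advance()
      v <- parse_or()
      if (is.na(peek()) || peek() != ")") fail()
      advance()
      return(v)
    }
    if (tok == ")" || tolower(tok) %in% c("and", "or")) fail()
    advance()
    !tok %in% deleted_genes
  }
  v <- parse_or()
  if (i != length(toks)) fail()
  v
}

#' Optimal biomass flux by flux balance analysis
#'
#' Maximizes the biomass flux subject to steady state (`S v = 0`) and the
#' flux bounds, after applying medium uptake limits to the named exchange
#' reactions (the uptake direction of each exchange is inferred from its
#' stoichiometry). The linear program is solved with the simplex method.
#'
#' @param model `fba_model`.
#' @param medium optional named vector: exchange reaction -> maximum
#'   uptake rate.
#' @param objective reaction id to maximize (defaults to the biomass
#'   reaction).
#' @param minimize maximize (default) or minimize the objective.
#' @return list: `growth` (objective value; 0 when infeasible), `status`
#'   (`"optimal"` or `"infeasible"`), `fluxes` (named vector).
#' @export
fba_growth <- function(model, medium = NULL, objective = model$biomass,
                       minimize = FALSE) {
  lb <- model$lb
  ub <- model$ub
  if (!is.null(medium)) {
    miss <- setdiff(names(medium), colnames(model$S))
    if (length(miss)) stop("medium names unknown reaction(s): ",
                           paste(miss, collapse = ", "))
    for (rx in names(medium)) {
      col <- model$S[, rx]
      if (all(col <= 0)) {          # export form: uptake = negative flux
        lb[rx] <- -medium[[rx]]
      } else {                      # uptake form: uptake = positive flux
        ub[rx] <- medium[[rx]]
      }
    }
  }
  solve_lp(model$S, lb, ub, objective, maximize = !minimize)
}

#' Single-gene-deletion essentiality predictions
#'
#' For every gene in the model, reactions whose GPR evaluates false after
#' the deletion are shut off (`bounds [0, 0]`) and the LP re-solved. A
#' gene is FBA-essential at the default cutoff when the knockout grows at
#' less than `threshold` (1\%) of wild type; the zero-growth call
#' (`growth < zero_tol`) is reported alongside for sensitivity analysis.
#'
#' @param model `fba_model`.
#' @param medium optional medium vector.
#' @param threshold relative-growth essentiality cutoff (default 0.01).
#' @param zero_tol computational zero for growth (default 1e-6).
#' @return data.frame: `gene`, `growth`, `call_1pct`, `call_zero`;
#'   attribute `wild_type` holds the wild-type growth.
#' @export
single_gene_deletions <- function(model, medium = NULL, threshold = 0.01,
                                  zero_tol = 1e-6) {
  wt <- fba_growth(model, medium)
  if (wt$status != "optimal" || wt$growth < zero_tol)
    stop("wild-type model does not grow (growth ", wt$growth,
         "); deletions not informative")
  res <- lapply(model$genes, function(g) {
    off <- !vapply(model$gpr, gpr_eval, logical(1), deleted_genes = g)
    m2 <- model
    m2$lb[off] <- 0
    m2$ub[off] <- 0
    fba_growth(m2, medium)$growth
  })
  growth <- unlist(res)
  out <- data.frame(gene = model$genes, growth = growth,
                    call_1pct = ifelse(growth < threshold * wt$growth,
                                       "essential", "nonessential"),
                    call_zero = ifelse(growth < zero_tol,
                                       "essential", "nonessential"),
                    stringsAsFactors = FALSE)
  attr(out, "wild_type") <- wt$growth
  out
}

#' Reactions that can never carry flux
#'
#' Flux-variability screen: a reaction is blocked when both its maximum
#' and minimum attainable flux under the bounds (and medium) are below
#' `tol` in absolute value.
#'
#' @param model `fba_model`.
#' @param medium optional medium vector.
#' @param tol numerical zero for flux (default 1e-9).
#' @return character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(model, medium = NULL, tol = 1e-9) {
  rxns <- colnames(model$S)
  blocked <- vapply(rxns, function(rx) {
    hi <- fba_growth(model, medium, objective = rx)$growth
    lo <- fba_growth(model, medium, objective = rx, minimize = TRUE)$growth
    abs(hi) < tol && abs(lo) < tol
  }, logical(1))
  rxns[blocked]
}

#' Relax network constraints
#'
#' `free_endpoints` adds an export reaction (`met ->`, bounds `[0, big]`)
#' for every metabolite, releasing stoichiometric constraints on endpoint
#' metabolites; `no_thermo` removes thermodynamic (irreversibility)
#' constraints by making every reaction reversible with symmetric bounds;
#' `both` composes the two (order-independent).
#'
#' @param model `fba_model`.
#' @param mode one of `"free_endpoints"`, `"no_thermo"`, `"both"`.
#' @param big bound magnitude for added/symmetrized fluxes (default 1000).
#' @return modified `fba_model`.
#' @export
relax_constraints <- function(model,
                              mode = c("free_endpoints", "no_thermo",
                                       "both"),
                              big = 1000) {
  mode <- match.arg(mode)
  if (mode %in% c("no_thermo", "both")) {
    M <- pmax(abs(model$lb), abs(model$ub))
    M[M == 0] <- big
    model$lb <- -M
    model$ub <- M
  }
  if (mode %in% c("free_endpoints", "both")) {
    mets <- rownames(model$S)
    exp_ids <- paste0("EXPORT_", mets)
    E <- -diag(length(mets))
    dimnames(E) <- list(mets, exp_ids)
    model$S <- cbind(model$S, E)
    model$lb <- c(model$lb, stats::setNames(rep(0, length(mets)), exp_ids))
    model$ub <- c(model$ub, stats::setNames(rep(big, length(mets)),
                                            exp_ids))
    model$gpr <- c(model$gpr, stats::setNames(rep("", length(mets)),
                                              exp_ids))
  }
  model
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Confusion statistics between TIFA calls and FBA predictions
#'
#' From the four agreement counts — TIFA-essential genes predicted
#' essential/nonessential by FBA and TIFA-nonessential genes predicted
#' nonessential/essential — computes the per-row percent-true (integer,
#' rounded half away from zero) and the overall percent correct.
#'
#' @param ess_agree,ess_disagree TIFA-essential counts (FBA essential /
#'   FBA nonessential).
#' @param non_agree,non_disagree TIFA-nonessential counts (FBA
#'   nonessential / FBA essential).
#' @return list of class `confusion_table`: `counts`,
#'   `pct_true_essential`, `pct_true_nonessential`, `pct_correct_overall`.
#' @export
confusion_stats <- function(ess_agree, ess_disagree, non_agree,
                            non_disagree) {
  counts <- c(ess_agree = ess_agree, ess_disagree = ess_disagree,
              non_agree = non_agree, non_disagree = non_disagree)
  structure(list(
    counts = counts,
    pct_true_essential =
      round_half_up(100 * ess_agree / (ess_agree + ess_disagree)),
    pct_true_nonessential =
      round_half_up(100 * non_agree / (non_agree + non_disagree)),
    pct_correct_overall =
      round_half_up(100 * (ess_agree + non_agree) / sum(counts))),
    class = "confusion_table")
}

#' Confusion table from per-gene call vectors
#'
#' Compares TIFA calls with FBA predictions on the genes present in both
#' (only genes with an essential or nonessential call on each side are
#' counted).
#'
#' @param tifa_calls named character vector (`essential` /
#'   `nonessential` / other) by gene id.
#' @param fba_calls named character vector (`essential` / `nonessential`)
#'   by gene id.
#' @return `confusion_table` (see [confusion_stats()]).
#' @export
confusion_table <- function(tifa_calls, fba_calls) {
  shared <- intersect(names(tifa_calls), names(fba_calls))
  tc <- tifa_calls[shared]
  fc <- fba_calls[shared]
  use <- tc %in% c("essential", "nonessential") &
    fc %in% c("essential", "nonessential")
  tc <- tc[use]; fc <- fc[use]
  confusion_stats(sum(tc == "essential" & fc == "essential"),
                  sum(tc == "essential" & fc == "nonessential"),
                  sum(tc == "nonessential" & fc == "nonessential"),
                  sum(tc == "nonessential" & fc == "essential"))
}
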