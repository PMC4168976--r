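# Shared fixture builders; everything is generated in code under fixed
# seeds.

# random ACGT sequence as a plain string
random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent oracle: count/locate TA occurrences by direct substring scan
scan_ta_oracle <- function(seq) {
  L <- nchar(seq)
  which(vapply(seq_len(L - 1L),
               function(i) substr(seq, i, i + 1L) == "TA",
               logical(1))) - 1L
}

# a small fitted dataset: synthetic genome + library + bias model
small_fitted <- function(seed = 42, length = 4e5, n_genes = 320,
                         n_ess = 20, m = 9000, ...) {
  gen <- generate_genome(seed = seed, length = length, n_genes = n_genes)
  set.seed(seed + 1)
  ess <- sample(gen$genes$locus_id, n_ess)
  lib <- generate_library(gen, essential_ids = ess, m = m, seed = seed,
                          ...)
  flt <- filter_insertions(lib$insertions, lib$ta_sites)
  sites <- combine_samples(lib$ta_sites, flt$retained)
  model <- fit_bias_model(sites, lib$genes)
  list(gen = gen, lib = lib, sites = sites, genes = lib$genes,
       model = model, essential_ids = ess, filter = flt)
}

# toy linear chain metabolic model: uptake -> conversion -> biomass
toy_chain_model <- function(uptake_bound = 10) {
  fba_model(list(
    EX_A = list(metabolites = list(A = 1), lb = 0, ub = uptake_bound),
    R1 = list(metabolites = list(A = -1, B = 1), lb = 0, ub = 1000,
              gpr = "g1"),
    BIOMASS = list(metabolites = list(B = -1), lb = 0, ub = 1000)
  ), biomass = "BIOMASS")
}

# independent GPR oracle: substitute ids for literals, eval as R logic
gpr_oracle <- function(expression, deleted, genes) {
  e <- expression
  for (g in genes) {
    e <- gsub(paste0("\\b", g, "\\b"),
              if (g %in% deleted) "FALSE" else "TRUE", e)
  }
  e <- gsub("\\band\\b", "&&", e, ignore.case = TRUE)
  e <- gsub("\\bor\\b", "||", e, ignore.case = TRUE)
  eval(parse(text = e))
}
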