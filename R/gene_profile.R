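#' Within-gene positional insertion profile
#'
#' Maps every TA site of the selected genes to a fractional gene
#' coordinate in `[0, 1)` (strand-aware: the 3' end is always the high
#' coordinate), tallies TA occurrences and insertions per bin, and reports
#' the relative insertion frequency per bin normalized by the class mean.
#' Used to detect positional tolerance such as the elevated insertion
#' frequency in the terminal ~2% of essential genes.
#'
#' @param ta_sites `ta_sites` with `inserted` set.
#' @param genes gene table from [assign_sites()] (uses all assigned sites,
#'   not just core).
#' @param which logical or index vector selecting the gene class to
#'   profile (default all genes).
#' @param bin_width bin width as a fraction of gene length (default 0.002).
#' @return data.frame: `bin_start`, `ta_count`, `ins_count`, `rel_freq`
#'   (insertions/TA per bin over the mean insertions/TA; `NA` for empty
#'   bins).
#' @export
positional_profile <- function(ta_sites, genes, which = NULL,
                               bin_width = 0.002) {
  if (is.null(which)) which <- rep(TRUE, nrow(genes))
  g <- genes[which, , drop = FALSE]
  L <- attr(ta_sites, "genome_length")
  len <- g$end - g$start
  frac <- unlist(lapply(seq_len(nrow(g)), function(i) {
    idx <- g$site_idx[[i]]
    if (!length(idx)) return(numeric(0))
    p <- ta_sites$position[idx]
    p <- ifelse(p < g$start[i], p + L, p)
    f <- (p - g$start[i] + 0.5) / len[i]
    if (g$strand[i] == "-") f <- 1 - f
    f
  }), use.names = FALSE)
  ins <- unlist(lapply(seq_len(nrow(g)), function(i)
    ta_sites$inserted[g$site_idx[[i]]]), use.names = FALSE)
  edges <- seq(0, 1, by = bin_width)
  bin <- findInterval(frac, edges, rightmost.closed = TRUE)
  ta_count <- tabulate(bin, nbins = length(edges) - 1L)
  ins_count <- tabulate(bin[ins], nbins = length(edges) - 1L)
  rate <- ifelse(ta_count > 0, ins_count / ta_count, NA_real_)
  mean_rate <- sum(ins_count) / sum(ta_count)
  data.frame(bin_start = head(edges, -1), ta_count = ta_count,
             ins_count = ins_count, rel_freq = rate / mean_rate)
}

#' Fitness of a single transposon clone
#'
#' Relative fitness from the clone's frequency before and after a
#' competitive expansion by factor `d`:
#' `W = ln(f_after d / f_before) / ln((1 - f_after) d / (1 - f_before))`.
#' A neutral clone (frequency unchanged) has `W = 1`; a clone absent after
#' growth is assigned `W = 0` by convention.
#'
#' @param freq_before,freq_after clone frequencies in the population.
#' @param d population expansion factor (> 1).
#' @return fitness values.
#' @export
clone_fitness <- function(freq_before, freq_after, d) {
  stopifnot(d > 1)
  if (any(freq_before <= 0))
    stop("clone absent from the initial pool: fitness undefined")
  ifelse(freq_after <= 0, 0,
         log(freq_after * d / freq_before) /
           log((1 - freq_after) * d / (1 - freq_before)))
}

#' Gene fitness as the median clone fitness
#'
#' @param w fitness values of all clones inserted in the gene.
#' @return the sample median (central-pair average for even counts), or
#'   `NA` for genes without clones.
#' @export
gene_fitness <- function(w) {
  if (length(w) == 0) return(NA_real_)
  stats::median(w)
}
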