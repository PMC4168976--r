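#' Generate a synthetic circular genome with genes and operons
#'
#' Nucleotides are drawn i.i.d. with `P(T) = P(A) = sqrt(ta_density)` so
#' the realized TA-dinucleotide density matches the target in expectation.
#' Genes are packed sequentially around the circle with random lengths and
#' intergenic gaps and random strands; consecutive genes are grouped into
#' operons with sizes drawn from `operon_size_dist`. Optionally a number
#' of overlapping gene pairs is planted (for exclusion-filter tests).
#' Everything is deterministic under the seed.
#'
#' @param seed integer seed.
#' @param length genome length in nt.
#' @param ta_density target TA sites per nt (default 0.032, a typical
#'   gamma-proteobacterial density).
#' @param n_genes number of genes.
#' @param gene_len_range min/max gene length (nt).
#' @param operon_size_dist probability vector over operon sizes 1, 2, ...
#' @param n_overlaps number of planted overlapping gene pairs.
#' @return list of class `synthetic_genome`: `seq` (character, with
#'   `circular = TRUE` attribute), `genes`, `operons` (named list),
#'   `params`.
#' @export
generate_genome <- function(seed, length = 5e6, ta_density = 0.032,
                            n_genes = 4200,
                            gene_len_range = c(300, 1800),
                            operon_size_dist = c(0.55, 0.2, 0.15, 0.1),
                            n_overlaps = 0) {
  if (length < 10 * max(n_genes, 1)) stop("genome too short for n_genes")
  set.seed(seed)
  t <- sqrt(ta_density)
  stopifnot(t < 0.5)
  nt_prob <- c(A = t, C = (1 - 2 * t) / 2, G = (1 - 2 * t) / 2, T = t)
  seq <- paste(sample(names(nt_prob), length, replace = TRUE,
                      prob = nt_prob), collapse = "")
  genes <- NULL
  if (n_genes > 0) {
    mean_len <- mean(gene_len_range)
    slack <- length - n_genes * mean_len
    if (slack <= 0) stop("infeasible gene packing")
    lens <- round(stats::runif(n_genes, gene_len_range[1],
                               gene_len_range[2]))
    # scale lengths down if the draw happens not to fit
    if (sum(lens) >= length * 0.95)
      lens <- floor(lens * (length * 0.9 / sum(lens)))
    gap_total <- length - sum(lens)
    gaps <- stats::rmultinom(1, gap_total, rep(1, n_genes))[, 1]
    starts <- cumsum(gaps) + cumsum(c(0, lens[-n_genes]))
    genes <- data.frame(locus_id = sprintf("g%04d", seq_len(n_genes)),
                        start = starts,
                        end = starts + lens,
                        strand = sample(c("+", "-"), n_genes,
                                        replace = TRUE),
                        stringsAsFactors = FALSE)
    if (n_overlaps > 0) {
      # shift some genes left so they overlap their predecessor's tail
      cand <- sample(2:n_genes, n_overlaps)
      shift <- pmin(genes$start[cand] - genes$start[cand - 1] - 50,
                    round(lens[cand] * 0.2))
      shift <- pmax(shift, 10)
      genes$start[cand] <- genes$start[cand] - shift
    }
  }
  operons <- list()
  if (n_genes > 0) {
    i <- 1L; k <- 1L
    while (i <= n_genes) {
      size <- sample(seq_along(operon_size_dist), 1,
                     prob = operon_size_dist)
      members <- genes$locus_id[i:min(i + size - 1L, n_genes)]
      operons[[sprintf("op%04d", k)]] <- members
      i <- i + base::length(members)
      k <- k + 1L
    }
  }
  structure(list(seq = structure(seq, circular = TRUE, name = "synthetic"),
                 genes = genes, operons = operons,
                 params = list(seed = seed, length = length,
                               ta_density = ta_density,
                               n_genes = n_genes,
                               n_overlaps = n_overlaps)),
            class = "synthetic_genome")
}

#' Default synthetic motif preference spectrum
#'
#' Relative insertion rates for the 136 canonical motif classes spanning a
#' configurable fold-spread (default 10x, log-uniform), deterministic
#' under the seed.
#'
#' @param seed integer seed.
#' @param spread max/min rate ratio (default 10).
#' @return named numeric vector over the 136 classes.
#' @export
synthetic_motif_spectrum <- function(seed, spread = 10) {
  cls <- enumerate_motif_classes()$motif_class
  set.seed(seed)
  r <- stats::runif(length(cls))
  r <- (r - min(r)) / (max(r) - min(r))          # exact [0, 1] span
  stats::setNames(spread^r, cls)
}

#' Generate a synthetic transposon insertion library
#'
#' Colonies are placed multinomially over the genome's TA sites with
#' per-site rates proportional to motif preference times the location-bias
#' polynomial. Core sites of planted essential genes insert at
#' `residual_rate` times the nonessential rate; the terminal fraction at
#' the 3' end of essential genes keeps the full rate (insertions there do
#' not disrupt function). Mapping-artifact records are layered on top so
#' that a fraction `non_ta_rate` of the unique insertion records sits at
#' non-TA positions (emulating the ~5% of raw events the TA filter
#' discards). Per-colony read counts are log-normal, summed per site and
#' split multinomially across `n_samples` samples. A small fraction of
#' records can be marked non-uniquely mapping.
#'
#' @param genome `synthetic_genome` from [generate_genome()].
#' @param loc_coeffs location polynomial `(a, b, c)` (defaults to the
#'   observed miniHimar values `0.0032, 0.0081, 0.1615`).
#' @param motif_spectrum named relative rates per motif class (defaults to
#'   [synthetic_motif_spectrum()] at 10x spread).
#' @param essential_ids locus ids of planted essential genes.
#' @param residual_rate residual insertion rate in essential cores
#'   (default 0.1).
#' @param m number of colonies (default 40000).
#' @param non_ta_rate fraction of unique insertion records planted at
#'   non-TA positions (default 0.05).
#' @param non_unique_rate fraction of records flagged non-unique.
#' @param read_meanlog,read_sdlog log-normal read-count parameters.
#' @param n_samples number of library samples (default 4).
#' @param terminal_frac 3'-terminal fraction kept at full rate (default
#'   0.02).
#' @param seed integer seed.
#' @return list of class `synthetic_library`: `insertions` (records
#'   data.frame), `truth` (planted parameters and per-site rates),
#'   `ta_sites` (the genome's `ta_sites` with true gene assignment).
#' @export
generate_library <- function(genome, loc_coeffs = c(a = 0.0032,
                                                    b = 0.0081,
                                                    c = 0.1615),
                             motif_spectrum = NULL,
                             essential_ids = character(0),
                             residual_rate = 0.1, m = 40000,
                             non_ta_rate = 0.05, non_unique_rate = 0,
                             read_meanlog = log(120), read_sdlog = 1,
                             n_samples = 4, terminal_frac = 0.02,
                             seed = 1L) {
  set.seed(seed)
  if (is.null(motif_spectrum))
    motif_spectrum <- synthetic_motif_spectrum(seed)
  sites <- find_ta_sites(genome$seq, circular = TRUE)
  genes <- NULL
  if (!is.null(genome$genes)) {
    asg <- assign_sites(sites, genome$genes,
                        terminal_frac = terminal_frac)
    sites <- asg$ta_sites
    genes <- asg$genes
  }
  L <- nchar(genome$seq)

  rate <- motif_spectrum[sites$motif_class] *
    loc_poly(midpoint_coord(sites$position, L), loc_coeffs)
  rate[is.na(rate)] <- 0
  ess <- genes$locus_id %in% essential_ids
  ess_core <- unique(unlist(genes$core_idx[ess], use.names = FALSE))
  rate[ess_core] <- rate[ess_core] * residual_rate

  m_ta <- m
  colonies <- stats::rmultinom(1, m_ta, rate)[, 1]
  hit <- which(colonies > 0)
  reads_total <- vapply(hit, function(i)
    sum(pmax(1, round(stats::rlnorm(colonies[i], read_meanlog,
                                    read_sdlog)))), numeric(1))
  rec <- data.frame(position = sites$position[hit],
                    unique = rep(TRUE, length(hit)),
                    stringsAsFactors = FALSE)

  # non-TA events are mapping artifacts layered on top of the colonies:
  # planted so they make up non_ta_rate of the unique insertion records,
  # the fraction the downstream filter observes and discards
  m_nonta <- round(non_ta_rate / (1 - non_ta_rate) * nrow(rec))
  if (m_nonta > 0) {
    is_ta <- logical(L)
    is_ta[sites$position + 1L] <- TRUE
    is_ta[(sites$position + 1L) %% L + 1L] <- TRUE  # A of the TA
    nonta_pos <- sample(which(!is_ta), min(m_nonta, sum(!is_ta))) - 1L
    rec2 <- data.frame(position = nonta_pos, unique = TRUE,
                       stringsAsFactors = FALSE)
    reads2 <- pmax(1, round(stats::rlnorm(nrow(rec2), read_meanlog,
                                          read_sdlog)))
    rec <- rbind(rec, rec2)
    reads_total <- c(reads_total, reads2)
  }
  if (non_unique_rate > 0) {
    flip <- stats::runif(nrow(rec)) < non_unique_rate
    rec$unique[flip] <- FALSE
  }
  split_reads <- t(vapply(reads_total, function(r)
    stats::rmultinom(1, r, rep(1, n_samples))[, 1], numeric(n_samples)))
  colnames(split_reads) <- paste0("reads_s", seq_len(n_samples))
  rec <- cbind(rec, as.data.frame(split_reads))

  truth <- list(seed = seed, loc_coeffs = as.list(loc_coeffs),
                spread = max(motif_spectrum) / min(motif_spectrum),
                essential_ids = essential_ids,
                residual_rate = residual_rate, m = m,
                m_ta = m_ta, m_nonta = m_nonta,
                non_ta_rate = non_ta_rate,
                non_unique_rate = non_unique_rate,
                read_meanlog = read_meanlog, read_sdlog = read_sdlog,
                n_samples = n_samples, terminal_frac = terminal_frac)
  structure(list(insertions = rec, truth = truth,
                 motif_spectrum = motif_spectrum,
                 ta_sites = sites, genes = genes),
            class = "synthetic_library")
}

#' Write synthetic genome artifacts to disk
#'
#' Writes the FASTA, gene TSV and operon TSV in the formats the readers in
#' this package consume.
#'
#' @param genome `synthetic_genome`.
#' @param dir output directory (created if needed).
#' @return named vector of the written paths, invisibly.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  set <- Biostrings::DNAStringSet(as.character(genome$seq))
  names(set) <- "synthetic"
  Biostrings::writeXStringSet(set, fa)
  gtsv <- file.path(dir, "genes.tsv")
  utils::write.table(genome$genes[, c("locus_id", "start", "end",
                                      "strand")],
                     gtsv, sep = "\t", quote = FALSE, row.names = FALSE)
  otsv <- file.path(dir, "operons.tsv")
  ops <- data.frame(operon_id = names(genome$operons),
                    genes = vapply(genome$operons, paste,
                                   character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  utils::write.table(ops, otsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, genes = gtsv, operons = otsv))
}

#' Write a synthetic library to disk
#'
#' @param library `synthetic_library`.
#' @param dir output directory.
#' @return named vector of paths (`insertions`, `truth`), invisibly.
#' @export
write_library_files <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  itsv <- file.path(dir, "insertions.tsv")
  rec <- library$insertions
  rec$unique <- as.integer(rec$unique)
  utils::write.table(rec, itsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ty <- file.path(dir, "truth.yaml")
  yaml::write_yaml(library$truth, ty)
  invisible(c(insertions = itsv, truth = ty))
}
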