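#' @import stats
#' @import utils
NULL

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of character vectors
#'
#' Plain-character reverse complement for short oligo vectors (contexts are
#' 6-mers; `Biostrings` machinery is unnecessary overhead at this size).
#'
#' @param x character vector over the alphabet ACGTN.
#' @return character vector of the same length.
#' @keywords internal
revcomp_chr <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Read a genome sequence from a FASTA file
#'
#' Reads a single-record FASTA file and returns the uppercased sequence as a
#' character scalar with a `circular` attribute. Multi-record files are
#' rejected: the model assumes one (circular) chromosome.
#'
#' @param path path to a FASTA file.
#' @param circular logical; is the chromosome circular? Default `TRUE`.
#' @return character scalar (the sequence) with attributes `circular` and
#'   `name` (the FASTA header).
#' @export
read_genome <- function(path, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  if (length(set) > 1L)
    stop("multiple FASTA records in ", path,
         "; a single chromosome is required")
  seq <- toupper(as.character(set[[1]]))
  if (grepl("[^ACGTN]", seq)) stop("genome alphabet must be ACGTN")
  structure(seq, circular = circular, name = names(set)[1])
}

#' Enumerate TA dinucleotide sites with flanking context
#'
#' Scans the plus strand for every occurrence of `TA` (overlapping
#' occurrences such as TATA yield two sites) and records the 6-mer context
#' (2 nt upstream + TA + 2 nt downstream). For circular genomes the context
#' wraps around the origin; for linear genomes sites within 2 nt of an end
#' get an `N`-padded context and are flagged `excluded` (kept for counting,
#' dropped from motif statistics). Sites whose context contains `N` are
#' likewise flagged.
#'
#' @param genome character scalar sequence (e.g. from [read_genome()]).
#' @param circular logical; defaults to the genome's `circular` attribute,
#'   or `TRUE`.
#' @return data.frame of class `ta_sites` with columns `position` (0-based
#'   index of the T), `context6`, `motif_class` (canonical class, `NA` where
#'   excluded), `inserted` (initialised `FALSE`), `excluded`, `reason`.
#' @export
find_ta_sites <- function(genome, circular = attr(genome, "circular")) {
  if (is.null(circular)) circular <- TRUE
  seq <- as.character(genome)
  L <- nchar(seq)
  if (L < 6) stop("genome length must be at least 6")
  hits <- gregexpr("(?=TA)", seq, perl = TRUE)[[1]]
  pos <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  pad <- if (circular) {
    paste0(substr(seq, L - 1L, L), seq, substr(seq, 1L, 2L))
  } else {
    paste0("NN", seq, "NN")
  }
  context6 <- substr(rep(pad, length(pos)), pos + 1L, pos + 6L)
  excluded <- grepl("N", context6, fixed = TRUE)
  reason <- ifelse(excluded, "context_N", NA_character_)
  motif <- rep(NA_character_, length(pos))
  if (any(!excluded)) motif[!excluded] <- canonical_motif(context6[!excluded])
  out <- data.frame(position = pos, context6 = context6,
                    motif_class = motif, inserted = FALSE,
                    excluded = excluded, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("ta_sites", "data.frame")
  attr(out, "genome_length") <- L
  attr(out, "circular") <- circular
  out
}

#' Canonical motif class of a TA-centred 6-mer
#'
#' The two strands of the duplex present a 6-mer context and its reverse
#' complement; both describe the same physical insertion target. The
#' canonical class identifier is the lexicographically smaller of the two,
#' making the classification strand-symmetric and idempotent.
#'
#' @param context6 character vector of 6-mers whose central dinucleotide is
#'   `TA`.
#' @return character vector of class representatives.
#' @export
canonical_motif <- function(context6) {
  if (any(nchar(context6) != 6L))
    stop("contexts must be 6-mers")
  if (any(substr(context6, 3, 4) != "TA"))
    stop("central dinucleotide must be TA")
  rc <- revcomp_chr(context6)
  pmin(context6, rc)
}

#' Enumerate all canonical flanking-motif classes
#'
#' There are 4^4 = 256 possible 6-mers with a central TA; merging each with
#' its reverse complement leaves (256-16)/2 + 16 = 136 classes, 16 of which
#' are palindromic (self-reverse-complementary).
#'
#' @return data.frame with columns `motif_class` and `palindromic`, one row
#'   per class (136 rows).
#' @export
enumerate_motif_classes <- function() {
  nt <- c("A", "C", "G", "T")
  g <- expand.grid(x1 = nt, x2 = nt, x5 = nt, x6 = nt,
                   stringsAsFactors = FALSE)
  ctx <- paste0(g$x1, g$x2, "TA", g$x5, g$x6)
  canon <- canonical_motif(ctx)
  cls <- sort(unique(canon))
  data.frame(motif_class = cls,
             palindromic = cls == revcomp_chr(cls),
             stringsAsFactors = FALSE)
}

#' Read gene annotations
#'
#' Accepts either a tab-delimited table with columns
#' `locus_id, start, end, strand` (0-based half-open coordinates, `#`
#' comments) or a GFF3 file (detected by extension `.gff`/`.gff3` or a
#' `##gff-version` first line; requires the `rtracklayer` package; `gene`
#' features are used and coordinates converted to 0-based half-open).
#' Genes spanning the origin of a circular chromosome are represented
#' unwrapped, i.e. `end` may exceed the genome length.
#'
#' @param path annotation file path.
#' @return data.frame with columns `locus_id`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path) {
  first <- readLines(path, n = 1L)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    startsWith(first, "##gff-version")
  if (is_gff) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    df <- as.data.frame(rtracklayer::import(path))
    if ("type" %in% names(df) && any(df$type == "gene"))
      df <- df[df$type == "gene", , drop = FALSE]
    ids <- if (!is.null(df$locus_tag) && !anyNA(df$locus_tag)) df$locus_tag
           else if (!is.null(df$ID)) df$ID
           else paste0("gene", seq_len(nrow(df)))
    genes <- data.frame(locus_id = as.character(ids),
                        start = df$start - 1L,
                        end = df$end,
                        strand = as.character(df$strand),
                        stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.delim(path, header = TRUE, comment.char = "#",
                               stringsAsFactors = FALSE)
    names(genes)[1:4] <- c("locus_id", "start", "end", "strand")
  }
  stopifnot(all(genes$strand %in% c("+", "-")),
            all(genes$end > genes$start))
  genes
}

#' Read a mapped-insertion table
#'
#' Tab-delimited, `#` comments, header `position`, `unique` (0/1), then one
#' `reads_s<k>` column per sample.
#'
#' @param path insertion TSV path.
#' @return data.frame with `position`, `unique` (logical) and the read-count
#'   columns.
#' @export
read_insertions <- function(path) {
  ins <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("position", "unique") %in% names(ins)))
  ins$unique <- as.logical(ins$unique)
  ins
}

#' Read an operon membership table
#'
#' Tab-delimited with columns `operon_id` and `genes` (comma-separated locus
#' ids in transcription order).
#'
#' @param path operon TSV path.
#' @return named list: operon id -> character vector of locus ids in order.
#' @export
read_operons <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  ops <- strsplit(tab$genes, ",", fixed = TRUE)
  names(ops) <- tab$operon_id
  lapply(ops, trimws)
}

read_count_cols <- function(records) {
  grep("^reads_", names(records), value = TRUE)
}

#' Map insertion records to TA sites
#'
#' The transposon targets the duplex TA, so a record reported at the A
#' (`position + 1`, e.g. from a minus-strand read) collapses to the same
#' site as one at the T. Returns, per record, the 0-based T position of the
#' matching site or `NA`.
#'
#' @param positions integer vector of record positions (0-based).
#' @param ta_sites `ta_sites` data.frame.
#' @param genome_length genome length (for wrap-around at the origin).
#' @return integer vector of site positions (`NA` = not at a TA).
#' @keywords internal
match_ta_position <- function(positions, ta_sites, genome_length) {
  site_pos <- ta_sites$position
  hit <- ifelse(positions %in% site_pos, positions,
                ifelse(((positions - 1L) %% genome_length) %in% site_pos,
                       (positions - 1L) %% genome_length, NA_integer_))
  as.integer(hit)
}

#' Filter mapped insertions
#'
#' Applies the library filters: records must map uniquely, must have a total
#' read count of at least `min_reads` across samples (default 8), and must
#' coincide with a TA site. A discard report tallies each reason
#' (`non_unique`, `low_count`, `non_ta`; assessed in that order).
#'
#' @param records insertion data.frame (see [read_insertions()]).
#' @param ta_sites `ta_sites` data.frame for the same genome.
#' @param min_reads minimum total read count (default 8).
#' @return list with `retained` (records plus a `site_position` column),
#'   `report` (named counts) and `n_input`.
#' @export
filter_insertions <- function(records, ta_sites, min_reads = 8) {
  L <- attr(ta_sites, "genome_length")
  if (any(records$position >= L | records$position < 0))
    stop("insertion position beyond genome length")
  counts <- records[, read_count_cols(records), drop = FALSE]
  total <- if (ncol(counts)) rowSums(counts) else rep(0, nrow(records))
  site <- match_ta_position(records$position, ta_sites, L)
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(site)] <- "non_ta"
  reason[total < min_reads] <- "low_count"
  reason[!records$unique] <- "non_unique"
  keep <- is.na(reason)
  retained <- records[keep, , drop = FALSE]
  retained$site_position <- site[keep]
  report <- c(non_unique = sum(reason == "non_unique", na.rm = TRUE),
              low_count = sum(reason == "low_count", na.rm = TRUE),
              non_ta = sum(reason == "non_ta", na.rm = TRUE))
  list(retained = retained, report = report, n_input = nrow(records))
}

#' Combine samples into per-site inserted flags
#'
#' A TA site is considered inserted if any retained record from any sample
#' maps to it (union over samples; viability is assessed on the pooled
#' library).
#'
#' @param ta_sites `ta_sites` data.frame.
#' @param retained retained records from [filter_insertions()] (must carry
#'   `site_position`).
#' @return `ta_sites` with the `inserted` column set.
#' @export
combine_samples <- function(ta_sites, retained) {
  ta_sites$inserted <- ta_sites$position %in% retained$site_position
  ta_sites
}

#' Assign TA sites to genes and mark core sites
#'
#' A TA site belongs to a gene iff its T position lies in `[start, end)`.
#' Sites covered by two or more genes are excluded (reason `overlap`). Core
#' sites additionally exclude the terminal 2\% of the gene length at the 3'
#' end (where insertions in essential genes are tolerated); the 5' end is
#' not trimmed.
#'
#' @param ta_sites `ta_sites` data.frame.
#' @param genes gene data.frame (see [read_genes()]).
#' @param terminal_frac fraction of gene length trimmed at the 3' end
#'   (default 0.02).
#' @return list with `ta_sites` (overlap-excluded flags updated) and
#'   `genes`: the gene table with list-columns `site_idx` (row indices into
#'   `ta_sites`), `core_idx`, and counts `s` (core sites) and `s_all`.
#' @export
assign_sites <- function(ta_sites, genes, terminal_frac = 0.02) {
  L <- attr(ta_sites, "genome_length")
  pos <- ta_sites$position
  # unwrapped origin-spanning genes (end > L) are matched via pos + L
  gr <- IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  q1 <- IRanges::IRanges(start = pos + 1L, width = 1L)
  q2 <- IRanges::IRanges(start = pos + L + 1L, width = 1L)
  ov <- rbind(as.data.frame(IRanges::findOverlaps(q1, gr)),
              as.data.frame(IRanges::findOverlaps(q2, gr)))
  ncover <- tabulate(ov$queryHits, nbins = length(pos))
  overlap <- ncover >= 2L
  ta_sites$excluded <- ta_sites$excluded | overlap
  ta_sites$reason[overlap & is.na(ta_sites$reason)] <- "overlap"

  ov <- ov[!overlap[ov$queryHits], , drop = FALSE]
  site_idx <- split(ov$queryHits, factor(ov$subjectHits,
                                         levels = seq_len(nrow(genes))))
  len <- genes$end - genes$start
  genes$site_idx <- unname(site_idx)
  genes$core_idx <- lapply(seq_len(nrow(genes)), function(g) {
    idx <- site_idx[[g]]
    if (!length(idx)) return(integer(0))
    p <- pos[idx]
    p <- ifelse(p < genes$start[g], p + L, p)  # origin-spanning genes
    off <- p - genes$start[g]
    core <- if (genes$strand[g] == "+") off < (1 - terminal_frac) * len[g]
            else off >= terminal_frac * len[g]
    idx[core]
  })
  genes$s_all <- lengths(genes$site_idx)
  genes$s <- lengths(genes$core_idx)
  list(ta_sites = ta_sites, genes = genes)
}
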