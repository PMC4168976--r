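#' Flag essential calls explainable by operon polar effects
#'
#' A transcriptionally terminated transposon inserted in an upstream operon
#' gene silences everything downstream, so an essential call on a
#' non-terminal operon gene may only reflect an essential gene further
#' downstream. An essential call is retained iff the gene is the terminal
#' gene of its operon (genes in no operon are monocistronic, hence
#' terminal) or its immediately downstream neighbor is called
#' nonessential; otherwise it is polar-flagged and excluded from
#' comparisons. A downstream neighbor with an unknown call does not rescue
#' the gene (conservative). Nonessential calls are never flagged.
#'
#' @param result `tifa_result` (or any data.frame with `gene_id` and
#'   `call`).
#' @param operons named list of operons: character vectors of locus ids in
#'   transcription order (see [read_operons()]).
#' @return the result with a logical `polar_flag` column added.
#' @export
polar_filter <- function(result, operons) {
  calls <- result$call
  names(calls) <- result$gene_id
  unknown_genes <- setdiff(unlist(operons, use.names = FALSE),
                           result$gene_id)
  if (length(unknown_genes))
    stop("operon references unknown gene(s): ",
         paste(head(unknown_genes, 5), collapse = ", "))
  downstream <- character(0)
  for (op in operons) {
    if (length(op) > 1) {
      ds <- op[-1]
      names(ds) <- op[-length(op)]
      downstream <- c(downstream, ds)
    }
  }
  flag <- vapply(seq_len(nrow(result)), function(i) {
    if (calls[i] != "essential") return(FALSE)
    id <- result$gene_id[i]
    if (!id %in% names(downstream)) return(FALSE)  # terminal/monocistronic
    calls[[downstream[[id]]]] != "nonessential"
  }, logical(1))
  result$polar_flag <- flag
  result
}
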