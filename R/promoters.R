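#' Extract promoter windows around annotated transcription start sites
#'
#' Cuts the window spanning 1,000 nt upstream to 200 nt downstream of each
#' TSS (the `[-1000, +200)` window in TSS-relative coordinates). For minus
#' strand genes the window is taken on the opposite side and
#' reverse-complemented, so every returned sequence reads 5' to 3' towards
#' the gene. Windows running off a contig end are clipped and flagged
#' truncated; genes whose TSS lies off its contig are skipped with an error
#' record.
#'
#' @param genome a named `DNAStringSet` (names are chromosome/contig ids)
#'   or the path to a FASTA file.
#' @param tss data.frame with columns `gene_id`, `chrom`, `strand` (`"+"` or
#'   `"-"`) and `tss` (1-based position of the transcription start).
#' @param upstream,downstream window extent in nt (defaults 1000 and 200).
#' @return list with `sequences` (a `DNAStringSet` named by gene),
#'   `table` (gene_id, chrom, strand, start, end in 1-based inclusive
#'   genome coordinates, width, truncated flag) and `errors` (data.frame of
#'   skipped genes with reasons).
#' @export
extract_promoters <- function(genome, tss, upstream = 1000L,
                              downstream = 200L) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(inherits(genome, "DNAStringSet"))
  required <- c("gene_id", "chrom", "strand", "tss")
  missing <- setdiff(required, names(tss))
  if (length(missing) > 0) stop("tss table missing: ", paste(missing, collapse = ", "))
  seqs <- character(0)
  rows <- list()
  errs <- list()
  for (i in seq_len(nrow(tss))) {
    g <- tss$gene_id[i]
    chrom <- tss$chrom[i]
    if (!chrom %in% names(genome)) {
      errs[[g]] <- data.frame(gene_id = g, reason = "unknown chromosome")
      next
    }
    L <- Biostrings::width(genome[chrom])
    t0 <- tss$tss[i]
    if (t0 < 1L || t0 > L) {
      errs[[g]] <- data.frame(gene_id = g, reason = "TSS off contig")
      next
    }
    if (tss$strand[i] == "+") {
      start <- t0 - upstream
      end <- t0 + downstream - 1L
    } else {
      start <- t0 - downstream + 1L
      end <- t0 + upstream
    }
    truncated <- start < 1L || end > L
    start_c <- max(start, 1L)
    end_c <- min(end, L)
    s <- Biostrings::subseq(genome[[chrom]], start_c, end_c)
    if (tss$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[g] <- as.character(s)
    rows[[g]] <- data.frame(gene_id = g, chrom = chrom,
                            strand = tss$strand[i],
                            start = start_c, end = end_c,
                            width = end_c - start_c + 1L,
                            truncated = truncated,
                            stringsAsFactors = FALSE)
  }
  list(
    sequences = Biostrings::DNAStringSet(seqs),
    table = if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
            else data.frame(),
    errors = if (length(errs)) do.call(rbind, c(errs, list(make.row.names = FALSE)))
             else data.frame(gene_id = character(0), reason = character(0))
  )
}
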