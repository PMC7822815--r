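#' Find the main open reading frame of a transcript
#'
#' Scans all AUG-initiated frames for the longest ORF ending at an in-frame
#' stop codon; ORFs running off the transcript end do not qualify, and
#' codons containing ambiguous bases neither initiate nor terminate. Ties
#' on length are broken by the 5'-most start. Transcripts whose longest
#' qualifying ORF encodes fewer than `min_codons` amino acids are called
#' non-coding.
#'
#' @param seq Transcript sequence 5' to 3' over A, C, G, T (N allowed).
#' @param min_codons Minimum protein length in amino acids to count as a
#'   significant ORF (default 100).
#' @return list with `coding` (logical), and when coding: `start` (0-based),
#'   `stop` (0-based exclusive end of the stop codon), `protein`.
#' @export
find_main_orf <- function(seq, min_codons = 100) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 6) return(list(coding = FALSE))
  chars <- strsplit(s, "")[[1]]
  ## ambiguous-base codons are inert: only exact ATG/stop triplets match
  starts <- .codon_pos(chars, "ATG")
  if (length(starts) == 0) return(list(coding = FALSE))
  stops <- sort(c(.codon_pos(chars, "TAA"), .codon_pos(chars, "TAG"),
                  .codon_pos(chars, "TGA")))
  best <- NULL
  for (st in starts) {
    fr_stops <- stops[stops > st & (stops - st) %% 3 == 0]
    if (length(fr_stops) == 0) next
    sp <- fr_stops[1]
    len_aa <- (sp - st) / 3  # sense codons before the stop
    if (is.null(best) || len_aa > best$len) best <- list(st = st, sp = sp,
                                                         len = len_aa)
  }
  if (is.null(best) || best$len < min_codons) return(list(coding = FALSE))
  list(coding = TRUE, start = best$st - 1L, stop = best$sp + 2L,
       protein = translate_orf(substr(s, best$st, best$sp - 1)))
}

.codon_pos <- function(chars, codon) {
  cc <- strsplit(codon, "")[[1]]
  which(chars == cc[1] & c(chars[-1], "") == cc[2] &
        c(chars[-(1:2)], "", "") == cc[3])
}

#' Translate an ORF nucleotide sequence
#'
#' Standard genetic code; translation stops at an internal stop codon only
#' if it is the final codon (an internal stop earlier signals a frame bug
#' and raises an error). Codons containing ambiguous bases give `X`.
#'
#' @param seq Nucleotide sequence with length divisible by 3 (the stop
#'   codon may be included or omitted).
#' @return Amino-acid string; attribute `stopless` is `TRUE` when no stop
#'   codon terminates the frame.
#' @export
translate_orf <- function(seq) {
  s <- toupper(chartr("U", "T", seq))
  if (nchar(s) %% 3 != 0) stop("ORF length not divisible by 3")
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  stops <- which(aa == "*")
  if (length(stops) > 0) {
    if (stops[1] != length(aa))
      stop("internal stop codon at codon ", stops[1])
    aa <- aa[-length(aa)]
    res <- paste(aa, collapse = "")
    attr(res, "stopless") <- FALSE
    return(res)
  }
  res <- paste(aa, collapse = "")
  attr(res, "stopless") <- TRUE
  res
}

#' Classify a stop codon as premature or mature
#'
#' Implements the standard exon-junction-complex rule: the stop is a
#' premature termination codon (PTC, predicting nonsense-mediated decay)
#' iff it lies more than `nmd_rule_nt` nucleotides upstream of the last
#' exon-exon junction of the transcript. Single-exon transcripts are always
#' mature.
#'
#' @param orf An [find_main_orf] result with `coding = TRUE`.
#' @param junction_positions Transcript-coordinate positions of exon-exon
#'   junctions: number of bases preceding each junction (strictly
#'   increasing, may be empty).
#' @param nmd_rule_nt Boundary distance in nt (default 50, strict
#'   inequality).
#' @return `"coding_PTC"` or `"coding_mature_stop"`.
#' @export
classify_termination <- function(orf, junction_positions, nmd_rule_nt = 50) {
  if (!isTRUE(orf$coding)) stop("orf is not coding")
  if (length(junction_positions) == 0) return("coding_mature_stop")
  last_j <- max(junction_positions)
  if (last_j - orf$stop > nmd_rule_nt) "coding_PTC" else "coding_mature_stop"
}

#' Annotate spliced transcripts with coding class
#'
#' Convenience wrapper: per transcript, finds the main ORF, classifies
#' termination, and returns a tidy table.
#'
#' @param transcripts data.frame with `transcript_id`, `sequence`,
#'   `junctions` (list-column or comma-separated string of transcript-
#'   coordinate junction positions), `diff_status`.
#' @param min_codons,nmd_rule_nt See [find_main_orf] and
#'   [classify_termination].
#' @return data.frame `transcript_id`, `diff_status`, `coding_class`
#'   (`noncoding`, `coding_PTC`, `coding_mature_stop`), `protein_length`.
#' @export
annotate_coding <- function(transcripts, min_codons = 100,
                            nmd_rule_nt = 50) {
  res <- lapply(seq_len(nrow(transcripts)), function(i) {
    jp <- transcripts$junctions[[i]]
    if (is.character(jp)) jp <- as.numeric(strsplit(jp, ",")[[1]])
    orf <- find_main_orf(transcripts$sequence[i], min_codons)
    if (!orf$coding)
      return(data.frame(transcript_id = transcripts$transcript_id[i],
                        diff_status = transcripts$diff_status[i],
                        coding_class = "noncoding",
                        protein_length = NA_integer_))
    data.frame(transcript_id = transcripts$transcript_id[i],
               diff_status = transcripts$diff_status[i],
               coding_class = classify_termination(orf, jp, nmd_rule_nt),
               protein_length = nchar(orf$protein))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Best percent identity of a protein against a reference set
#'
#' Global (Needleman-Wunsch) alignment against every reference; identity is
#' matches divided by alignment length, and the best hit is retained.
#'
#' @param protein Amino-acid string.
#' @param references Named character vector or `AAStringSet` of reference
#'   proteins.
#' @return list `best_reference`, `identity` (percent).
#' @export
identity_vs_reference <- function(protein, references) {
  if (length(references) == 0) stop("empty reference set")
  if (!methods::is(references, "AAStringSet"))
    references <- Biostrings::AAStringSet(references)
  subj <- Biostrings::AAString(protein)
  best <- -Inf; best_nm <- NA_character_
  for (i in seq_along(references)) {
    al <- Biostrings::pairwiseAlignment(references[[i]], subj,
                                        type = "global")
    idn <- 100 * Biostrings::nmatch(al) / Biostrings::nchar(al)
    if (idn > best) { best <- idn; best_nm <- names(references)[i] }
  }
  list(best_reference = best_nm, identity = best)
}

#' Compare PTC fractions between differential and non-differential isoforms
#'
#' Among coding transcripts only, computes the PTC fraction per
#' `diff_status` group and tests the 2x2 association with a two-sided
#' Fisher exact test (cross-product odds ratio).
#'
#' @param calls Output of [annotate_coding].
#' @return One-row data.frame with per-group fractions, `odds_ratio`, `p`.
#' @export
ptc_fraction_test <- function(calls) {
  coding <- calls[calls$coding_class != "noncoding", , drop = FALSE]
  groups <- c("differential", "nondifferential")
  if (!all(groups %in% coding$diff_status))
    stop("both diff_status groups must contain coding transcripts")
  is_ptc <- coding$coding_class == "coding_PTC"
  a <- sum(is_ptc & coding$diff_status == "differential")
  b <- sum(!is_ptc & coding$diff_status == "differential")
  c_ <- sum(is_ptc & coding$diff_status == "nondifferential")
  d <- sum(!is_ptc & coding$diff_status == "nondifferential")
  or <- if (any(c(a, b, c_, d) == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)) else (a * d) / (b * c_)
  p <- stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value
  data.frame(ptc_fraction_diff = a / (a + b),
             ptc_fraction_nondiff = c_ / (c_ + d),
             odds_ratio = or, p = p)
}
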