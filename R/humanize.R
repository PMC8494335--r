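#' Pyrimidine-centred trinucleotide frequencies of a genome
#'
#' Counts every overlapping trinucleotide on both strands, collapses the 64
#' contexts onto the 32 pyrimidine-centred classes (centre base C or T), and
#' normalizes to frequencies summing to 1. Windows containing N are skipped.
#'
#' @param genome A `reference_genome`.
#' @param label Source label stored on the result.
#' @return A `trinuc_freqs`: named numeric vector over the 32 contexts, with
#'   attribute `label`.
#' @export
trinuc_frequencies <- function(genome, label = "genome") {
  x <- Biostrings::DNAStringSet(genome$seqs)
  counts <- colSums(Biostrings::trinucleotideFrequency(x)) +
    colSums(Biostrings::trinucleotideFrequency(
      Biostrings::reverseComplement(x)))
  centre <- substr(names(counts), 2, 2)
  pyr <- counts[centre %in% c("C", "T")]
  if (sum(pyr) == 0) stop("genome contains no valid trinucleotide")
  freqs <- pyr / sum(pyr)
  attr(freqs, "label") <- label
  class(freqs) <- c("trinuc_freqs", class(freqs))
  freqs
}

.check_freqs <- function(f) {
  stopifnot(length(f) == 32L)
  if (abs(sum(f) - 1) > 1e-9) stop("trinucleotide frequencies must sum to 1")
  invisible(f)
}

#' Adjust a mutation spectrum between trinucleotide compositions
#'
#' Reweights each trinucleotide-context SNV channel by the ratio of target
#' to source context frequency and renormalizes to a distribution — the
#' standard translation used to compare signatures between genomes with
#' different base composition (e.g. "humanizing" a worm spectrum). When a
#' full 119-channel vector is supplied, only the 96 SNV channels are
#' reweighted; the remaining channels pass through before renormalization.
#'
#' @param spectrum Numeric vector of length 96 (SNV channels, scheme order)
#'   or 119.
#' @param from_freqs Source `trinuc_freqs` (all entries must be positive).
#' @param to_freqs Target `trinuc_freqs`.
#' @param scheme A `channel_scheme`.
#' @return Adjusted spectrum normalized to sum 1, same length as the input.
#' @export
adjust_spectrum <- function(spectrum, from_freqs, to_freqs,
                            scheme = channel_scheme()) {
  .check_freqs(from_freqs); .check_freqs(to_freqs)
  if (any(from_freqs <= 0))
    stop("source trinucleotide frequency of zero: adjustment undefined")
  n <- length(spectrum)
  if (!n %in% c(96L, 119L))
    stop("spectrum must have 96 or 119 channels")
  ctx <- paste0(scheme$snv_fiveprime, scheme$snv_ref, scheme$snv_threeprime)
  w <- as.numeric(to_freqs[ctx] / from_freqs[ctx])
  if (anyNA(w)) stop("frequency tables must be named by trinucleotide")
  out <- spectrum
  out[seq_len(96L)] <- spectrum[seq_len(96L)] * w
  s <- sum(out)
  if (s == 0) stop("adjusted spectrum is zero")
  out / s
}

#' Read / write trinucleotide frequency tables as TSV
#'
#' Two columns: `context` (32 pyrimidine-centred trinucleotides) and
#' `frequency`.
#'
#' @param path File path.
#' @param label Label attached on read.
#' @export
read_trinuc_freqs <- function(path, label = basename(path)) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("context", "frequency") %in% names(df)))
  f <- stats::setNames(df$frequency, df$context)
  f <- f / sum(f)
  .check_freqs(f)
  attr(f, "label") <- label
  class(f) <- c("trinuc_freqs", class(f))
  f
}

#' @rdname read_trinuc_freqs
#' @param freqs A `trinuc_freqs`.
#' @export
write_trinuc_freqs <- function(freqs, path) {
  utils::write.table(
    data.frame(context = names(freqs), frequency = as.numeric(freqs)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic human-like trinucleotide composition
#'
#' Generates a CpG-depleted genome from a first-order Markov chain (CpG
#' dinucleotides suppressed to emulate the 5-methylcytosine-deamination
#' depletion characteristic of mammalian genomes) and returns its
#' trinucleotide frequencies. This is a synthetic stand-in for comparing
#' adjustment behaviour; it is not derived from the human genome.
#'
#' @param length_bp Length of the generated genome.
#' @param cpg_suppression Multiplier (< 1) on the probability of G
#'   following C.
#' @param seed Integer seed.
#' @return A `trinuc_freqs` labelled `"synthetic-human"`.
#' @export
synthetic_human_freqs <- function(length_bp = 2e5, cpg_suppression = 0.2,
                                  seed = 20260101L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  # GC-poor base composition, roughly mammalian
  p0 <- c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)
  trans <- matrix(rep(p0, 4), 4, 4, byrow = TRUE,
                  dimnames = list(bases, bases))
  trans["C", "G"] <- trans["C", "G"] * cpg_suppression
  trans <- trans / rowSums(trans)
  seq <- character(length_bp)
  seq[1] <- sample(bases, 1, prob = p0)
  for (i in 2:length_bp)
    seq[i] <- sample(bases, 1, prob = trans[seq[i - 1], ])
  g <- reference_genome(c(synthetic_human = paste(seq, collapse = "")))
  trinuc_frequencies(g, label = "synthetic-human")
}
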