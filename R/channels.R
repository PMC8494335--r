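#' The fixed 119-channel mutation classification scheme
#'
#' Builds the ordered channel scheme used throughout the package:
#' 96 single-nucleotide-variant channels (the six pyrimidine-centred
#' substitution types C>A, C>G, C>T, T>A, T>C, T>G crossed with the 16
#' combinations of 5' and 3' flanking base, COSMIC-style labels such as
#' `A[C>T]G`), one aggregate dinucleotide-variant channel (`DNV`), one
#' aggregate multi-nucleotide-variant channel (`MNV`), 14 indel channels
#' (deletions and insertions binned by size 1, 2-5, 6-50, 51-400, >400 bp,
#' plus deletion-with-insertion events binned by deleted length 1-5, 6-50,
#' 51-400, >400 bp), and 7 structural-variant channels (tandem duplication,
#' large deletion, inversion, complex, translocation, interchromosomal
#' rearrangement, foldback).
#'
#' @return An object of class `channel_scheme`: a list with elements
#'   `labels` (length-119 character), `group` (factor with levels
#'   `snv`, `dnv`, `mnv`, `indel`, `sv`), and for SNV channels the parsed
#'   `snv_fiveprime`, `snv_ref`, `snv_alt`, `snv_threeprime` vectors.
#' @examples
#' sch <- channel_scheme()
#' length(sch$labels)       # 119
#' table(sch$group)
#' @export
channel_scheme <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  grid <- expand.grid(b3 = bases, b5 = bases, sub = subs,
                      stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder to
  # substitution-major, then 5' base, then 3' base
  grid <- grid[, c("sub", "b5", "b3")]
  snv_labels <- sprintf("%s[%s]%s", grid$b5, grid$sub, grid$b3)
  snv_ref <- substr(grid$sub, 1, 1)
  snv_alt <- substr(grid$sub, 3, 3)

  indel_labels <- c(
    "DEL_1", "DEL_2_5", "DEL_6_50", "DEL_51_400", "DEL_gt400",
    "INS_1", "INS_2_5", "INS_6_50", "INS_51_400", "INS_gt400",
    "INDEL_1_5", "INDEL_6_50", "INDEL_51_400", "INDEL_gt400"
  )
  sv_labels <- paste0("SV_", c("TD", "DEL", "INV", "COMPLEX",
                               "TRSL", "INTCHR", "FOLDBACK"))

  labels <- c(snv_labels, "DNV", "MNV", indel_labels, sv_labels)
  stopifnot(length(labels) == 119L, !anyDuplicated(labels))
  group <- factor(
    c(rep("snv", 96L), "dnv", "mnv",
      rep("indel", 14L), rep("sv", 7L)),
    levels = c("snv", "dnv", "mnv", "indel", "sv")
  )
  scheme <- list(
    labels = labels,
    group = group,
    snv_fiveprime = grid$b5,
    snv_ref = snv_ref,
    snv_alt = snv_alt,
    snv_threeprime = grid$b3,
    index = stats::setNames(seq_along(labels), labels)
  )
  class(scheme) <- "channel_scheme"
  scheme
}

#' @export
print.channel_scheme <- function(x, ...) {
  cat("channel_scheme: 119 channels",
      sprintf("(%d SNV, 1 DNV, 1 MNV, %d indel, %d SV)\n",
              sum(x$group == "snv"), sum(x$group == "indel"),
              sum(x$group == "sv")))
  invisible(x)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(s) {
  vapply(strsplit(s, ""), function(ch)
    paste(rev(unname(.complement[ch])), collapse = ""), character(1))
}

# indel size -> bin suffix used in channel labels
.indel_bin <- function(size, kind) {
  stopifnot(size >= 1)
  if (kind == "INDEL") {
    if (size <= 5) "1_5"
    else if (size <= 50) "6_50"
    else if (size <= 400) "51_400"
    else "gt400"
  } else {
    if (size == 1) "1"
    else if (size <= 5) "2_5"
    else if (size <= 50) "6_50"
    else if (size <= 400) "51_400"
    else "gt400"
  }
}

#' Classify variant records into the 119-channel scheme
#'
#' Assigns each variant its channel index. SNVs are placed by their
#' trinucleotide context read from the supplied reference; substitutions
#' with a purine reference base are reverse-complemented (mutated base and
#' both flanks) onto the pyrimidine-centred channel. DNVs and MNVs go to
#' their aggregate channels, indels are binned by type and size, and
#' structural variants by their type annotation.
#'
#' SNVs whose trinucleotide context is undefined (first or last base of a
#' chromosome) or contains `N` are unclassifiable and receive `NA`; they are
#' excluded from spectra but counted, so classified + unclassifiable always
#' equals the number of input records. A reference base that contradicts the
#' record's REF allele is an error.
#'
#' @param variants A `variant_records` data frame (see [read_variants()]).
#' @param genome A `reference_genome` (see [read_reference()]).
#' @param scheme A `channel_scheme`; built fresh if omitted.
#' @return Integer vector of channel indices (1..119), `NA` for
#'   unclassifiable records.
#' @export
classify_variants <- function(variants, genome, scheme = channel_scheme()) {
  n <- nrow(variants)
  idx <- rep(NA_integer_, n)
  if (n == 0L) return(idx)
  for (i in seq_len(n)) {
    cls <- variants$var_class[i]
    if (cls == "SNV") {
      chrom <- variants$chrom[i]
      pos <- variants$pos[i]
      len <- genome_length(genome, chrom)
      refbase <- ref_base(genome, chrom, pos)
      if (refbase != variants$ref[i]) {
        stop(sprintf(
          "reference mismatch at %s:%d: reference has %s, record REF is %s",
          chrom, pos, refbase, variants$ref[i]))
      }
      if (pos <= 1L || pos >= len) next  # boundary: no trinucleotide
      b5 <- ref_base(genome, chrom, pos - 1L)
      b3 <- ref_base(genome, chrom, pos + 1L)
      ref <- variants$ref[i]
      alt <- variants$alt[i]
      if (b5 == "N" || b3 == "N" || ref == "N" || alt == "N") next
      if (ref %in% c("G", "A")) {  # pyrimidine strand normalization
        tmp <- b5
        b5 <- unname(.complement[b3])
        b3 <- unname(.complement[tmp])
        ref <- unname(.complement[ref])
        alt <- unname(.complement[alt])
      }
      lab <- sprintf("%s[%s>%s]%s", b5, ref, alt, b3)
      idx[i] <- scheme$index[[lab]]
    } else if (cls == "DNV") {
      idx[i] <- scheme$index[["DNV"]]
    } else if (cls == "MNV") {
      idx[i] <- scheme$index[["MNV"]]
    } else if (cls == "DEL") {
      idx[i] <- scheme$index[[paste0("DEL_", .indel_bin(nchar(variants$ref[i]), "DEL"))]]
    } else if (cls == "INS") {
      idx[i] <- scheme$index[[paste0("INS_", .indel_bin(nchar(variants$alt[i]), "INS"))]]
    } else if (cls == "INDEL") {
      idx[i] <- scheme$index[[paste0("INDEL_", .indel_bin(nchar(variants$ref[i]), "INDEL"))]]
    } else if (cls == "SV") {
      sv <- variants$sv_type[i]
      if (is.na(sv)) stop("SV record without sv_type")
      idx[i] <- scheme$index[[paste0("SV_", sv)]]
    } else {
      stop("unknown var_class: ", cls)
    }
  }
  idx
}

#' @rdname classify_variants
#' @param variant A single-row `variant_records` data frame.
#' @export
classify_variant <- function(variant, genome, scheme = channel_scheme()) {
  classify_variants(variant[1, , drop = FALSE], genome, scheme)
}

#' Build a per-sample mutation spectrum
#'
#' Counts classified variants per channel. Unclassifiable records (SNVs with
#' undefined or N-containing context) are excluded from the counts and
#' reported in the `unclassified` field, so that
#' `sum(counts) + unclassified == nrow(variants)`.
#'
#' @inheritParams classify_variants
#' @param sample_id Label stored on the spectrum; defaults to the (single)
#'   sample id present in `variants`.
#' @return A `mutation_spectrum`: list with `sample_id`, `counts`
#'   (named length-119 integer vector) and `unclassified` (integer).
#' @export
count_spectrum <- function(variants, genome, scheme = channel_scheme(),
                           sample_id = NULL) {
  if (is.null(sample_id)) {
    ids <- unique(variants$sample_id)
    if (length(ids) > 1L)
      stop("variants from multiple samples; pass sample_id explicitly")
    sample_id <- if (length(ids)) ids else NA_character_
  }
  idx <- classify_variants(variants, genome, scheme)
  counts <- tabulate(idx, nbins = 119L)
  names(counts) <- scheme$labels
  out <- list(sample_id = sample_id, counts = counts,
              unclassified = sum(is.na(idx)))
  class(out) <- "mutation_spectrum"
  out
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("mutation_spectrum for %s: %d mutations (%d unclassified)\n",
              x$sample_id, sum(x$counts), x$unclassified))
  invisible(x)
}

#' Spectrum matrix over many samples
#'
#' @inheritParams count_spectrum
#' @param sample_sheet A sample sheet data frame (see [read_sample_sheet()]);
#'   one spectrum row is produced per sample, in sheet order (samples with no
#'   variants get zero rows).
#' @return Integer matrix samples x 120 (119 channels plus an
#'   `unclassified` column), rownames = sample ids.
#' @export
spectrum_matrix <- function(variants, sample_sheet, genome,
                            scheme = channel_scheme()) {
  ids <- sample_sheet$sample_id
  mat <- matrix(0L, nrow = length(ids), ncol = 120L,
                dimnames = list(ids, c(scheme$labels, "unclassified")))
  for (id in ids) {
    sp <- count_spectrum(variants[variants$sample_id == id, , drop = FALSE],
                         genome, scheme, sample_id = id)
    mat[id, ] <- c(sp$counts, sp$unclassified)
  }
  mat
}

#' Per-class totals of a spectrum
#'
#' Collapses channel counts into the three broad reporting classes used for
#' dose-response screening: substitutions (SNV + DNV + MNV channels), indels
#' (14 channels) and structural variants (7 channels).
#'
#' @param counts A `mutation_spectrum`, or a numeric vector of length 119
#'   (or a matrix with 119 columns, optionally followed by an
#'   `unclassified` column which is ignored).
#' @param scheme A `channel_scheme`.
#' @return Named vector (or matrix) with entries `substitutions`, `indels`,
#'   `svs`; the three always sum to the total channel count.
#' @export
class_totals <- function(counts, scheme = channel_scheme()) {
  if (inherits(counts, "mutation_spectrum")) counts <- counts$counts
  grp <- scheme$group
  sub_idx <- which(grp %in% c("snv", "dnv", "mnv"))
  ind_idx <- which(grp == "indel")
  sv_idx <- which(grp == "sv")
  if (is.matrix(counts)) {
    counts <- counts[, seq_len(119L), drop = FALSE]
    cbind(substitutions = rowSums(counts[, sub_idx, drop = FALSE]),
          indels = rowSums(counts[, ind_idx, drop = FALSE]),
          svs = rowSums(counts[, sv_idx, drop = FALSE]))
  } else {
    counts <- counts[seq_len(119L)]
    c(substitutions = sum(counts[sub_idx]),
      indels = sum(counts[ind_idx]),
      svs = sum(counts[sv_idx]))
  }
}

#' Channel indices of the finer reporting classes
#'
#' The four classes used for genotype-versus-wild-type comparisons:
#' `snv` (96 channels), `mnv` (DNV + MNV aggregate channels),
#' `indel` and `sv`.
#'
#' @param scheme A `channel_scheme`.
#' @return Named list of integer index vectors.
#' @export
reporting_classes <- function(scheme = channel_scheme()) {
  list(snv = which(scheme$group == "snv"),
       mnv = which(scheme$group %in% c("dnv", "mnv")),
       indel = which(scheme$group == "indel"),
       sv = which(scheme$group == "sv"))
}

#' Write a spectrum matrix as TSV
#'
#' Rows are samples, columns the 119 labelled channels plus `unclassified`.
#'
#' @param mat Matrix from [spectrum_matrix()].
#' @param path Output file.
#' @export
write_spectra <- function(mat, path) {
  df <- data.frame(sample = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
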