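#' Read a reference genome from FASTA
#'
#' Sequences are uppercased; chromosome order in the file is preserved.
#' Names are truncated at the first whitespace (FASTA description lines).
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `reference_genome`: list with `seqs` (named character vector of
#'   uppercase sequences) preserving file order.
#' @export
read_reference <- function(fasta_path) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  nms <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nms))
    stop("duplicate chromosome name in FASTA: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  seqs <- toupper(as.character(x))
  names(seqs) <- nms
  reference_genome(seqs)
}

#' Construct a reference genome from named sequences
#'
#' @param seqs Named character vector of sequences over A, C, G, T, N.
#' @return A `reference_genome`.
#' @export
reference_genome <- function(seqs) {
  if (length(seqs) == 0L) stop("empty reference genome")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all chromosomes must be named")
  g <- list(seqs = toupper(seqs))
  class(g) <- "reference_genome"
  g
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("reference_genome: %d chromosomes, %s bp total\n",
              length(x$seqs),
              format(sum(nchar(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' Write a reference genome as FASTA
#' @param genome A `reference_genome`.
#' @param path Output path.
#' @export
write_reference <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$seqs), path)
  invisible(path)
}

#' Chromosome length lookup
#' @param genome A `reference_genome`.
#' @param chrom Chromosome name.
#' @export
genome_length <- function(genome, chrom) {
  if (!chrom %in% names(genome$seqs))
    stop("chromosome not in reference: ", chrom)
  nchar(genome$seqs[[chrom]])
}

#' Reference base lookup (1-based, inclusive)
#'
#' @param genome A `reference_genome`.
#' @param chrom Chromosome name.
#' @param pos 1-based start position.
#' @param len Number of bases to return.
#' @export
ref_base <- function(genome, chrom, pos, len = 1L) {
  n <- genome_length(genome, chrom)
  if (pos < 1L || pos + len - 1L > n)
    stop(sprintf("position %d..%d outside chromosome %s [1, %d]",
                 pos, pos + len - 1L, chrom, n))
  substr(genome$seqs[[chrom]], pos, pos + len - 1L)
}

.sv_types <- c("TD", "DEL", "INV", "TRSL", "INTCHR", "FOLDBACK", "COMPLEX")
.var_classes <- c("SNV", "DNV", "MNV", "INS", "DEL", "INDEL", "SV")

#' Construct a variant-record table
#'
#' Internal record model shared by all stages. Coordinates are 1-based
#' inclusive; `pos` is the first affected reference base (for pure
#' insertions, the reference base before which the new sequence is
#' inserted). Indels are stored unanchored: `ref` holds the deleted bases,
#' `alt` the inserted bases, either possibly empty.
#'
#' @param sample_id,chrom,pos,ref,alt,var_class,sv_type,sv_end_chrom,sv_end
#'   Field vectors, recycled to a common length.
#' @return A data frame of class `variant_records`, sorted by
#'   (chrom, pos, ref, alt).
#' @export
variant_records <- function(sample_id, chrom, pos, ref, alt, var_class,
                            sv_type = NA_character_,
                            sv_end_chrom = NA_character_,
                            sv_end = NA_integer_) {
  if (length(chrom) == 0L) return(sort_variants(read_variants_empty()))
  df <- data.frame(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, var_class = var_class,
    sv_type = sv_type, sv_end_chrom = sv_end_chrom,
    sv_end = as.integer(sv_end),
    stringsAsFactors = FALSE
  )
  validate_variants(df)
  sort_variants(df)
}

#' @rdname variant_records
#' @param df A data frame with variant-record columns.
#' @export
validate_variants <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  stopifnot(all(df$pos >= 1L))
  bad <- !df$var_class %in% .var_classes
  if (any(bad)) stop("unknown var_class: ", df$var_class[which(bad)[1]])
  is_sub <- df$var_class %in% c("SNV", "DNV", "MNV")
  if (any(is_sub & (nchar(df$ref) != nchar(df$alt) | df$ref == df$alt)))
    stop("substitution records must have equal-length, differing ref/alt")
  if (any(df$var_class == "SNV" & nchar(df$ref) != 1L))
    stop("SNV records must have ref/alt of length 1")
  if (any(df$var_class == "DNV" & nchar(df$ref) != 2L))
    stop("DNV records must have ref/alt of length 2")
  if (any(df$var_class == "MNV" & nchar(df$ref) < 3L))
    stop("MNV records must have ref/alt of length >= 3")
  if (any(df$var_class == "DEL" & (nchar(df$ref) == 0L | nchar(df$alt) > 0L)))
    stop("DEL records must have non-empty ref and empty alt")
  if (any(df$var_class == "INS" & (nchar(df$alt) == 0L | nchar(df$ref) > 0L)))
    stop("INS records must have empty ref and non-empty alt")
  if (any(df$var_class == "INDEL" &
          (nchar(df$ref) == 0L | nchar(df$alt) == 0L |
           nchar(df$ref) == nchar(df$alt))))
    stop("INDEL records must have non-empty ref/alt of different length")
  sv <- df$var_class == "SV"
  if (any(sv & is.na(df$sv_type)))
    stop("SV records require sv_type")
  if (any(sv & !df$sv_type %in% .sv_types))
    stop("unknown sv_type: ", df$sv_type[sv & !df$sv_type %in% .sv_types][1])
  if (any(!sv & !is.na(df$sv_type)))
    stop("sv_type set on a non-SV record")
  intra <- sv & df$sv_type %in% c("TD", "DEL", "INV", "FOLDBACK", "TRSL")
  if (any(intra & is.na(df$sv_end)))
    stop("intra-chromosomal SV records require sv_end")
  invisible(df)
}

#' @rdname variant_records
#' @export
sort_variants <- function(df) {
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("variant_records", "data.frame")
  df
}

# left-trim the shared anchor prefix of a VCF REF/ALT pair,
# advancing pos; returns list(pos, ref, alt)
.trim_anchor <- function(pos, ref, alt) {
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# classify a trimmed (unanchored) ref/alt pair into a var_class
.classify_refalt <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) {
    if (nr == 1L) "SNV" else if (nr == 2L) "DNV" else "MNV"
  } else if (na == 0L) "DEL"
  else if (nr == 0L) "INS"
  else "INDEL"
}

# map a VCF SVTYPE string (+ end chromosome) onto the 7-type enum
.map_svtype <- function(svtype, chrom, end_chrom, strict, line) {
  up <- toupper(svtype)
  if (up == "DUP") return("TD")
  if (up %in% c("DEL", "INV", "FOLDBACK", "COMPLEX", "TD",
                "TRSL", "INTCHR")) {
    return(switch(up, DEL = "DEL", INV = "INV", FOLDBACK = "FOLDBACK",
                  COMPLEX = "COMPLEX", TD = "TD", TRSL = "TRSL",
                  INTCHR = "INTCHR"))
  }
  if (up %in% c("BND", "TRA")) {
    if (!is.na(end_chrom) && end_chrom != chrom) return("INTCHR")
    return("TRSL")
  }
  if (strict)
    stop(sprintf("unknown SVTYPE '%s' at line %d (strict mode)",
                 svtype, line))
  warning(sprintf("unknown SVTYPE '%s' at line %d mapped to COMPLEX",
                  svtype, line))
  "COMPLEX"
}

.info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' Read variant calls from a VCF file
#'
#' Parses a VCF v4.x file into the internal record model. Variant class is
#' inferred from REF/ALT lengths after left-trimming the shared anchor base
#' (so indels are stored unanchored), or from the `SVTYPE` INFO key for
#' structural variants. Multi-allelic lines are split into one record per
#' ALT allele. `SVTYPE` strings are mapped onto the 7-type scheme:
#' DUP to TD; DEL, INV unchanged; BND/TRA to TRSL (same chromosome partner)
#' or INTCHR (different chromosome, via a `CHR2` INFO key or a breakend ALT);
#' FOLDBACK and COMPLEX honoured when explicitly annotated; anything else is
#' an error in strict mode, otherwise mapped to COMPLEX with a warning.
#'
#' @param vcf_path Path to a VCF file.
#' @param sample_id Sample label attached to every record.
#' @param strict If `TRUE`, unknown SVTYPE values are errors.
#' @return A `variant_records` data frame sorted by (chrom, pos, ref, alt).
#' @export
read_variants <- function(vcf_path, sample_id, strict = FALSE) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_header <- length(vcf@meta) + 1L  # meta lines + column header line
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    line_no <- n_header + i
    chrom <- fix[i, "CHROM"]
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    ref <- toupper(fix[i, "REF"])
    alt_field <- fix[i, "ALT"]
    info <- fix[i, "INFO"]
    if (is.na(pos) || is.na(ref) || is.na(alt_field))
      stop(sprintf("malformed VCF record at line %d", line_no))
    svtype <- .info_field(info, "SVTYPE")
    alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
    recs <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (!is.na(svtype) || grepl("^<", alt) ||
          grepl("[][]", alt)) {
        # structural variant
        end <- suppressWarnings(as.integer(.info_field(info, "END")))
        end_chrom <- .info_field(info, "CHR2")
        # breakend ALT like N[chrII:123[ encodes the partner locus
        bnd <- regmatches(alt, regexec("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]",
                                       alt, perl = TRUE))[[1]]
        if (length(bnd) == 3L) {
          end_chrom <- bnd[2]
          if (is.na(end)) end <- as.integer(bnd[3])
        }
        st <- if (is.na(svtype)) {
          if (grepl("[][]", alt)) "BND" else gsub("[<>]", "", alt)
        } else svtype
        sv_type <- .map_svtype(st, chrom, end_chrom, strict, line_no)
        if (is.na(end_chrom)) end_chrom <- chrom
        if (sv_type %in% c("TD", "DEL", "INV", "FOLDBACK", "TRSL") &&
            is.na(end))
          stop(sprintf("SV record without END at line %d", line_no))
        recs[[j]] <- data.frame(
          sample_id = sample_id, chrom = chrom, pos = pos,
          ref = "", alt = "", var_class = "SV", sv_type = sv_type,
          sv_end_chrom = end_chrom, sv_end = end,
          stringsAsFactors = FALSE)
      } else {
        alt <- toupper(alt)
        if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
          stop(sprintf("malformed alleles '%s'/'%s' at line %d",
                       ref, alt, line_no))
        if (ref == alt)
          stop(sprintf("parse error at line %d: REF equals ALT", line_no))
        tr <- .trim_anchor(pos, ref, alt)
        if (nchar(tr$ref) == 0L && nchar(tr$alt) == 0L)
          stop(sprintf("parse error at line %d: REF equals ALT", line_no))
        recs[[j]] <- data.frame(
          sample_id = sample_id, chrom = chrom, pos = tr$pos,
          ref = tr$ref, alt = tr$alt,
          var_class = .classify_refalt(tr$ref, tr$alt),
          sv_type = NA_character_, sv_end_chrom = NA_character_,
          sv_end = NA_integer_, stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- do.call(rbind, recs)
  }
  out <- Filter(Negate(is.null), out)
  df <- if (length(out))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  else read_variants_empty()
  validate_variants(df)
  sort_variants(df)
}

#' Write variant records as VCF v4.2
#'
#' The inverse of [read_variants()]: indels are re-anchored on the reference
#' base preceding the event (which requires `genome` and `pos >= 2`), and
#' structural variants are written with symbolic ALT alleles and
#' `SVTYPE`/`END`/`CHR2` INFO keys.
#'
#' @param variants A `variant_records` data frame.
#' @param path Output path.
#' @param genome A `reference_genome`; required when indel records are
#'   present (anchor bases) and used for SNV REF sanity.
#' @export
write_variants <- function(variants, path, genome = NULL) {
  svmap <- c(TD = "DUP", DEL = "DEL", INV = "INV", TRSL = "BND",
             INTCHR = "BND", FOLDBACK = "FOLDBACK", COMPLEX = "COMPLEX")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radsig",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Chromosome of the second breakpoint\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$var_class %in% c("SNV", "DNV", "MNV")) {
      lines[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                          v$chrom, v$pos, v$ref, v$alt)
    } else if (v$var_class == "SV") {
      svt <- svmap[[v$sv_type]]
      info <- sprintf("SVTYPE=%s", svt)
      if (v$sv_type %in% c("TD", "DEL", "INV", "FOLDBACK", "COMPLEX") ||
          !is.na(v$sv_end))
        info <- paste0(info, sprintf(";END=%d", v$sv_end))
      if (v$sv_type %in% c("TRSL", "INTCHR"))
        info <- paste0(info, sprintf(";CHR2=%s", v$sv_end_chrom))
      alt <- sprintf("<%s>", svt)
      refb <- if (!is.null(genome)) ref_base(genome, v$chrom, v$pos) else "N"
      lines[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                          v$chrom, v$pos, refb, alt, info)
    } else {
      # indel classes need the left anchor base
      if (is.null(genome))
        stop("writing indel records requires the reference genome")
      if (v$pos < 2L)
        stop("cannot anchor an indel at chromosome position 1")
      anchor <- ref_base(genome, v$chrom, v$pos - 1L)
      lines[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                          v$chrom, v$pos - 1L,
                          paste0(anchor, v$ref), paste0(anchor, v$alt))
    }
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects a TSV with header columns `sample`, `genotype`, `dose_gy`,
#' `replicate`, `generation`.
#'
#' @param tsv_path Path to the sample sheet.
#' @return A data frame of class `sample_sheet` with columns `sample_id`,
#'   `genotype`, `dose_gy`, `replicate`, `generation`.
#' @export
read_sample_sheet <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("sample", "genotype", "dose_gy", "replicate", "generation")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sample sheet missing columns: ", paste(missing, collapse = ", "))
  sample_sheet(sample_id = df$sample, genotype = df$genotype,
               dose_gy = df$dose_gy, replicate = df$replicate,
               generation = df$generation)
}

#' @rdname read_sample_sheet
#' @param sample_id,genotype,dose_gy,replicate,generation Column vectors.
#' @export
sample_sheet <- function(sample_id, genotype, dose_gy, replicate,
                         generation = "F1") {
  df <- data.frame(sample_id = as.character(sample_id),
                   genotype = as.character(genotype),
                   dose_gy = as.numeric(dose_gy),
                   replicate = as.integer(replicate),
                   generation = as.character(generation),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id: ",
         df$sample_id[duplicated(df$sample_id)][1])
  if (any(is.na(df$dose_gy) | df$dose_gy < 0 | df$dose_gy > 200))
    stop("dose_gy must lie in [0, 200] Gy")
  if (any(is.na(df$replicate) | df$replicate < 1L))
    stop("replicate must be a positive integer")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet as TSV
#' @param sheet A `sample_sheet`.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  out <- data.frame(sample = sheet$sample_id, genotype = sheet$genotype,
                    dose_gy = sheet$dose_gy, replicate = sheet$replicate,
                    generation = sheet$generation)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
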