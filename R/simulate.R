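#' Simulation configuration
#'
#' Encodes the generative counterpart of the analysis model: per-channel
#' counts in each sample are Poisson with mean
#' `background_k + (dose/80) * ir_rate_k * exp(lfc_{g,k})`, a small fraction
#' of substitution and indel events is re-placed into tight clusters, and
#' counts are realized as concrete variant records on a toy genome.
#'
#' @param seed Integer seed driving every random choice.
#' @param chrom_lengths Named integer vector of chromosome lengths for the
#'   generated toy genome (i.i.d. uniform bases).
#' @param doses_gy Dose levels in Gray.
#' @param replicates_per_dose Clonal lines per genotype and dose.
#' @param background_per_genome Length-119 non-negative vector: expected
#'   dose-independent counts per sample.
#' @param ir_rate_per_80gy Length-119 non-negative vector: expected
#'   radiation-induced counts per sample at 80 Gy in wild-type.
#' @param genotype_lfc Named list mapping genotype to a length-119 vector of
#'   log fold-changes applied to the radiation component; must contain
#'   `"wild-type"` (all zero).
#' @param cluster_fraction Fraction of substitution + indel events placed
#'   into clusters.
#' @param cluster_size_range Integer pair: mutations per cluster.
#' @param cluster_span_range Integer pair: cluster span in bp.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = stats::setNames(
                         rep(1e6L, 5L),
                         c("chrI", "chrII", "chrIII", "chrIV", "chrV")),
                       doses_gy = c(0, 20, 40, 60, 80),
                       replicates_per_dose = 3L,
                       background_per_genome = rep(1 / 119, 119L),
                       ir_rate_per_80gy = rep(0, 119L),
                       genotype_lfc = list("wild-type" = rep(0, 119L)),
                       cluster_fraction = 0.06,
                       cluster_size_range = c(2L, 3L),
                       cluster_span_range = c(10L, 20L)) {
  cfg <- list(seed = as.integer(seed),
              chrom_lengths = chrom_lengths,
              doses_gy = doses_gy,
              replicates_per_dose = as.integer(replicates_per_dose),
              background_per_genome = background_per_genome,
              ir_rate_per_80gy = ir_rate_per_80gy,
              genotype_lfc = genotype_lfc,
              cluster_fraction = cluster_fraction,
              cluster_size_range = as.integer(cluster_size_range),
              cluster_span_range = as.integer(cluster_span_range))
  stopifnot(
    length(cfg$background_per_genome) == 119L,
    length(cfg$ir_rate_per_80gy) == 119L,
    all(cfg$background_per_genome >= 0),
    all(cfg$ir_rate_per_80gy >= 0),
    all(vapply(cfg$genotype_lfc, length, 1L) == 119L),
    "wild-type" %in% names(cfg$genotype_lfc),
    cfg$cluster_fraction >= 0, cfg$cluster_fraction <= 1,
    cfg$cluster_size_range[1] >= 2L, cfg$cluster_size_range[2] <= 10L,
    cfg$cluster_size_range[1] <= cfg$cluster_size_range[2],
    cfg$cluster_span_range[1] >= 2L, cfg$cluster_span_range[2] <= 1000L,
    cfg$cluster_span_range[1] <= cfg$cluster_span_range[2],
    # a cluster of max size must fit distinct positions in the min span
    cfg$cluster_span_range[1] + 1L >= cfg$cluster_size_range[2],
    length(cfg$doses_gy) >= 1L, all(cfg$doses_gy >= 0),
    cfg$replicates_per_dose >= 1L
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default wild-type configuration
#'
#' Defaults reproduce the wild-type study conditions: triplicate clonal F1
#' lines at doses 0, 20, 40, 60 and 80 Gy; radiation per-80-Gy class totals
#' of 36.63 SNVs (flat across the 96 trinucleotide channels, a radiation
#' signature affecting all nucleotides equally), 1.3 DNVs, 4 indels (flat
#' across the 14 indel channels) and 1.4 SVs (flat across the 7 SV
#' channels); 6% of substitution + indel mutations placed in clusters of
#' 2-3 mutations spanning 10-20 bp. The spontaneous background is a small
#' flat vector totalling 1 expected mutation per genome.
#'
#' @param seed Integer seed.
#' @param scheme A `channel_scheme`.
#' @return A `sim_config`.
#' @export
default_wildtype_config <- function(seed = 1L, scheme = channel_scheme()) {
  ir <- numeric(119L)
  ir[scheme$group == "snv"] <- 36.63 / 96
  ir[scheme$group == "dnv"] <- 1.3
  ir[scheme$group == "mnv"] <- 0
  ir[scheme$group == "indel"] <- 4 / 14
  ir[scheme$group == "sv"] <- 1.4 / 7
  sim_config(seed = seed, ir_rate_per_80gy = ir)
}

# random toy genome: i.i.d. uniform bases per chromosome
.random_genome <- function(chrom_lengths) {
  seqs <- vapply(chrom_lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  reference_genome(seqs)
}

# sample a chromosome proportional to its length, then a position in
# [lo, len - margin]; returns c(chrom index, pos)
.sample_locus <- function(lens, margin = 1L, lo = 2L) {
  k <- sample.int(length(lens), 1L, prob = lens)
  len <- lens[k]
  hi <- len - margin
  if (hi < lo) stop("chromosome too short for requested event")
  c(k, sample.int(hi - lo + 1L, 1L) + lo - 1L)
}

# find a genome position whose trinucleotide context matches
# (b5, ref, b3) on either strand; bounded retries
.find_context <- function(genome, b5, ref, b3, max_tries = 2000L) {
  lens <- nchar(genome$seqs)
  want_f <- paste0(b5, ref, b3)
  want_r <- .revcomp(want_f)
  for (t in seq_len(max_tries)) {
    loc <- .sample_locus(lens, margin = 1L, lo = 2L)
    tri <- substr(genome$seqs[[loc[1]]], loc[2] - 1L, loc[2] + 1L)
    if (tri == want_f) return(list(chrom = loc[1], pos = loc[2],
                                   strand = "+"))
    if (tri == want_r) return(list(chrom = loc[1], pos = loc[2],
                                   strand = "-"))
  }
  stop(sprintf("context %s not found in toy genome after %d tries",
               want_f, max_tries))
}

.other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)

# random substitution string differing from ref at every position
.random_sub <- function(ref) {
  paste(vapply(strsplit(ref, "")[[1]],
               function(b) sample(.other_bases(b), 1L), character(1)),
        collapse = "")
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform draw of an event size within an indel bin
.bin_size <- function(bin) {
  lim <- switch(bin,
                "1" = c(1L, 1L), "2_5" = c(2L, 5L), "6_50" = c(6L, 50L),
                "51_400" = c(51L, 400L), "gt400" = c(401L, 1000L),
                "1_5" = c(1L, 5L))
  sample(seq(lim[1], lim[2]), 1L)
}

#' Simulate a full irradiation experiment
#'
#' For every genotype, dose and replicate, draws per-channel Poisson counts
#' under the additive model and realizes them as variant records placed on
#' the toy genome: SNVs at positions whose trinucleotide context matches
#' their channel (searching both strands, bounded retries), indel and SV
#' lengths uniform within their channel's size bin, and structural variants
#' with plausible end coordinates. A fraction `cluster_fraction` of
#' substitution and indel events is then re-placed into tight clusters;
#' relocated substitutions take their reference allele from the new locus
#' (a random differing alternative allele), so realized channel counts for
#' clustered SNVs follow the genome's local context. The generator returns
#' its own record-level tally of realized channel counts, which
#' [count_spectrum()] reproduces exactly.
#'
#' @param cfg A `sim_config`.
#' @param genotypes Genotypes to simulate; defaults to all in
#'   `cfg$genotype_lfc`.
#' @param genome Optional pre-built `reference_genome` to reuse across
#'   simulations; by default a fresh toy genome is generated from the seed.
#' @param scheme A `channel_scheme`.
#' @return A list of class `sim_experiment` with elements `variants`
#'   (a `variant_records` data frame over all samples), `samples`
#'   (a `sample_sheet`), `genome`, and `realized` (samples x 119 count
#'   matrix of the realized spectra).
#' @export
simulate_experiment <- function(cfg, genotypes = names(cfg$genotype_lfc),
                                genome = NULL, scheme = channel_scheme()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (is.null(genome)) genome <- .random_genome(cfg$chrom_lengths)
  chroms <- names(genome$seqs)
  lens <- nchar(genome$seqs)

  meta <- expand.grid(replicate = seq_len(cfg$replicates_per_dose),
                      dose_gy = cfg$doses_gy, genotype = genotypes,
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_d%g_r%d",
                            gsub("[^A-Za-z0-9]+", ".", meta$genotype),
                            meta$dose_gy, meta$replicate)
  sheet <- sample_sheet(meta$sample_id, meta$genotype, meta$dose_gy,
                        meta$replicate, "F1")

  realized <- matrix(0L, nrow = nrow(sheet), ncol = 119L,
                     dimnames = list(sheet$sample_id, scheme$labels))
  all_recs <- vector("list", nrow(sheet))

  # generator-side channel derivation for a substitution placed at a new
  # locus (pyrimidine-centred, like the scheme definition)
  snv_channel_at <- function(b5, ref, alt, b3) {
    if (ref %in% c("G", "A")) {
      tmp <- b5
      b5 <- unname(.complement[b3]); b3 <- unname(.complement[tmp])
      ref <- unname(.complement[ref]); alt <- unname(.complement[alt])
    }
    scheme$index[[sprintf("%s[%s>%s]%s", b5, ref, alt, b3)]]
  }

  for (s in seq_len(nrow(sheet))) {
    g <- sheet$genotype[s]
    d <- sheet$dose_gy[s]
    mu <- cfg$background_per_genome +
      (d / 80) * cfg$ir_rate_per_80gy * exp(cfg$genotype_lfc[[g]])
    counts <- stats::rpois(119L, mu)
    events <- rep(seq_len(119L), counts)
    n <- length(events)
    if (n == 0L) {
      all_recs[[s]] <- NULL
      next
    }
    rec <- data.frame(sample_id = sheet$sample_id[s],
                      chrom = NA_character_, pos = NA_integer_,
                      ref = NA_character_, alt = NA_character_,
                      var_class = NA_character_, sv_type = NA_character_,
                      sv_end_chrom = NA_character_, sv_end = NA_integer_,
                      channel = events, stringsAsFactors = FALSE)
    used <- new.env(hash = TRUE)
    place_unique <- function(chrom, pos) {
      key <- paste0(chrom, ":", pos)
      if (exists(key, envir = used, inherits = FALSE)) return(FALSE)
      assign(key, TRUE, envir = used)
      TRUE
    }
    for (e in seq_len(n)) {
      k <- events[e]
      grp <- as.character(scheme$group[k])
      repeat {
        if (grp == "snv") {
          loc <- .find_context(genome, scheme$snv_fiveprime[k],
                               scheme$snv_ref[k], scheme$snv_threeprime[k])
          chrom <- chroms[loc$chrom]; pos <- loc$pos
          if (loc$strand == "+") {
            ref <- scheme$snv_ref[k]; alt <- scheme$snv_alt[k]
          } else {
            ref <- unname(.complement[scheme$snv_ref[k]])
            alt <- unname(.complement[scheme$snv_alt[k]])
          }
          cls <- "SNV"; svt <- NA; ec <- NA; se <- NA
        } else if (grp %in% c("dnv", "mnv")) {
          w <- if (grp == "dnv") 2L else 3L
          loc <- .sample_locus(lens, margin = w - 1L, lo = 2L)
          chrom <- chroms[loc[1]]; pos <- loc[2]
          ref <- substr(genome$seqs[[loc[1]]], pos, pos + w - 1L)
          alt <- .random_sub(ref)
          cls <- if (grp == "dnv") "DNV" else "MNV"
          svt <- NA; ec <- NA; se <- NA
        } else if (grp == "indel") {
          lab <- scheme$labels[k]
          kind <- sub("_.*$", "", lab)
          bin <- sub("^[A-Z]+_", "", lab)
          size <- .bin_size(bin)
          if (kind == "DEL") {
            loc <- .sample_locus(lens, margin = size, lo = 2L)
            chrom <- chroms[loc[1]]; pos <- loc[2]
            ref <- substr(genome$seqs[[loc[1]]], pos, pos + size - 1L)
            alt <- ""
            cls <- "DEL"
          } else if (kind == "INS") {
            loc <- .sample_locus(lens, margin = 1L, lo = 2L)
            chrom <- chroms[loc[1]]; pos <- loc[2]
            ref <- ""; alt <- .random_seq(size)
            cls <- "INS"
          } else {
            loc <- .sample_locus(lens, margin = size, lo = 2L)
            chrom <- chroms[loc[1]]; pos <- loc[2]
            ref <- substr(genome$seqs[[loc[1]]], pos, pos + size - 1L)
            ins <- if (size > 1L) sample(seq_len(size - 1L), 1L)
                   else size + sample(1:4, 1L)
            alt <- .random_seq(ins)
            cls <- "INDEL"
          }
          svt <- NA; ec <- NA; se <- NA
        } else {  # sv
          svt <- sub("^SV_", "", scheme$labels[k])
          loc <- .sample_locus(lens, margin = 1L, lo = 2L)
          chrom <- chroms[loc[1]]; pos <- loc[2]
          ref <- ""; alt <- ""; cls <- "SV"
          span <- sample(1000:10000, 1L)
          if (svt == "INTCHR") {
            others <- setdiff(seq_along(chroms), loc[1])
            if (length(others) == 0L) others <- loc[1]
            oc <- if (length(others) == 1L) others else sample(others, 1L)
            ec <- chroms[oc]
            se <- sample.int(lens[oc] - 1L, 1L) + 1L
          } else {
            ec <- chrom
            se <- min(pos + span, lens[loc[1]])
          }
        }
        if (place_unique(chrom, pos)) break
      }
      rec$chrom[e] <- chrom; rec$pos[e] <- pos
      rec$ref[e] <- ref; rec$alt[e] <- alt
      rec$var_class[e] <- cls; rec$sv_type[e] <- svt
      rec$sv_end_chrom[e] <- ec; rec$sv_end[e] <- se
    }

    # cluster placement: re-place a fraction of substitution/indel events
    eligible <- which(rec$var_class != "SV")
    n_clust <- round(cfg$cluster_fraction * length(eligible))
    if (n_clust >= 2L) {
      pool <- sample(eligible, n_clust)
      while (length(pool) >= 2L) {
        size <- sample(seq(cfg$cluster_size_range[1],
                           cfg$cluster_size_range[2]), 1L)
        size <- min(size, length(pool))
        if (length(pool) - size == 1L) size <- length(pool)  # avoid orphan
        size <- min(size, length(pool))
        members <- pool[seq_len(size)]
        pool <- pool[-seq_len(size)]
        span <- sample(seq(cfg$cluster_span_range[1],
                           cfg$cluster_span_range[2]), 1L)
        repeat {
          loc <- .sample_locus(lens, margin = span + 1L, lo = 2L)
          offs <- c(0L, span)
          if (size > 2L)
            offs <- c(offs, sample(seq_len(span - 1L), size - 2L))
          poss <- loc[2] + offs
          free <- vapply(poss, function(p)
            !exists(paste0(chroms[loc[1]], ":", p), envir = used,
                    inherits = FALSE), TRUE)
          if (all(free)) break
        }
        for (p in poss) assign(paste0(chroms[loc[1]], ":", p), TRUE,
                               envir = used)
        for (j in seq_len(size)) {
          e <- members[j]
          chrom <- chroms[loc[1]]; pos <- poss[j]
          rec$chrom[e] <- chrom; rec$pos[e] <- pos
          cls <- rec$var_class[e]
          if (cls %in% c("SNV", "DNV", "MNV")) {
            w <- nchar(rec$ref[e])
            ref <- substr(genome$seqs[[loc[1]]], pos, pos + w - 1L)
            rec$ref[e] <- ref
            rec$alt[e] <- .random_sub(ref)
            if (cls == "SNV") {
              # context changed: re-derive the channel at the new locus
              b5 <- substr(genome$seqs[[loc[1]]], pos - 1L, pos - 1L)
              b3 <- substr(genome$seqs[[loc[1]]], pos + w, pos + w)
              rec$channel[e] <- snv_channel_at(b5, ref, rec$alt[e], b3)
            }
          } else if (cls %in% c("DEL", "INDEL")) {
            w <- nchar(rec$ref[e])
            rec$ref[e] <- substr(genome$seqs[[loc[1]]], pos, pos + w - 1L)
          }
          # INS records keep their inserted sequence; indel and aggregate
          # channels do not depend on position
        }
      }
    }

    realized[s, ] <- tabulate(rec$channel, nbins = 119L)
    rec$channel <- NULL
    all_recs[[s]] <- rec
  }

  keep <- Filter(Negate(is.null), all_recs)
  variants <- if (length(keep))
    do.call(rbind, c(keep, list(make.row.names = FALSE)))
  else read_variants_empty()
  validate_variants(variants)
  variants <- sort_variants(variants)

  out <- list(variants = variants, samples = sheet, genome = genome,
              realized = realized)
  class(out) <- "sim_experiment"
  out
}

read_variants_empty <- function() {
  data.frame(sample_id = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             var_class = character(), sv_type = character(),
             sv_end_chrom = character(), sv_end = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d samples, %d variants, %d chromosomes\n",
              nrow(x$samples), nrow(x$variants), length(x$genome$seqs)))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits one VCF per sample, the toy genome as FASTA, and the sample sheet
#' as TSV. Byte-identical for identical configurations and seeds.
#'
#' @param sim A `sim_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  write_reference(sim$genome, fasta)
  sheet <- file.path(dir, "samples.tsv")
  write_sample_sheet(sim$samples, sheet)
  vcfs <- character(nrow(sim$samples))
  for (i in seq_len(nrow(sim$samples))) {
    id <- sim$samples$sample_id[i]
    vcfs[i] <- file.path(dir, paste0(id, ".vcf"))
    write_variants(sim$variants[sim$variants$sample_id == id, , drop = FALSE],
                   vcfs[i], sim$genome)
  }
  invisible(list(genome = fasta, samples = sheet, vcfs = vcfs))
}
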