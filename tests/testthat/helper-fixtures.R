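# Shared fixtures, built in code.

# deterministic toy genome: small chromosomes with all contexts present
toy_genome <- function(lengths = c(c1 = 6000L, c2 = 4000L), seed = 424242L) {
  withr::with_seed(seed, {
    seqs <- vapply(lengths, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = ""), character(1))
  })
  reference_genome(seqs)
}

# hand-written 7-record VCF: 1 SNV, 1 DNV, 1 insertion, 1 deletion,
# 1 tandem duplication, 1 inversion, 1 inter-chromosomal breakend
write_fixture_vcf <- function(path, genome) {
  a200 <- ref_base(genome, "c1", 200L)   # anchor for the insertion
  a300 <- ref_base(genome, "c1", 300L)   # anchor for the deletion
  d3 <- ref_base(genome, "c1", 301L, 3L) # the three deleted bases
  snv_ref <- ref_base(genome, "c1", 100L)
  snv_alt <- setdiff(c("A", "C", "G", "T"), snv_ref)[1]
  dnv_ref <- ref_base(genome, "c2", 150L, 2L)
  dnv_alt <- paste0(setdiff(c("A", "C", "G", "T"), substr(dnv_ref, 1, 1))[1],
                    setdiff(c("A", "C", "G", "T"), substr(dnv_ref, 2, 2))[1])
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("c1\t100\t.\t%s\t%s\t.\tPASS\t.", snv_ref, snv_alt),
    sprintf("c2\t150\t.\t%s\t%s\t.\tPASS\t.", dnv_ref, dnv_alt),
    sprintf("c1\t200\t.\t%s\t%sTTAA\t.\tPASS\t.", a200, a200),
    sprintf("c1\t300\t.\t%s%s\t%s\t.\tPASS\t.", a300, d3, a300),
    "c1\t1000\t.\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=3000",
    "c2\t1200\t.\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=2200",
    "c1\t1500\t.\tN\tN[c2:500[\t.\tPASS\tSVTYPE=BND"
  )
  writeLines(lines, path)
  path
}

# a small simulated experiment with reduced burden, for fast tests
small_config <- function(seed = 1L, ...) {
  cfg <- default_wildtype_config(seed = seed)
  cfg$chrom_lengths <- c(cA = 300000L, cB = 300000L)
  modifyList(cfg, list(...))
}

# brute-force grid-search MLE for the additive Poisson model (oracle)
grid_poisson_mle <- function(dose, count, b_max = NULL, r_max = NULL,
                             n_grid = 400L) {
  if (is.null(b_max)) b_max <- max(count) + 2
  if (is.null(r_max)) r_max <- (max(count) + 2) / max(dose)
  bs <- seq(0, b_max, length.out = n_grid)
  rs <- seq(0, r_max, length.out = n_grid)
  best <- c(NA, NA); best_ll <- -Inf
  for (b in bs) {
    mu <- outer(rs, dose) + b  # rows: r values
    mu[mu <= 0] <- 1e-12
    ll <- rowSums(dpois(matrix(count, nrow = length(rs), ncol = length(count),
                               byrow = TRUE), mu, log = TRUE))
    j <- which.max(ll)
    if (ll[j] > best_ll) { best_ll <- ll[j]; best <- c(b, rs[j]) }
  }
  # refine around the coarse optimum
  for (rep in 1:2) {
    db <- diff(bs[1:2]); dr <- diff(rs[1:2])
    bs <- seq(max(0, best[1] - 2 * db), best[1] + 2 * db,
              length.out = n_grid)
    rs <- seq(max(0, best[2] - 2 * dr), best[2] + 2 * dr,
              length.out = n_grid)
    for (b in bs) {
      mu <- outer(rs, dose) + b
      mu[mu <= 0] <- 1e-12
      ll <- rowSums(dpois(matrix(count, nrow = length(rs),
                                 ncol = length(count), byrow = TRUE),
                          mu, log = TRUE))
      j <- which.max(ll)
      if (ll[j] > best_ll) { best_ll <- ll[j]; best <- c(b, rs[j]) }
    }
  }
  list(b = best[1], r = best[2], loglik = best_ll)
}

# O(n^2) transitive-linkage clustering oracle: link positions closer than
# the window, take connected components of size >= 2
linkage_cluster_oracle <- function(pos, window_bp = 1000L) {
  n <- length(pos)
  if (n == 0L) return(list())
  pos <- sort(pos)
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(pos[i] - pos[j]) <= window_bp) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  grps <- split(pos, comp)
  Filter(function(g) length(g) >= 2L, unname(grps))
}

# exhaustive-path Viterbi oracle over gap states (1 = background,
# 2 = clustered)
viterbi_oracle <- function(gaps, params, mean_background) {
  n <- length(gaps)
  lt <- log(matrix(c(1 - params$p_enter, params$p_enter,
                     params$p_exit, 1 - params$p_exit), 2, 2,
                   byrow = TRUE))
  pi0 <- log(c(params$p_exit, params$p_enter) /
             (params$p_enter + params$p_exit))
  em <- function(g, s)
    dgeom(max(g, 1L) - 1L,
          1 / max(if (s == 1) mean_background else params$mean_clustered,
                  1.000001), log = TRUE)
  best <- NULL; best_lp <- -Inf
  for (code in 0:(2^n - 1)) {
    path <- as.integer(intToBits(code)[seq_len(n)]) + 1L
    lp <- pi0[path[1]] + em(gaps[1], path[1])
    if (n > 1) for (i in 2:n)
      lp <- lp + lt[path[i - 1], path[i]] + em(gaps[i], path[i])
    if (lp > best_lp) { best_lp <- lp; best <- path }
  }
  best
}

# all permutations of 1..n (small n)
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) for (k in 0:(n - 1L)) {
    out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

# textbook Benjamini-Hochberg step-up: find the largest k with
# p_(k) <= k/m * q; adjusted p by the standard monotone formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
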