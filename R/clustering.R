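#' Sliding-window mutation cluster caller
#'
#' Clusters are maximal runs of two or more mutation start points in which
#' every consecutive inter-mutation gap is at most `window_bp` (1000 bp by
#' default, matching a 1000-bp sliding-window scan's connected components).
#' Coordinates are 1-based inclusive; clusters never span chromosomes, and
#' every position belongs to at most one cluster.
#'
#' @param positions Data frame with columns `chrom` and `pos` (substitution
#'   and indel start points), or a `variant_records` data frame (SV records
#'   are dropped automatically).
#' @param window_bp Maximum allowed gap between consecutive cluster members.
#' @return Data frame of class `cluster_calls`: one row per cluster with
#'   `chrom`, `start`, `end`, `n`, `span_bp`, and a `members` list-column of
#'   sorted member positions.
#' @export
call_clusters_window <- function(positions, window_bp = 1000L) {
  pts <- .cluster_points(positions)
  out <- list()
  for (chrom in unique(pts$chrom)) {
    p <- sort(pts$pos[pts$chrom == chrom])
    if (length(p) < 2L) next
    gap_ok <- diff(p) <= window_bp
    r <- rle(gap_ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      members <- p[starts[j]:(ends[j] + 1L)]  # k gaps span k+1 positions
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = members[1],
        end = members[length(members)],
        n = length(members),
        span_bp = members[length(members)] - members[1],
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- list(members)
    }
  }
  .cluster_frame(out)
}

.cluster_points <- function(positions) {
  if (inherits(positions, "variant_records") ||
      ("var_class" %in% names(positions)))
    positions <- positions[positions$var_class != "SV", , drop = FALSE]
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  positions[, c("chrom", "pos")]
}

.cluster_frame <- function(rows) {
  if (length(rows) == 0L) {
    df <- data.frame(chrom = character(), start = integer(),
                     end = integer(), n = integer(), span_bp = integer(),
                     stringsAsFactors = FALSE)
    df$members <- list()
  } else {
    df <- do.call(rbind, rows)
  }
  class(df) <- c("cluster_calls", "data.frame")
  df
}

#' Two-state HMM parameters for cluster decoding
#'
#' Transition probabilities default to the values used for the cancer-genome
#' analysis: 0.01 to leave the clustered state and 0.1 to enter it.
#' Emissions are geometric distributions over inter-mutation gaps with
#' state-specific means (`mean_clustered` bp within clusters; the
#' non-clustered mean defaults at decode time to genome span divided by
#' mutation count).
#'
#' @param p_enter Non-clustered to clustered transition probability.
#' @param p_exit Clustered to non-clustered transition probability.
#' @param mean_clustered Mean gap (bp) inside clusters.
#' @param mean_background Mean gap (bp) outside clusters; `NA` means
#'   estimate per chromosome as span / number of gaps.
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(p_enter = 0.1, p_exit = 0.01,
                       mean_clustered = 100, mean_background = NA_real_) {
  stopifnot(p_enter > 0, p_enter < 1, p_exit > 0, p_exit < 1,
            is.finite(mean_clustered), mean_clustered > 0)
  out <- list(p_enter = p_enter, p_exit = p_exit,
              mean_clustered = mean_clustered,
              mean_background = mean_background)
  class(out) <- "hmm_params"
  out
}

# log geometric density for a gap with given mean (support gap >= 1)
.lgeom <- function(gap, mean) {
  prob <- 1 / max(mean, 1.000001)
  stats::dgeom(pmax(gap, 1L) - 1L, prob, log = TRUE)
}

#' HMM-based mutation cluster caller
#'
#' A two-state hidden Markov model over the inter-mutation gaps of each
#' chromosome: state 1 (non-clustered) emits geometrically distributed gaps
#' with a long mean, state 2 (clustered) with a short mean. The Viterbi path
#' is decoded exactly; each maximal run of clustered gaps becomes one
#' cluster whose members are the touched mutation positions (so a single
#' clustered gap yields a 2-mutation cluster). The initial state follows the
#' chain's stationary distribution. Decoding is deterministic.
#'
#' @inheritParams call_clusters_window
#' @param params An `hmm_params`.
#' @return A `cluster_calls` data frame, as for [call_clusters_window()].
#' @export
call_clusters_hmm <- function(positions, params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"))
  pts <- .cluster_points(positions)
  out <- list()
  for (chrom in unique(pts$chrom)) {
    p <- sort(pts$pos[pts$chrom == chrom])
    if (length(p) < 2L) next
    gaps <- diff(p)
    mb <- params$mean_background
    if (is.na(mb)) mb <- max((p[length(p)] - p[1]) / length(gaps),
                             params$mean_clustered * 10)
    if (!is.finite(mb) || mb <= 0)
      stop("non-finite background emission mean")
    state <- .viterbi_gaps(gaps, params, mb)
    r <- rle(state == 2L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      members <- p[starts[j]:(ends[j] + 1L)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = members[1],
        end = members[length(members)],
        n = length(members),
        span_bp = members[length(members)] - members[1],
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- list(members)
    }
  }
  .cluster_frame(out)
}

# exact Viterbi decode of gap states; state 1 background, state 2 clustered
.viterbi_gaps <- function(gaps, params, mean_background) {
  n <- length(gaps)
  # log transition matrix [from, to]
  lt <- log(matrix(c(1 - params$p_enter, params$p_enter,
                     params$p_exit, 1 - params$p_exit),
                   2, 2, byrow = TRUE))
  # stationary initial distribution
  pi0 <- c(params$p_exit, params$p_enter) /
    (params$p_enter + params$p_exit)
  em <- rbind(.lgeom(gaps, mean_background),
              .lgeom(gaps, params$mean_clustered))
  delta <- matrix(-Inf, 2, n)
  psi <- matrix(0L, 2, n)
  delta[, 1] <- log(pi0) + em[, 1]
  if (n > 1L) for (i in 2:n) {
    for (s in 1:2) {
      cand <- delta[, i - 1L] + lt[, s]
      psi[s, i] <- which.max(cand)
      delta[s, i] <- cand[psi[s, i]] + em[s, i]
    }
  }
  state <- integer(n)
  state[n] <- which.max(delta[, n])
  if (n > 1L) for (i in (n - 1L):1L) state[i] <- psi[state[i + 1L], i + 1L]
  state
}

#' Detect clusters across the samples of an experiment
#'
#' Runs a cluster caller per sample (the default: a cluster cannot span
#' animals) or pooled per genotype x generation for fidelity with analyses
#' that pool clonal lines.
#'
#' @param variants A `variant_records` data frame over all samples.
#' @param metas A `sample_sheet`.
#' @param method `"window"` or `"hmm"`.
#' @param pooled Pool positions across samples of the same genotype and
#'   generation before calling.
#' @param window_bp Window for the window method.
#' @param params `hmm_params` for the HMM method.
#' @return A `cluster_calls` data frame with an additional `sample_id`
#'   (or `genotype`) column.
#' @export
detect_clusters <- function(variants, metas, method = c("window", "hmm"),
                            pooled = FALSE, window_bp = 1000L,
                            params = hmm_params()) {
  method <- match.arg(method)
  call1 <- function(v) {
    if (method == "window") call_clusters_window(v, window_bp)
    else call_clusters_hmm(v, params)
  }
  if (pooled) {
    keys <- unique(metas[, c("genotype", "generation")])
    out <- lapply(seq_len(nrow(keys)), function(i) {
      ids <- metas$sample_id[metas$genotype == keys$genotype[i] &
                             metas$generation == keys$generation[i]]
      cc <- call1(variants[variants$sample_id %in% ids, , drop = FALSE])
      if (nrow(cc)) {
        cc$genotype <- keys$genotype[i]
        cc$generation <- keys$generation[i]
      }
      cc
    })
  } else {
    out <- lapply(metas$sample_id, function(id) {
      cc <- call1(variants[variants$sample_id == id, , drop = FALSE])
      if (nrow(cc)) cc$sample_id <- id
      cc
    })
  }
  out <- Filter(nrow, out)
  if (length(out) == 0L) {
    df <- .cluster_frame(list())
    df$sample_id <- character(0)
    return(df)
  }
  df <- do.call(rbind, out)
  class(df) <- c("cluster_calls", "data.frame")
  df
}

#' Per-genotype clustering summary
#'
#' Summarizes per-sample cluster calls: the proportion of eligible
#' (substitution + indel) mutations inside clusters, the cluster rate per
#' genome normalized to 80 Gy via the additive Poisson dose-response fit of
#' per-sample cluster counts, and the distributions of cluster span and
#' size (median, interquartile range).
#'
#' @param calls Per-sample `cluster_calls` from [detect_clusters()].
#' @param variants The `variant_records` the calls were produced from.
#' @param metas A `sample_sheet`.
#' @return Data frame of class `cluster_summary`, one row per genotype;
#'   the per-sample table is attached as attribute `per_sample`.
#' @export
summarize_clusters <- function(calls, variants, metas) {
  stopifnot("sample_id" %in% names(calls) || nrow(calls) == 0L)
  elig <- variants[variants$var_class != "SV", , drop = FALSE]
  per_sample <- data.frame(
    sample_id = metas$sample_id, genotype = metas$genotype,
    dose_gy = metas$dose_gy,
    n_eligible = vapply(metas$sample_id, function(id)
      sum(elig$sample_id == id), 0L),
    n_clusters = vapply(metas$sample_id, function(id)
      sum(calls$sample_id == id), 0L),
    n_clustered = vapply(metas$sample_id, function(id)
      sum(calls$n[calls$sample_id == id]), 0),
    stringsAsFactors = FALSE, row.names = NULL)

  out <- lapply(unique(metas$genotype), function(g) {
    ps <- per_sample[per_sample$genotype == g, ]
    cg <- calls[calls$sample_id %in% ps$sample_id, , drop = FALSE]
    rate <- if (length(unique(ps$dose_gy)) >= 2L)
      fit_rate(ps$dose_gy, ps$n_clusters, genotype = g,
               class_label = "clusters")
    else NULL
    spans <- cg$span_bp; sizes <- cg$n
    # Tukey whiskers: most extreme observations within 1.5 IQR of the box
    whisk <- function(x, side) {
      if (!length(x)) return(NA_real_)
      q <- stats::quantile(x, c(0.25, 0.75))
      iqr <- q[2] - q[1]
      if (side == "lo") min(x[x >= q[1] - 1.5 * iqr])
      else max(x[x <= q[2] + 1.5 * iqr])
    }
    data.frame(
      genotype = g,
      clusters_per_80gy = if (is.null(rate)) NA_real_ else rate$per80,
      clusters_se = if (is.null(rate)) NA_real_ else rate$se_per80,
      prop_clustered = if (sum(ps$n_eligible) > 0)
        sum(ps$n_clustered) / sum(ps$n_eligible) else 0,
      n_clusters = nrow(cg),
      span_median = if (length(spans)) stats::median(spans) else NA_real_,
      span_iqr_lo = if (length(spans))
        unname(stats::quantile(spans, 0.25)) else NA_real_,
      span_iqr_hi = if (length(spans))
        unname(stats::quantile(spans, 0.75)) else NA_real_,
      span_whisker_lo = whisk(spans, "lo"),
      span_whisker_hi = whisk(spans, "hi"),
      size_median = if (length(sizes)) stats::median(sizes) else NA_real_,
      size_iqr_lo = if (length(sizes))
        unname(stats::quantile(sizes, 0.25)) else NA_real_,
      size_iqr_hi = if (length(sizes))
        unname(stats::quantile(sizes, 0.75)) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "per_sample") <- per_sample
  class(out) <- c("cluster_summary", "data.frame")
  out
}

#' Linear model of a clustering response on dose
#'
#' Ordinary least squares of a per-sample clustering response (proportion
#' clustered, or cluster count) on dose, with coefficient standard errors
#' and the residual variance.
#'
#' @param dose_gy Dose vector (at least 3 distinct levels).
#' @param response Per-sample clustering response.
#' @return List with `intercept`, `slope`, their `se`, and `sigma2`.
#' @export
clustering_dose_model <- function(dose_gy, response) {
  stopifnot(length(dose_gy) == length(response))
  if (length(unique(dose_gy)) < 3L)
    stop("at least 3 dose levels are required")
  fit <- stats::lm(response ~ dose_gy)
  sm <- summary(fit)
  co <- sm$coefficients
  list(intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
       se_intercept = unname(co[1, 2]), se_slope = unname(co[2, 2]),
       sigma2 = sm$sigma^2)
}

#' Compare a genotype's clustering rate to wild-type
#'
#' z-test on the per-80-Gy cluster rates (or any pair of estimates with
#' standard errors), identical in form to the signature-model comparison.
#'
#' @param rate_g,se_g Genotype clustering rate and SE.
#' @param rate_wt,se_wt Wild-type clustering rate and SE.
#' @return List with `z`, `p` and `direction`.
#' @export
compare_clustering <- function(rate_g, se_g, rate_wt, se_wt) {
  zt <- z_test_rates(rate_g, se_g, rate_wt, se_wt)
  c(zt, list(direction = if (zt$z >= 0) "up" else "down"))
}

#' Compare clustering across all genotypes with FDR control
#'
#' @param summary A `cluster_summary` (from [summarize_clusters()]).
#' @param wt_label Reference genotype.
#' @param q_threshold FDR threshold.
#' @return Data frame with per-genotype z, p, BH q and `significant`.
#' @export
compare_clustering_table <- function(summary, wt_label = "wild-type",
                                     q_threshold = 0.05) {
  wt <- summary[summary$genotype == wt_label, ]
  if (nrow(wt) != 1L) stop("wild-type row not found in summary")
  others <- summary[summary$genotype != wt_label, , drop = FALSE]
  rows <- lapply(seq_len(nrow(others)), function(i) {
    zt <- compare_clustering(others$clusters_per_80gy[i],
                             others$clusters_se[i],
                             wt$clusters_per_80gy, wt$clusters_se)
    data.frame(genotype = others$genotype[i],
               rate = others$clusters_per_80gy[i],
               rate_wt = wt$clusters_per_80gy,
               z = zt$z, p = zt$p, direction = zt$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_threshold
  out
}

#' Write cluster calls as BED
#'
#' BED uses 0-based half-open intervals; the name field carries the member
#' count, and the sample (or genotype) of each call when present.
#'
#' @param calls A `cluster_calls` data frame.
#' @param path Output path.
#' @export
write_clusters_bed <- function(calls, path) {
  if (nrow(calls) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  id <- if ("sample_id" %in% names(calls)) calls$sample_id
        else if ("genotype" %in% names(calls)) calls$genotype
        else "."
  lines <- sprintf("%s\t%d\t%d\t%s", calls$chrom, calls$start - 1L,
                   calls$end, paste0(id, ":n=", calls$n))
  writeLines(lines, path)
  invisible(path)
}
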