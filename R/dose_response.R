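#' Non-zero-intercept additive Poisson rate fit
#'
#' Maximum-likelihood fit of the additive dose-response model
#' `count_i ~ Poisson(b + r * dose_i)` with `b >= 0` (background mutations
#' per sample at dose 0) and `r >= 0` (mutations per Gray), identity link.
#' Standard errors come from the observed Fisher information at the maximum;
#' at a boundary solution (`b = 0` or `r = 0`) the one-sided standard error
#' from the corresponding diagonal information element is reported. Rates
#' are reported per 80 Gy, the conventional dose unit of the assay.
#'
#' @param dose_gy Numeric vector of doses in Gray.
#' @param count Non-negative integer vector of per-sample mutation counts.
#' @param genotype,class_label Labels carried into the result.
#' @return A `rate_estimate`: list with `background`, `rate_per_gy`,
#'   `se_rate`, `per80` (= 80 * rate), `se_per80`, `ci95` (on the per-80-Gy
#'   scale, truncated at 0), `degenerate` flag, and `loglik`.
#' @examples
#' fit_rate(c(0, 40, 80), c(2, 4, 6))$per80  # 4
#' @export
fit_rate <- function(dose_gy, count, genotype = NA_character_,
                     class_label = NA_character_) {
  stopifnot(length(dose_gy) == length(count), all(count >= 0),
            all(dose_gy >= 0))
  if (length(unique(dose_gy)) < 2L)
    stop("at least two distinct dose levels are required")
  count <- as.numeric(count)

  if (all(count == 0)) {
    out <- list(genotype = genotype, class_label = class_label,
                background = 0, rate_per_gy = 0, se_rate = NA_real_,
                per80 = 0, se_per80 = NA_real_, ci95 = c(0, 0),
                degenerate = TRUE, loglik = 0)
    class(out) <- "rate_estimate"
    return(out)
  }

  nll <- function(par) {
    mu <- par[1] + par[2] * dose_gy
    if (any(mu <= 0 & count > 0)) return(1e12)
    mu <- pmax(mu, 1e-12)
    sum(mu - count * log(mu))
  }
  # moment-style starting values
  b0 <- max(mean(count[dose_gy == min(dose_gy)]), 0.1)
  r0 <- max((mean(count) - b0) / max(mean(dose_gy), 1e-9), 1e-3)
  ctl <- list(factr = 1e2, maxit = 1000,
              parscale = c(max(b0, 0.1), max(r0, 1e-6)))
  opt <- stats::optim(c(b0, r0), nll, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(Inf, Inf), control = ctl)
  # polish from the first solution (L-BFGS-B can stop on a shallow slope)
  opt <- stats::optim(opt$par, nll, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(Inf, Inf), control = ctl)
  b <- opt$par[1]; r <- opt$par[2]

  # observed information of the negative log-likelihood
  mu <- pmax(b + r * dose_gy, 1e-12)
  i_bb <- sum(count / mu^2)
  i_br <- sum(dose_gy * count / mu^2)
  i_rr <- sum(dose_gy^2 * count / mu^2)
  eps <- 1e-8
  at_boundary <- (b < eps) || (r < eps)
  se_r <- if (at_boundary) {
    if (i_rr > 0) 1 / sqrt(i_rr) else NA_real_
  } else {
    det <- i_bb * i_rr - i_br^2
    if (det > 0) sqrt(i_bb / det) else NA_real_
  }

  per80 <- 80 * r
  se80 <- 80 * se_r
  ci <- if (is.na(se80)) c(NA_real_, NA_real_)
        else c(max(0, per80 - 1.96 * se80), per80 + 1.96 * se80)
  out <- list(genotype = genotype, class_label = class_label,
              background = b, rate_per_gy = r, se_rate = se_r,
              per80 = per80, se_per80 = se80, ci95 = ci,
              degenerate = FALSE, loglik = -opt$value)
  class(out) <- "rate_estimate"
  out
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "rate_estimate%s: background %.3f, %.3f per 80 Gy (se %.3f)%s\n",
    if (is.na(x$genotype)) "" else paste0(" [", x$genotype, "]"),
    x$background, x$per80, x$se_per80,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Screen genotypes for a dose-dependent mutation increase
#'
#' For each genotype, the per-sample totals of the three broad mutation
#' classes (substitutions, indels, structural variants) are correlated with
#' dose; a genotype passes the screen when at least two classes show a
#' positive Pearson correlation with two-sided p below `alpha`. Classes
#' with zero variance have an undefined correlation and are treated as
#' non-significant.
#'
#' @param spectra Samples x channels count matrix from [spectrum_matrix()]
#'   (119 or 120 columns; rownames are sample ids).
#' @param metas A `sample_sheet`.
#' @param alpha Screen significance threshold (two-sided).
#' @param scheme A `channel_scheme`.
#' @return A data frame of class `dose_screen`, one row per genotype, with
#'   per-class `r_` and `p_` columns and a logical `passes`.
#' @export
screen_dose_response <- function(spectra, metas, alpha = 0.05,
                                 scheme = channel_scheme()) {
  stopifnot(all(rownames(spectra) %in% metas$sample_id))
  totals <- class_totals(spectra, scheme)
  metas <- metas[match(rownames(spectra), metas$sample_id), ]
  genos <- unique(metas$genotype)
  res <- lapply(genos, function(g) {
    sel <- metas$genotype == g
    if (sum(sel) < 3L || length(unique(metas$dose_gy[sel])) < 2L)
      stop("genotype ", g,
           " needs >= 3 samples spanning >= 2 doses for the screen")
    d <- metas$dose_gy[sel]
    row <- list(genotype = g)
    n_sig <- 0L
    for (cl in colnames(totals)) {
      y <- totals[sel, cl]
      if (stats::sd(y) == 0 || stats::sd(d) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(d, y, method = "pearson",
                              alternative = "two.sided")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      row[[paste0("r_", cl)]] <- r
      row[[paste0("p_", cl)]] <- p
      if (!is.na(r) && r > 0 && !is.na(p) && p < alpha) n_sig <- n_sig + 1L
    }
    row$n_significant <- n_sig
    row$passes <- n_sig >= 2L
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("dose_screen", "data.frame")
  out
}

#' Write a screen/rate table as TSV
#' @param df A data frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
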