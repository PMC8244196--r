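# Empirical-Bayes moderated two-group t. Gene-wise pooled variances are
# shrunk towards a common prior estimated by method of moments on the log
# sample variances (log s^2 of a scaled chi^2 has known digamma/trigamma
# moments). With prior df d0 = 0 this reduces exactly to the ordinary
# pooled-variance t; d0 = Inf uses the prior variance alone.

trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

# Method-of-moments fit of (d0, s0^2) from gene-wise variances s2 on d df.
# Returns list(d0, s02) or NULL when estimation fails.
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2 || d <= 0) return(NULL)
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  if (!is.finite(emean) || !is.finite(evar)) return(NULL)
  rhs <- evar - trigamma(d / 2)
  if (rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  if (!is.finite(s02) || s02 <= 0) return(NULL)
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group differential expression
#'
#' For every gene computes the log2 fold change (treatment minus control
#' mean), a moderated t-statistic with empirical-Bayes variance shrinkage,
#' a two-sided p-value on `d + d0` degrees of freedom, and Benjamini-
#' Hochberg adjusted FDR over all tested genes. When the prior cannot be
#' estimated (e.g. all variances zero) the ordinary pooled-variance t is
#' used instead.
#'
#' @param m A log2-scale `expr_matrix` with >= 2 samples per group.
#' @param d0 Optional override of the prior degrees of freedom; `d0 = 0`
#'   forces the ordinary pooled t, `Inf` full shrinkage to the prior.
#' @return Data frame with columns `gene`, `log2fc`, `t_stat`, `p_value`,
#'   `fdr`, one row per gene, in input row order. The fitted prior is
#'   attached as attributes `d0` and `s02`.
#' @export
differential_expression <- function(m, d0 = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("differential_expression expects log2 scale")
  ctrl <- m$values[, m$sheet$sample_id[m$sheet$group == "control"], drop = FALSE]
  trt <- m$values[, m$sheet$sample_id[m$sheet$group == "treatment"], drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(trt)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  d <- n1 + n2 - 2
  lfc <- rowMeans(trt) - rowMeans(ctrl)
  ss1 <- apply(ctrl, 1, stats::var)
  ss2 <- apply(trt, 1, stats::var)
  s2 <- ((n1 - 1) * ss1 + (n2 - 1) * ss2) / d
  if (all(s2 == 0) && all(lfc == 0)) {
    warning("all genes constant; all p-values are 1")
  }

  if (is.null(d0)) {
    prior <- fit_variance_prior(s2, d)
    if (is.null(prior)) {
      d0 <- 0
      s02 <- NA_real_
    } else {
      d0 <- prior$d0
      s02 <- prior$s02
    }
  } else {
    s02 <- if (d0 > 0) {
      pr <- fit_variance_prior(s2, d)
      if (is.null(pr)) stop("cannot estimate prior variance for d0 > 0")
      pr$s02
    } else NA_real_
  }

  s2_post <- if (d0 == 0) s2 else if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- d + d0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tt)) else
    2 * stats::pt(-abs(tt), df = df_total)
  p[se == 0 & lfc == 0] <- 1
  p <- pmin(p, 1)
  res <- data.frame(gene = toupper(rownames(m$values)), log2fc = lfc,
                    t_stat = tt, p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  res
}

#' Binarize differential-expression results into indicator vectors
#'
#' A gene is flagged 1 in the `all` variant when it passes both the linear
#' fold-change cutoff (`|log2fc| >= log2(fc_cutoff)`) and the FDR cutoff
#' (`fdr < fdr_cutoff`); the `up` and `down` variants additionally require
#' a positive or negative log2 fold change.
#'
#' @param de Data frame from [differential_expression()].
#' @param fc_cutoff Linear fold-change cutoff, > 1 (default 2).
#' @param fdr_cutoff FDR cutoff in (0, 1) (default 5e-3; the alternative
#'   preset used for noisier datasets is 1e-2).
#' @return An object of class `indicator_set`: list with named 0/1 vectors
#'   `all`, `up`, `down` plus the cutoffs used.
#' @export
binarize <- function(de, fc_cutoff = 2, fdr_cutoff = 5e-3) {
  stopifnot(fc_cutoff > 1, fdr_cutoff > 0, fdr_cutoff < 1)
  hit <- abs(de$log2fc) >= log2(fc_cutoff) & de$fdr < fdr_cutoff
  mk <- function(sel) stats::setNames(as.integer(sel), de$gene)
  structure(list(all = mk(hit),
                 up = mk(hit & de$log2fc > 0),
                 down = mk(hit & de$log2fc < 0),
                 fc_cutoff = fc_cutoff, fdr_cutoff = fdr_cutoff),
            class = "indicator_set")
}

#' @export
print.indicator_set <- function(x, ...) {
  cat(sprintf("indicator_set: %d genes, all=%d up=%d down=%d (FC>=%g, FDR<%g)\n",
              length(x$all), sum(x$all), sum(x$up), sum(x$down),
              x$fc_cutoff, x$fdr_cutoff))
  invisible(x)
}
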