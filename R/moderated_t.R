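#' Expression study container
#'
#' Log-scale gene-by-sample matrix with per-sample annotations. Each cell
#' line contributes two timepoint samples (0 h and 48 h) which behave as
#' biological replicates; phenotypes are `"strong"`, `"weak"` or
#' `"test"` (held out from signature discovery).
#'
#' @param expr Numeric matrix, genes as rows (rownames), samples as
#'   columns (colnames).
#' @param annotation data.frame with columns `sample`, `cell_line`,
#'   `phenotype`, `timepoint`; `sample` must match `colnames(expr)`.
#' @return An `expression_study` object.
#' @export
expression_study <- function(expr, annotation) {
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expr needs gene rownames and sample colnames", call. = FALSE)
  req <- c("sample", "cell_line", "phenotype", "timepoint")
  miss <- setdiff(req, names(annotation))
  if (length(miss))
    stop("annotation missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  annotation <- annotation[match(colnames(expr), annotation$sample), ]
  if (any(is.na(annotation$sample)))
    stop("every expr column needs an annotation row", call. = FALSE)
  bad <- setdiff(unique(annotation$phenotype), c("strong", "weak", "test"))
  if (length(bad))
    stop("unknown phenotype(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (ph in c("strong", "weak")) {
    nl <- length(unique(annotation$cell_line[annotation$phenotype == ph]))
    if (nl < 2)
      stop("need >= 2 cell lines with phenotype '", ph, "'", call. = FALSE)
  }
  structure(list(expr = expr, annotation = annotation),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  ph <- table(x$annotation$phenotype)
  cat(sprintf("<expression_study> %d genes x %d samples (%s)\n",
              nrow(x$expr), ncol(x$expr),
              paste(names(ph), ph, sep = ":", collapse = ", ")))
  invisible(x)
}

# Moment-matching estimate of the inverse-chi-square prior (d0, s0^2)
# from observed log-variances; d_g may vary per gene.
.fit_variance_prior <- function(s2, dg) {
  G <- length(s2)
  # work on the log scale; zero variances get a tiny floor only for the
  # hyperparameter fit (the shrinkage itself handles them exactly)
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(dg / 2) + log(dg / 2)
  ebar <- mean(e)
  rhs <- mean((e - ebar)^2 * G / (G - 1) - trigamma(dg / 2))
  if (!is.finite(rhs) || rhs <= 0) {
    return(list(d0 = Inf, s02 = exp(ebar)))
  }
  # trigamma(d0/2) = rhs, trigamma is monotone decreasing: bisection
  lo <- 1e-8; hi <- 1e8
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > rhs) lo <- mid else hi <- mid
  }
  d0 <- 2 * sqrt(lo * hi)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated t-test
#'
#' Two-group comparison with gene-wise variances shrunk toward a common
#' prior, the method of choice for very small sample sizes. Per gene, the
#' pooled two-group variance \eqn{s^2_g} (on \eqn{d_g = n_a + n_b - 2}
#' df) is combined with a scaled inverse-chi-square prior
#' \eqn{(d_0, s_0^2)} fitted by moment matching on the log-variances:
#' \deqn{\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g) / (d_0 + d_g)}
#' and the moderated statistic \eqn{\tilde t_g = \hat\beta_g / (\tilde
#' s_g \sqrt{1/n_a + 1/n_b})} is referred to a Student t distribution on
#' \eqn{d_0 + d_g} df. When the observed log-variances show no excess
#' spread the prior df is infinite and \eqn{\tilde s^2_g = s_0^2}.
#'
#' @param study An [expression_study()] (or plain matrix with `groups`).
#' @param group_a,group_b Phenotype labels (default strong vs weak) or,
#'   for a matrix input, logical/character vectors selecting columns.
#' @param use_samples Optional character vector restricting the samples
#'   considered (used by the LOOCV driver).
#' @return A data.frame (one row per gene): `gene`, `mean_a`, `mean_b`,
#'   `beta` (a - b), `s2`, `df_resid`, `s2_post`, `t`, `p`; attributes
#'   `d0` and `s02` carry the prior.
#' @export
moderated_t_test <- function(study, group_a = "strong", group_b = "weak",
                             use_samples = NULL) {
  if (inherits(study, "expression_study")) {
    ann <- study$annotation
    expr <- study$expr
    if (!is.null(use_samples)) {
      keep <- ann$sample %in% use_samples
      ann <- ann[keep, ]
      expr <- expr[, ann$sample, drop = FALSE]
    }
    cols_a <- ann$sample[ann$phenotype == group_a]
    cols_b <- ann$sample[ann$phenotype == group_b]
  } else {
    expr <- study
    cols_a <- group_a
    cols_b <- group_b
  }
  na <- length(cols_a); nb <- length(cols_b)
  if (na < 2 || nb < 2)
    stop("each group needs at least 2 samples (got ", na, " and ", nb,
         ")", call. = FALSE)
  if (nrow(expr) < 30)
    warning("fewer than 30 genes; hyperparameter estimation is unstable")
  A <- expr[, cols_a, drop = FALSE]
  B <- expr[, cols_b, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  dg <- na + nb - 2
  s2 <- (rowSums((A - ma)^2) + rowSums((B - mb)^2)) / dg
  pri <- .fit_variance_prior(s2, rep(dg, length(s2)))
  s2_post <- if (is.infinite(pri$d0)) rep(pri$s02, length(s2)) else
    (pri$d0 * pri$s02 + dg * s2) / (pri$d0 + dg)
  beta <- ma - mb
  tstat <- beta / sqrt(s2_post * (1 / na + 1 / nb))
  df_total <- pri$d0 + dg
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  out <- data.frame(gene = rownames(expr), mean_a = ma, mean_b = mb,
                    beta = beta, s2 = s2, df_resid = dg,
                    s2_post = s2_post, t = tstat, p = p,
                    row.names = NULL)
  attr(out, "d0") <- pri$d0
  attr(out, "s02") <- pri$s02
  attr(out, "df_total") <- df_total
  out
}

#' Benjamini-Hochberg adjusted replicate check
#'
#' Tests whether the two timepoints of each cell line differ, the
#' justification for pooling 0 h and 48 h samples as biological
#' replicates. Returns the per-gene moderated test between timepoints
#' with BH-adjusted p-values.
#'
#' @param study An [expression_study()].
#' @return Data.frame as [moderated_t_test()] plus `p_bh`.
#' @export
timepoint_replicate_check <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  ann <- study$annotation
  tps <- sort(unique(ann$timepoint))
  if (length(tps) != 2)
    stop("replicate check expects exactly 2 timepoints", call. = FALSE)
  res <- moderated_t_test(study$expr,
                          ann$sample[ann$timepoint == tps[1]],
                          ann$sample[ann$timepoint == tps[2]])
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Collapse probe-set rows to gene level
#'
#' Keeps, per gene, the probe set with the highest mean expression.
#'
#' @param expr Matrix with probe-set rownames.
#' @param probe_to_gene Named character vector mapping probe set -> gene.
#' @return Gene-level matrix.
#' @export
collapse_probes <- function(expr, probe_to_gene) {
  genes <- probe_to_gene[rownames(expr)]
  if (any(is.na(genes)))
    stop("unmapped probe sets: ",
         paste(utils::head(rownames(expr)[is.na(genes)], 5),
               collapse = ", "), call. = FALSE)
  means <- rowMeans(expr)
  ord <- order(genes, -means)
  keep <- ord[!duplicated(genes[ord])]
  out <- expr[keep, , drop = FALSE]
  rownames(out) <- genes[keep]
  out[order(rownames(out)), , drop = FALSE]
}
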