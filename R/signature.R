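#' Leave-one-cell-line-out discriminative gene lists
#'
#' For each labeled (strong/weak) cell line, both of its timepoint
#' samples are held out and the moderated t-test is run on the remaining
#' strong-vs-weak samples; the `top_k` genes by ascending p-value form
#' that fold's candidate list. Samples with phenotype `"test"` never
#' enter any fold. Ties in p are broken by larger |t|, then gene name.
#'
#' @param study An [expression_study()].
#' @param top_k List length per fold (default 100).
#' @return A list of fold results, one per labeled cell line: each a list
#'   with `excluded`, `genes` (length `top_k`), `stats` and `retained`
#'   (`NA` until [validate_fold_by_clustering()]).
#' @export
loocv_discriminative_lists <- function(study, top_k = 100) {
  stopifnot(inherits(study, "expression_study"))
  if (top_k > nrow(study$expr))
    stop("top_k exceeds the number of genes", call. = FALSE)
  ann <- study$annotation
  labeled <- ann[ann$phenotype %in% c("strong", "weak"), ]
  lines <- unique(labeled$cell_line)
  lapply(lines, function(cl) {
    keep <- labeled$sample[labeled$cell_line != cl]
    kept_ann <- labeled[labeled$cell_line != cl, ]
    for (ph in c("strong", "weak")) {
      if (length(unique(kept_ann$cell_line[kept_ann$phenotype == ph])) < 2)
        stop("excluding '", cl, "' leaves < 2 cell lines in phenotype '",
             ph, "'", call. = FALSE)
    }
    st <- moderated_t_test(study, use_samples = keep)
    ord <- order(st$p, -abs(st$t), st$gene)
    list(excluded = cl, genes = st$gene[ord[seq_len(top_k)]],
         stats = st[ord, ], retained = NA)
  })
}

# Pearson-distance + Ward hierarchical clustering of sample columns,
# cut into two groups. Constant columns are dropped with a warning.
.cluster_two <- function(mat, ward = c("ward.D2", "ward.D")) {
  ward <- match.arg(ward)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant sample column(s): ",
            paste(colnames(mat)[sds == 0], collapse = ", "))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  d <- stats::as.dist(1 - stats::cor(mat))
  hc <- stats::hclust(d, method = ward)
  stats::cutree(hc, k = 2)
}

#' Validate a LOOCV fold by clustering the excluded line
#'
#' Restricts the expression matrix to the fold's gene list and all
#' strong/weak samples (including the excluded line), clusters samples by
#' Pearson distance (1 - correlation) with Ward linkage cut at two
#' groups, and retains the fold only when both excluded-line samples land
#' in the cluster whose majority phenotype matches theirs.
#'
#' @param study An [expression_study()].
#' @param fold One element of [loocv_discriminative_lists()] output.
#' @param ward Ward recurrence dialect: `"ward.D2"` (squared-update,
#'   default) or `"ward.D"`.
#' @return The fold with `retained` set.
#' @export
validate_fold_by_clustering <- function(study, fold,
                                        ward = c("ward.D2", "ward.D")) {
  stopifnot(inherits(study, "expression_study"))
  ann <- study$annotation
  lab <- ann[ann$phenotype %in% c("strong", "weak"), ]
  mat <- study$expr[fold$genes, lab$sample, drop = FALSE]
  cl <- .cluster_two(mat, ward = match.arg(ward))
  lab <- lab[lab$sample %in% names(cl), ]
  excl <- lab$sample[lab$cell_line == fold$excluded]
  ok <- vapply(excl, function(s) {
    members <- names(cl)[cl == cl[s]]
    others <- setdiff(members, lab$sample[lab$cell_line == fold$excluded])
    if (!length(others)) return(FALSE)
    ph <- lab$phenotype[match(others, lab$sample)]
    maj <- names(sort(table(ph), decreasing = TRUE))[1]
    maj == lab$phenotype[match(s, lab$sample)]
  }, TRUE)
  fold$retained <- length(ok) > 0 && all(ok)
  fold
}

#' Intersect retained fold lists into the final signature
#'
#' Set intersection over the gene lists of all retained folds, ordered by
#' each gene's best (minimum) p-value across folds. The result is
#' invariant to fold order.
#'
#' @param folds Output of [loocv_discriminative_lists()] after
#'   validation; folds with `retained = FALSE` are skipped (folds with
#'   `retained = NA` count as retained, so unvalidated runs intersect
#'   everything).
#' @return Character vector of signature genes (possibly empty);
#'   attribute `"best_p"` carries the ordering p-values.
#' @export
intersect_lists <- function(folds) {
  use <- Filter(function(f) !isFALSE(f$retained), folds)
  if (!length(use))
    stop("no retained folds; nothing to intersect", call. = FALSE)
  genes <- Reduce(intersect, lapply(use, `[[`, "genes"))
  if (!length(genes)) return(character(0))
  best_p <- vapply(genes, function(g) {
    min(vapply(use, function(f) f$stats$p[match(g, f$stats$gene)], 0.0))
  }, 0.0)
  ord <- order(best_p, genes)
  out <- genes[ord]
  attr(out, "best_p") <- unname(best_p[ord])
  out
}

#' Classify a sample or cell line from a gene signature
#'
#' Default mode mirrors the discovery procedure: the query sample(s) are
#' co-clustered with all labeled strong/weak samples on the signature
#' genes (Pearson distance, Ward linkage, two clusters) and assigned the
#' majority phenotype of the joined cluster. The alternative
#' `"centroid"` mode assigns the phenotype whose mean profile correlates
#' best with the query; exact ties give `"unclassified"`.
#'
#' @param study An [expression_study()] containing both the labeled
#'   samples and the query.
#' @param signature Character vector of signature genes; at least 80\%
#'   must be present in the matrix.
#' @param query Sample name(s) or a cell-line label present in the
#'   annotation.
#' @param mode `"cocluster"` (default) or `"centroid"`.
#' @return Character phenotype: `"strong"`, `"weak"` or `"unclassified"`.
#' @export
classify_sample <- function(study, signature, query,
                            mode = c("cocluster", "centroid")) {
  stopifnot(inherits(study, "expression_study"))
  mode <- match.arg(mode)
  present <- intersect(signature, rownames(study$expr))
  if (length(present) < 0.8 * length(signature))
    stop(sprintf("only %d/%d signature genes present (< 80%%)",
                 length(present), length(signature)), call. = FALSE)
  ann <- study$annotation
  qs <- if (all(query %in% ann$sample)) query else
    ann$sample[ann$cell_line %in% query]
  if (!length(qs)) stop("query not found in study", call. = FALSE)
  lab <- ann[ann$phenotype %in% c("strong", "weak") &
               !ann$sample %in% qs, ]

  if (mode == "centroid") {
    cs <- rowMeans(study$expr[present,
                              lab$sample[lab$phenotype == "strong"],
                              drop = FALSE])
    cw <- rowMeans(study$expr[present,
                              lab$sample[lab$phenotype == "weak"],
                              drop = FALSE])
    q <- rowMeans(study$expr[present, qs, drop = FALSE])
    rs <- stats::cor(q, cs); rw <- stats::cor(q, cw)
    if (isTRUE(all.equal(rs, rw))) return("unclassified")
    return(if (rs > rw) "strong" else "weak")
  }

  mat <- study$expr[present, c(lab$sample, qs), drop = FALSE]
  cl <- .cluster_two(mat)
  votes <- vapply(qs, function(s) {
    others <- setdiff(names(cl)[cl == cl[s]], qs)
    if (!length(others)) return("unclassified")
    ph <- lab$phenotype[match(others, lab$sample)]
    tab <- sort(table(ph), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) "unclassified" else
      names(tab)[1]
  }, "")
  votes <- votes[votes != "unclassified"]
  if (!length(votes)) return("unclassified")
  tab <- sort(table(votes), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) "unclassified" else
    names(tab)[1]
}

#' Exact binomial tail test of classification success
#'
#' Probability of observing at least `correct` successes in `total`
#' independent classifications at chance level `chance_p`; e.g. 7 of 8
#' at chance 0.5 gives 9/256 = 0.03516.
#'
#' @param correct Number of correctly classified cases.
#' @param total Number of cases.
#' @param chance_p Per-case chance success probability in (0, 1).
#' @return One-sided upper-tail p-value.
#' @export
#' @examples
#' binomial_classification_test(7, 8) # 0.03516
binomial_classification_test <- function(correct, total, chance_p = 0.5) {
  if (chance_p <= 0 || chance_p >= 1)
    stop("chance_p must lie strictly inside (0, 1)", call. = FALSE)
  if (correct < 0 || correct > total)
    stop("need 0 <= correct <= total", call. = FALSE)
  if (chance_p == 0.5 && total <= 1000) {
    # dyadic case in exact arithmetic: sum of C(n, k) / 2^n
    return(sum(choose(total, correct:total)) / 2^total)
  }
  sum(stats::dbinom(correct:total, size = total, prob = chance_p))
}
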