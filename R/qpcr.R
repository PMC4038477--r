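#' qPCR cycle-threshold table
#'
#' Container for raw CT values from SYBR-green quantitative real-time
#' PCR, together with the housekeeping reference gene and the calibrator
#' sample used for relative quantification.
#'
#' @param data A data.frame with columns `sample`, `timepoint`, `gene`,
#'   `ct` (finite numeric cycle thresholds).
#' @param reference_gene Housekeeping gene (default `"GAPDH"`), which must
#'   be measured for every (sample, timepoint).
#' @param calibrator_sample Sample id of the control cell line.
#' @param calibrator_timepoint Timepoint of the calibrator measurement;
#'   defaults to the calibrator sample's earliest timepoint (time 0).
#' @return A `ct_table` object.
#' @export
ct_table <- function(data, reference_gene = "GAPDH", calibrator_sample,
                     calibrator_timepoint = NULL) {
  req <- c("sample", "timepoint", "gene", "ct")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("ct data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(data$ct)))
    stop("all CT values must be finite", call. = FALSE)
  if (!reference_gene %in% data$gene)
    stop("reference gene '", reference_gene, "' not present", call. = FALSE)
  if (!calibrator_sample %in% data$sample)
    stop("calibrator sample '", calibrator_sample, "' not present",
         call. = FALSE)
  if (is.null(calibrator_timepoint))
    calibrator_timepoint <-
      min(data$timepoint[data$sample == calibrator_sample])
  structure(list(data = data, reference_gene = reference_gene,
                 calibrator_sample = calibrator_sample,
                 calibrator_timepoint = calibrator_timepoint),
            class = "ct_table")
}

#' Relative expression by the 2^(-ddCT) method
#'
#' Normalizes each gene's CT to the reference gene within the same
#' (sample, timepoint) (dCT), calibrates against the control sample's
#' time-0 dCT for that gene (ddCT), and reports `2^(-ddCT)`.
#'
#' @param ct A [ct_table()].
#' @return A data.frame with columns `sample`, `timepoint`, `gene`,
#'   `dct`, `ddct`, `rel_expr`.
#' @export
#' @examples
#' d <- data.frame(sample = c("ctrl", "ctrl", "ras", "ras"),
#'                 timepoint = 0, gene = c("GAPDH", "PER2", "GAPDH", "PER2"),
#'                 ct = c(20, 24, 20, 25))
#' ddct_quantify(ct_table(d, calibrator_sample = "ctrl"))
ddct_quantify <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  d <- ct$data
  key <- interaction(d$sample, d$timepoint, drop = TRUE)
  ref <- d$gene == ct$reference_gene
  ref_ct <- tapply(d$ct[ref], key[ref], function(x) x[1])
  missing_ref <- setdiff(levels(key), names(ref_ct)[!is.na(ref_ct)])
  if (length(missing_ref))
    stop("reference gene '", ct$reference_gene,
         "' missing for: ", paste(missing_ref, collapse = ", "),
         call. = FALSE)
  out <- d[!ref, c("sample", "timepoint", "gene"), drop = FALSE]
  out$dct <- d$ct[!ref] - as.numeric(ref_ct[as.character(key[!ref])])
  cal <- out$sample == ct$calibrator_sample &
    out$timepoint == ct$calibrator_timepoint
  cal_dct <- stats::setNames(out$dct[cal], out$gene[cal])
  no_cal <- setdiff(unique(out$gene), names(cal_dct))
  if (length(no_cal))
    stop("no calibrator measurement for gene(s): ",
         paste(no_cal, collapse = ", "), call. = FALSE)
  out$ddct <- out$dct - as.numeric(cal_dct[out$gene])
  out$rel_expr <- 2^(-out$ddct)
  rownames(out) <- NULL
  out
}

#' Expression relative to a reference gene
#'
#' Divides each gene's level by the level of a reference gene within the
#' same sample, e.g. clock-gene mRNA levels plotted relative to Bmal1.
#'
#' @param expr Numeric matrix, genes as rows (rownames required), samples
#'   as columns.
#' @param reference_gene Row to normalize by (default `"BMAL1"`).
#' @return A matrix of fold changes; the reference row is all ones.
#' @export
relative_to_reference_gene <- function(expr, reference_gene = "BMAL1") {
  if (is.null(rownames(expr)))
    stop("expr must have gene rownames", call. = FALSE)
  if (!reference_gene %in% rownames(expr))
    stop("reference gene '", reference_gene, "' not in matrix",
         call. = FALSE)
  ref <- expr[reference_gene, ]
  if (any(ref == 0)) {
    bad <- colnames(expr)[ref == 0]
    stop("reference gene has value 0 in sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(expr, 2, ref, "/")
}
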