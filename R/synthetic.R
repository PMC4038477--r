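#' Generate a synthetic luciferase trace
#'
#' Emulates a bioluminescence recording: a damped cosine riding on an
#' exponentially decaying baseline (luciferin consumption) with
#' multiplicative-baseline Gaussian noise,
#' \deqn{y(t) = B_0 e^{-\beta t} (1 + A e^{-\lambda t} \cos(2\pi (t -
#' \phi)/\tau)) + \epsilon,\quad \epsilon \sim N(0, \sigma B_0
#' e^{-\beta t}).}
#' The `"strong"` preset mirrors a robust ~24 h oscillator; `"weak"`
#' forces low amplitude or heavy damping.
#'
#' @param tau_h,amplitude,phase_h,damping_per_h Oscillation parameters.
#' @param baseline,baseline_decay Baseline level B0 and decay rate
#'   (per h).
#' @param noise_sd Relative noise SD sigma (>= 0).
#' @param duration_h,sampling_per_h Record length and sampling rate
#'   (LumiCycle convention: 6 counts/h).
#' @param mode `"strong"` or `"weak"`; weak mode caps amplitude at 0.1
#'   unless damping >= 0.05/h already makes it weak.
#' @param seed Integer seed.
#' @param cell_line Label stored in the trace metadata.
#' @return A [lumi_trace()]; attribute `"truth"` stores every parameter.
#' @export
gen_luminescence <- function(tau_h = 24, amplitude = 0.4, phase_h = 16,
                             damping_per_h = 0.01, baseline = 1000,
                             baseline_decay = 0.01, noise_sd = 0.05,
                             duration_h = 120, sampling_per_h = 6,
                             mode = c("strong", "weak"), seed = 1,
                             cell_line = NA_character_) {
  mode <- match.arg(mode)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (tau_h <= 0) stop("tau_h must be positive", call. = FALSE)
  if (mode == "weak" && damping_per_h < 0.05)
    amplitude <- min(amplitude, 0.1)
  set.seed(seed)
  t <- seq(0, duration_h, by = 1 / sampling_per_h)
  base <- baseline * exp(-baseline_decay * t)
  y <- base * (1 + amplitude * exp(-damping_per_h * t) *
                 cos(2 * pi * (t - phase_h) / tau_h)) +
    stats::rnorm(length(t), 0, noise_sd * base)
  tr <- lumi_trace(t, pmax(y, .Machine$double.eps), cell_line = cell_line)
  attr(tr, "truth") <- list(tau_h = tau_h, amplitude = amplitude,
                            phase_h = phase_h,
                            damping_per_h = damping_per_h,
                            baseline = baseline,
                            baseline_decay = baseline_decay,
                            noise_sd = noise_sd, mode = mode, seed = seed)
  tr
}

#' Generate a synthetic two-phenotype expression study
#'
#' Emulates the cell-line microarray design: `lines_per_phenotype`
#' strong and weak cell lines, two timepoint samples each (replicates
#' sharing a line-level random effect), gene variances drawn from a
#' scaled inverse-chi-square prior `s0^2 * d0 / chisq(d0)`, and
#' `planted` discriminative genes whose phenotype means differ by
#' `effect_sd` gene-level standard deviations. The `"paper2014"` design
#' preset uses the 2 strong + 4 weak split.
#'
#' @param n_genes Number of genes G.
#' @param lines_per_phenotype Cell lines per phenotype (default 3);
#'   ignored when `design = "paper2014"`.
#' @param planted Number of true discriminative genes.
#' @param effect_sd Effect size delta in units of each gene's SD.
#' @param d0,s02 Variance-prior hyperparameters.
#' @param line_sd Line-level random-effect SD.
#' @param n_test_lines Extra held-out lines drawn from the strong
#'   generator with phenotype label `"test"`.
#' @param design `"balanced"` or `"paper2014"` (2 strong + 4 weak).
#' @param seed Integer seed.
#' @return An [expression_study()]; attribute `"truth"` holds the
#'   planted gene names, per-gene SDs and all parameters.
#' @export
gen_expression <- function(n_genes = 5000, lines_per_phenotype = 3,
                           planted = 30, effect_sd = 2.0, d0 = 4,
                           s02 = 0.04, line_sd = 0.1, n_test_lines = 0,
                           design = c("balanced", "paper2014"),
                           seed = 1) {
  design <- match.arg(design)
  if (planted >= n_genes)
    stop("planted must be smaller than n_genes", call. = FALSE)
  if (effect_sd < 0) stop("effect_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  ns <- if (design == "paper2014") 2L else lines_per_phenotype
  nw <- if (design == "paper2014") 4L else lines_per_phenotype
  genes <- sprintf("G%05d", seq_len(n_genes))
  s2 <- s02 * d0 / stats::rchisq(n_genes, df = d0)
  sg <- sqrt(s2)
  planted_genes <- genes[seq_len(planted)]
  mu0 <- stats::rnorm(n_genes, 7, 1)    # log2-scale baseline

  lines <- c(sprintf("S%d", seq_len(ns)), sprintf("W%d", seq_len(nw)),
             if (n_test_lines) sprintf("T%d", seq_len(n_test_lines)))
  pheno <- c(rep("strong", ns), rep("weak", nw),
             rep("test", n_test_lines))
  samples <- as.vector(t(outer(lines, c("_t0", "_t48"), paste0)))
  ann <- data.frame(sample = samples,
                    cell_line = rep(lines, each = 2),
                    phenotype = rep(pheno, each = 2),
                    timepoint = rep(c(0, 48), length(lines)),
                    stringsAsFactors = FALSE)
  expr <- matrix(NA_real_, n_genes, length(samples),
                 dimnames = list(genes, samples))
  # phenotype mean shift of delta*s_g on each side of the grand mean
  shift <- ifelse(genes %in% planted_genes, effect_sd * sg, 0)
  for (i in seq_along(lines)) {
    up <- pheno[i] %in% c("strong", "test")  # test lines from the strong generator
    line_mu <- mu0 + (if (up) shift else -shift) +
      stats::rnorm(n_genes, 0, line_sd)
    for (tp in 1:2) {
      expr[, (i - 1) * 2 + tp] <- line_mu + stats::rnorm(n_genes, 0, sg)
    }
  }
  st <- expression_study(expr, ann)
  attr(st, "truth") <- list(planted = planted_genes, gene_sd = sg,
                            effect_sd = effect_sd, d0 = d0, s02 = s02,
                            line_sd = line_sd, design = design,
                            seed = seed)
  st
}

#' Generate a citation-biased interaction network
#'
#' Random gene universe with log-normal PubMed citation counts and a
#' background edge probability proportional to the product of the
#' endpoints' normalized citations (well-studied genes accumulate more
#' reported interactions). Edges between the planted query and target
#' sets are `rho`-fold enriched.
#'
#' @param n_genes Universe size N (>= 100).
#' @param query_size,target_size Planted set sizes.
#' @param rho Enrichment factor (>= 1) for query-target edges.
#' @param mean_log_cite,sd_log_cite Citation log-normal parameters.
#' @param base_edge_p Baseline edge probability scale.
#' @param seed Integer seed.
#' @return List with `edges`, `citations` (named vector), `query`,
#'   `target`, and `truth` (expected background and excess counts).
#' @export
gen_network <- function(n_genes = 500, query_size = 45, target_size = 60,
                        rho = 1, mean_log_cite = 3, sd_log_cite = 1.5,
                        base_edge_p = 0.02, seed = 1) {
  if (n_genes < 100) stop("n_genes must be >= 100", call. = FALSE)
  if (rho < 1) stop("rho must be >= 1", call. = FALSE)
  set.seed(seed)
  genes <- sprintf("N%04d", seq_len(n_genes))
  cites <- round(exp(stats::rnorm(n_genes, mean_log_cite, sd_log_cite)))
  names(cites) <- genes
  w <- cites / mean(cites)
  # expected degree guard
  if (base_edge_p * mean(w)^2 * n_genes > n_genes / 2)
    stop("parameters imply expected degree > N/2", call. = FALSE)
  query <- sample(genes, query_size)
  target <- sample(setdiff(genes, query), target_size)
  ij <- utils::combn(n_genes, 2)
  p_edge <- pmin(base_edge_p * w[ij[1, ]] * w[ij[2, ]], 0.9)
  is_qt <- (genes[ij[1, ]] %in% query & genes[ij[2, ]] %in% target) |
    (genes[ij[1, ]] %in% target & genes[ij[2, ]] %in% query)
  p_edge <- pmin(ifelse(is_qt, rho * p_edge, p_edge), 0.95)
  draw <- stats::runif(ncol(ij)) < p_edge
  edges <- data.frame(src = genes[ij[1, draw]], dst = genes[ij[2, draw]],
                      type = "other", source = "textmine",
                      pubmed_ids = "", confidence = NA_real_,
                      stringsAsFactors = FALSE)
  list(edges = edges, citations = cites, query = query, target = target,
       truth = list(rho = rho, seed = seed,
                    expected_qt = sum(p_edge[is_qt]),
                    expected_qt_background = sum(p_edge[is_qt] / rho)))
}

#' Generate a synthetic qPCR CT table
#'
#' CT values for cosine-modulated target genes over a timepoint series
#' plus a flat reference gene, with Gaussian CT noise. A higher
#' expression halves CT per doubling, so modulation enters as
#' `-log2(1 + A cos(...))`.
#'
#' @param genes Character vector of target gene names.
#' @param timepoints Numeric hours (e.g. `seq(24, 45, by = 3)`).
#' @param tau_h,amplitude,phase_h Modulation parameters.
#' @param reference_gene Flat housekeeping gene name.
#' @param ct_ref Reference CT level.
#' @param noise_sd CT measurement noise SD.
#' @param sample_id Sample label.
#' @param seed Integer seed.
#' @return A [ct_table()]; attribute `"truth"` stores the parameters.
#' @export
gen_ct_table <- function(genes = c("PER2", "CRY1"),
                         timepoints = seq(24, 45, by = 3), tau_h = 24,
                         amplitude = 0.5, phase_h = 30,
                         reference_gene = "GAPDH", ct_ref = 20,
                         noise_sd = 0.05, sample_id = "ctrl", seed = 1) {
  if (reference_gene %in% genes)
    stop("reference gene cannot be a modulated target", call. = FALSE)
  if (amplitude < 0 || amplitude >= 1)
    stop("amplitude must be in [0, 1)", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (tp in timepoints) {
    rows[[length(rows) + 1]] <- data.frame(
      sample = sample_id, timepoint = tp, gene = reference_gene,
      ct = ct_ref + stats::rnorm(1, 0, noise_sd))
    for (g in genes) {
      mod <- 1 + amplitude * cos(2 * pi * (tp - phase_h) / tau_h)
      rows[[length(rows) + 1]] <- data.frame(
        sample = sample_id, timepoint = tp, gene = g,
        ct = ct_ref + 5 - log2(mod) + stats::rnorm(1, 0, noise_sd))
    }
  }
  ct <- ct_table(do.call(rbind, rows), reference_gene = reference_gene,
                 calibrator_sample = sample_id)
  attr(ct, "truth") <- list(tau_h = tau_h, amplitude = amplitude,
                            phase_h = phase_h, noise_sd = noise_sd,
                            seed = seed)
  ct
}
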