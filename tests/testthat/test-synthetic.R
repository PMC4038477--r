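test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_luminescence(seed = 4)
  b <- gen_luminescence(seed = 4)
  expect_identical(a$value, b$value)
  sa <- gen_expression(n_genes = 200, seed = 4)
  sb <- gen_expression(n_genes = 200, seed = 4)
  expect_identical(sa$expr, sb$expr)
  na <- gen_network(seed = 4)
  nb <- gen_network(seed = 4)
  expect_identical(na$edges, nb$edges)
  expect_identical(na$citations, nb$citations)
})

test_that("noiseless trace round-trips through detrend + fit to 1e-3", {
  tr <- gen_luminescence(tau_h = 23.5, amplitude = 0.45, phase_h = 12,
                         damping_per_h = 0.004, baseline = 1,
                         baseline_decay = 0, noise_sd = 0,
                         duration_h = 144, seed = 1)
  fit <- fit_damped_cosine(lumi_trace(tr$time_h, tr$value,
                                      detrended = TRUE))
  expect_lt(abs(fit$tau_h - 23.5) / 23.5, 1e-3)
  expect_lt(abs(fit$amplitude - 0.45) / 0.45, 1e-3)
})

test_that("strong and weak presets classify accordingly over 20 seeds", {
  for (s in 1:20) {
    strong <- gen_luminescence(mode = "strong", seed = s)
    weak <- gen_luminescence(mode = "weak", seed = s)
    cls <- function(tr) {
      dt <- detrend_running_average(tr)
      classify_oscillator(fit_damped_cosine(dt))$label
    }
    expect_equal(cls(strong), "strong", info = paste("seed", s))
    expect_equal(cls(weak), "weak", info = paste("seed", s))
  }
})

test_that("expression generator plants detectable signal and null p-values are uniform", {
  st0 <- gen_expression(n_genes = 2000, planted = 0, effect_sd = 0,
                        line_sd = 0, seed = 31)
  p <- moderated_t_test(st0)$p
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("within-line replicate correlation exceeds between-line correlation", {
  st <- gen_expression(n_genes = 1000, planted = 0, effect_sd = 0,
                       line_sd = 0.3, seed = 17)
  cm <- cor(st$expr)
  ann <- st$annotation
  same_line <- outer(ann$cell_line, ann$cell_line, "==") &
    upper.tri(cm)
  diff_line <- !outer(ann$cell_line, ann$cell_line, "==") & upper.tri(cm)
  expect_gt(mean(cm[same_line]), mean(cm[diff_line]))
})

test_that("gene variances follow the scaled inverse-chi-square prior", {
  st <- gen_expression(n_genes = 5000, planted = 0, effect_sd = 0,
                       d0 = 4, s02 = 0.04, line_sd = 0, seed = 23)
  truth_sd <- attr(st, "truth")$gene_sd
  qq <- qchisq(ppoints(5000), df = 4)
  emp <- sort(0.04 * 4 / truth_sd^2)
  expect_gt(cor(sort(qq), emp), 0.99)
})

test_that("network generator validates its parameters", {
  expect_error(gen_network(n_genes = 50), ">= 100")
  expect_error(gen_network(rho = 0.5), "rho")
  expect_error(gen_expression(n_genes = 100, planted = 100), "planted")
  expect_error(gen_luminescence(noise_sd = -1), "noise_sd")
})

test_that("CT generator round-trips modulation through ddCT within 1.5 h", {
  ct <- gen_ct_table(genes = "PER2", timepoints = seq(24, 75, by = 3),
                     tau_h = 24, amplitude = 0.5, phase_h = 30,
                     noise_sd = 0.02, seed = 6)
  rel <- ddct_quantify(ct)
  # fit the relative expression with a cosinor to find peak time
  fit <- fit_damped_cosine(lumi_trace(rel$timepoint, rel$rel_expr,
                                      detrended = TRUE),
                           fix_lambda = TRUE)
  peak <- fit$phase_h
  # wrap distance to the true phase 30 (mod 24 -> 6)
  dist <- min(abs(peak - 30 %% fit$tau_h), abs(peak - 30 + fit$tau_h),
              abs(peak - 30 %% fit$tau_h + fit$tau_h))
  expect_lt(min(abs(c(peak - 6, peak - 30, peak - 54))), 1.5)
})

test_that("zero modulation gives flat relative expression", {
  ct <- gen_ct_table(genes = "PER2", amplitude = 0, noise_sd = 0.01,
                     seed = 2)
  rel <- ddct_quantify(ct)
  expect_lt(max(abs(rel$rel_expr - 1)), 0.1)
  expect_error(gen_ct_table(genes = "GAPDH"), "reference gene")
})
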