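#' Gene-interaction edge list utilities
#'
#' Edges are held as a data.frame with columns `src`, `dst`, `type`
#' (activation/inhibition/other), `source` (textmine/string/both),
#' `pubmed_ids` (";"-separated) and `confidence`. Symbols are
#' uppercase-normalized and undirected duplicates are merged with
#' provenance union; self-loops are dropped.
#'
#' @param edges data.frame with at least `src` and `dst`; missing
#'   metadata columns are filled with defaults.
#' @return Normalized, merged edge data.frame.
#' @export
normalize_edges <- function(edges) {
  stopifnot(all(c("src", "dst") %in% names(edges)))
  e <- data.frame(
    src = normalize_symbols(edges$src),
    dst = normalize_symbols(edges$dst),
    type = if ("type" %in% names(edges)) as.character(edges$type) else
      "other",
    source = if ("source" %in% names(edges)) as.character(edges$source)
      else "textmine",
    pubmed_ids = if ("pubmed_ids" %in% names(edges))
      as.character(edges$pubmed_ids) else "",
    confidence = if ("confidence" %in% names(edges))
      as.numeric(edges$confidence) else NA_real_,
    stringsAsFactors = FALSE)
  e <- e[e$src != e$dst, , drop = FALSE]
  # canonical undirected orientation
  flip <- e$src > e$dst
  tmp <- e$src[flip]; e$src[flip] <- e$dst[flip]; e$dst[flip] <- tmp
  key <- paste(e$src, e$dst, sep = "\r")
  dup_keys <- unique(key[duplicated(key)])
  # fast path: unique edges pass through untouched
  uniq <- e[!key %in% dup_keys, , drop = FALSE]
  merged <- lapply(dup_keys, function(k) {
    sub <- e[key == k, , drop = FALSE]
    src_set <- unique(sub$source)
    pm <- unique(unlist(strsplit(sub$pubmed_ids, ";", fixed = TRUE)))
    pm <- pm[nzchar(pm)]
    data.frame(src = sub$src[1], dst = sub$dst[1],
               type = sub$type[which.max(sub$type != "other")],
               source = if (length(setdiff(src_set, "both")) > 1 ||
                            "both" %in% src_set) "both" else src_set,
               pubmed_ids = paste(sort(pm), collapse = ";"),
               confidence = suppressWarnings(max(sub$confidence,
                                                 na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- rbind(uniq, do.call(rbind, merged))
  out$confidence[!is.finite(out$confidence)] <- NA_real_
  out <- out[order(out$src, out$dst), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Cross-set edge count on an already-normalized edge table.
.count_cross <- function(e, a, b) {
  a <- setdiff(a, b)
  if (!length(b) || !length(a)) return(0L)
  sum((e$src %in% a & e$dst %in% b) | (e$src %in% b & e$dst %in% a))
}

#' Assemble a shelled interaction network
#'
#' Places nodes into three shells: the declared core set, a declared
#' first shell of known direct interactors, and an outer shell of any
#' remaining edge-list genes with at least one edge to the core. Edges
#' are restricted to placed nodes.
#'
#' @param edges Edge data.frame (see [normalize_edges()]).
#' @param core_set Character vector of core genes (non-empty).
#' @param first_shell Character vector of declared direct interactors.
#' @return An `interaction_network`: list with `nodes` (data.frame
#'   `gene`, `shell`), `edges`, and a `summary` of per-shell counts.
#' @export
assemble_network <- function(edges, core_set, first_shell = character(0)) {
  if (!length(core_set)) stop("core set must be non-empty", call. = FALSE)
  e <- normalize_edges(edges)
  core <- unique(normalize_symbols(core_set))
  first <- setdiff(unique(normalize_symbols(first_shell)), core)
  touch_core <- unique(c(e$dst[e$src %in% core], e$src[e$dst %in% core]))
  outer <- setdiff(touch_core, c(core, first))
  nodes <- data.frame(
    gene = c(core, first, outer),
    shell = rep(c("core", "first_shell", "outer_shell"),
                c(length(core), length(first), length(outer))),
    stringsAsFactors = FALSE)
  keep <- e$src %in% nodes$gene & e$dst %in% nodes$gene
  e <- e[keep, , drop = FALSE]
  structure(list(
    nodes = nodes, edges = e,
    summary = list(n_core = length(core), n_first = length(first),
                   n_outer = length(outer), n_nodes = nrow(nodes),
                   n_edges = nrow(e))),
    class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<interaction_network> %d nodes (%d core + %d first + %d outer), %d edges\n",
    s$n_nodes, s$n_core, s$n_first, s$n_outer, s$n_edges))
  invisible(x)
}

#' Count connections between two gene sets
#'
#' Number of edges with one endpoint in `set_a` and the other in
#' `set_b`; within-set edges never count. Symbols appearing in both sets
#' are kept on the `set_b` (target) side and removed from `set_a`, so a
#' shared gene's edges to the rest of `set_a` still count once.
#'
#' @param network An `interaction_network` or plain edge data.frame.
#' @param set_a,set_b Character gene sets.
#' @return Integer edge count.
#' @export
cross_set_connections <- function(network, set_a, set_b) {
  e <- if (inherits(network, "interaction_network")) network$edges else
    normalize_edges(network)
  a <- unique(normalize_symbols(set_a))
  b <- unique(normalize_symbols(set_b))
  a <- setdiff(a, b)  # common genes counted on the target side
  if (!length(b)) return(0L)
  univ <- unique(c(e$src, e$dst))
  if (!length(intersect(univ, a)) || !length(intersect(univ, b)))
    warning("a set has no overlap with the network; count is 0")
  .count_cross(e, a, b)
}

#' Citation-bin-matched random-set null for cross-set connectivity
#'
#' Tests whether a query set (e.g. the 45 discriminative genes) is more
#' connected to target sets (clock and cancer genes) than random gene
#' sets of equal size and comparable literature visibility. Genes are
#' binned by `floor(log2(citations + 1))`; each of `B` replicates
#' replaces every query gene with a uniform draw from its bin (excluding
#' query and target genes, without replacement within a replicate), and
#' the inter-set connection count is recorded.
#'
#' @param citations Named integer vector of PubMed citation counts for
#'   the gene universe.
#' @param query_set Query genes (all must have citation counts).
#' @param target_sets List (or single vector) of target gene sets.
#' @param edges Edge data.frame or `interaction_network`.
#' @param B Number of random sets (default 50).
#' @param seed Integer seed (required for reproducibility).
#' @param exclude_targets Exclude query/target genes from null draws
#'   (default TRUE).
#' @return A `null_distribution`: `observed`, `counts` (length B),
#'   `mean`, `sd`, `z`, `p_empirical` = (1 + #\{count >= observed\}) /
#'   (1 + B), `p_wilcoxon` (one-sided signed-rank), `seed`, `bins`.
#' @export
citation_bin_null <- function(citations, query_set, target_sets, edges,
                              B = 50, seed, exclude_targets = TRUE) {
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (is.null(names(citations)))
    stop("citations must be a named vector", call. = FALSE)
  names(citations) <- normalize_symbols(names(citations))
  if (!is.list(target_sets)) target_sets <- list(target_sets)
  target_sets <- lapply(target_sets, normalize_symbols)
  targets <- unique(unlist(target_sets))
  query <- unique(normalize_symbols(query_set))
  query <- setdiff(query, targets)  # common genes live on the target side
  missing_cite <- setdiff(query, names(citations))
  if (length(missing_cite))
    stop("no citation count for query gene(s): ",
         paste(missing_cite, collapse = ", "), call. = FALSE)
  universe <- names(citations)
  if (length(universe) < 10 * length(query))
    stop("citation universe must be >= 10 x query size", call. = FALSE)

  bin_of <- floor(log2(citations + 1))
  pool <- universe
  if (exclude_targets) pool <- setdiff(pool, c(query, targets))
  pool_bins <- split(pool, bin_of[pool])
  qbins <- bin_of[query]

  e <- if (inherits(edges, "interaction_network")) edges$edges else
    normalize_edges(edges)
  obs <- .count_cross(e, query, targets)

  set.seed(seed)
  counts <- vapply(seq_len(B), function(b) {
    taken <- character(0)
    repl <- vapply(seq_along(query), function(i) {
      bn <- qbins[i]
      cand <- setdiff(pool_bins[[as.character(bn)]], taken)
      # walk to the nearest non-empty bin if needed
      offset <- 1
      while (!length(cand)) {
        for (nb in c(bn - offset, bn + offset)) {
          cand <- setdiff(pool_bins[[as.character(nb)]], taken)
          if (length(cand)) break
        }
        offset <- offset + 1
        if (offset > 64) stop("citation bins exhausted", call. = FALSE)
      }
      if (offset > 1)
        warning("empty citation bin ", bn,
                "; fell back to a neighbouring bin")
      g <- cand[sample.int(length(cand), 1)]
      taken <<- c(taken, g)
      g
    }, "")
    .count_cross(e, repl, targets)
  }, 0L)

  mu <- mean(counts); sdv <- stats::sd(counts)
  structure(list(
    observed = obs, counts = counts, mean = mu, sd = sdv,
    z = if (sdv > 0) (obs - mu) / sdv else NA_real_,
    p_empirical = (1 + sum(counts >= obs)) / (1 + B),
    p_wilcoxon = wilcoxon_one_sample(counts, obs,
                                     alternative = "greater"),
    B = B, seed = seed,
    bins = sort(table(qbins))),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> observed %d vs %d nulls: mean %.1f, sd %.1f, z = %.2f\n  empirical p = %.4g, Wilcoxon p = %.4g\n",
    x$observed, x$B, x$mean, x$sd, x$z, x$p_empirical, x$p_wilcoxon))
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test against a reference value
#'
#' Signed-rank test of the null counts against the observed value; by
#' default one-sided with alternative "the observed value exceeds the
#' null location". Exact distribution for n <= 25 without ties or
#' zeros, otherwise a normal approximation with continuity and tie
#' correction.
#'
#' @param x Numeric sample (e.g. null counts).
#' @param mu Reference value (the observed count).
#' @param alternative `"greater"` (observed greater than the null
#'   location, i.e. the sample lies below `mu`), `"less"` or
#'   `"two.sided"`.
#' @return p-value.
#' @export
wilcoxon_one_sample <- function(x, mu,
                                alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) < 5) stop("need at least 5 values", call. = FALSE)
  d <- x - mu
  if (all(d == 0)) {
    warning("all differences are zero; p = 1")
    return(1)
  }
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  # W = sum of ranks of positive differences (x above mu)
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 12) {
    # exact enumeration over all sign assignments; midranks make this
    # valid under ties as well
    masks <- 0:(2^n - 1)
    Wd <- vapply(masks, function(m)
      sum(r[bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0]), 0.0)
    p <- switch(alternative,
                greater = mean(Wd <= W + 1e-9),
                less = mean(Wd >= W - 1e-9),
                two.sided = min(1, 2 * min(mean(Wd <= W + 1e-9),
                                           mean(Wd >= W - 1e-9))))
    return(p)
  }
  if (n <= 25 && !ties) {
    p <- switch(alternative,
      greater = stats::psignrank(W, n),                 # P(W <= w): x below mu
      less = stats::psignrank(W - 1, n, lower.tail = FALSE),
      two.sided = min(1, 2 * min(stats::psignrank(W, n),
                                 stats::psignrank(W - 1, n,
                                                  lower.tail = FALSE))))
    return(p)
  }
  mu_w <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  znum <- switch(alternative,
                 greater = W - mu_w + 0.5,
                 less = W - mu_w - 0.5,
                 two.sided = W - mu_w)
  z <- znum / sqrt(sigma2)
  switch(alternative,
         greater = stats::pnorm(z),
         less = stats::pnorm(z, lower.tail = FALSE),
         two.sided = 2 * stats::pnorm(-abs(z) +
                                        0.5 / sqrt(sigma2)))
}

#' Per-query-gene incidence to two target sets
#'
#' For each query gene, flags whether it has at least one network edge to
#' `set_a`, to `set_b`, and to both; reports the three tallies (e.g. 20
#' of 45 discriminative genes touching clock genes, 27 touching cancer
#' genes, 18 touching both).
#'
#' @param network `interaction_network` or edge data.frame.
#' @param query_set,set_a,set_b Character gene sets.
#' @return List with `counts` (named: `to_a`, `to_b`, `to_both`) and the
#'   per-gene logical `incidence` data.frame.
#' @export
overlap_summary <- function(network, query_set, set_a, set_b) {
  e <- if (inherits(network, "interaction_network")) network$edges else
    normalize_edges(network)
  q <- unique(normalize_symbols(query_set))
  a <- unique(normalize_symbols(set_a))
  b <- unique(normalize_symbols(set_b))
  touch <- function(g, s) {
    s <- setdiff(s, g)
    any((e$src == g & e$dst %in% s) | (e$dst == g & e$src %in% s))
  }
  inc <- data.frame(
    gene = q,
    to_a = vapply(q, touch, TRUE, s = a),
    to_b = vapply(q, touch, TRUE, s = b),
    stringsAsFactors = FALSE)
  inc$to_both <- inc$to_a & inc$to_b
  list(counts = c(to_a = sum(inc$to_a), to_b = sum(inc$to_b),
                  to_both = sum(inc$to_both)),
       incidence = inc)
}
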