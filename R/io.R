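#' Normalize gene symbols
#'
#' Uppercases symbols, strips surrounding whitespace, maps Greek suffixes
#' to Latin, and resolves known aliases (e.g. ARNTL -> BMAL1, NR1D1 ->
#' REV-ERBA) through the packaged alias table.
#'
#' @param x Character vector of gene symbols.
#' @return Normalized character vector.
#' @export
normalize_symbols <- function(x) {
  s <- toupper(trimws(as.character(x)))
  greek <- c("Α" = "A", "Β" = "B", "Γ" = "G",
             "Δ" = "D", "Ε" = "E",
             "α" = "A", "β" = "B", "γ" = "G",
             "δ" = "D", "ε" = "E")
  for (g in names(greek)) s <- gsub(g, greek[[g]], s, fixed = TRUE)
  al <- symbol_aliases()
  hit <- match(s, al$alias)
  s[!is.na(hit)] <- al$symbol[hit[!is.na(hit)]]
  s
}

#' Packaged symbol alias table
#'
#' @return data.frame with columns `alias`, `symbol`.
#' @export
symbol_aliases <- function() {
  utils::read.delim(system.file("extdata", "symbol_aliases.tsv",
                                package = "clocksig"),
                    stringsAsFactors = FALSE)
}

#' Read a delimited table against a schema
#'
#' Header-keyed reader: columns may appear in any order, required
#' columns must exist, and declared-numeric columns must parse, with the
#' offending rows named otherwise.
#'
#' @param path File path (tab-delimited by default).
#' @param schema Named character vector: column name -> `"numeric"` or
#'   `"character"`.
#' @param sep Field separator.
#' @return data.frame with typed columns.
#' @export
read_table_schema <- function(path, schema, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
      if (length(bad))
        stop("non-numeric value in column '", col, "' at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      df[[col]] <- v
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  df
}

#' Read and write luminescence traces
#'
#' Two-column delimited text (`time_h`, `value`) with a required header;
#' the writer adds provenance columns for the detrended/smoothed flags.
#'
#' @param path File path.
#' @return [lumi_trace()] for the reader.
#' @export
read_trace <- function(path) {
  df <- read_table_schema(path, c(time_h = "numeric", value = "numeric"))
  detr <- "detrended" %in% names(df) && isTRUE(as.logical(df$detrended[1]))
  smoo <- "smoothed" %in% names(df) && isTRUE(as.logical(df$smoothed[1]))
  cl <- if ("cell_line" %in% names(df)) df$cell_line[1] else NA_character_
  lumi_trace(df$time_h, df$value, cell_line = cl, detrended = detr,
             smoothed = smoo)
}

#' @rdname read_trace
#' @param trace A [lumi_trace()] to write.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_h = trace$time_h, value = trace$value,
                   detrended = trace$meta$detrended,
                   smoothed = trace$meta$smoothed,
                   cell_line = trace$meta$cell_line)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression study from matrix + annotation files
#'
#' @param expr_path Tab-delimited matrix, genes as rows (first column =
#'   gene ids), samples as columns.
#' @param ann_path Tab-delimited annotation (`sample`, `cell_line`,
#'   `phenotype`, `timepoint`).
#' @return An [expression_study()].
#' @export
read_expression_study <- function(expr_path, ann_path) {
  mat <- utils::read.delim(expr_path, row.names = 1, check.names = FALSE)
  ann <- read_table_schema(ann_path,
                           c(sample = "character",
                             cell_line = "character",
                             phenotype = "character",
                             timepoint = "numeric"))
  expression_study(as.matrix(mat), ann)
}

#' Read and write GMT gene-set files
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", l, call. = FALSE)
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors to write.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "clocksig", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a provenance-tagged edge list
#'
#' @param path Tab-delimited file with columns `src`, `dst` and optional
#'   `type`, `source`, `pubmed_ids`, `confidence`.
#' @return Normalized edge data.frame (see [normalize_edges()]).
#' @export
read_edge_list <- function(path) {
  df <- read_table_schema(path, c(src = "character", dst = "character"))
  normalize_edges(df)
}

#' Export a network as SIF
#'
#' @param network An `interaction_network`.
#' @param path Output path.
#' @export
write_sif <- function(network, path) {
  e <- network$edges
  writeLines(paste(e$src, e$type, e$dst, sep = "\t"), path)
  invisible(path)
}

#' Read a two-column citation-count table
#'
#' @param path Tab-delimited `gene`, `citations`.
#' @return Named integer vector.
#' @export
read_citations <- function(path) {
  df <- read_table_schema(path, c(gene = "character",
                                  citations = "numeric"))
  stats::setNames(as.integer(df$citations), normalize_symbols(df$gene))
}

#' Packaged gene-set catalog
#'
#' The gene sets anchoring the clock-cancer network analysis: the
#' 14-gene circadian core (Per1/2/3, Cry1/2, Bmal1/2, Rev-Erb alpha/beta,
#' Ror alpha/beta/gamma, Clock, Npas2), the curated clock-related and
#' colon-cancer-related lists, and the 45-gene strong/weak oscillator
#' discriminative signature.
#'
#' @return Named list of character vectors: `core_clock`,
#'   `clock_related`, `cancer_related`, `discriminative`.
#' @export
gene_set_catalog <- function() {
  read_gmt(system.file("extdata", "gene_sets.gmt", package = "clocksig"))
}
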