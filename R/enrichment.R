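#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions kept as attribute
#'   `"description"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop_("GMT line ", bad[1L], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Over-representation of a gene list in gene sets
#'
#' One-sided Fisher exact test of the query against each gene set, within
#' the given background, with Benjamini-Hochberg adjustment across sets.
#' The log-odds (LOD) column is the log10 odds ratio of the 2x2 table with
#' Haldane correction (0.5 added to every cell) when any cell is zero.
#'
#' @param genes character vector, the query; must lie within `background`.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param background character vector of all scoreable genes.
#' @return data.frame per set: `set`, `n_set` (members in background),
#'   `n_overlap`, `odds_ratio`, `lod`, `p`, `p_adjusted`; sorted by `p`.
#' @export
overrepresentation <- function(genes, gene_sets, background) {
  if (length(background) == 0L) stop_("empty background")
  background <- unique(background)
  genes <- unique(genes)
  outside <- setdiff(genes, background)
  if (length(outside)) {
    stop_("query gene(s) outside the background: ",
          paste(head(outside, 5L), collapse = ", "))
  }
  if (is.null(names(gene_sets))) names(gene_sets) <- paste0("set", seq_along(gene_sets))
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], background)
    a <- length(intersect(genes, set))
    b <- length(setdiff(genes, set))
    c_ <- length(setdiff(set, genes))
    d <- length(background) - a - b - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L),
                            alternative = "greater")$p.value
    or <- (a * d) / (b * c_)
    if (!is.finite(or) || a == 0 || b == 0 || c_ == 0 || d == 0) {
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    }
    data.frame(set = nm, n_set = length(set), n_overlap = a,
               odds_ratio = or, lod = log10(or), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p, "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
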