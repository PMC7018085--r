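#' Signed directed protein network
#'
#' A `signed_network` holds proteins (nodes) plus directed signed edges, each
#' edge carrying a tunable weight. Edge *sign* is fixed biology (+1 activation,
#' -1 inhibition); the *weight* is the fitted interaction strength. By default
#' a fitted weight is confined to the half-interval matching its sign
#' (`[0, 1]` for activating edges, `[-1, 0]` for inhibiting ones); see the
#' `free_sign` argument of [netmoa()].
#'
#' @param edges data.frame with columns `source`, `target`, `sign` and
#'   optionally `weight`. Signs must be +1/-1; missing weights default to 0.
#' @param nodes optional character vector of node names; defaults to the
#'   union of edge endpoints. Extra isolated nodes are allowed.
#' @return An object of class `signed_network`: a list with elements `nodes`
#'   (character) and `edges` (data.frame `source`, `target`, `sign`, `weight`).
#' @examples
#' net <- signed_network(data.frame(
#'   source = c("A", "B"), target = c("B", "C"), sign = c(1, -1)
#' ))
#' net
#' @export
signed_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges)) stop_("`edges` must be a data.frame")
  required <- c("source", "target", "sign")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols)) {
    stop_("`edges` is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.numeric(edges$sign)
  if (!all(edges$sign %in% c(-1, 1))) {
    stop_("edge signs must be +1 or -1")
  }
  if (is.null(edges$weight)) edges$weight <- 0
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight))) stop_("edge weights must be finite")
  if (any(abs(edges$weight) > 1 + 1e-12)) {
    stop_("edge weights must lie in [-1, 1]")
  }
  if (any(edges$source == edges$target)) {
    bad <- edges$source[edges$source == edges$target][1L]
    stop_("self-loop on node '", bad, "' is not allowed")
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    pair <- strsplit(dup, "\r", fixed = TRUE)[[1L]]
    stop_("duplicate edge ", pair[1L], " -> ", pair[2L])
  }
  nodes <- sort(unique(c(nodes, edges$source, edges$target)))
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges[, c("source", "target", "sign", "weight")]),
    class = "signed_network"
  )
}

#' @export
print.signed_network <- function(x, ...) {
  cat("Signed directed protein network\n")
  cat("  nodes:", length(x$nodes), "\n")
  cat("  edges:", nrow(x$edges),
      sprintf("(%d activating, %d inhibiting)\n",
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Number of nodes/edges of a signed network
#' @param network a [signed_network()]
#' @return integer count.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Replace edge weights
#'
#' @param network a [signed_network()]
#' @param weights numeric vector, one weight per edge row, in `[-1, 1]`.
#' @return the network with updated weights.
#' @export
set_weights <- function(network, weights) {
  stopifnot(inherits(network, "signed_network"))
  if (length(weights) != nrow(network$edges)) {
    stop_("`weights` must have one value per edge (",
          nrow(network$edges), ")")
  }
  if (any(!is.finite(weights))) stop_("weights must be finite")
  network$edges$weight <- as.numeric(weights)
  network
}

sign_token <- function(x, where = "") {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA_real_, length(x))
  out[x %in% c("+1", "1", "activation", "activates", "active", "+")] <- 1
  out[x %in% c("-1", "inhibition", "inhibits", "inactive", "-")] <- -1
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop_("unknown sign/state token '", x[bad], "'", where,
          " (row ", bad, ")")
  }
  out
}

#' Read a signed network from an edge-list file
#'
#' Accepts a headered TSV with columns `source`, `target`, `sign` and an
#' optional `weight` column, or the SIF dialect
#' `source<TAB>rel<TAB>target` with `rel` one of `activates`/`inhibits`.
#'
#' @param path file path.
#' @param format `"auto"` (sniff the header), `"tsv"` or `"sif"`.
#' @param undirected if `TRUE`, each input row is expanded to the two
#'   directed edges; signal otherwise flows source to target only.
#' @return a [signed_network()].
#' @seealso [write_network()]
#' @export
read_network <- function(path, format = c("auto", "tsv", "sif"),
                         undirected = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("network file not found: ", path)
  first <- readLines(path, n = 1L)
  if (format == "auto") {
    format <- if (grepl("^source\t", first)) "tsv" else "sif"
  }
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("source", "target", "sign")
    if (!all(need %in% names(df))) {
      stop_("TSV network needs header columns source, target, sign")
    }
    edges <- data.frame(
      source = as.character(df$source),
      target = as.character(df$target),
      sign = sign_token(df$sign, where = paste0(" in ", path)),
      weight = if ("weight" %in% names(df)) as.numeric(df$weight) else 0,
      stringsAsFactors = FALSE
    )
  } else {
    df <- read.delim(path, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE,
                     col.names = c("source", "rel", "target"))
    edges <- data.frame(
      source = as.character(df$source),
      target = as.character(df$target),
      sign = sign_token(df$rel, where = paste0(" in ", path)),
      weight = 0,
      stringsAsFactors = FALSE
    )
  }
  if (undirected) {
    rev <- edges
    names(rev)[1:2] <- c("target", "source")
    edges <- rbind(edges, rev[, names(edges)])
  }
  signed_network(edges)
}

#' Write a signed network as a TSV edge list
#'
#' @param network a [signed_network()]
#' @param path output file path; UTF-8, tab-separated, with header.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "signed_network"))
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Internal: edge list in 0-based index form for the C++ core.
edge_index <- function(network) {
  idx <- seq_along(network$nodes)
  names(idx) <- network$nodes
  list(
    src = idx[network$edges$source] - 1L,
    dst = idx[network$edges$target] - 1L,
    sign = network$edges$sign,
    weight = network$edges$weight,
    node_index = idx
  )
}
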