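#' Pairwise Euclidean distances between two point clouds
#' @noRd
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

as_cloud <- function(x, arg = "x") {
  if (inherits(x, "netmoa") || inherits(x, "moa_ensemble")) {
    x <- signal_matrix(x)
  }
  if (!is.matrix(x)) x <- rbind(x)
  if (!is.numeric(x) || anyNA(x)) {
    stop_("`", arg, "` must be a numeric matrix of signals without NAs")
  }
  x
}

#' Modified Hausdorff distance between two MoA sets
#'
#' The Dubuisson-Jain modified Hausdorff distance between point sets:
#' `d(A, B) = max( mean_a min_b ||a - b|| , mean_b min_a ||a - b|| )`.
#' Each MoA is a point in protein-signal space (one coordinate per
#' protein). The measure is symmetric and non-negative, but does not obey
#' the triangle inequality in general.
#'
#' @param A,B numeric matrices (rows = MoAs, columns = proteins, same
#'   column set) or `netmoa`/`moa_ensemble` objects.
#' @param proteins optional character vector restricting the comparison to
#'   a protein subset (e.g. effectors only); default all shared columns.
#' @return a single non-negative number.
#' @export
mhd <- function(A, B, proteins = NULL) {
  A <- as_cloud(A, "A"); B <- as_cloud(B, "B")
  if (!is.null(proteins)) {
    A <- A[, proteins, drop = FALSE]
    B <- B[, proteins, drop = FALSE]
  }
  if (ncol(A) != ncol(B)) {
    stop_("point clouds have different dimensions (", ncol(A), " vs ",
          ncol(B), ")")
  }
  if (nrow(A) == 0L || nrow(B) == 0L) stop_("both clouds must be non-empty")
  D <- cross_dist(A, B)
  max(mean(apply(D, 1L, min)), mean(apply(D, 2L, min)))
}

#' Within-group dispersion of a MoA set
#'
#' Mean Euclidean distance between each point and the group centroid (the
#' coordinate-wise average of all points).
#'
#' @inheritParams mhd
#' @return a single non-negative number.
#' @export
dispersion <- function(A, proteins = NULL) {
  A <- as_cloud(A, "A")
  if (!is.null(proteins)) A <- A[, proteins, drop = FALSE]
  if (nrow(A) == 0L) stop_("cloud must be non-empty")
  ctr <- colMeans(A)
  mean(sqrt(rowSums(sweep(A, 2L, ctr)^2)))
}

#' Pairwise modified Hausdorff distances between labelled groups
#'
#' @param clouds named list of signal matrices (or objects [mhd()]
#'   accepts), e.g. the four High/Low groups of two phenotypes.
#' @param proteins optional protein subset.
#' @return symmetric matrix of MHD values with zero diagonal.
#' @export
group_distances <- function(clouds, proteins = NULL) {
  stopifnot(is.list(clouds), length(clouds) >= 2L,
            !is.null(names(clouds)), all(names(clouds) != ""))
  n <- length(clouds)
  D <- matrix(0, n, n, dimnames = list(names(clouds), names(clouds)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      D[i, j] <- D[j, i] <- mhd(clouds[[i]], clouds[[j]], proteins)
    }
  }
  D
}

#' Average-linkage (UPGMA) dendrogram of MoA groups
#'
#' Agglomerative clustering of a small group-level distance matrix.
#' Cluster-cluster distance is the size-weighted average of member
#' distances; equal-distance merge candidates are resolved
#' lexicographically by cluster name, so the tree is fully deterministic.
#'
#' @param D symmetric numeric matrix with zero diagonal and dimnames.
#' @return object of class `group_dendrogram`: list with `merges`
#'   (data.frame `a`, `b`, `height`), `newick` (ultrametric Newick string,
#'   leaf depth = height/2) and `cophenetic` (matrix of join heights).
#' @export
group_dendrogram <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop_("D must be square")
  if (is.null(rownames(D))) stop_("D needs group names as dimnames")
  if (max(abs(D - t(D))) > 1e-9) stop_("D must be symmetric")
  if (any(diag(D) != 0)) stop_("D must have a zero diagonal")
  labels <- rownames(D)
  n <- length(labels)
  if (n < 2L) stop_("need at least two groups")
  # active clusters: name (lexicographically sorted member string), members,
  # size, newick fragment, height of the cluster's own join
  cl <- lapply(seq_len(n), function(i) {
    list(name = labels[i], members = labels[i], size = 1L,
         newick = labels[i], height = 0)
  })
  W <- D
  merges <- data.frame(a = character(0), b = character(0),
                       height = numeric(0), stringsAsFactors = FALSE)
  coph <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(coph) <- 0
  while (length(cl) > 1L) {
    k <- length(cl)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        cand <- list(i = i, j = j, d = W[i, j],
                     key = paste(sort(c(cl[[i]]$name, cl[[j]]$name)),
                                 collapse = "|"))
        if (is.null(best) || cand$d < best$d ||
            (cand$d == best$d && cand$key < best$key)) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j; h <- best$d
    a <- cl[[i]]; b <- cl[[j]]
    first <- if (a$name <= b$name) a else b
    second <- if (a$name <= b$name) b else a
    merges <- rbind(merges, data.frame(a = first$name, b = second$name,
                                       height = h,
                                       stringsAsFactors = FALSE))
    coph[a$members, b$members] <- h
    coph[b$members, a$members] <- h
    nk <- sprintf("(%s:%.10g,%s:%.10g)",
                  first$newick, h / 2 - first$height / 2,
                  second$newick, h / 2 - second$height / 2)
    new <- list(name = min(a$name, b$name),
                members = c(a$members, b$members),
                size = a$size + b$size, newick = nk, height = h)
    # UPGMA update: size-weighted average distance to the merged cluster
    keep <- setdiff(seq_len(k), c(i, j))
    newd <- (a$size * W[i, keep] + b$size * W[j, keep]) / (a$size + b$size)
    W2 <- matrix(0, k - 1L, k - 1L)
    if (length(keep)) {
      W2[seq_along(keep), seq_along(keep)] <- W[keep, keep]
      W2[length(keep) + 1L, seq_along(keep)] <- newd
      W2[seq_along(keep), length(keep) + 1L] <- newd
    }
    W <- W2
    cl <- c(cl[keep], list(new))
  }
  structure(list(merges = merges,
                 newick = paste0(cl[[1L]]$newick, ";"),
                 cophenetic = coph),
            class = "group_dendrogram")
}

#' @export
print.group_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram:\n")
  for (i in seq_len(nrow(x$merges))) {
    cat(sprintf("  %s + %s at height %.4g\n",
                x$merges$a[i], x$merges$b[i], x$merges$height[i]))
  }
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling of MoA signals
#'
#' Embeds MoAs in `dims` dimensions from their pairwise Euclidean
#' distances via [stats::cmdscale()]. The embedding is centred at the
#' origin, axes are ordered by decreasing eigenvalue, and each axis's sign
#' is fixed so its first nonzero coordinate is positive (classical MDS is
#' otherwise only defined up to reflection). When the points truly live in
#' `dims` dimensions the embedded distances reproduce the input distances
#' exactly.
#'
#' @param points numeric matrix (rows = MoAs) or a `netmoa` fit.
#' @param dims embedding dimension (default 2).
#' @return numeric matrix of coordinates (rows = MoAs, `dims` columns),
#'   with the eigenvalue spectrum as attribute `"eig"`.
#' @export
mds_embed <- function(points, dims = 2L) {
  points <- as_cloud(points, "points")
  if (nrow(points) < dims + 1L) stop_("need at least dims + 1 points")
  mds <- stats::cmdscale(dist(points), k = dims, eig = TRUE)
  npos <- sum(mds$eig > max(mds$eig) * 1e-10)
  if (npos < dims) {
    stop_("only ", npos, " positive eigenvalues; spectrum: ",
          paste(signif(head(mds$eig, dims + 2L), 4L), collapse = ", "))
  }
  xy <- mds$points
  for (k in seq_len(ncol(xy))) {
    nz <- which(abs(xy[, k]) > 1e-12)
    if (length(nz) && xy[nz[1L], k] < 0) xy[, k] <- -xy[, k]
  }
  rownames(xy) <- rownames(points)
  colnames(xy) <- paste0("MDS", seq_len(ncol(xy)))
  attr(xy, "eig") <- mds$eig
  xy
}
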