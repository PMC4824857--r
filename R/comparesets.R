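#' Rescale copies per cell to parts per million
#'
#' ppm = cpc / total_molecules x 1e6, the PaxDb-style unit that puts
#' datasets with different absolute scales on a common footing. The
#' default total of 6e7 molecules per cell is the conventional figure for
#' a yeast cell.
#'
#' @param cpc Copies per cell (>= 0).
#' @param total_molecules Assumed total protein molecules per cell.
#' @return Abundance in ppm.
#' @examples
#' cpc_to_ppm(60)  # 1 ppm
#' @export
cpc_to_ppm <- function(cpc, total_molecules = 6e7) {
  if (any(total_molecules <= 0)) stop("`total_molecules` must be > 0",
                                      call. = FALSE)
  if (any(cpc < 0, na.rm = TRUE)) stop("`cpc` must be >= 0", call. = FALSE)
  cpc / total_molecules * 1e6
}

#' Pairwise Spearman correlation between abundance datasets
#'
#' Computes Spearman rank correlations between every pair of datasets on
#' their shared, strictly positive proteins (pairwise-complete; zeros and
#' missing values are excluded, never imputed). Pairs whose overlap falls
#' below `min_overlap` are reported as `NA` rather than fabricated.
#'
#' @param tables Named list of abundance tables, each a data frame with
#'   columns `protein_id` and `abundance` (any common scale; Spearman is
#'   invariant to monotone rescaling).
#' @param min_overlap Minimum number of shared quantified proteins per
#'   pair (default 50).
#' @return List of class `correlation_matrix` with `rho` (symmetric
#'   matrix, unit diagonal) and `overlap` (pair overlap counts).
#' @export
correlation_matrix <- function(tables, min_overlap = 50L) {
  stopifnot(is.list(tables), length(tables) >= 2L,
            !is.null(names(tables)), !anyDuplicated(names(tables)))
  ids <- names(tables)
  get <- function(tb) {
    stopifnot(all(c("protein_id", "abundance") %in% names(tb)))
    ok <- is.finite(tb$abundance) & tb$abundance > 0
    stats::setNames(tb$abundance[ok], tb$protein_id[ok])
  }
  vecs <- lapply(tables, get)
  k <- length(ids)
  rho <- diag(1, k)
  dimnames(rho) <- list(ids, ids)
  overlap <- matrix(0L, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      shared <- intersect(names(vecs[[i]]), names(vecs[[j]]))
      overlap[i, j] <- overlap[j, i] <- length(shared)
      if (length(shared) >= min_overlap) {
        r <- stats::cor(vecs[[i]][shared], vecs[[j]][shared],
                        method = "spearman")
      } else {
        r <- NA_real_
      }
      rho[i, j] <- rho[j, i] <- r
    }
  }
  diag(overlap) <- vapply(vecs, length, 0L)
  structure(list(rho = rho, overlap = overlap, min_overlap = min_overlap),
            class = "correlation_matrix")
}

#' Hierarchically cluster datasets from their correlation matrix
#'
#' Agglomerative clustering on the distance d = 1 - rho with average
#' linkage (paper-style dataset dendrograms; the linkage is
#' configurable). Input order does not affect the tree: datasets are
#' sorted by id before clustering.
#'
#' @param cm A [correlation_matrix()] result (or a plain symmetric
#'   correlation matrix).
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return List with `hclust` (the tree) and `newick` (Newick text with
#'   branch lengths).
#' @export
cluster_datasets <- function(cm, method = "average") {
  rho <- if (inherits(cm, "correlation_matrix")) cm$rho else as.matrix(cm)
  if (anyNA(rho)) {
    stop("correlation matrix has missing pairs; increase overlap or drop ",
         "the affected datasets (values are never imputed)", call. = FALSE)
  }
  ord <- order(rownames(rho))
  rho <- rho[ord, ord]
  hc <- stats::hclust(stats::as.dist(1 - rho), method = method)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy))
}

#' M-versus-A transform for paired abundances
#'
#' M = log2(x/y) (the log ratio) and A = (log2 x + log2 y)/2 (the average
#' log abundance), the standard rotation for visualising systematic
#' differences between two quantifications of the same proteins.
#' Non-positive pairs are excluded and counted.
#'
#' @param x,y Paired positive abundances (same proteins, same order).
#' @param protein_id Optional ids carried through.
#' @return Tibble with columns `protein_id` (if given), `M`, `A`;
#'   attribute `n_excluded` counts dropped non-positive pairs.
#' @export
ma_transform <- function(x, y, protein_id = NULL) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  out <- tibble::tibble(
    M = log2(x[ok] / y[ok]),
    A = (log2(x[ok]) + log2(y[ok])) / 2
  )
  if (!is.null(protein_id)) {
    out <- tibble::add_column(out, protein_id = protein_id[ok],
                              .before = 1L)
  }
  attr(out, "n_excluded") <- sum(!ok)
  out
}
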