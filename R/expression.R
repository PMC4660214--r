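#' Filter an FPKM expression matrix on mean and coefficient of variation
#'
#' A gene is retained iff its mean across all samples is strictly above
#' `min_mean` (FPKM) and its coefficient of variation (sample standard
#' deviation divided by mean) is strictly above `min_cv`.  Optionally
#' drops ribosomal-protein genes by the RPL/RPS identifier prefix.
#' Idempotent.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @param min_mean Mean-FPKM threshold (strict).
#' @param min_cv Coefficient-of-variation threshold (strict).
#' @param drop_ribosomal Drop genes whose identifier starts with RPL/RPS?
#' @return The filtered matrix.
#' @export
filter_genes <- function(mat, min_mean = 1.5, min_cv = 0.3,
                         drop_ribosomal = FALSE) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("CV undefined: need at least 2 samples")
  if (any(mat < 0)) stop("FPKM values must be non-negative")
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  cv <- ifelse(mu > 0, s / mu, 0)
  keep <- mu > min_mean & cv > min_cv
  if (drop_ribosomal && !is.null(rownames(mat)))
    keep <- keep & !grepl("^RP[LS]", rownames(mat))
  mat[keep, , drop = FALSE]
}

#' Spearman-correlation distance between samples
#'
#' `d(i, j) = 1 - Spearman correlation` of the gene vectors of samples
#' `i` and `j` (average ranks on ties).  Errors if a sample has zero
#' variance (correlation undefined), naming the sample.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @return Symmetric distance matrix with zero diagonal, entries in
#'   `[0, 2]`.
#' @export
spearman_distance <- function(mat) {
  mat <- as.matrix(mat)
  v <- apply(mat, 2, function(x) length(unique(x)) > 1)
  if (any(!v))
    stop("zero-variance sample(s): ",
         paste(colnames(mat)[!v] %||% which(!v), collapse = ", "))
  d <- 1 - cor(mat, method = "spearman")
  d[abs(d) < .Machine$double.eps^0.5] <- 0
  d
}

#' UPGMA hierarchical clustering of samples
#'
#' Average-linkage (UPGMA) agglomeration over the `(1 - Spearman)` sample
#' distance.  Ties between equally distant pairs are broken by merging
#' the pair whose member labels are lexicographically smallest, so the
#' dendrogram is deterministic across platforms.  The linkage record is
#' returned as a standard `hclust` object (usable with
#' [stats::cutree()]), with the merge history also exposed as a data
#' frame.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns; or a
#'   precomputed symmetric distance matrix (detected by attribute or
#'   squareness with zero diagonal being impossible for expression data,
#'   so pass distances via `dist_mat`).
#' @param dist_mat Optional precomputed distance matrix (overrides `mat`).
#' @return An `hclust` object with an extra `$linkage` data frame
#'   (`a`, `b`, `height`, `size`).
#' @export
cluster_samples <- function(mat, dist_mat = NULL) {
  d <- if (!is.null(dist_mat)) as.matrix(dist_mat) else spearman_distance(mat)
  n <- ncol(d)
  if (n < 3) stop("need at least 3 samples to cluster")
  labels <- colnames(d) %||% paste0("S", seq_len(n))
  colnames(d) <- rownames(d) <- labels
  # active clusters: id (negative leaf / positive merge), members, size
  act <- data.frame(id = -seq_len(n), size = 1L, stringsAsFactors = FALSE)
  act$min_label <- labels
  dm <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  linkage <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- nrow(act)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      key <- sort(c(act$min_label[i], act$min_label[j]))
      cand <- list(i = i, j = j, d = dm[i, j], key = key)
      if (is.null(best) || cand$d < best$d - 1e-12 ||
          (abs(cand$d - best$d) <= 1e-12 &&
           (cand$key[1] < best$key[1] ||
            (cand$key[1] == best$key[1] && cand$key[2] < best$key[2]))))
        best <- cand
    }
    i <- best$i; j <- best$j
    merge[step, ] <- c(act$id[i], act$id[j])
    height[step] <- best$d
    linkage[[step]] <- data.frame(a = act$min_label[i], b = act$min_label[j],
                                  height = best$d,
                                  size = act$size[i] + act$size[j],
                                  stringsAsFactors = FALSE)
    # UPGMA update: size-weighted average distance to the new cluster
    ni <- act$size[i]; nj <- act$size[j]
    newd <- (ni * dm[i, ] + nj * dm[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    act <- rbind(act[keep, , drop = FALSE],
                 data.frame(id = step, size = ni + nj,
                            min_label = min(act$min_label[c(i, j)]),
                            stringsAsFactors = FALSE))
  }
  order <- integer(0)
  expand <- function(id) {
    if (id < 0) return(-id)
    c(expand(merge[id, 1]), expand(merge[id, 2]))
  }
  hc <- structure(list(merge = merge, height = height,
                       order = expand(n - 1L), labels = labels,
                       method = "average", call = match.call(),
                       dist.method = "1 - spearman",
                       linkage = do.call(rbind, linkage)),
                  class = "hclust")
  hc
}

#' Export a dendrogram as a Newick string or file
#'
#' @param hc An `hclust` object (e.g. from [cluster_samples()]).
#' @param path Optional output path; when omitted, the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
as_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Signal-to-noise gene ranking between two phenotypes
#'
#' Score per gene: `(mean_A - mean_B) / (sd_A + sd_B)`, with each class
#' standard deviation floored at `floor_frac x |class mean|` (and at
#' `floor_frac` when the class mean is zero), the usual default of the
#' metric in enrichment analysis.  Genes are returned sorted by
#' decreasing score.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @param labels Phenotype label per sample (exactly two levels, each with
#'   at least 2 samples).
#' @param phenotype Level treated as class A (defaults to the first
#'   level).
#' @param floor_frac Standard-deviation floor fraction.
#' @return Data frame `gene`, `score`, `mean_a`, `mean_b`, sorted by
#'   decreasing score (ties keep input order).
#' @export
signal_to_noise_rank <- function(mat, labels, phenotype = NULL,
                                 floor_frac = 0.2) {
  mat <- as.matrix(mat)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("labels must have exactly two phenotypes")
  a <- phenotype %||% lev[1]
  b <- setdiff(lev, a)
  if (sum(labels == a) < 2 || sum(labels == b) < 2)
    stop("each phenotype needs at least 2 samples")
  A <- mat[, labels == a, drop = FALSE]
  B <- mat[, labels == b, drop = FALSE]
  floor_sd <- function(s, m) {
    fl <- ifelse(abs(m) > 0, floor_frac * abs(m), floor_frac)
    pmax(s, fl)
  }
  ma <- rowMeans(A); mb <- rowMeans(B)
  sa <- floor_sd(apply(A, 1, sd), ma)
  sb <- floor_sd(apply(B, 1, sd), mb)
  score <- (ma - mb) / (sa + sb)
  out <- data.frame(gene = rownames(mat) %||% paste0("g", seq_len(nrow(mat))),
                    score = score, mean_a = ma, mean_b = mb,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a two-group FPKM matrix with planted structure
#'
#' Log-normal baseline expression; a subset of genes carries a
#' multiplicative group effect (the planted differential signal).  Used
#' to exercise the clustering and ranking recipe.
#'
#' @param seed RNG seed.
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group.
#' @param n_de Number of differentially expressed genes.
#' @param effect Log2 fold change of planted genes.
#' @param noise_sd Log2 within-group noise standard deviation.
#' @return List: `mat` (matrix), `labels`, `de_genes`.
#' @export
simulate_fpkm_matrix <- function(seed = 1L, n_genes = 200L, n_per_group = 5L,
                                 n_de = max(1L, round(n_genes / 5)),
                                 effect = 3, noise_sd = 0.5) {
  with_seed(seed, {
    n_s <- 2L * n_per_group
    base <- rnorm(n_genes, mean = 3, sd = 1.5)
    lmat <- matrix(rnorm(n_genes * n_s, sd = noise_sd), n_genes, n_s) + base
    de <- sample.int(n_genes, n_de)
    lmat[de, seq_len(n_per_group)] <- lmat[de, seq_len(n_per_group)] + effect
    mat <- 2^lmat
    rownames(mat) <- sprintf("G%04d", seq_len(n_genes))
    colnames(mat) <- c(sprintf("A%02d", seq_len(n_per_group)),
                       sprintf("B%02d", seq_len(n_per_group)))
    list(mat = mat, labels = rep(c("A", "B"), each = n_per_group),
         de_genes = rownames(mat)[de])
  })
}

#' Read/write expression matrices as TSV (genes in rows)
#'
#' @param mat Matrix to write.
#' @param path File path.
#' @return `path` (writer, invisibly) or the matrix (reader).
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
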