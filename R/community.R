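#' Subtract reagent (kitome) contamination from an ASV table
#'
#' For every ASV, the number of reads observed in the kitome (extraction
#' and library reagent blank) is subtracted from each sample's count,
#' clamping at zero; cells that were clamped are flagged.
#'
#' @param table an [asv_table()] with a kitome vector
#' @return a `corrected_table`: corrected counts, the raw counts, a
#'   logical `clamped` matrix, and the carried-over taxonomy/metadata
#' @export
kitome_correct <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  if (is.null(table$kitome)) stop("ASV table has no kitome vector", call. = FALSE)
  sub <- sweep(table$counts, 2, table$kitome, `-`)
  clamped <- sub < 0
  corrected <- pmax(sub, 0)
  structure(list(corrected = corrected, raw = table$counts,
                 clamped = clamped, taxonomy = table$taxonomy,
                 kitome = table$kitome, meta = table$meta),
            class = "corrected_table")
}

#' @export
print.corrected_table <- function(x, ...) {
  cat(sprintf("<corrected_table> %d samples x %d ASVs; %d cells clamped at 0\n",
              nrow(x$corrected), ncol(x$corrected), sum(x$clamped)))
  invisible(x)
}

#' Per-sample relative abundance
#'
#' Normalises each sample's corrected counts by that sample's
#' post-subtraction total. Samples whose corrected counts are all zero are
#' excluded (and listed in the `dropped` attribute) since they have no
#' defined composition.
#'
#' @param corrected a [kitome_correct()] result, or a bare non-negative
#'   count matrix (samples x ASVs)
#' @return proportion matrix whose rows sum to 1, with attribute
#'   `dropped` naming any excluded all-zero samples
#' @export
relative_abundance <- function(corrected) {
  m <- if (inherits(corrected, "corrected_table")) corrected$corrected else as.matrix(corrected)
  if (length(m) == 0) stop("empty table", call. = FALSE)
  if (any(m < 0)) stop("counts must be >= 0", call. = FALSE)
  tot <- rowSums(m)
  dropped <- rownames(m)[tot == 0]
  keep <- tot > 0
  if (!any(keep)) stop("all samples have zero corrected reads", call. = FALSE)
  p <- m[keep, , drop = FALSE] / tot[keep]
  attr(p, "dropped") <- dropped
  p
}

#' Reactor-level mean relative abundance
#'
#' Averages raw reads across all samples first, then removes the kitome
#' contribution and normalises - the reads-first order used for
#' per-reactor community summaries. Note this differs from averaging
#' per-sample proportions.
#'
#' @param table an [asv_table()]
#' @return named vector of mean relative abundances (sums to 1)
#' @export
reactor_mean_abundance <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  mean_reads <- colMeans(table$counts)
  corr <- pmax(mean_reads - table$kitome, 0)
  if (sum(corr) == 0) stop("no reads left after kitome removal", call. = FALSE)
  corr / sum(corr)
}

#' Confirm the presence of a taxon against the kitome
#'
#' A taxon's presence in a group of samples is confirmed only when its
#' mean raw read count over the group strictly exceeds its kitome read
#' count; means at or below the kitome are indistinguishable from reagent
#' contamination and the taxon is "not confirmed" (ties included).
#'
#' @param table an [asv_table()]
#' @param taxon ASV id (name or index)
#' @param group sample ids (or row indices); must be non-empty
#' @return TRUE if confirmed, FALSE otherwise
#' @export
confirm_presence <- function(table, taxon, group) {
  stopifnot(inherits(table, "asv_table"))
  if (is.character(taxon) && !taxon %in% colnames(table$counts)) {
    stop(sprintf("unknown taxon '%s'", taxon), call. = FALSE)
  }
  if (is.numeric(taxon) && (taxon < 1 || taxon > ncol(table$counts))) {
    stop("taxon index out of range", call. = FALSE)
  }
  if (length(group) == 0) stop("'group' must be non-empty", call. = FALSE)
  j <- if (is.character(taxon)) match(taxon, colnames(table$counts)) else taxon
  reads <- table$counts[group, j]
  mean(reads) > table$kitome[[j]]
}

#' Hellinger transformation
#'
#' Elementwise square root of relative abundances, mapping compositions
#' onto the unit sphere so that Euclidean distances (and hence PCA) become
#' appropriate for community data. Rows that are proportions (sum 1) come
#' out with unit sum of squares.
#'
#' @param p proportion matrix (rows = samples); negative entries are an
#'   error
#' @return transformed matrix of the same shape
#' @export
hellinger <- function(p) {
  p <- as.matrix(p)
  if (any(p < 0)) stop("proportions must be >= 0", call. = FALSE)
  sqrt(p)
}

#' PCA ordination of a (transformed) community matrix
#'
#' Column-centred singular value decomposition. Explained-variance
#' fractions are non-increasing and sum to at most 1; a request for more
#' components than the matrix rank is truncated with a warning. Degenerate
#' input with zero total variance is flagged.
#'
#' @param x numeric matrix (samples x variables), typically
#'   [hellinger()]-transformed proportions
#' @param n_components number of components to return (default 2)
#' @return list: `scores` (samples x k), `loadings` (variables x k),
#'   `explained` (variance fractions, length k), `degenerate` flag
#' @export
pca_ordination <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least 2 samples are required", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (total == 0 || rank == 0) {
    k <- min(n_components, ncol(pc$x))
    return(list(scores = pc$x[, seq_len(k), drop = FALSE],
                loadings = pc$rotation[, seq_len(k), drop = FALSE],
                explained = rep(0, k), degenerate = TRUE))
  }
  if (n_components > rank) {
    warning(sprintf("n_components truncated to the matrix rank (%d)", rank),
            call. = FALSE)
    n_components <- rank
  }
  k <- seq_len(n_components)
  list(scores = pc$x[, k, drop = FALSE],
       loadings = pc$rotation[, k, drop = FALSE],
       explained = pc$sdev[k]^2 / total,
       degenerate = FALSE)
}

#' Column-wise biomass comparisons on the sampling grid
#'
#' For each off-centre column (OL, CL, CR, OR) versus the central column
#' C, tests whether biomass (16S copies per gram) is lower off-centre: a
#' two-sided variance-ratio (F) test at `alpha_var` chooses between the
#' pooled and the unequal-variance (Welch) two-sample t-test, which is
#' then run one-sided with alternative "off-centre < centre". Raw
#' p-values are reported without multiplicity correction (the convention
#' of the original analysis; interpret jointly with care). Values can be
#' log10-transformed first via `log10_scale`.
#'
#' @param biomass data.frame with columns `column` (OL/CL/C/CR/OR) and
#'   `copies_per_g`, e.g. the `meta` of [generate_asv_table()]
#' @param alpha_var level of the variance gate (default 0.05)
#' @param log10_scale test on log10 copies (default FALSE, natural scale)
#' @return data.frame, one row per off-centre column: variance-test p,
#'   test variant, t statistic, one-sided p, direction
#' @export
column_biomass_tests <- function(biomass, alpha_var = 0.05,
                                 log10_scale = FALSE) {
  stopifnot(all(c("column", "copies_per_g") %in% names(biomass)))
  vals <- biomass$copies_per_g
  if (log10_scale) vals <- log10(vals)
  center <- vals[biomass$column == "C"]
  if (length(center) < 2) stop("central column needs >= 2 observations", call. = FALSE)
  out <- list()
  for (col in c("OL", "CL", "CR", "OR")) {
    x <- vals[biomass$column == col]
    if (length(x) < 2) {
      warning(sprintf("column %s has < 2 values; comparison skipped", col),
              call. = FALSE)
      next
    }
    vt <- stats::var.test(x, center)
    pooled <- vt$p.value >= alpha_var
    tt <- stats::t.test(x, center, alternative = "less", var.equal = pooled)
    out[[col]] <- data.frame(
      column = col, var_p = vt$p.value,
      variant = if (pooled) "pooled" else "unequal-variance",
      t = unname(tt$statistic), p = tt$p.value,
      direction = "off-center < center"
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Interpolate grid values to a dense spatial field
#'
#' Bilinear interpolation of the 5 x 7 sampling-grid values onto a dense
#' raster for heat-map display; the 35 node values are reproduced exactly
#' at the node coordinates. Missing nodes (at most 50 %) are filled by
#' iterative neighbour averaging before interpolation.
#'
#' @param values numeric 7 x 5 matrix (rows 1-7 top-to-bottom, columns
#'   OL..OR), or a data.frame with `grid_col` (0-4), `grid_row` (1-7) and
#'   `value`
#' @param nx,ny output raster size (default 41 x 61)
#' @return list: `x` (column coordinate, 0-4), `y` (row coordinate, 1-7),
#'   `field` (ny x nx matrix)
#' @export
spatial_map <- function(values, nx = 41, ny = 61) {
  if (is.data.frame(values)) {
    m <- matrix(NA_real_, nrow = 7, ncol = 5)
    m[cbind(values$grid_row, values$grid_col + 1)] <- values$value
    values <- m
  }
  values <- as.matrix(values)
  if (!all(dim(values) == c(7, 5))) {
    stop("'values' must be a 7 x 5 grid (rows x columns)", call. = FALSE)
  }
  n_miss <- sum(is.na(values))
  if (n_miss > 0.5 * length(values)) {
    stop("more than 50 % of grid nodes are missing", call. = FALSE)
  }
  while (anyNA(values)) {
    filled <- values
    for (i in 1:7) for (j in 1:5) {
      if (is.na(values[i, j])) {
        nb <- c(if (i > 1) values[i - 1, j], if (i < 7) values[i + 1, j],
                if (j > 1) values[i, j - 1], if (j < 5) values[i, j + 1])
        if (any(!is.na(nb))) filled[i, j] <- mean(nb, na.rm = TRUE)
      }
    }
    values <- filled
  }
  xg <- 0:4
  yg <- 1:7
  xp <- seq(0, 4, length.out = nx)
  yp <- seq(1, 7, length.out = ny)
  grid <- expand.grid(x = xp, y = yp)
  z <- pracma::interp2(xg, yg, values, grid$x, grid$y, method = "linear")
  list(x = xp, y = yp, field = matrix(z, nrow = ny, ncol = nx, byrow = TRUE))
}
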