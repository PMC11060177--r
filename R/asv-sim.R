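# Default taxonomy strings for the synthetic community: the taxa observed
# to dominate sand-bentonite reactor microbiomes (sulfate reducers,
# the Methanosarcina methanogen, fermenters), semicolon-delimited ranks.
default_taxonomy <- function(n_asvs) {
  base <- c(
    "Bacteria;Bacteroidota;Bacteroidia;Marinilabiliales;Prolixibacteraceae;Sunxiuqinia",
    "Bacteria;Desulfobacterota;Desulfovibrionia;Desulfovibrionales;Desulfovibrionaceae;Desulfocurvibacter",
    "Bacteria;Desulfobacterota;Desulfobacteria;Desulfobacterales;Desulfobacteraceae;unclassified",
    "Archaea;Halobacterota;Methanosarcinia;Methanosarcinales;Methanosarcinaceae;Methanosarcina",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas",
    "Bacteria;Desulfobacterota;Desulfuromonadia;Desulfuromonadales;Desulfuromonadaceae;unclassified",
    "Bacteria;Firmicutes;Clostridia;Eubacteriales;Peptococcaceae;Desulfallas",
    "Bacteria;Firmicutes;Clostridia;Eubacteriales;Peptococcaceae;Desulfotomaculum",
    "Bacteria;Firmicutes;Clostridia;Symbiobacteriales;Symbiobacteriaceae;Symbiobacterium",
    "Bacteria;Firmicutes;Clostridia;Eubacteriales;Gracilibacteraceae;Gracilibacter",
    "Bacteria;Firmicutes;Clostridia;Eubacteriales;Peptococcaceae;Desulfosporosinus",
    "Bacteria;Firmicutes;Bacilli;Bacillales;Paenibacillaceae;Paenibacillus"
  )
  tax <- rep("Bacteria;unclassified", n_asvs)
  tax[seq_len(min(n_asvs, length(base)))] <- base[seq_len(min(n_asvs, length(base)))]
  tax
}

#' Generate a synthetic spatial ASV count table
#'
#' Emulates the post-mortem 16S amplicon survey of a reactor: 35 samples on
#' a 5 x 7 grid (radial columns OL, CL, C, CR, OR x depth rows 1-7), with
#' an H2-proximity hotspot for one hydrogenotroph taxon, reagent ("kitome")
#' contaminant reads per ASV, and a per-sample 16S copies-per-gram biomass
#' proxy enriched in the central column where H2 is delivered.
#'
#' Counts are negative-binomial around expected compositions: a fixed
#' power-law base profile whose hotspot taxon is multiplied by
#' `1 + amplitude * exp(-d^2 / (2 * decay^2))`, with `d` the grid distance
#' to the hotspot centre. Kitome reads are Poisson, proportional to the
#' base profile with overall mean `kitome_level`; biomass is log-normal
#' with a central-column enrichment factor.
#'
#' @param n_asvs number of ASVs (default 20)
#' @param hotspot list with `taxon` (ASV index), `center` (c(col, row),
#'   columns 0-4 = OL..OR, rows 1-7), `amplitude` (>= 0) and `decay`
#'   (grid units)
#' @param kitome_level mean contaminant reads per ASV (0 = clean reagents)
#' @param depth mean library size, reads per sample
#' @param overdisp negative-binomial size parameter (larger = closer to
#'   Poisson)
#' @param biomass_mean geometric-mean 16S copies per gram of substrate
#' @param biomass_sdlog log-scale SD of the biomass distribution
#' @param center_enrich multiplicative biomass enrichment of column C
#' @param seed integer seed
#' @return an object of class `asv_table`: integer count matrix (35
#'   samples x ASVs), taxonomy strings, kitome vector, sample metadata
#'   (grid coordinates, copies per gram) and the expected count matrix
#'   used for the draws
#' @export
generate_asv_table <- function(n_asvs = 20,
                               hotspot = list(taxon = 2, center = c(2, 4),
                                              amplitude = 4, decay = 1),
                               kitome_level = 40, depth = 2e4,
                               overdisp = 8,
                               biomass_mean = 8.2e8, biomass_sdlog = 0.6,
                               center_enrich = 3, seed = 1L) {
  assert_pos(n_asvs, "n_asvs")
  assert_pos(depth, "depth")
  assert_nonneg(kitome_level, "kitome_level")
  assert_nonneg(hotspot$amplitude, "hotspot$amplitude")
  assert_pos(hotspot$decay, "hotspot$decay")
  if (hotspot$taxon < 1 || hotspot$taxon > n_asvs) {
    stop("'hotspot$taxon' must be an ASV index in 1..n_asvs", call. = FALSE)
  }

  cols <- c("OL", "CL", "C", "CR", "OR")
  meta <- expand.grid(grid_col = 0:4, grid_row = 1:7)
  meta <- meta[order(meta$grid_row, meta$grid_col), ]
  meta$column <- cols[meta$grid_col + 1]
  meta$sample <- paste0(meta$column, "-", meta$grid_row)
  rownames(meta) <- NULL

  base <- seq_len(n_asvs)^(-0.9)
  base <- base / sum(base)

  d2 <- (meta$grid_col - hotspot$center[1])^2 +
    (meta$grid_row - hotspot$center[2])^2
  mult <- 1 + hotspot$amplitude * exp(-d2 / (2 * hotspot$decay^2))

  expected <- matrix(0, nrow = nrow(meta), ncol = n_asvs)
  for (s in seq_len(nrow(meta))) {
    w <- base
    w[hotspot$taxon] <- w[hotspot$taxon] * mult[s]
    expected[s, ] <- depth * w / sum(w)
  }

  set.seed(as.integer(seed))
  counts <- matrix(
    stats::rnbinom(length(expected), mu = as.numeric(t(expected)),
                   size = overdisp),
    nrow = nrow(meta), ncol = n_asvs, byrow = TRUE
  )
  kit_lambda <- if (kitome_level > 0) kitome_level * base / mean(base) else rep(0, n_asvs)
  kitome <- stats::rpois(n_asvs, kit_lambda)
  meta$copies_per_g <- stats::rlnorm(nrow(meta), log(biomass_mean), biomass_sdlog) *
    ifelse(meta$column == "C", center_enrich, 1)

  asv_ids <- paste0("ASV", seq_len(n_asvs))
  dimnames(counts) <- list(meta$sample, asv_ids)
  dimnames(expected) <- dimnames(counts)

  structure(list(
    counts = counts,
    taxonomy = stats::setNames(default_taxonomy(n_asvs), asv_ids),
    kitome = stats::setNames(as.numeric(kitome), asv_ids),
    meta = meta[, c("sample", "column", "grid_col", "grid_row", "copies_per_g")],
    expected = expected,
    hotspot = hotspot,
    seed = as.integer(seed)
  ), class = "asv_table")
}

#' Construct / validate an ASV table
#'
#' @param counts integer matrix, samples x ASVs
#' @param taxonomy character vector of semicolon-delimited ranks, one per
#'   ASV
#' @param kitome numeric vector of contaminant reads, one per ASV
#' @param meta data.frame of per-sample metadata (must contain a `sample`
#'   column matching the count rows)
#' @return an `asv_table`
#' @export
asv_table <- function(counts, taxonomy, kitome, meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(kitome) != ncol(counts)) {
    stop("kitome vector length must equal the number of ASVs", call. = FALSE)
  }
  if (any(kitome < 0)) stop("kitome reads must be >= 0", call. = FALSE)
  if (length(taxonomy) != ncol(counts)) {
    stop("one taxonomy string per ASV is required", call. = FALSE)
  }
  if (!"sample" %in% names(meta) || nrow(meta) != nrow(counts)) {
    stop("'meta' must have one row per sample with a 'sample' column",
         call. = FALSE)
  }
  structure(list(counts = counts, taxonomy = taxonomy, kitome = kitome,
                 meta = meta),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d samples x %d ASVs; kitome mean %.1f reads\n",
              nrow(x$counts), ncol(x$counts), mean(x$kitome)))
  invisible(x)
}
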