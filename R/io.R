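# Delimited-text dialect: comma-separated, UTF-8, "." decimal, days as
# numbers. Tab-separated files are accepted on read.

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a porewater monitoring series from delimited text
#'
#' Expects a header row with columns `day, analyte, mean, sd, n`
#' (comma- or tab-separated). Rows are validated and offending lines are
#' reported by number: analytes must be one of sulfate/sulfide/fe, days
#' strictly increasing within an analyte, concentrations non-negative.
#'
#' @param path file path
#' @return a [porewater_series()]
#' @export
read_porewater <- function(path) {
  x <- read_delim_auto(path)
  need <- c("day", "analyte", "mean", "sd", "n")
  if (!all(need %in% names(x))) {
    stop("porewater file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  line <- seq_len(nrow(x)) + 1L   # header is line 1
  bad <- !x$analyte %in% c("sulfate", "sulfide", "fe")
  if (any(bad)) {
    stop(sprintf("unknown analyte '%s' at line %d", x$analyte[bad][1],
                 line[bad][1]), call. = FALSE)
  }
  neg <- x$mean < 0
  if (any(neg)) {
    stop(sprintf("negative concentration at line %d", line[neg][1]),
         call. = FALSE)
  }
  for (an in unique(x$analyte)) {
    idx <- which(x$analyte == an)
    if (any(diff(x$day[idx]) <= 0)) {
      off <- idx[which(diff(x$day[idx]) <= 0)[1] + 1]
      stop(sprintf("non-monotone days for analyte '%s' at line %d", an,
                   line[off]), call. = FALSE)
    }
  }
  porewater_series(x[, need])
}

#' Write a porewater series (or any data.frame) as delimited text
#'
#' @param x data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_porewater <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ASV table as delimited text
#'
#' Two files: a counts file with one row per ASV (columns `asv_id`,
#' `taxonomy`, the reserved `KITOME` column, then one column per sample)
#' and a sample metadata file (`sample`, `column`, `grid_col`,
#' `grid_row`, `copies_per_g`).
#'
#' @param table an [asv_table()]
#' @param counts_path,meta_path output paths
#' @return `counts_path`, invisibly
#' @export
write_asv_table <- function(table, counts_path, meta_path) {
  stopifnot(inherits(table, "asv_table"))
  df <- data.frame(asv_id = colnames(table$counts),
                   taxonomy = unname(table$taxonomy),
                   KITOME = unname(table$kitome),
                   t(table$counts), check.names = FALSE)
  utils::write.csv(df, counts_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(table$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}

#' Read an ASV table written by [write_asv_table()]
#'
#' @param counts_path,meta_path input paths
#' @return an [asv_table()]
#' @export
read_asv_table <- function(counts_path, meta_path) {
  df <- read_delim_auto(counts_path)
  need <- c("asv_id", "taxonomy", "KITOME")
  if (!all(need %in% names(df))) {
    stop("ASV counts file must have columns asv_id, taxonomy, KITOME",
         call. = FALSE)
  }
  samples <- setdiff(names(df), need)
  counts <- t(as.matrix(df[, samples, drop = FALSE]))
  colnames(counts) <- df$asv_id
  meta <- read_delim_auto(meta_path)
  meta <- meta[match(rownames(counts), meta$sample), , drop = FALSE]
  asv_table(counts,
            taxonomy = stats::setNames(df$taxonomy, df$asv_id),
            kitome = stats::setNames(df$KITOME, df$asv_id),
            meta = meta)
}

# strict RunConfig schema: every known key, by section ---------------------

config_schema <- list(
  seed = NULL,
  reactor = c("v_voids", "v_total", "c_in_sulfate", "c_in_fe", "c0_sulfate",
              "c0_fe", "gypsum0", "c_sat", "duration", "flow_profile",
              "h2_schedule"),
  kinetics = c("vmax_sr", "k_so4", "k_h2", "k_gyp", "vmax_meth", "so4_gate",
               "growth"),
  scaleup = c("h2_inventory", "horizon", "backfill_volume", "porosity",
              "days_per_year"),
  estimators = c("n_gypsum", "window", "weighted", "bin_days"),
  community = c("alpha_var", "log10_scale", "n_asvs", "kitome_level",
                "depth", "amplitude"),
  observation = c("interval_days", "noise_sulfate", "noise_sulfide",
                  "noise_fe", "n_reps"),
  paths = c("supply_ledger", "printed_rates")
)

#' Read and validate a run configuration
#'
#' YAML configuration with sections `reactor`, `kinetics`, `scaleup`,
#' `estimators`, `community`, `observation`, `paths` and a top-level
#' `seed`. The schema is strict: unknown sections or keys are an error,
#' so every configured option is guaranteed to be consumed. Referenced
#' paths must exist.
#'
#' @param path YAML file path
#' @return a validated `run_config` list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || !length(cfg)) stop("empty configuration", call. = FALSE)
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown)) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in setdiff(names(cfg), "seed")) {
    extra <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(extra)) {
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(cfg$paths)) {
    for (p in unlist(cfg$paths)) {
      if (!file.exists(p)) stop("configured path does not exist: ", p,
                                call. = FALSE)
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

config_to_profile <- function(x) {
  if (is.list(x) && !is.null(x$day)) data.frame(day = x$day, value = x$value)
  else x
}
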