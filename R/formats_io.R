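#' Read a protein FASTA file
#'
#' Reads protein sequences, taking the first whitespace-delimited token
#' of each header as the id, uppercasing the sequence and stripping gap
#' characters. Records containing characters outside the 20 standard
#' amino acids (after gap stripping) and header-only records are parse
#' errors naming the offending record.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `protein_id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("the Biostrings package is required to read FASTA", call. = FALSE)
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- unname(toupper(gsub("[-. ]", "", as.character(set))))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("header-only FASTA record(s): ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  }
  legal <- paste(names(residue_masses()), collapse = "")
  bad <- grepl(sprintf("[^%s]", legal), seqs)
  if (any(bad)) {
    stop("non-amino-acid characters in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(protein_id = ids, sequence = seqs, length = nchar(seqs))
}

#' Write a table as TSV
#'
#' Canonical table dialect of the pipeline: tab-separated, UTF-8, "."
#' decimal mark, header row, no quoting or row names, stable column
#' order as given.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  x <- as.data.frame(x)
  listish <- vapply(x, is.list, logical(1))
  x <- x[, !listish, drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV table
#'
#' @param path Input path.
#' @return Tibble.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE,
                                      fileEncoding = "UTF-8"))
}

.PEAK_COLS <- c("peptide_id", "protein_group", "replicate", "spike_label",
                "spike_amount_mol", "light_area", "heavy_area", "sn", "q")

#' Read a replicate-level peak-area table
#'
#' Reads and validates the TSV schema used for replicate-level light and
#' heavy peak areas: one row per peptide x replicate x spike level, with
#' the light/heavy areas, signal-to-noise and q-value. A missing light
#' area marks a Type B candidate and is allowed; negative areas and
#' q-values outside [0, 1] are rejected.
#'
#' @param path TSV path.
#' @return Validated tibble with a `ratio` column added (light/heavy
#'   where both areas are positive).
#' @export
read_peak_table <- function(path) {
  tb <- read_tsv_table(path)
  miss <- setdiff(.PEAK_COLS, names(tb))
  if (length(miss) > 0L) {
    stop("peak table lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(tb$light_area < 0, na.rm = TRUE) ||
      any(tb$heavy_area < 0, na.rm = TRUE)) {
    stop("negative peak areas are not allowed", call. = FALSE)
  }
  if (any(tb$q < 0 | tb$q > 1, na.rm = TRUE)) {
    stop("q-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(tb$spike_amount_mol <= 0, na.rm = TRUE)) {
    stop("spike amounts must be > 0", call. = FALSE)
  }
  tb$ratio <- ifelse(!is.na(tb$light_area) & !is.na(tb$heavy_area) &
                       tb$light_area > 0 & tb$heavy_area > 0,
                     tb$light_area / tb$heavy_area, NA_real_)
  tb
}

#' Write a replicate-level peak-area table
#'
#' @param tb Tibble with at least the mandatory peak-table columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(tb, path) {
  miss <- setdiff(.PEAK_COLS, names(tb))
  if (length(miss) > 0L) {
    stop("peak table lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  write_tsv_table(tb[, c(.PEAK_COLS,
                         setdiff(names(tb), c(.PEAK_COLS, "ratio")))],
                  path)
}

#' Write a Skyline-style transition list
#'
#' Comma-separated transition list with the conventional columns:
#' protein, peptide sequence, precursor m/z, precursor charge, product
#' m/z, fragment ion, label type, expected RT.
#'
#' @param transitions Tibble such as `simulate_srm()$transitions`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_list <- function(transitions, path) {
  cols <- c("protein", "peptide_sequence", "precursor_mz",
            "precursor_charge", "product_mz", "fragment_ion",
            "fragment_charge", "label_type", "expected_rt")
  miss <- setdiff(cols, names(transitions))
  if (length(miss) > 0L) {
    stop("transition list lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(as.data.frame(transitions)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a simulation configuration
#'
#' Round-trips a [sim_config()] through a structured YAML file.
#'
#' @param config A `sim_config` object.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$spike_levels <- lapply(seq_len(nrow(x$spike_levels)), function(i) {
    as.list(x$spike_levels[i, ])
  })
  x$feature_te_cors <- as.list(x$feature_te_cors)
  if (!is.null(x$feature_effects)) {
    x$feature_effects <- lapply(x$feature_effects, as.list)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  x$spike_levels <- dplyr::bind_rows(lapply(x$spike_levels,
                                            tibble::as_tibble))
  x$feature_te_cors <- unlist(x$feature_te_cors)
  if (!is.null(x$feature_effects)) {
    fe <- x$feature_effects
    for (nm in c("main", "interaction")) {
      if (!is.null(fe[[nm]])) fe[[nm]] <- unlist(fe[[nm]])
    }
    if (!is.null(fe$r2)) fe$r2 <- as.numeric(fe$r2)
    x$feature_effects <- fe
  }
  x$turnover_labels <- unlist(x$turnover_labels)
  do.call(sim_config, x)
}

#' Write a run manifest
#'
#' Records the seed, the md5 of the serialised configuration and the
#' produced output files, so a stochastic run can be reproduced and
#' audited.
#'
#' @param path Manifest path (YAML).
#' @param config The `sim_config` used.
#' @param outputs Character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, outputs = character(0)) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_sim_config(config, tmp)
  yaml::write_yaml(list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  ), path)
  invisible(path)
}
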