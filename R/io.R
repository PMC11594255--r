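#' Write a cohort of spectra to a directory
#'
#' One two-column CSV (`ppm,intensity`) per sample, a `manifest.csv`
#' linking sample ids to files and biofluids, and a `metadata.csv` when
#' metadata is supplied. The writer/reader pair round-trips exactly (full
#' double precision).
#'
#' @param spectra List of `nmr_spectrum` objects.
#' @param dir Output directory (created if absent).
#' @param metadata Optional data frame with a `sample_id` column.
#' @return `dir`, invisibly.
#' @export
write_spectra <- function(spectra, dir, metadata = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(spectra, `[[`, character(1L), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_ids", call. = FALSE)
  files <- paste0(gsub("[^A-Za-z0-9._-]", "_", ids), ".csv")
  for (i in seq_along(spectra)) {
    df <- data.frame(ppm = format(spectra[[i]]$ppm, digits = 17),
                     intensity = format(spectra[[i]]$intensity, digits = 17))
    utils::write.csv(df, file.path(dir, files[i]), row.names = FALSE,
                     quote = FALSE)
  }
  manifest <- data.frame(
    sample_id = ids, file = files,
    biofluid = vapply(spectra, `[[`, character(1L), "biofluid"),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(metadata)) {
    utils::write.csv(metadata, file.path(dir, "metadata.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a cohort of spectra written by [write_spectra()]
#'
#' @param dir Directory containing `manifest.csv` and per-sample CSVs.
#' @return List with `spectra` and `metadata` (NULL when absent).
#' @export
read_spectra <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicate sample_ids in manifest", call. = FALSE)
  }
  spectra <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, manifest$file[i])
    if (!file.exists(path)) {
      stop("manifest references missing spectrum file: ", manifest$file[i],
           call. = FALSE)
    }
    df <- utils::read.csv(path, colClasses = "numeric")
    if (!all(c("ppm", "intensity") %in% names(df))) {
      stop("malformed spectrum file (need ppm,intensity columns): ",
           manifest$file[i], call. = FALSE)
    }
    spectra[[i]] <- new_spectrum(manifest$sample_id[i], manifest$biofluid[i],
                                 df$ppm, df$intensity)
  }
  meta_path <- file.path(dir, "metadata.csv")
  metadata <- if (file.exists(meta_path)) {
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  }
  list(spectra = spectra, metadata = metadata)
}

#' Write a bucket table as CSV (with a config sidecar)
#'
#' First column `sample_id`, remaining columns named by bin center to three
#' decimals (`bin_0.805`). The binning configuration is serialized next to
#' it as `<path>.config.yaml` for provenance.
#'
#' @param table A `bucket_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bucket_table <- function(table, path) {
  stopifnot(inherits(table, "bucket_table"))
  df <- data.frame(sample_id = table$sample_ids,
                   apply(table$values, 2L, format, digits = 17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cfg <- table$config
  cfg_list <- list(biofluid = cfg$biofluid, bin_width_ppm = cfg$bin_width_ppm,
                   range_ppm = cfg$range_ppm,
                   exclusions = lapply(cfg$exclusions, as.numeric),
                   scaling_mode = cfg$scaling_mode,
                   scaling_region_ppm = cfg$scaling_region_ppm,
                   baseline_percentile = cfg$baseline_percentile)
  yaml::write_yaml(cfg_list, paste0(path, ".config.yaml"))
  invisible(path)
}

#' Read a bucket table written by [write_bucket_table()]
#'
#' @param path CSV path; the `.config.yaml` sidecar is read when present.
#' @return A `bucket_table`.
#' @export
read_bucket_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id") stop("first column must be sample_id", call. = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df$sample_id
  centers <- as.numeric(sub("^bin_", "", colnames(values)))
  cfg_path <- paste0(path, ".config.yaml")
  config <- if (file.exists(cfg_path)) {
    cl <- yaml::read_yaml(cfg_path)
    binning_config(cl$biofluid, cl$bin_width_ppm, unlist(cl$range_ppm),
                   exclusions = lapply(cl$exclusions, unlist),
                   scaling_mode = cl$scaling_mode,
                   scaling_region_ppm = if (!is.null(cl$scaling_region_ppm))
                     unlist(cl$scaling_region_ppm),
                   baseline_percentile = cl$baseline_percentile %||% 5)
  }
  structure(
    list(sample_ids = df$sample_id, bin_centers_ppm = centers,
         values = values, config = config),
    class = "bucket_table"
  )
}

#' Read a GMT pathway-set file
#'
#' Standard tab-separated layout: set name, description, then member names.
#' Empty member fields are dropped; duplicate set names and empty sets are
#' errors (with line numbers).
#'
#' @param path Path to a `.gmt` file.
#' @return Named list `pathway -> character vector of members`, with the
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop("malformed GMT line ", i, ": need name, description, >= 1 member",
           call. = FALSE)
    }
    members <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    if (length(members) == 0L) stop("empty set at GMT line ", i, call. = FALSE)
    if (parts[1L] %in% names(sets)) {
      stop("duplicate set name at GMT line ", i, ": ", parts[1L], call. = FALSE)
    }
    sets[[parts[1L]]] <- members
    desc[parts[1L]] <- parts[2L]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a pathway library as GMT
#'
#' @param sets Named list `pathway -> character vector of members`.
#' @param path Output path.
#' @param description Optional named descriptions (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- description[[nm]] %||% "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
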